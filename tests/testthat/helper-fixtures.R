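# Shared fixtures, all built in code.

make_scheme <- function(nf = 4, nr = 4, n_samples = nf * nr,
                        seed_f = 101, seed_r = 202, prefix = "S") {
  barcode_scheme(design_barcodes(nf, seed = seed_f),
                 design_barcodes(nr, seed = seed_r),
                 sample_ids = sprintf("%s%03d", prefix, seq_len(n_samples)))
}

# A small complete study: library, scheme, truth, reads.
make_small_sim <- function(n_plants = 30, depth = 100, error_rate = 0,
                           chimera_rate = 0, seed = 7, n_genes = 5) {
  lib <- simulate_library(n_genes = n_genes, sgrnas_per_gene = 2, seed = seed)
  k <- ceiling(sqrt(n_plants))
  scheme <- make_scheme(k, ceiling(n_plants / k), n_samples = n_plants,
                        prefix = "T0_")
  cfg <- sim_config(n_plants = n_plants, depth = depth, error_rate = error_rate,
                    chimera_rate = chimera_rate, seed = seed)
  truth <- simulate_t0(cfg, lib$library, lib$amplicons, scheme)
  reads <- synthesize_reads(truth, lib$library, lib$amplicons, scheme)
  list(lib = lib, scheme = scheme, cfg = cfg, truth = truth, reads = reads)
}

# Build a minimal edit_profile carrying an editing frequency (and optional
# event table) without going through reads.
stub_profile <- function(freq, plant = "p", target = "t", events = NULL) {
  if (is.null(events)) {
    events <- data.frame(kind = character(0), start = integer(0),
                         length = integer(0), alt_seq = character(0),
                         read_count = integer(0), frequency = numeric(0),
                         notation = character(0), stringsAsFactors = FALSE)
  }
  structure(list(plant_id = plant, target_id = target, total_reads = 1000L,
                 n_unalignable = 0L, events = events,
                 edited_reads = as.integer(round(freq * 1000)),
                 editing_frequency = freq,
                 status = if (freq > 0.01) "edited" else "non-edited",
                 putative_homozygous = FALSE),
            class = "edit_profile")
}

event_df <- function(kind, start, length, alt_seq = "") {
  data.frame(kind = kind, start = as.integer(start), length = as.integer(length),
             alt_seq = alt_seq, stringsAsFactors = FALSE)
}
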