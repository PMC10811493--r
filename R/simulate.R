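## Truth-tracked amplicon read simulator.
##
## Emulates pooled-transformation genotyping data: each plant carries
## 0..4 sgRNAs (cohort multiplicities follow the genotyped T0 population),
## its target amplicons carry a mixture of indel/substitution alleles
## around the cut site, and reads are flanked by 9-nt dual barcodes with
## optional per-base substitution error and barcode chimerism.

#' First 12 nt of the invariant sgRNA scaffold, used as the protospacer
#' extraction anchor in cassette reads.
#' @export
SGRNA_SCAFFOLD_ANCHOR <- "GTTTTAGAGCTA"

SGRNA_SCAFFOLD <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCG"
CASSETTE_PAD5 <- "TGTGGAAAGGACGAAACACCG"  # promoter-side invariant context
CASSETTE_PAD3 <- "TTTTTTTGCACCGACTCGGTG"  # terminator-side invariant context

#' Simulation configuration
#'
#' Defaults mirror the genotyped T0 cohort: per-plant sgRNA multiplicity
#' probabilities over 0/1/2/3/>3 guides (21.81/73.55/4.20/0.29/0.14%),
#' editing-outcome kind mixture (deletions 77.66%, insertions 17.90%,
#' substitutions 4.44%), short indel lengths (geometric deletions on
#' 1..30 bp, insertions dominated by +1, substitution runs of 1-4 bp).
#' Probability vectors may carry printed-rounding slack (up to 1e-3) and
#' are renormalised to sum to 1.
#'
#' @param n_plants Number of T0 plants.
#' @param sgrna_multiplicity_probs Probabilities over 0,1,2,3,4 sgRNAs per
#'   plant (the ">3" class is simulated as exactly 4).
#' @param edit_kind_probs Probabilities over deletion/insertion/substitution.
#' @param del_len_geom_p Geometric parameter for deletion lengths
#'   (truncated to 1..30 bp).
#' @param ins_len_p1 Probability of a 1-bp insertion; the remainder follows
#'   a geometric tail over 2..10 bp.
#' @param sub_len_max Substitution run lengths are uniform on 1..`sub_len_max`.
#' @param editing_freq_mix Mixture over per-plant edited-read fractions:
#'   list of `weights`, `lower`, `upper` (uniform components).
#' @param events_per_plant_probs Probabilities over 1..10 editing events
#'   per plant and target.
#' @param depth Reads per plant per amplicon.
#' @param error_rate Per-base substitution error probability (`< 0.1`).
#' @param chimera_rate Probability a read's barcode pair is swapped with
#'   another plant's.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plants = 1380L,
                       sgrna_multiplicity_probs = c(`0` = 0.2181, `1` = 0.7355,
                                                    `2` = 0.0420, `3` = 0.0029,
                                                    `4` = 0.0014),
                       edit_kind_probs = c(deletion = 0.7766,
                                           insertion = 0.1790,
                                           substitution = 0.0444),
                       del_len_geom_p = 0.55,
                       ins_len_p1 = 0.9,
                       sub_len_max = 4L,
                       editing_freq_mix = list(weights = c(0.7561, 0.2168, 0.0271),
                                               lower = c(0.80, 0.01, 0.001),
                                               upper = c(1.00, 0.80, 0.010)),
                       events_per_plant_probs = c(0.1300, 0.3902,
                                                  rep(0.4093 / 7, 7), 0.0705),
                       depth = 500L, error_rate = 0.001, chimera_rate = 0,
                       seed = 1L) {
  norm_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-3) {
      stop(sprintf("%s must sum to 1 (got %.6f)", what, sum(p)), call. = FALSE)
    }
    p / sum(p)
  }
  stopifnot(depth >= 1, error_rate >= 0, error_rate < 0.1,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(
    n_plants = as.integer(n_plants),
    sgrna_multiplicity_probs = norm_probs(sgrna_multiplicity_probs,
                                          "sgrna_multiplicity_probs"),
    edit_kind_probs = norm_probs(edit_kind_probs, "edit_kind_probs"),
    del_len_geom_p = del_len_geom_p,
    ins_len_p1 = ins_len_p1,
    sub_len_max = as.integer(sub_len_max),
    editing_freq_mix = editing_freq_mix,
    events_per_plant_probs = norm_probs(events_per_plant_probs,
                                        "events_per_plant_probs"),
    depth = as.integer(depth), error_rate = error_rate,
    chimera_rate = chimera_rate, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a small sgRNA library with per-gene amplicons
#'
#' Generates one random genotyping amplicon per gene, enumerates NGG sites
#' on it, and picks guides whose cut sites leave room for the editing
#' window and primer regions. Protospacers are unique across the library
#' so that exact 20-mer identification is unambiguous.
#'
#' @param n_genes Number of genes.
#' @param sgrnas_per_gene Guides per gene.
#' @param amplicon_len Amplicon length (bp, at most 280).
#' @param margin Distance (bp) a cut site must keep from amplicon ends.
#' @param seed Integer RNG seed.
#' @return List with `amplicons` (named character vector, one per gene)
#'   and `library` (sgRNA manifest data.frame).
#' @export
simulate_library <- function(n_genes = 20L, sgrnas_per_gene = 2L,
                             amplicon_len = 240L, margin = 60L, seed = 1L) {
  stopifnot(amplicon_len <= 280L, amplicon_len > 2 * margin)
  with_seed(seed, {
    amplicons <- character(0)
    rows <- list()
    seen <- character(0)
    g <- 0L
    while (g < n_genes) {
      amp <- random_dna(1, amplicon_len)
      gene <- sprintf("gene%03d", g + 1L)
      sites <- enumerate_sites(setNames(amp, gene))
      ok <- sites$cut_offset >= margin & sites$cut_offset <= amplicon_len - margin &
        !(sites$protospacer %in% seen) & !duplicated(sites$protospacer)
      sites <- sites[ok, , drop = FALSE]
      if (nrow(sites) < sgrnas_per_gene) next
      pick <- sites[sample.int(nrow(sites), sgrnas_per_gene), , drop = FALSE]
      pick$sgrna_id <- sprintf("%s_g%d", gene, seq_len(sgrnas_per_gene))
      pick$gene_id <- gene
      seen <- c(seen, pick$protospacer)
      amplicons[gene] <- amp
      rows[[gene]] <- pick
      g <- g + 1L
    }
    lib <- do.call(rbind, rows)
    rownames(lib) <- NULL
    list(amplicons = amplicons, library = lib)
  })
}

# Draw one editing event on an amplicon; interval overlaps
# [cut_offset - 5, cut_offset + 5] after left-normalization.
random_edit_event <- function(amplicon, cut_offset, config, margin = 25L,
                              exclude_keys = character(0), max_tries = 100L) {
  len_amp <- nchar(amplicon)
  ref_chars <- strsplit(amplicon, "", fixed = TRUE)[[1]]
  for (try in seq_len(max_tries)) {
    kind <- draw_discrete(1, names(config$edit_kind_probs), config$edit_kind_probs)
    if (kind == "deletion") {
      L <- draw_discrete(1, 1:30, stats::dgeom(0:29, config$del_len_geom_p))
    } else if (kind == "insertion") {
      tail_p <- stats::dgeom(0:8, 0.5)
      L <- draw_discrete(1, 1:10, c(config$ins_len_p1,
                                    (1 - config$ins_len_p1) * tail_p / sum(tail_p)))
    } else {
      L <- sample.int(config$sub_len_max, 1)
    }
    if (kind == "insertion") {
      lo <- max(cut_offset - 5L, margin)
      hi <- min(cut_offset + 5L, len_amp - margin)
    } else {
      lo <- max(cut_offset - 5L - L + 1L, margin)
      hi <- min(cut_offset + 5L, len_amp - margin - L)
    }
    if (lo > hi) next
    start <- sample(lo:hi, 1)
    if (kind == "deletion") {
      start <- left_align_deletion(ref_chars, start, L)$start
      alt <- ""
    } else if (kind == "insertion") {
      ins <- sample(DNA_BASES, L, replace = TRUE)
      nrm <- left_align_insertion(ref_chars, start, ins)
      start <- nrm$start
      alt <- paste(nrm$alt, collapse = "")
    } else {
      alt <- paste(vapply((start + 1L):(start + L), function(i)
        sample(setdiff(DNA_BASES, ref_chars[i]), 1), character(1)), collapse = "")
    }
    ev <- data.frame(kind = kind, start = start, length = L, alt_seq = alt,
                     stringsAsFactors = FALSE)
    # keep only events still overlapping the cut window after normalization
    if (!event_overlaps_window(ev$kind, ev$start, ev$length,
                               cut_offset - 5L, cut_offset + 5L)) next
    if (event_key(ev) %in% exclude_keys) next
    return(ev)
  }
  stop("could not place an editing event after ", max_tries, " tries", call. = FALSE)
}

draw_editing_freq <- function(mix) {
  i <- draw_discrete(1, seq_along(mix$weights), mix$weights)
  runif(1, mix$lower[i], mix$upper[i])
}

#' Simulate ground truth for a T0 cohort
#'
#' Draws per-plant sgRNA multiplicities, assigns guides from the library,
#' and generates editing events with intended allele frequencies per
#' plant x target. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param library sgRNA manifest (from [simulate_library()] or
#'   [design_library()]; only rows with 20-nt protospacers are used).
#' @param amplicons Named character vector of per-gene amplicons.
#' @param scheme A [barcode_scheme()]; if its sample map is empty, one is
#'   built for the cohort. Capacity must cover `n_plants`.
#' @return A `crispr_truth` list: `generation`, `plants`, `targets`
#'   (per plant x sgRNA editing frequency), `events` (true events with
#'   intended allele frequencies) and the echoed `config`.
#' @export
simulate_t0 <- function(config, library, amplicons, scheme) {
  n <- config$n_plants
  nf <- length(scheme$forward); nr <- length(scheme$reverse)
  if (n > nf * nr) {
    stop(sprintf("capacity exceeded: %d plants > %d barcode pairs", n, nf * nr),
         call. = FALSE)
  }
  if (nrow(scheme$sample_map) == 0L) {
    scheme$sample_map <- build_sample_sheet(scheme, sprintf("T0_%04d", seq_len(n)))
  }
  if (nrow(scheme$sample_map) < n) {
    stop("sample sheet has fewer slots than plants", call. = FALSE)
  }
  with_seed(config$seed, {
    plant_id <- as.character(scheme$sample_map$sample_id[seq_len(n)])
    mult <- as.integer(draw_discrete(n, names(config$sgrna_multiplicity_probs),
                                     config$sgrna_multiplicity_probs))
    targets <- list(); events <- list()
    sgrna_ids <- character(n)
    for (i in seq_len(n)) {
      if (mult[i] == 0L) next
      rows <- library[sample.int(nrow(library), mult[i]), , drop = FALSE]
      sgrna_ids[i] <- paste(rows$sgrna_id, collapse = ",")
      for (j in seq_len(nrow(rows))) {
        sg <- rows[j, ]
        amp <- amplicons[[sg$ref_id]]
        k <- draw_discrete(1, 1:10, config$events_per_plant_probs)
        f <- draw_editing_freq(config$editing_freq_mix)
        keys <- character(0)
        evs <- list()
        for (e in seq_len(k)) {
          ev <- random_edit_event(amp, sg$cut_offset, config, exclude_keys = keys)
          keys <- c(keys, event_key(ev))
          evs[[e]] <- ev
        }
        evs <- do.call(rbind, evs)
        w <- runif(k)
        evs$freq <- w / sum(w) * f
        evs$plant_id <- plant_id[i]
        evs$sgrna_id <- sg$sgrna_id
        events[[length(events) + 1L]] <- evs
        targets[[length(targets) + 1L]] <- data.frame(
          plant_id = plant_id[i], sgrna_id = sg$sgrna_id, ref_id = sg$ref_id,
          editing_frequency = f, stringsAsFactors = FALSE)
      }
    }
    plants <- data.frame(
      plant_id = plant_id, generation = "T0", line_id = plant_id,
      fwd_index = scheme$sample_map$fwd_index[seq_len(n)],
      rev_index = scheme$sample_map$rev_index[seq_len(n)],
      n_sgrnas = mult, sgrna_ids = sgrna_ids, stringsAsFactors = FALSE)
    structure(list(
      generation = "T0", plants = plants,
      targets = if (length(targets)) do.call(rbind, targets) else
        data.frame(plant_id = character(0), sgrna_id = character(0),
                   ref_id = character(0), editing_frequency = numeric(0)),
      events = if (length(events)) do.call(rbind, events) else NULL,
      config = config), class = "crispr_truth")
  })
}

# Introduce per-base substitution errors into reads.
apply_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Synthesize barcoded amplicon reads from a truth table
#'
#' Every plant with at least one sgRNA emits `depth` cassette-amplicon
#' reads (carrying one of its protospacers followed by the invariant
#' scaffold) and `depth` target-amplicon reads per assigned guide, each
#' read flanked by its sample's forward barcode (5') and the reverse
#' complement of its reverse barcode (3'). Target alleles are drawn
#' multinomially at the true frequencies; per-base substitution errors are
#' applied after allele construction, and with probability `chimera_rate`
#' a read's barcode pair is swapped for another plant's. Deterministic
#' (byte-identical FASTQ) given the seed.
#'
#' @param truth A `crispr_truth` from [simulate_t0()] / [simulate_t1()].
#' @param library sgRNA manifest.
#' @param amplicons Named character vector of amplicons.
#' @param scheme The [barcode_scheme()] used for the cohort.
#' @param depth,error_rate,chimera_rate,seed Override the truth's config.
#' @param dir Optional output directory; when given, writes
#'   `cassette.fastq`, `targets.fastq`, truth TSVs and a flat key-value
#'   config echo.
#' @return A `sim_reads` list: `cassette` and `target` read tables
#'   (`read_id`, `seq`), `read_truth` (per-read provenance: true plant,
#'   read type, sgRNA, allele, chimeric flag, barcode plant), and
#'   `realized` (per event: realized read count and depth).
#' @export
synthesize_reads <- function(truth, library, amplicons, scheme,
                             depth = truth$config$depth,
                             error_rate = truth$config$error_rate,
                             chimera_rate = truth$config$chimera_rate,
                             seed = truth$config$seed + 1L, dir = NULL) {
  plants <- truth$plants
  if (anyNA(plants$fwd_index) || anyNA(plants$rev_index)) {
    stop("every plant in truth needs a sample-sheet slot", call. = FALSE)
  }
  lib_idx <- setNames(seq_len(nrow(library)), library$sgrna_id)
  with_seed(seed, {
    ev_by_plant <- if (!is.null(truth$events)) {
      split(truth$events, truth$events$plant_id)
    } else list()
    body_l <- list(); plant_l <- list(); type_l <- list()
    sg_l <- list(); allele_l <- list()
    realized <- list()
    push <- function(env, body, pid, type, sg, allele) {
      k <- length(env$body_l) + 1L
      env$body_l[[k]] <- body
      env$plant_l[[k]] <- rep(pid, length(body))
      env$type_l[[k]] <- rep(type, length(body))
      env$sg_l[[k]] <- sg
      env$allele_l[[k]] <- allele
    }
    env <- environment()
    for (i in seq_len(nrow(plants))) {
      pid <- plants$plant_id[i]
      if (plants$n_sgrnas[i] == 0L) next
      sgs <- strsplit(plants$sgrna_ids[i], ",", fixed = TRUE)[[1]]
      # cassette reads: each read shows one of the plant's guides
      counts <- as.integer(rmultinom(1, depth, rep(1, length(sgs))))
      cass <- paste0(CASSETTE_PAD5, library$protospacer[lib_idx[sgs]],
                     SGRNA_SCAFFOLD, CASSETTE_PAD3)
      push(env, rep(cass, counts), pid, "cassette", rep(sgs, counts),
           rep("cassette", depth))
      # target reads per assigned guide
      pl_ev <- ev_by_plant[[pid]]
      for (sg in sgs) {
        amp <- amplicons[[library$ref_id[lib_idx[sg]]]]
        ev <- if (is.null(pl_ev)) {
          data.frame(kind = character(0), start = integer(0),
                     length = integer(0), alt_seq = character(0),
                     freq = numeric(0), plant_id = character(0),
                     sgrna_id = character(0), stringsAsFactors = FALSE)
        } else pl_ev[pl_ev$sgrna_id == sg, , drop = FALSE]
        probs <- c(ev$freq, max(0, 1 - sum(ev$freq)))
        acounts <- as.integer(rmultinom(1, depth, probs))
        alleles <- c(vapply(seq_len(nrow(ev)), function(j)
          apply_event(amp, ev$kind[j], ev$start[j], ev$length[j], ev$alt_seq[j]),
          character(1)), amp)
        labels <- c(event_key(ev), "ref")
        push(env, rep(alleles, acounts), pid, "target", rep(sg, depth),
             rep(labels, acounts))
        if (nrow(ev)) {
          realized[[length(realized) + 1L]] <- cbind(
            ev[, c("plant_id", "sgrna_id", "kind", "start", "length",
                   "alt_seq", "freq")],
            count = acounts[seq_len(nrow(ev))], depth = depth)
        }
      }
    }
    body <- unlist(body_l, use.names = FALSE)
    plant_of <- unlist(plant_l, use.names = FALSE)
    rtype <- unlist(type_l, use.names = FALSE)
    sg_of <- unlist(sg_l, use.names = FALSE)
    allele <- unlist(allele_l, use.names = FALSE)
    if (is.null(body)) body <- character(0)
    n_reads <- length(body)
    bc_plant <- plant_of
    chimeric <- rep(FALSE, n_reads)
    if (chimera_rate > 0 && nrow(plants) > 1L) {
      swap <- which(runif(n_reads) < chimera_rate)
      chimeric[swap] <- TRUE
      for (k in swap) {
        bc_plant[k] <- sample(setdiff(plants$plant_id, plant_of[k]), 1)
      }
    }
    pi <- match(bc_plant, plants$plant_id)
    reads <- paste0(scheme$forward[plants$fwd_index[pi]], body,
                    revcomp(scheme$reverse[plants$rev_index[pi]]))
    reads <- apply_seq_errors(reads, error_rate)
    read_id <- sprintf("read%07d", seq_len(n_reads))
    read_truth <- data.frame(read_id = read_id, plant_id = plant_of,
                             read_type = rtype, sgrna_id = sg_of,
                             allele = allele, chimeric = chimeric,
                             barcode_plant = bc_plant, stringsAsFactors = FALSE)
    out <- list(
      cassette = data.frame(read_id = read_id[rtype == "cassette"],
                            seq = reads[rtype == "cassette"],
                            stringsAsFactors = FALSE),
      target = data.frame(read_id = read_id[rtype == "target"],
                          seq = reads[rtype == "target"],
                          stringsAsFactors = FALSE),
      read_truth = read_truth,
      realized = if (length(realized)) do.call(rbind, realized) else NULL,
      depth = depth)
    class(out) <- "sim_reads"
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_fastq(out$cassette$read_id, out$cassette$seq,
                  file.path(dir, "cassette.fastq"))
      write_fastq(out$target$read_id, out$target$seq,
                  file.path(dir, "targets.fastq"))
      write_tsv(read_truth, file.path(dir, "read_truth.tsv"))
      write_tsv(truth$plants, file.path(dir, "plants.tsv"))
      if (!is.null(truth$events)) write_tsv(truth$events, file.path(dir, "events.tsv"))
      cfg <- truth$config
      flat <- c(list(depth = depth, error_rate = error_rate,
                     chimera_rate = chimera_rate, seed = seed),
                cfg[vapply(cfg, function(v) is.numeric(v) && length(v) == 1L,
                           logical(1))])
      writeLines(sprintf("%s: %s", names(flat), unlist(flat)),
                 file.path(dir, "config.yaml"))
    }
    out
  })
}

#' Simulate a T1 progeny generation from a T0 truth table
#'
#' Each selected T0 line contributes `n_progeny_per_line` progeny. Every
#' T0 event is transmitted to each progeny independently with probability
#' `inherit_prob`, keeping its identity (kind, position, length, sequence)
#' unchanged; with probability `novel_rate` a progeny additionally gains
#' one novel event (continued Cas9 activity) on one of its parent's
#' targets. Per-target editing frequencies are redrawn high (0.8-1):
#' editing consolidates in progeny.
#'
#' @param truth_t0 T0 `crispr_truth`.
#' @param library,amplicons As in [simulate_t0()].
#' @param n_progeny_per_line Progeny assayed per line.
#' @param inherit_prob Per-event transmission probability.
#' @param novel_rate Per-progeny probability of one novel event.
#' @param seed Integer RNG seed.
#' @param lines T0 plant ids to propagate; defaults to all plants with at
#'   least one true event.
#' @param scheme Optional [barcode_scheme()] for the T1 cohort (needed to
#'   synthesize reads); slots are assigned in order.
#' @return A `crispr_truth` with `generation = "T1"`; `line_id` points at
#'   the T0 parent.
#' @export
simulate_t1 <- function(truth_t0, library, amplicons, n_progeny_per_line = 3L,
                        inherit_prob = 0.8478, novel_rate = 0.0836,
                        seed = truth_t0$config$seed + 2L, lines = NULL,
                        scheme = NULL) {
  stopifnot(inherit_prob >= 0, inherit_prob <= 1, novel_rate >= 0, novel_rate <= 1)
  if (is.null(lines)) lines <- unique(truth_t0$events$plant_id)
  with_seed(seed, {
    plants <- list(); targets <- list(); events <- list()
    for (line in lines) {
      par_ev <- truth_t0$events[truth_t0$events$plant_id == line, , drop = FALSE]
      par_tg <- truth_t0$targets[truth_t0$targets$plant_id == line, , drop = FALSE]
      for (j in seq_len(n_progeny_per_line)) {
        pid <- sprintf("%s_T1_%d", line, j)
        inh <- par_ev[runif(nrow(par_ev)) < inherit_prob, , drop = FALSE]
        nov <- NULL
        if (runif(1) < novel_rate && nrow(par_tg)) {
          tg <- par_tg[sample.int(nrow(par_tg), 1), ]
          sg <- library[library$sgrna_id == tg$sgrna_id, ]
          nov <- random_edit_event(
            amplicons[[sg$ref_id]], sg$cut_offset, truth_t0$config,
            exclude_keys = event_key(par_ev[par_ev$sgrna_id == tg$sgrna_id, ,
                                            drop = FALSE]))
          nov$plant_id <- pid
          nov$sgrna_id <- tg$sgrna_id
        }
        sg_list <- character(0)
        for (t in seq_len(nrow(par_tg))) {
          sg <- par_tg$sgrna_id[t]
          core <- c("kind", "start", "length", "alt_seq", "plant_id", "sgrna_id")
          evs <- inh[inh$sgrna_id == sg, core, drop = FALSE]
          if (!is.null(nov) && nov$sgrna_id == sg) {
            evs <- rbind(evs, nov[, core])
          }
          evs$plant_id <- rep(pid, nrow(evs))
          k <- nrow(evs)
          f1 <- if (k > 0L) runif(1, 0.8, 1) else 0
          if (k > 0L) {
            w <- runif(k)
            evs$freq <- w / sum(w) * f1
            events[[length(events) + 1L]] <- evs
          }
          sg_list <- c(sg_list, sg)
          targets[[length(targets) + 1L]] <- data.frame(
            plant_id = pid, sgrna_id = sg, ref_id = par_tg$ref_id[t],
            editing_frequency = f1, stringsAsFactors = FALSE)
        }
        plants[[length(plants) + 1L]] <- data.frame(
          plant_id = pid, generation = "T1", line_id = line,
          fwd_index = NA_integer_, rev_index = NA_integer_,
          n_sgrnas = length(sg_list),
          sgrna_ids = paste(sg_list, collapse = ","), stringsAsFactors = FALSE)
      }
    }
    plants <- do.call(rbind, plants)
    if (!is.null(scheme)) {
      if (nrow(scheme$sample_map) == 0L) {
        scheme$sample_map <- build_sample_sheet(scheme, plants$plant_id)
      }
      slot <- match(plants$plant_id, scheme$sample_map$sample_id)
      if (anyNA(slot)) stop("T1 scheme sample map does not cover all progeny",
                            call. = FALSE)
      plants$fwd_index <- scheme$sample_map$fwd_index[slot]
      plants$rev_index <- scheme$sample_map$rev_index[slot]
    }
    structure(list(
      generation = "T1", plants = plants,
      targets = do.call(rbind, targets),
      events = if (length(events)) do.call(rbind, events) else NULL,
      config = truth_t0$config), class = "crispr_truth")
  })
}

#' Build editing profiles directly from a truth table
#'
#' Converts the simulator's ground truth into `edit_profile` objects (one
#' per plant x target) so that inheritance statistics can be computed on
#' truth without read synthesis.
#'
#' @param truth A `crispr_truth`.
#' @return Named list of `edit_profile`s, keyed `plant_id|sgrna_id`.
#' @export
truth_profiles <- function(truth) {
  out <- list()
  for (t in seq_len(nrow(truth$targets))) {
    pid <- truth$targets$plant_id[t]
    sg <- truth$targets$sgrna_id[t]
    ev <- truth$events[truth$events$plant_id == pid &
                         truth$events$sgrna_id == sg, , drop = FALSE]
    ev <- ev[, c("kind", "start", "length", "alt_seq", "freq"), drop = FALSE]
    names(ev)[names(ev) == "freq"] <- "frequency"
    ev$read_count <- rep(NA_integer_, nrow(ev))
    ev$notation <- if (nrow(ev)) format_notation(ev) else character(0)
    rownames(ev) <- NULL
    prof <- new_edit_profile(pid, sg, total_reads = 0L, n_unalignable = 0L,
                             events = ev, edited_reads = 0L)
    prof$editing_frequency <- truth$targets$editing_frequency[t]
    prof$status <- if (prof$editing_frequency > 0.01) "edited" else "non-edited"
    out[[paste(pid, sg, sep = "|")]] <- prof
  }
  out
}
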