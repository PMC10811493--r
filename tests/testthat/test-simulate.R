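test_that("config probability vectors are validated and normalised", {
  cfg <- sim_config()
  expect_equal(sum(cfg$sgrna_multiplicity_probs), 1, tolerance = 1e-9)
  expect_equal(sum(cfg$edit_kind_probs), 1, tolerance = 1e-9)
  expect_equal(sum(cfg$events_per_plant_probs), 1, tolerance = 1e-9)
  expect_error(sim_config(edit_kind_probs = c(deletion = 0.5, insertion = 0.1,
                                              substitution = 0.1)), "sum to 1")
  expect_error(sim_config(error_rate = 0.2))
})

test_that("cohort multiplicities follow the configured class probabilities", {
  lib <- simulate_library(n_genes = 10, sgrnas_per_gene = 2, seed = 2)
  scheme <- make_scheme(38, 37, n_samples = 1380, prefix = "T0_")
  cfg <- sim_config(n_plants = 1380, seed = 41)
  truth <- simulate_t0(cfg, lib$library, lib$amplicons, scheme)
  frac <- as.numeric(table(factor(truth$plants$n_sgrnas, levels = 0:4)) / 1380)
  want <- c(0.2181, 0.7355, 0.0420, 0.0029, 0.0014)
  expect_true(all(abs(frac - want) <= 0.015))  # binomial 95% envelope at n=1380

  # degenerate settings pin the draw
  cfg1 <- sim_config(n_plants = 50, sgrna_multiplicity_probs = c(`1` = 1),
                     seed = 4)
  t1 <- simulate_t0(cfg1, lib$library, lib$amplicons, scheme)
  expect_true(all(t1$plants$n_sgrnas == 1L))
  cfg2 <- sim_config(n_plants = 30, sgrna_multiplicity_probs = c(`1` = 1),
                     edit_kind_probs = c(deletion = 1, insertion = 0,
                                         substitution = 0), seed = 5)
  t2 <- simulate_t0(cfg2, lib$library, lib$amplicons, scheme)
  expect_true(all(t2$events$kind == "deletion"))

  # capacity guard
  tiny <- make_scheme(2, 2)
  expect_error(simulate_t0(sim_config(n_plants = 5), lib$library,
                           lib$amplicons, tiny), "capacity")
})

test_that("true events sit in the cut window with frequencies summing below 1", {
  sim <- make_small_sim(n_plants = 40, depth = 50, seed = 31)
  ev <- sim$truth$events
  lib <- sim$lib$library
  cut <- lib$cut_offset[match(ev$sgrna_id, lib$sgrna_id)]
  expect_true(all(poolcrispr:::event_overlaps_window(ev$kind, ev$start,
                                                     ev$length, cut - 5L,
                                                     cut + 5L)))
  by_target <- tapply(ev$freq, paste(ev$plant_id, ev$sgrna_id), sum)
  expect_true(all(by_target <= 1 + 1e-9))
})

test_that("read synthesis conserves counts and is byte-deterministic", {
  sim <- make_small_sim(n_plants = 15, depth = 60, seed = 19)
  plants <- sim$truth$plants
  expected <- sum((plants$n_sgrnas > 0) * (1 + plants$n_sgrnas)) * 60
  expect_equal(nrow(sim$reads$cassette) + nrow(sim$reads$target), expected)
  # per plant per amplicon exactly depth reads
  rt <- sim$reads$read_truth
  cass <- table(rt$plant_id[rt$read_type == "cassette"])
  expect_true(all(cass == 60))
  tgt <- table(paste(rt$plant_id, rt$sgrna_id)[rt$read_type == "target"])
  expect_true(all(tgt == 60))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  synthesize_reads(sim$truth, sim$lib$library, sim$lib$amplicons, sim$scheme,
                   dir = d1)
  synthesize_reads(sim$truth, sim$lib$library, sim$lib$amplicons, sim$scheme,
                   dir = d2)
  for (f in c("cassette.fastq", "targets.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # FASTQ round-trips through the reader
  back <- read_fastq(file.path(d1, "cassette.fastq"))
  expect_equal(back$seq, sim$reads$cassette$seq)
})

test_that("an allele at frequency 1 edits every read", {
  lib <- simulate_library(n_genes = 1, sgrnas_per_gene = 1, seed = 8)
  scheme <- make_scheme(2, 2, n_samples = 1, prefix = "T0_")
  cfg <- sim_config(n_plants = 1, depth = 200, error_rate = 0,
                    sgrna_multiplicity_probs = c(`1` = 1),
                    events_per_plant_probs = c(1, rep(0, 9)),
                    editing_freq_mix = list(weights = 1, lower = 1, upper = 1),
                    seed = 44)
  truth <- simulate_t0(cfg, lib$library, lib$amplicons, scheme)
  reads <- synthesize_reads(truth, lib$library, lib$amplicons, scheme)
  expect_equal(reads$realized$count, 200L)
  sg <- lib$library[1, ]
  prof <- call_target(demultiplex(reads$target, scheme)$reads_by_sample[[1]],
                      lib$amplicons[[sg$ref_id]], sg$cut_offset)
  expect_equal(prof$editing_frequency, 1)
  expect_equal(prof$status, "edited")
})

test_that("T1 inheritance is exact at the probability extremes", {
  sim <- make_small_sim(n_plants = 20, depth = 50, seed = 51)
  keyset <- function(tr) {
    if (is.null(tr$events)) return(character(0))
    sort(paste(tr$events$sgrna_id, poolcrispr:::event_key(tr$events)))
  }
  t1_all <- simulate_t1(sim$truth, sim$lib$library, sim$lib$amplicons,
                        n_progeny_per_line = 2, inherit_prob = 1,
                        novel_rate = 0, seed = 52)
  for (pid in unique(t1_all$plants$plant_id)) {
    parent <- t1_all$plants$line_id[t1_all$plants$plant_id == pid][1]
    pe <- sim$truth$events[sim$truth$events$plant_id == parent, ]
    ce <- t1_all$events[t1_all$events$plant_id == pid, ]
    expect_equal(sort(paste(ce$sgrna_id, poolcrispr:::event_key(ce))),
                 sort(paste(pe$sgrna_id, poolcrispr:::event_key(pe))))
  }
  t1_none <- simulate_t1(sim$truth, sim$lib$library, sim$lib$amplicons,
                         n_progeny_per_line = 2, inherit_prob = 0,
                         novel_rate = 0, seed = 53)
  expect_null(t1_none$events)
})

test_that("heritability and novel-edit rates are recovered from truth", {
  # full-rate check lives in the acceptance suite; here a single fast seed
  sim <- make_small_sim(n_plants = 60, depth = 50, seed = 61)
  t1 <- simulate_t1(sim$truth, sim$lib$library, sim$lib$amplicons,
                    n_progeny_per_line = 3, inherit_prob = 0.8478,
                    novel_rate = 0.0836, seed = 62)
  p0 <- truth_profiles(sim$truth)
  p1 <- truth_profiles(t1)
  ped <- unique(data.frame(t1_plant_id = t1$plants$plant_id,
                           t0_line_id = t1$plants$line_id))
  cmp <- compare_generations(p0, p1, ped)
  n <- nrow(cmp$per_plant)
  expect_equal(n, nrow(t1$plants))
  expect_lt(abs(cmp$cohort$mean_heritability_pct - 84.78), 15)  # coarse, n small
  expect_true(cmp$cohort$novel_pct >= 0 && cmp$cohort$novel_pct <= 100)
})
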