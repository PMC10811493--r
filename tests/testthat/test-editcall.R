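# reference amplicon printed for the single-site mutant line in the study
FIG_AMP <- "GGTGAAGATTTCTTTCCTCGGAACGGGAGATGGAATTTTA"

test_that("alignment of identical sequences yields no events", {
  a <- align_read(FIG_AMP, FIG_AMP)
  expect_equal(nrow(a$events), 0L)
  expect_equal(a$identity, 1)
  expect_error(align_read("ACGU", "ACGT"), "non-ACGTN")
  expect_error(align_read("", "ACGT"))
})

test_that("single deletions and homopolymer insertions are left-aligned", {
  # deleting one base near the cut region gives exactly one -1 call
  for (pos0 in 15:25) {
    rd <- paste0(substr(FIG_AMP, 1, pos0), substring(FIG_AMP, pos0 + 2))
    ev <- align_read(rd, FIG_AMP)$events
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$kind, "deletion")
    expect_equal(ev$length, 1L)
    # placement agrees with the leftmost placement among ALL optimal
    # alignments, enumerated exhaustively
    paths <- nw_enumerate(rd, FIG_AMP)
    evs <- lapply(paths, function(p) oracle_events(p$pattern, p$subject))
    singles <- evs[vapply(evs, nrow, 1L) == 1]
    starts <- vapply(singles, function(e) e$start, numeric(1))
    expect_equal(ev$start, min(starts))
  }

  # inserting T anywhere inside the TTT run at offsets 12-14 reports the
  # insertion at the leftmost position of the run (gap offset 12)
  for (at in 12:15) {
    rd <- paste0(substr(FIG_AMP, 1, at), "T", substring(FIG_AMP, at + 1))
    ev <- align_read(rd, FIG_AMP)$events
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$kind, "insertion")
    expect_equal(ev$start, 12L)
    expect_equal(ev$alt_seq, "T")
  }
})

test_that("contiguous mismatches form one maximal substitution run", {
  ch <- strsplit(FIG_AMP, "")[[1]]
  ch[21] <- setdiff(c("A", "C", "G", "T"), ch[21])[1]
  ch[22] <- setdiff(c("A", "C", "G", "T"), ch[22])[1]
  ev <- align_read(paste(ch, collapse = ""), FIG_AMP)$events
  expect_equal(nrow(ev), 1L)  # one "/2", not two "/1"
  expect_equal(ev$kind, "substitution")
  expect_equal(ev$length, 2L)
  expect_equal(ev$start, 20L)
  expect_equal(format_notation(ev), "/2")
})

test_that("event calls agree with exhaustive co-optimal enumeration", {
  set.seed(99)
  for (rep in 1:30) {
    ref <- paste(sample(c("A", "C", "G", "T"), sample(20:30, 1), replace = TRUE),
                 collapse = "")
    kind <- sample(c("deletion", "insertion", "substitution"), 1)
    L <- sample(1:3, 1)
    pos <- sample(3:(nchar(ref) - 5), 1)
    rd <- switch(kind,
      deletion = paste0(substr(ref, 1, pos), substring(ref, pos + L + 1)),
      insertion = paste0(substr(ref, 1, pos),
                         paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                               collapse = ""),
                         substring(ref, pos + 1)),
      substitution = paste0(substr(ref, 1, pos),
                            chartr("ACGT", "TGCA", substr(ref, pos + 1, pos + L)),
                            substring(ref, pos + L + 1)))
    if (rd == ref) next
    a <- align_read(rd, ref)
    paths <- nw_enumerate(rd, ref)
    expect_equal(a$score, paths[[1]]$score)
    evs <- lapply(paths, function(p) oracle_events(p$pattern, p$subject))
    singles <- evs[vapply(evs, nrow, 1L) == 1]
    if (length(singles) && nrow(a$events) == 1) {
      starts <- vapply(singles, function(e) e$start, numeric(1))
      left <- singles[[which.min(starts)]]
      expect_equal(a$events$kind, left$kind)
      expect_equal(a$events$start, left$start)
      expect_equal(a$events$length, left$length)
      expect_equal(a$events$alt_seq, left$alt_seq)
    }
  }
})

test_that("re-aligning a reconstructed allele reproduces the event exactly", {
  lib <- simulate_library(n_genes = 2, sgrnas_per_gene = 1, seed = 17)
  cfg <- sim_config(seed = 17)
  sg <- lib$library[1, ]
  amp <- lib$amplicons[[sg$ref_id]]
  set.seed(18)
  for (rep in 1:1000) {
    ev <- poolcrispr:::random_edit_event(amp, sg$cut_offset, cfg)
    allele <- poolcrispr:::apply_event(amp, ev$kind, ev$start, ev$length, ev$alt_seq)
    got <- align_read(allele, amp)$events
    expect_equal(nrow(got), 1L)
    expect_equal(got$kind, ev$kind)
    expect_equal(got$start, ev$start)
    expect_equal(got$length, ev$length)
    expect_equal(got$alt_seq, ev$alt_seq)
  }
})

test_that("editing frequency, noise thresholds and status follow the rules", {
  amp <- FIG_AMP
  cut <- 17L
  mk_profile <- function(n_edited, n_total, ...) {
    del <- paste0(substr(amp, 1, cut - 1), substring(amp, cut + 2))
    call_target(c(rep(del, n_edited), rep(amp, n_total - n_edited)), amp, cut, ...)
  }
  # 50 of 1000 reads carry a -2 at the cut: frequency 5%, edited
  del2 <- paste0(substr(amp, 1, cut), substring(amp, cut + 3))
  prof <- call_target(c(rep(del2, 50), rep(amp, 950)), amp, cut)
  expect_equal(prof$total_reads, 1000L)
  expect_equal(prof$editing_frequency, 0.05)
  expect_equal(prof$status, "edited")
  expect_equal(nrow(prof$events), 1L)
  expect_equal(prof$events$kind, "deletion")
  expect_equal(prof$events$length, 2L)
  expect_equal(prof$events$read_count, 50L)
  expect_equal(prof$events$frequency, 0.05)

  # 9 of 1000 -> 0.9% -> non-edited
  expect_equal(mk_profile(9, 1000)$status, "non-edited")

  # boundary: exactly 1.0% is non-edited (the rule is strictly > 1%)
  expect_equal(mk_profile(10, 1000)$status, "non-edited")
  expect_equal(mk_profile(10, 1000)$editing_frequency, 0.01)
  expect_equal(mk_profile(11, 1000)$status, "edited")

  # zero reads -> empty non-edited profile
  empty <- call_events(list(), cut_offset = cut)
  expect_equal(empty$total_reads, 0L)
  expect_equal(empty$editing_frequency, 0)
  expect_equal(empty$status, "non-edited")

  # events below both noise thresholds are dropped and do not edit reads
  one <- call_target(c(del2, rep(amp, 999)), amp, cut)  # 1 read, freq 0.001
  expect_equal(nrow(one$events), 0L)
  expect_equal(one$editing_frequency, 0)

  # homozygous flag at a single >= 90% event
  hom <- call_target(c(rep(del2, 95), rep(amp, 5)), amp, cut)
  expect_true(hom$putative_homozygous)
  expect_false(prof$putative_homozygous)
})

test_that("events outside the window or on unalignable reads are excluded", {
  amp <- strrep("ACGTT", 20)  # 100 nt
  cut <- 50L
  # deletion 30 bp away from the cut: read aligns but is not edited
  far <- paste0(substr(amp, 1, 85), substring(amp, 87))
  prof <- call_target(c(rep(far, 100), rep(amp, 100)), amp, cut)
  expect_equal(prof$editing_frequency, 0)
  expect_equal(nrow(prof$events), 0L)
  # garbage reads drop out of the denominator
  junk <- strrep("T", 100)
  prof2 <- call_target(c(rep(junk, 50), rep(amp, 50)), amp, cut)
  expect_equal(prof2$total_reads, 50L)
  expect_equal(prof2$n_unalignable, 50L)
})

test_that("notation formats, parses and round-trips", {
  expect_equal(format_notation(event_df(c("deletion", "deletion"), c(10, 20),
                                        c(5, 1))), c("-5", "-1"))
  expect_equal(format_notation(event_df(c("insertion", "deletion"), c(1, 2),
                                        c(1, 21))), c("+1", "-21"))
  p <- parse_notation("-42")
  expect_equal(p$kind, "deletion")
  expect_equal(p$length, 42L)
  # Unicode minus as printed in tables
  expect_equal(parse_notation("−5")$length, 5L)
  expect_error(parse_notation("x5"), "malformed")
  expect_error(parse_notation("-"), "malformed")
  set.seed(7)
  for (rep in 1:50) {
    e <- event_df(sample(c("deletion", "insertion", "substitution"), 1),
                  0, sample(1:60, 1))
    back <- parse_notation(format_notation(e))
    expect_equal(back$kind, e$kind)
    expect_equal(back$length, e$length)
  }
})

test_that("spectrum and type-count summaries add up", {
  alldel <- event_df(rep("deletion", 5), 1:5, rep(1, 5))
  sp <- classify_spectrum(alldel)
  expect_equal(unname(sp$proportions), c(1, 0, 0))
  mix <- event_df(rep(c("deletion", "insertion"), each = 10), 1:20, rep(1, 20))
  expect_equal(unname(classify_spectrum(mix)$proportions), c(0.5, 0.5, 0))
  expect_equal(sum(classify_spectrum(mix)$proportions), 1)
  expect_error(classify_spectrum(event_df(character(0), integer(0), integer(0))))

  mk <- function(n_events) {
    ev <- event_df(rep("deletion", n_events), seq_len(n_events),
                   rep(1, n_events))
    ev$read_count <- 10L; ev$frequency <- 0.5; ev$notation <- format_notation(ev)
    stub_profile(0.5, events = ev)
  }
  profiles <- c(lapply(rep(1, 48), mk), lapply(rep(2, 144), mk),
                lapply(rep(5, 151), mk), lapply(rep(12, 26), mk))
  tc <- type_count_summary(profiles)
  expect_equal(tc$count, c(48L, 144L, 151L, 26L))
  # 48/369 = 13.008% -> 13.01 at two decimals; 144/369 -> 39.02
  expect_equal(tc$pct, c(13.01, 39.02, 40.92, 7.05))
  expect_equal(type_count_summary(lapply(rep(1, 4), mk))$pct[1], 100)
  expect_equal(nrow(type_count_summary(list())), 0L)
})

test_that("simulated allele mixtures are recovered at exact read counts", {
  lib <- simulate_library(n_genes = 1, sgrnas_per_gene = 1, seed = 23)
  sg <- lib$library[1, ]
  amp <- lib$amplicons[[sg$ref_id]]
  cfg <- sim_config(seed = 23)
  set.seed(24)
  evs <- list()
  keys <- character(0)
  for (i in 1:3) {
    evs[[i]] <- poolcrispr:::random_edit_event(amp, sg$cut_offset, cfg,
                                               exclude_keys = keys)
    keys <- c(keys, poolcrispr:::event_key(evs[[i]]))
  }
  freqs <- c(0.4, 0.3, 0.2)
  counts <- round(freqs * 2000)
  reads <- c(unlist(lapply(1:3, function(i)
    rep(poolcrispr:::apply_event(amp, evs[[i]]$kind, evs[[i]]$start,
                                 evs[[i]]$length, evs[[i]]$alt_seq),
        counts[i]))), rep(amp, 2000 - sum(counts)))
  prof <- call_target(reads, amp, sg$cut_offset)
  expect_equal(nrow(prof$events), 3L)
  for (i in 1:3) {
    hit <- prof$events$kind == evs[[i]]$kind & prof$events$start == evs[[i]]$start &
      prof$events$length == evs[[i]]$length & prof$events$alt_seq == evs[[i]]$alt_seq
    expect_equal(sum(hit), 1L)
    expect_equal(prof$events$read_count[hit], counts[i])
    expect_lte(abs(prof$events$frequency[hit] - freqs[i]), 1 / 2000)
  }
  expect_equal(prof$editing_frequency, 0.9)
})
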