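test_that("site enumeration finds NGG windows on both strands", {
  # single + strand site occupying the whole 23-mer
  s <- enumerate_sites(c(a = "ACGTACGTACGTACGTACGTAGG"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "+")
  expect_equal(s$protospacer, "ACGTACGTACGTACGTACGT")
  expect_equal(s$pam, "AGG")
  expect_equal(s$protospacer_start, 0L)
  expect_equal(s$cut_offset, 17L)

  # reverse complement of the above: one - strand site
  s2 <- enumerate_sites(c(a = "CCTACGTACGTACGTACGTACGT"))
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$strand, "-")
  expect_equal(s2$pam, "AGG")
  expect_equal(s2$cut_offset, 6L)

  # below the 23-nt window
  expect_equal(nrow(enumerate_sites(c(a = strrep("G", 22)))), 0L)
  expect_equal(nrow(enumerate_sites(character(0))), 0L)
  expect_error(enumerate_sites(c(a = "ACGTXGGTACGTACGTACGTAGG")), "non-ACGTN")
})

test_that("enumeration matches a brute-force scan and strand flip round-trips", {
  set.seed(11)
  for (rep in 1:15) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(30:80, 1), replace = TRUE),
                 collapse = "")
    got <- enumerate_sites(c(x = seq))
    want <- brute_sites(seq)
    expect_equal(nrow(got), nrow(want))
    key <- function(st, str) sort(paste(st, str))
    expect_equal(key(got$protospacer_start, got$strand),
                 key(want$start, want$strand))
    expect_setequal(got$protospacer, want$protospacer)
    # sites on the reverse complement map onto each other under strand flip
    flip <- enumerate_sites(c(x = revcomp(seq)))
    L <- nchar(seq)
    expect_setequal(paste(L - flip$protospacer_start - 23,
                          chartr("+-", "-+", flip$strand)),
                    paste(got$protospacer_start, got$strand))
    expect_setequal(flip$protospacer, got$protospacer)
  }
})

test_that("off-target mismatch counting is exact, symmetric, and sentinelled", {
  # duplicate protospacer+NGG -> distance 0
  dup <- paste0("ACGTACGTACGTACGTACGTAGG", "TTTTT", "ACGTACGTACGTACGTACGTAGG")
  sites <- enumerate_sites(c(a = dup))
  plus <- sites[sites$strand == "+" & sites$pam == "AGG" &
                  sites$protospacer == "ACGTACGTACGTACGTACGT", ]
  expect_gte(nrow(plus), 2L)
  expect_equal(min_offtarget_mismatch(plus[1, ], sites), 0L)

  # single-site genome -> sentinel 21
  one <- enumerate_sites(c(a = "ACGTACGTACGTACGTACGTAGG"))
  expect_equal(min_offtarget_mismatch(one[1, ], one), 21L)

  # two embedded sites differing at exactly 3 protospacer positions;
  # expected minimum derived by exhaustive pairwise Hamming over all sites
  p1 <- "ACGTACGTACGTACGTACGT"
  p2 <- "TCGTACGAACGTACGTACGA"  # differs from p1 at positions 1, 8, 20
  g <- c(a = paste0(p1, "AGG", strrep("C", 10), p2, "TGG"))
  sites <- enumerate_sites(g)
  pair <- sites[sites$protospacer %in% c(p1, p2), ]
  expect_equal(nrow(pair), 2L)
  exhaustive <- function(cand) {
    others <- sites$protospacer[sites$sgrna_id != cand$sgrna_id]
    min(vapply(others, function(o)
      sum(strsplit(cand$protospacer, "")[[1]] != strsplit(o, "")[[1]]),
      numeric(1)))
  }
  for (i in 1:2) {
    expect_equal(min_offtarget_mismatch(pair[i, ], sites), exhaustive(pair[i, ]))
  }
  expect_equal(min_offtarget_mismatch(pair[1, ], sites), 3L)

  # pairwise symmetry on random toy genomes
  set.seed(5)
  for (rep in 1:5) {
    g <- c(x = paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                     collapse = ""))
    ss <- enumerate_sites(g)
    if (nrow(ss) < 2) next
    for (i in seq_len(min(4, nrow(ss)))) {
      for (j in seq_len(min(4, nrow(ss)))) {
        dij <- hamming(ss$protospacer[i], ss$protospacer[j], n_mismatches_all = TRUE)
        dji <- hamming(ss$protospacer[j], ss$protospacer[i], n_mismatches_all = TRUE)
        expect_equal(dij, dji)
      }
    }
  }
  expect_error(
    min_offtarget_mismatch(data.frame(protospacer = "ACGT", ref_id = "a",
                                      protospacer_start = 0, strand = "+"),
                           one), "length")
})

test_that("mismatch filter excludes the boundary and shrinks monotonically", {
  p1 <- "ACGTACGTACGTACGTACGT"
  p2 <- "TCGTACGAACGTACGTACGT"  # 2 mismatches from p1
  p3 <- "TTTTTTTTTTTTTTTTTTTT"
  g <- c(a = paste0(p1, "AGG", "CCCCC", p2, "TGG", "CCCCC", p3, "AGG"))
  sites <- enumerate_sites(g)
  f <- filter_sgrnas(sites, threshold = 2)
  at <- function(p) f[f$protospacer == p & f$strand == "+", ]
  expect_false(at(p1)$accepted)      # min mismatch 2 -> rejected ("greater than 2")
  expect_false(at(p2)$accepted)
  expect_true(at(p3)$accepted)       # far from everything
  expect_match(at(p1)$reject_reason, "threshold")

  # threshold 0 accepts exactly candidates without an identical twin;
  # raising the threshold never grows the accepted set
  set.seed(21)
  for (rep in 1:5) {
    g <- c(x = paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                     collapse = ""))
    ss <- enumerate_sites(g)
    if (nrow(ss) == 0) next
    prev <- rep(TRUE, nrow(ss))
    f0 <- filter_sgrnas(ss, threshold = 0)
    dup_free <- !(duplicated(ss$protospacer) | duplicated(ss$protospacer, fromLast = TRUE))
    expect_equal(f0$accepted, dup_free)
    for (th in 0:4) {
      acc <- filter_sgrnas(ss, threshold = th)$accepted
      expect_true(all(!acc | prev))  # acc subset of prev
      prev <- acc
    }
  }
})

test_that("sub-pool partition is balanced, deterministic and conserving", {
  expect_equal(partition_pools(969, 24), c(rep(41L, 9), rep(40L, 15)))
  expect_equal(partition_pools(40, 1), 40L)
  expect_equal(partition_pools(5, 2), c(3L, 2L))
  expect_error(partition_pools(5, 6), "k_pools")
  set.seed(31)
  for (rep in 1:1000) {
    n <- sample(1:2000, 1)
    k <- sample(1:n, 1)
    sizes <- partition_pools(n, k)
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_equal(length(sizes), k)
  }
})

test_that("amplicon validation reports length, gap and Tm failures", {
  good_primer <- paste0(strrep("G", 14), strrep("A", 6))  # Tm 59.98
  cons <- design_constraints()
  v <- validate_amplicon(281, 20, 230, 120, c(good_primer, good_primer), cons)
  expect_false(v$pass)
  expect_equal(v$reasons, "length")

  # forward primer ending 29 bp before the cut site
  v <- validate_amplicon(240, 91, 210, 120, c(good_primer, good_primer), cons)
  expect_false(v$pass)
  expect_equal(v$reasons, "gap")

  # all constraints satisfied
  v <- validate_amplicon(240, 20, 210, 120, c(good_primer, good_primer), cons)
  expect_true(v$pass)
  expect_equal(v$reasons, character(0))

  # Tm out of band
  at_primer <- paste0(strrep("A", 10), strrep("T", 10))
  v <- validate_amplicon(240, 20, 210, 120, c(at_primer, good_primer), cons)
  expect_false(v$pass)
  expect_equal(v$reasons, "tm")
  expect_error(design_constraints(max_amplicon_len = 50, min_primer_target_gap = 30))
})

test_that("design_library produces a coherent manifest with pools", {
  set.seed(3)
  g <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""),
    character(1)), c("g1", "g2", "g3"))
  lib <- design_library(g, threshold = 2, k_pools = 3)
  expect_true(all(nchar(lib$protospacer) == 20))
  expect_true(all(substr(lib$pam, 2, 3) == "GG"))
  expect_true(all(is.na(lib$pool_id) | lib$accepted))
  acc <- lib[lib$accepted, ]
  if (nrow(acc) >= 3) {
    expect_equal(sort(unique(acc$pool_id)), 1:3)
    expect_lte(max(table(acc$pool_id)) - min(table(acc$pool_id)), 1)
  }
})
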