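#' Design a set of sample barcodes by greedy randomized search
#'
#' Draws random candidate barcodes and keeps one whenever it satisfies the
#' composition constraints (GC content, homopolymer cap) and is at Hamming
#' distance at least `min_dist` from every barcode kept so far.
#' Deterministic given `seed`. The default `min_dist = 3` guarantees
#' unambiguous nearest-neighbour decoding of any single sequencing error.
#'
#' @param count Number of barcodes required.
#' @param length Barcode length in nt (9 for dual-index genotyping primers).
#' @param min_dist Minimum pairwise Hamming distance within the set.
#' @param gc_range Allowed GC fraction range.
#' @param max_homopolymer Longest allowed single-base run.
#' @param seed Integer RNG seed.
#' @param max_tries Candidate draws before giving up.
#' @return Character vector of `count` barcodes.
#' @export
#' @examples
#' design_barcodes(4, seed = 1)
design_barcodes <- function(count, length = 9L, min_dist = 3L,
                            gc_range = c(0.3, 0.7), max_homopolymer = 3L,
                            seed = 1L, max_tries = 5000L * count) {
  stopifnot(count >= 1, min_dist >= 0)
  if (min_dist > length) stop("min_dist must not exceed barcode length", call. = FALSE)
  with_seed(seed, {
    kept <- character(0)
    tries <- 0L
    while (base::length(kept) < count && tries < max_tries) {
      tries <- tries + 1L
      cand <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
      gc <- gc_fraction(cand)
      if (gc < gc_range[1] || gc > gc_range[2]) next
      if (max_homopolymer_run(cand) > max_homopolymer) next
      if (base::length(kept) &&
          min(hamming(rep(cand, base::length(kept)), kept)) < min_dist) next
      kept <- c(kept, cand)
    }
    if (base::length(kept) < count) {
      stop(sprintf(
        "barcode space exhausted: found %d of %d barcodes (length %d, min_dist %d)",
        base::length(kept), count, length, min_dist), call. = FALSE)
    }
    kept
  })
}

#' Combinatorial dual-index sample capacity of a primer budget
#'
#' With `n_primers` barcoded primers split into `a` forward and `b = n - a`
#' reverse primers, `a * b` samples can be distinguished by the (forward,
#' reverse) barcode pair. Returns the maximum over all splits.
#'
#' @param n_primers Total number of barcoded primers (`>= 2`).
#' @return List with `max_samples` and `best_split = c(a, b)` (`a <= b`).
#' @export
#' @examples
#' capacity(44)  # 484 samples from a 22 x 22 split
capacity <- function(n_primers) {
  if (n_primers < 2) stop("n_primers must be at least 2", call. = FALSE)
  a <- seq_len(n_primers - 1L)
  prod <- a * (n_primers - a)
  best <- which.max(prod)  # ties resolve to the smallest a, hence a <= b
  list(max_samples = as.integer(prod[best]),
       best_split = as.integer(sort(c(best, n_primers - best))))
}

#' Build a dual-index barcode scheme
#'
#' @param forward,reverse Character vectors of forward / reverse barcodes
#'   (equal length strings; the two sets may overlap).
#' @param sample_ids Optional sample identifiers; when given, a sample map
#'   is built with [build_sample_sheet()].
#' @return A `barcode_scheme`: list with `forward`, `reverse`,
#'   `min_pairwise_hamming` (the realised minimum within each set) and
#'   `sample_map` (data.frame `fwd_index`, `rev_index`, `sample_id`).
#' @export
barcode_scheme <- function(forward, reverse, sample_ids = NULL) {
  stopifnot(length(forward) >= 1, length(reverse) >= 1)
  w <- nchar(forward[1])
  if (any(nchar(c(forward, reverse)) != w)) {
    stop("all barcodes must have equal length", call. = FALSE)
  }
  assert_dna(c(forward, reverse), "barcode", allow_n = FALSE)
  if (anyDuplicated(forward) || anyDuplicated(reverse)) {
    stop("barcodes within a set must be unique", call. = FALSE)
  }
  min_set_dist <- function(set) {
    if (length(set) < 2) return(as.integer(w))
    min(vapply(seq_along(set)[-1], function(i)
      min(hamming(rep(set[i], i - 1L), set[seq_len(i - 1L)])), integer(1)))
  }
  scheme <- structure(
    list(forward = forward, reverse = reverse,
         min_pairwise_hamming = min(min_set_dist(forward), min_set_dist(reverse)),
         sample_map = data.frame(fwd_index = integer(0), rev_index = integer(0),
                                 sample_id = character(0))),
    class = "barcode_scheme")
  if (!is.null(sample_ids)) scheme$sample_map <- build_sample_sheet(scheme, sample_ids)
  scheme
}

#' Assign samples to barcode pairs (row-major sample sheet)
#'
#' Samples are assigned to (forward, reverse) index pairs in row-major
#' order: all reverse barcodes of forward barcode 1, then of 2, and so on.
#' The assignment is a bijection over the used pairs.
#'
#' @param scheme A [barcode_scheme()].
#' @param sample_ids Character vector of unique sample identifiers.
#' @return Data.frame `fwd_index`, `rev_index`, `sample_id`, `fwd_seq`,
#'   `rev_seq`.
#' @export
build_sample_sheet <- function(scheme, sample_ids) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  nf <- length(scheme$forward); nr <- length(scheme$reverse)
  n <- length(sample_ids)
  if (n > nf * nr) {
    stop(sprintf("capacity exceeded: %d samples > %d x %d = %d barcode pairs",
                 n, nf, nr, nf * nr), call. = FALSE)
  }
  k <- seq_len(n) - 1L
  data.frame(fwd_index = k %/% nr + 1L,
             rev_index = k %% nr + 1L,
             sample_id = sample_ids,
             fwd_seq = scheme$forward[k %/% nr + 1L],
             rev_seq = scheme$reverse[k %% nr + 1L],
             stringsAsFactors = FALSE)
}

#' Write / read a barcode scheme as TSV
#'
#' The scheme serialises to a long table (`side`, `index`, `sequence`) plus
#' the sample map; `read_barcode_scheme()` inverts `write_barcode_scheme()`.
#'
#' @param scheme A [barcode_scheme()].
#' @param path Barcode TSV path.
#' @param sheet_path Optional sample-sheet TSV path.
#' @export
write_barcode_scheme <- function(scheme, path, sheet_path = NULL) {
  bc <- rbind(
    data.frame(side = "fwd", index = seq_along(scheme$forward),
               sequence = scheme$forward, stringsAsFactors = FALSE),
    data.frame(side = "rev", index = seq_along(scheme$reverse),
               sequence = scheme$reverse, stringsAsFactors = FALSE))
  write_tsv(bc, path)
  if (!is.null(sheet_path)) write_tsv(scheme$sample_map, sheet_path)
  invisible(path)
}

#' @rdname write_barcode_scheme
#' @export
read_barcode_scheme <- function(path, sheet_path = NULL) {
  bc <- read_tsv(path)
  scheme <- barcode_scheme(bc$sequence[bc$side == "fwd"][order(bc$index[bc$side == "fwd"])],
                           bc$sequence[bc$side == "rev"][order(bc$index[bc$side == "rev"])])
  if (!is.null(sheet_path)) {
    scheme$sample_map <- read_tsv(sheet_path)
    scheme$sample_map$sample_id <- as.character(scheme$sample_map$sample_id)
  }
  scheme
}
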