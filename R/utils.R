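#' @importFrom stats rbinom rmultinom runif setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement for plain character vectors (IUPAC codes
#' supported via Biostrings).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGGAA"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  bad <- which(!is_dna(x, allow_n = allow_n))
  if (length(bad)) {
    stop(sprintf("%s contains non-%s characters (first offender: element %d)",
                 what, if (allow_n) "ACGTN" else "ACGT", bad[1]), call. = FALSE)
  }
  invisible(x)
}

# Half-up rounding; base round() is round-half-even and does not reproduce
# printed cohort percentages such as 4/1380 -> 0.29.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage of num/den, half-up to 2 decimals. den == 0 -> 0.
pct2 <- function(num, den) {
  if (length(den) == 1L && den == 0) return(rep(0, length(num)))
  round_half_up(100 * num / den, 2)
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Equal-length strings as a raw matrix (one column per string).
str_raw_matrix <- function(x, width = nchar(x[1])) {
  if (length(x) == 0L) return(matrix(raw(0), nrow = width, ncol = 0))
  stopifnot(all(nchar(x) == width))
  matrix(unlist(lapply(x, charToRaw), use.names = FALSE), nrow = width)
}

#' Hamming distance between equal-length DNA strings
#'
#' @param a,b Character vectors of equal-length strings (recycled pairwise).
#' @param n_mismatches_all If `TRUE`, an `N` in either string counts as a
#'   mismatch even against another `N` (conservative off-target counting).
#' @return Integer vector of distances.
#' @export
#' @examples
#' hamming("ACGT", "AGGT")
hamming <- function(a, b, n_mismatches_all = FALSE) {
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) stop("hamming(): unequal string lengths", call. = FALSE)
  rawN <- charToRaw("N")
  vapply(seq_len(n), function(i) {
    ra <- charToRaw(a[i]); rb <- charToRaw(b[i])
    d <- ra != rb
    if (n_mismatches_all) d <- d | ra == rawN | rb == rawN
    sum(d)
  }, integer(1))
}

# Distances from each query string to each member of a barcode set.
# Returns an integer matrix (length(queries) x length(set)).
hamming_to_set <- function(queries, set) {
  w <- nchar(set[1])
  qm <- str_raw_matrix(queries, w)
  out <- matrix(0L, nrow = length(queries), ncol = length(set))
  for (j in seq_along(set)) {
    out[, j] <- as.integer(colSums(qm != charToRaw(set[j])))
  }
  out
}

gc_fraction <- function(x) {
  vapply(x, function(s) {
    r <- charToRaw(s)
    sum(r == charToRaw("G") | r == charToRaw("C")) / length(r)
  }, numeric(1), USE.NAMES = FALSE)
}

max_homopolymer_run <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""), character(1))
}

# Draw from a discrete distribution given values and probabilities.
draw_discrete <- function(n, values, probs) {
  values[sample.int(length(values), n, replace = TRUE, prob = probs)]
}
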