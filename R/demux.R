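## Dual-index demultiplexing.
##
## A read is assigned to a sample when both its 5'-terminal 9-mer (forward
## barcode) and the reverse complement of its 3'-terminal 9-mer (reverse
## barcode) decode uniquely within the mismatch budget and the decoded
## pair is present in the sample map.

# Decode sequences against a barcode set: index of the unique nearest
# barcode within max_mismatch, 0L when tied (ambiguous), NA when too far.
decode_barcodes <- function(x, barcodes, max_mismatch = 0L) {
  out <- match(x, barcodes)  # exact hits
  if (max_mismatch > 0L) {
    todo <- which(is.na(out) & nchar(x) == nchar(barcodes[1]))
    if (length(todo)) {
      ux <- unique(x[todo])
      d <- hamming_to_set(ux, barcodes)
      best <- apply(d, 1L, min)
      nbest <- rowSums(d == best)
      idx <- max.col(-d, ties.method = "first")
      code <- ifelse(best > max_mismatch, NA_integer_,
                     ifelse(nbest > 1L, 0L, idx))
      out[todo] <- code[match(x[todo], ux)]
    }
  }
  out[is.na(out) & nchar(x) != nchar(barcodes[1])] <- NA_integer_
  out
}

#' Demultiplex pooled reads by dual 9-nt barcodes
#'
#' @param reads A data.frame with `read_id` and `seq` columns, a character
#'   vector of sequences (optionally named by read id), or a FASTQ path.
#' @param scheme A [barcode_scheme()] with a populated sample map.
#' @param max_mismatch Decoding radius per barcode; must be below
#'   `min_pairwise_hamming / 2` so nearest-neighbour decoding is
#'   unambiguous by construction. Reads equidistant from two barcodes at
#'   the minimum are counted ambiguous, never assigned.
#' @return A `demux_result`: list with `assignments` (per read:
#'   `read_id`, `sample_id`, `status` in assigned/unassigned/ambiguous),
#'   `reads_by_sample` (named list of barcode-trimmed sequences, one
#'   entry per sample in the map), `counts` (named assigned-read counts),
#'   `unassigned`, `ambiguous`, `total`.
#' @export
demultiplex <- function(reads, scheme, max_mismatch = 0L) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (max_mismatch >= scheme$min_pairwise_hamming / 2) {
    stop(sprintf(
      "max_mismatch %d >= min barcode distance %d / 2: decoding would be ambiguous",
      max_mismatch, scheme$min_pairwise_hamming), call. = FALSE)
  }
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) {
    reads <- data.frame(
      read_id = if (is.null(names(reads))) sprintf("read%07d", seq_along(reads))
                else names(reads),
      seq = unname(reads), stringsAsFactors = FALSE)
  }
  w <- nchar(scheme$forward[1])
  n <- nrow(reads)
  len <- nchar(reads$seq)
  long_enough <- len >= 2L * w
  fwd <- ifelse(long_enough, substr(reads$seq, 1L, w), "")
  rev_raw <- ifelse(long_enough, substr(reads$seq, len - w + 1L, len), "")
  rev <- ifelse(long_enough, revcomp(ifelse(rev_raw == "", "A", rev_raw)), "")
  fi <- decode_barcodes(fwd, scheme$forward, max_mismatch)
  ri <- decode_barcodes(rev, scheme$reverse, max_mismatch)
  fi[!long_enough] <- NA_integer_
  ri[!long_enough] <- NA_integer_

  ambiguous <- (!is.na(fi) & fi == 0L) | (!is.na(ri) & ri == 0L)
  pair_key <- paste(fi, ri, sep = ":")
  map_key <- paste(scheme$sample_map$fwd_index, scheme$sample_map$rev_index, sep = ":")
  sample_id <- as.character(scheme$sample_map$sample_id)[match(pair_key, map_key)]
  status <- ifelse(ambiguous, "ambiguous",
                   ifelse(is.na(fi) | is.na(ri) | is.na(sample_id),
                          "unassigned", "assigned"))
  sample_id[status != "assigned"] <- NA_character_
  trimmed <- substr(reads$seq, w + 1L, len - w)

  all_samples <- as.character(scheme$sample_map$sample_id)
  assigned <- status == "assigned"
  reads_by_sample <- split(trimmed[assigned],
                           factor(sample_id[assigned], levels = all_samples))
  counts <- vapply(reads_by_sample, length, integer(1))
  res <- list(
    assignments = data.frame(read_id = reads$read_id, sample_id = sample_id,
                             status = status, stringsAsFactors = FALSE),
    reads_by_sample = reads_by_sample,
    counts = counts,
    unassigned = sum(status == "unassigned"),
    ambiguous = sum(status == "ambiguous"),
    total = n)
  class(res) <- "demux_result"
  stopifnot(sum(res$counts) + res$unassigned + res$ambiguous == res$total)
  res
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demux_result: %d reads, %d assigned to %d samples, %d unassigned, %d ambiguous\n",
              x$total, sum(x$counts), sum(x$counts > 0), x$unassigned, x$ambiguous))
  invisible(x)
}

#' Per-sample demultiplexing report
#'
#' @param result A [demultiplex()] result.
#' @return Data.frame with one row per sample plus `unassigned` and
#'   `ambiguous` rows; `n_reads` sums to the total and `rate` to 1
#'   (all-zero on empty input).
#' @export
demux_report <- function(result) {
  stopifnot(inherits(result, "demux_result"))
  out <- data.frame(
    sample_id = c(names(result$counts), "unassigned", "ambiguous"),
    n_reads = c(unname(result$counts), result$unassigned, result$ambiguous),
    stringsAsFactors = FALSE)
  out$rate <- if (result$total > 0) out$n_reads / result$total else 0
  out
}

#' Write demultiplexed reads to per-sample FASTQ files
#'
#' @param result A [demultiplex()] result.
#' @param dir Output directory (created if needed).
#' @param min_reads Samples with fewer assigned reads are skipped.
#' @return Invisibly, the written file paths.
#' @export
write_demux_fastq <- function(result, dir, min_reads = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in names(result$reads_by_sample)) {
    seqs <- result$reads_by_sample[[s]]
    if (length(seqs) < min_reads) next
    p <- file.path(dir, paste0(s, ".fastq"))
    write_fastq(sprintf("%s_%06d", s, seq_along(seqs)), seqs, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
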