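## Per-plant sgRNA identification from cassette amplicon reads.
##
## The 20 bp protospacer is extracted from each read immediately 5' of an
## exact occurrence of the invariant scaffold anchor, tallied, and matched
## against the library by exact 20-mer identity.

#' Extract 20-nt protospacers from cassette reads
#'
#' For each read containing an exact occurrence of `cassette_anchor`, the
#' 20 nt immediately 5' of the (first) anchor occurrence are tallied;
#' reads lacking the anchor, or with fewer than 20 nt upstream of it, are
#' counted discarded.
#'
#' @param reads Character vector of barcode-trimmed cassette reads.
#' @param cassette_anchor Anchor sequence (at least 10 nt; default the
#'   first 12 nt of the invariant sgRNA scaffold).
#' @return List with `counts` (named integer vector of 20-mers, decreasing),
#'   `n_reads` and `n_discarded`.
#' @export
extract_protospacers <- function(reads, cassette_anchor = SGRNA_SCAFFOLD_ANCHOR) {
  if (nchar(cassette_anchor) < 10L) {
    stop("cassette_anchor must be at least 10 nt", call. = FALSE)
  }
  n <- length(reads)
  if (n == 0L) {
    return(list(counts = integer(0), n_reads = 0L, n_discarded = 0L))
  }
  pos <- regexpr(cassette_anchor, reads, fixed = TRUE)
  ok <- pos >= 21L
  spacers <- substr(reads[ok], pos[ok] - 20L, pos[ok] - 1L)
  counts <- sort(table(spacers), decreasing = TRUE)
  list(counts = setNames(as.integer(counts), names(counts)),
       n_reads = n, n_discarded = n - sum(ok))
}

#' Call the sgRNAs carried by one plant
#'
#' A library protospacer is called iff its extracted-read count is at
#' least `min_reads` *and* its fraction of all extracted 20-mers is at
#' least `min_fraction`. Extracted 20-mers absent from the library are
#' reported separately as unmatched. A plant with no extracted
#' protospacers is labelled Negative.
#'
#' @param counts Named integer vector of extracted 20-mer counts (the
#'   `counts` element of [extract_protospacers()]).
#' @param library sgRNA manifest with unique `protospacer` values.
#' @param min_reads,min_fraction Positive calling thresholds.
#' @param plant_id Label carried into the calls.
#' @return Data.frame of calls (`plant_id`, `sgrna_id`, `read_count`,
#'   `fraction`) with attributes `unmatched` (counts of non-library
#'   20-mers) and `negative` (no extracted protospacers at all).
#' @export
call_sgrnas <- function(counts, library, min_reads = 10L, min_fraction = 0.05,
                        plant_id = NA_character_) {
  stopifnot(min_reads > 0, min_fraction > 0)
  if (anyDuplicated(library$protospacer)) {
    stop("library protospacers must be unique for exact 20-mer calling",
         call. = FALSE)
  }
  empty <- data.frame(plant_id = character(0), sgrna_id = character(0),
                      read_count = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(counts) == 0L || sum(counts) == 0L) {
    attr(empty, "unmatched") <- integer(0)
    attr(empty, "negative") <- TRUE
    return(empty)
  }
  total <- sum(counts)
  idx <- match(names(counts), library$protospacer)
  matched <- !is.na(idx)
  keep <- matched & counts >= min_reads & counts / total >= min_fraction
  out <- data.frame(plant_id = plant_id,
                    sgrna_id = library$sgrna_id[idx[keep]],
                    read_count = unname(counts[keep]),
                    fraction = unname(counts[keep] / total),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$read_count), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- counts[!matched]
  attr(out, "negative") <- FALSE
  out
}

#' Identify sgRNAs for every demultiplexed plant
#'
#' @param demux A [demultiplex()] result over cassette reads.
#' @param library sgRNA manifest.
#' @param cassette_anchor Anchor passed to [extract_protospacers()].
#' @param ... Thresholds passed to [call_sgrnas()].
#' @return List with `calls` (row-bound call tables over all plants) and
#'   `multiplicity` (named integer: called sgRNAs per plant, 0 for
#'   Negative plants).
#' @export
identify_sgrnas <- function(demux, library,
                            cassette_anchor = SGRNA_SCAFFOLD_ANCHOR, ...) {
  samples <- names(demux$reads_by_sample)
  calls <- list()
  multiplicity <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    ex <- extract_protospacers(demux$reads_by_sample[[s]], cassette_anchor)
    cl <- call_sgrnas(ex$counts, library, plant_id = s, ...)
    multiplicity[s] <- nrow(cl)
    if (nrow(cl)) calls[[s]] <- cl
  }
  list(calls = if (length(calls)) do.call(rbind, c(calls, make.row.names = FALSE))
       else call_sgrnas(integer(0), library),
       multiplicity = multiplicity)
}

#' Cohort sgRNA multiplicity summary
#'
#' Tabulates plants by number of called sgRNAs into the classes Negative,
#' 1, 2, 3 and >3, with percentages of `n_tested` (half-up, 2 decimals),
#' plus the single-sgRNA share among positive plants. Plants not present
#' in `multiplicity` (no reads at all) count as Negative.
#'
#' @param multiplicity Integer vector of called-sgRNA counts per plant.
#' @param n_tested Cohort size (`>=` the number of plants tallied).
#' @return List with `table` (class, count, pct) and
#'   `single_among_positive_pct`.
#' @export
#' @examples
#' multiplicity_summary(rep(c(0, 1, 2, 3, 4), c(301, 1015, 58, 4, 2)), 1380)
multiplicity_summary <- function(multiplicity, n_tested) {
  if (n_tested < length(multiplicity)) {
    stop("n_tested must be at least the number of plants tallied", call. = FALSE)
  }
  counts <- c(
    Negative = sum(multiplicity == 0L) + (n_tested - length(multiplicity)),
    `1` = sum(multiplicity == 1L),
    `2` = sum(multiplicity == 2L),
    `3` = sum(multiplicity == 3L),
    `>3` = sum(multiplicity > 3L))
  stopifnot(sum(counts) == n_tested)
  positives <- n_tested - counts[["Negative"]]
  list(table = data.frame(class = names(counts), count = unname(counts),
                          pct = pct2(unname(counts), n_tested),
                          stringsAsFactors = FALSE),
       single_among_positive_pct =
         if (positives > 0) pct2(counts[["1"]], positives) else 0)
}
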