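## Target-site editing-event calling.
##
## Reads are aligned globally to their reference amplicon, differences are
## collapsed into normalized events (deletion / insertion / substitution),
## and a per-plant profile is summarised with the editing-frequency
## statistic (edited reads / total reads; a plant is "edited" when the
## frequency exceeds 1%).

ALIGN_MATCH <- 2
ALIGN_MISMATCH <- -4
ALIGN_GAP_OPEN <- 10   # cost of opening a gap
ALIGN_GAP_EXTEND <- 1  # additional cost per gap base

#' Globally align one read to its reference amplicon
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap scoring
#' (match +2, mismatch -4, gap open -10, gap extend -1 per gap base). Among
#' co-optimal placements, indels are normalized to their leftmost
#' equivalent position.
#'
#' @param read,amplicon DNA strings (A/C/G/T/N, non-empty, at most 500 nt).
#' @return A `read_alignment`: list with gapped `pattern` (read) and
#'   `subject` (amplicon), `score`, `identity` (matches / alignment
#'   columns) and `events` (data.frame `kind`, `start`, `length`,
#'   `alt_seq`; 0-based reference coordinates, left-aligned).
#' @export
#' @examples
#' align_read("ACGTACTACGT", "ACGTACGTACGT")$events
align_read <- function(read, amplicon) {
  res <- align_reads(read, amplicon)
  out <- list(read = read, pattern = res$pattern[1], subject = res$subject[1],
              score = res$score[1], identity = res$identity[1],
              events = res$events[[1]])
  class(out) <- "read_alignment"
  out
}

# Vectorised core: many reads against one amplicon.
align_reads <- function(reads, amplicon) {
  stopifnot(length(amplicon) == 1L, nzchar(amplicon), nchar(amplicon) <= 500)
  if (!length(reads)) {
    return(list(pattern = character(0), subject = character(0),
                score = numeric(0), identity = numeric(0), events = list()))
  }
  if (any(!nzchar(reads)) || any(nchar(reads) > 500)) {
    stop("reads must be non-empty and at most 500 nt", call. = FALSE)
  }
  assert_dna(reads, "read"); assert_dna(amplicon, "amplicon")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALIGN_MATCH, mismatch = ALIGN_MISMATCH, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(amplicon),
    substitutionMatrix = mat, gapOpening = ALIGN_GAP_OPEN,
    gapExtension = ALIGN_GAP_EXTEND, type = "global")
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  n <- length(reads)
  events <- vector("list", n)
  identity <- numeric(n)
  for (i in seq_len(n)) {
    ev <- alignment_events(pat[i], sub[i], amplicon)
    events[[i]] <- ev$events
    identity[i] <- ev$identity
    pat[i] <- ev$pattern
    sub[i] <- ev$subject
  }
  list(pattern = pat, subject = sub, score = Biostrings::score(aln),
       identity = identity, events = events)
}

empty_events <- function() {
  data.frame(kind = character(0), start = integer(0), length = integer(0),
             alt_seq = character(0), stringsAsFactors = FALSE)
}

# Collapse a gapped alignment into events, left-normalize indels, and
# re-render the aligned strings at the normalized positions.
alignment_events <- function(pattern, subject, amplicon) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  stopifnot(length(p) == length(s))
  cls <- ifelse(p == "-", 3L, ifelse(s == "-", 4L, ifelse(p == s, 1L, 2L)))
  identity <- sum(cls == 1L) / length(cls)
  runs <- rle(cls)
  ref_chars <- strsplit(amplicon, "", fixed = TRUE)[[1]]
  events <- list()
  r <- 0L   # reference bases consumed (0-based offset of next ref base)
  col <- 0L # alignment columns consumed
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    cl <- runs$values[k]
    if (cl == 2L) {        # substitution run: maximal contiguous mismatches
      events[[length(events) + 1L]] <- data.frame(
        kind = "substitution", start = r, length = len,
        alt_seq = paste(p[(col + 1L):(col + len)], collapse = ""),
        stringsAsFactors = FALSE)
    } else if (cl == 3L) { # gap in read: deletion from the reference
      ev <- left_align_deletion(ref_chars, r, len)
      events[[length(events) + 1L]] <- data.frame(
        kind = "deletion", start = ev$start, length = len, alt_seq = "",
        stringsAsFactors = FALSE)
    } else if (cl == 4L) { # gap in reference: insertion at offset r
      ev <- left_align_insertion(ref_chars, r, p[(col + 1L):(col + len)])
      events[[length(events) + 1L]] <- data.frame(
        kind = "insertion", start = ev$start, length = len,
        alt_seq = paste(ev$alt, collapse = ""), stringsAsFactors = FALSE)
    }
    if (cl != 4L) r <- r + len
    col <- col + len
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  ev <- ev[order(ev$start, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  rendered <- render_alignment(amplicon, ev, degap(pattern))
  list(events = ev, identity = identity,
       pattern = rendered$pattern, subject = rendered$subject)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Shift a deletion of `len` ref bases starting at 0-based `start` to its
# leftmost equivalent placement.
left_align_deletion <- function(ref_chars, start, len) {
  while (start > 0L && ref_chars[start] == ref_chars[start + len]) {
    start <- start - 1L
  }
  list(start = start)
}

# Shift an insertion (alt chars before ref offset `start`) left: while the
# preceding reference base equals the last inserted base, rotate.
left_align_insertion <- function(ref_chars, start, alt) {
  n <- length(alt)
  while (start > 0L && ref_chars[start] == alt[n]) {
    alt <- c(ref_chars[start], alt[-n])
    start <- start - 1L
  }
  list(start = start, alt = alt)
}

# Rebuild gapped pattern/subject strings from normalized events. Falls back
# to NULL-free rendering only if events reconstruct the read exactly
# (guaranteed for events from a single alignment).
render_alignment <- function(amplicon, events, read) {
  ref_chars <- strsplit(amplicon, "", fixed = TRUE)[[1]]
  pat <- character(0); sub <- character(0)
  r <- 0L
  ord <- order(events$start, match(events$kind, c("deletion", "substitution", "insertion")))
  for (i in ord) {
    e <- events[i, ]
    if (e$start > r) {
      seg <- ref_chars[(r + 1L):e$start]
      pat <- c(pat, seg); sub <- c(sub, seg)
      r <- e$start
    }
    if (e$kind == "deletion") {
      sub <- c(sub, ref_chars[(r + 1L):(r + e$length)])
      pat <- c(pat, rep("-", e$length))
      r <- r + e$length
    } else if (e$kind == "insertion") {
      pat <- c(pat, strsplit(e$alt_seq, "", fixed = TRUE)[[1]])
      sub <- c(sub, rep("-", e$length))
    } else {
      sub <- c(sub, ref_chars[(r + 1L):(r + e$length)])
      pat <- c(pat, strsplit(e$alt_seq, "", fixed = TRUE)[[1]])
      r <- r + e$length
    }
  }
  if (r < length(ref_chars)) {
    seg <- ref_chars[(r + 1L):length(ref_chars)]
    pat <- c(pat, seg); sub <- c(sub, seg)
  }
  pattern <- paste(pat, collapse = ""); subject <- paste(sub, collapse = "")
  if (degap(pattern) != read) {
    # overlapping events after normalization cannot be re-rendered; keep them
    return(list(pattern = NA_character_, subject = NA_character_))
  }
  list(pattern = pattern, subject = subject)
}

# Apply one event to a reference amplicon, returning the mutant allele.
apply_event <- function(amplicon, kind, start, length, alt_seq) {
  left <- substr(amplicon, 1L, start)
  if (kind == "deletion") {
    paste0(left, substring(amplicon, start + length + 1L))
  } else if (kind == "insertion") {
    paste0(left, alt_seq, substring(amplicon, start + 1L))
  } else {
    paste0(left, alt_seq, substring(amplicon, start + length + 1L))
  }
}

event_overlaps_window <- function(kind, start, length, lo, hi) {
  ifelse(kind == "insertion",
         start >= lo & start <= hi,
         start <= hi & (start + length - 1L) >= lo)
}

event_key <- function(ev) {
  sprintf("%s:%d:%d:%s", ev$kind, ev$start, ev$length, ev$alt_seq)
}

#' Call editing events and the editing frequency for one plant x target
#'
#' A read is *edited* when its alignment contains at least one retained
#' event overlapping the window `[cut_offset - window, cut_offset +
#' window]`. Events are aggregated by identity (kind, start, length,
#' alt_seq); an event is retained when it is supported by at least
#' `min_event_reads` reads *and* at least a fraction `min_event_freq` of
#' aligned reads (a noise filter against sequencing and PCR artefacts).
#' The editing frequency is edited reads / total aligned reads, and the
#' plant is classified `"edited"` when it strictly exceeds 1%.
#'
#' Reads aligning at below `min_identity` are counted unalignable and
#' excluded from the denominator (off-target amplification artefacts).
#'
#' @param alignments List of [align_read()] results (one per read, or one
#'   per distinct read with `weights` giving read counts).
#' @param cut_offset 0-based cut-site offset on the amplicon.
#' @param window Half-width (bp) of the analysis window around the cut.
#' @param min_event_reads Minimum supporting reads for a retained event.
#' @param min_event_freq Minimum supporting-read fraction for a retained
#'   event.
#' @param weights Integer read multiplicities (default 1 per alignment).
#' @param min_identity Minimum alignment identity for a usable read.
#' @param plant_id,target_id Labels carried into the profile.
#' @return An `edit_profile`: list with `plant_id`, `target_id`,
#'   `total_reads`, `n_unalignable`, `events` (data.frame with
#'   `read_count`, `frequency`, `notation`), `edited_reads`,
#'   `editing_frequency`, `status` (`"edited"` / `"non-edited"`) and
#'   `putative_homozygous` (single event at frequency >= 0.9; a flag only).
#' @export
call_events <- function(alignments, cut_offset, window = 10L,
                        min_event_reads = 2L, min_event_freq = 0.005,
                        weights = NULL, min_identity = 0.6,
                        plant_id = NA_character_, target_id = NA_character_) {
  if (is.null(weights)) weights <- rep(1L, length(alignments))
  stopifnot(length(weights) == length(alignments))
  usable <- vapply(alignments, function(a) a$identity >= min_identity, logical(1))
  n_unalignable <- sum(weights[!usable])
  alignments <- alignments[usable]
  weights <- weights[usable]
  total <- sum(weights)
  lo <- cut_offset - window; hi <- cut_offset + window

  if (total == 0L) {
    return(new_edit_profile(plant_id, target_id, total_reads = 0L,
                            n_unalignable = n_unalignable,
                            events = cbind(empty_events(),
                                           read_count = integer(0),
                                           frequency = numeric(0),
                                           notation = character(0)),
                            edited_reads = 0L))
  }

  # per read: keys of window-overlapping events
  read_keys <- lapply(alignments, function(a) {
    ev <- a$events
    if (!nrow(ev)) return(character(0))
    keep <- event_overlaps_window(ev$kind, ev$start, ev$length, lo, hi)
    unique(event_key(ev[keep, , drop = FALSE]))
  })
  all_keys <- unlist(read_keys, use.names = FALSE)
  if (length(all_keys)) {
    counts <- tapply(rep(weights, lengths(read_keys)), all_keys, sum)
    keep <- counts >= min_event_reads & counts / total >= min_event_freq
    kept_keys <- names(counts)[keep]
  } else {
    counts <- integer(0); kept_keys <- character(0)
  }

  edited <- vapply(read_keys, function(k) any(k %in% kept_keys), logical(1))
  edited_reads <- sum(weights[edited])

  # materialise kept events from the first read carrying each
  ev_rows <- lapply(kept_keys, function(key) {
    i <- which(vapply(read_keys, function(k) key %in% k, logical(1)))[1]
    ev <- alignments[[i]]$events
    ev[event_key(ev) == key, , drop = FALSE][1, ]
  })
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else empty_events()
  if (nrow(events)) {
    events$read_count <- as.integer(counts[kept_keys])
    events$frequency <- events$read_count / total
    events$notation <- format_notation(events)
    events <- events[order(-events$read_count, events$start), ]
    rownames(events) <- NULL
  } else {
    events$read_count <- integer(0)
    events$frequency <- numeric(0)
    events$notation <- character(0)
  }
  new_edit_profile(plant_id, target_id, total_reads = total,
                   n_unalignable = n_unalignable, events = events,
                   edited_reads = edited_reads)
}

new_edit_profile <- function(plant_id, target_id, total_reads, n_unalignable,
                             events, edited_reads) {
  freq <- if (total_reads > 0L) edited_reads / total_reads else 0
  structure(list(
    plant_id = plant_id, target_id = target_id,
    total_reads = as.integer(total_reads),
    n_unalignable = as.integer(n_unalignable),
    events = events,
    edited_reads = as.integer(edited_reads),
    editing_frequency = freq,
    status = if (freq > 0.01) "edited" else "non-edited",
    putative_homozygous = nrow(events) == 1L && events$frequency[1] >= 0.9
  ), class = "edit_profile")
}

#' Assemble an edit profile from an event table
#'
#' Builds an `edit_profile` from pre-computed events (e.g. re-read from an
#' events TSV) so that inheritance comparisons can run on serialised
#' calls.
#'
#' @param plant_id,target_id Profile labels.
#' @param events Data.frame with `kind`, `start`, `length`, `alt_seq` and
#'   optionally `read_count` / `frequency`.
#' @param editing_frequency Editing frequency of the profile; defaults to
#'   the sum of event frequencies when available.
#' @param total_reads Total aligned reads behind the profile, if known.
#' @return An `edit_profile`.
#' @export
as_edit_profile <- function(plant_id, target_id, events,
                            editing_frequency = NULL, total_reads = 0L) {
  if (is.null(events$read_count)) events$read_count <- rep(NA_integer_, nrow(events))
  if (is.null(events$frequency)) events$frequency <- rep(NA_real_, nrow(events))
  events$notation <- if (nrow(events)) format_notation(events) else character(0)
  if (is.null(editing_frequency)) {
    editing_frequency <- if (all(is.na(events$frequency))) 0 else
      min(1, sum(events$frequency, na.rm = TRUE))
  }
  prof <- new_edit_profile(plant_id, target_id, total_reads = total_reads,
                           n_unalignable = 0L, events = events,
                           edited_reads = 0L)
  prof$editing_frequency <- editing_frequency
  prof$status <- if (editing_frequency > 0.01) "edited" else "non-edited"
  prof
}

#' @export
print.edit_profile <- function(x, ...) {
  cat(sprintf("edit_profile %s / %s: %d reads, editing frequency %.2f%% (%s)\n",
              x$plant_id, x$target_id, x$total_reads,
              100 * x$editing_frequency, x$status))
  if (nrow(x$events)) {
    cat(" events:", paste(x$events$notation, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call events for a set of reads against one amplicon
#'
#' Deduplicates identical reads before alignment (reads from an amplicon
#' pool collapse onto few distinct alleles), aligns each distinct read
#' once, and weights events by read multiplicity.
#'
#' @param reads Character vector of reads (barcodes already trimmed).
#' @param amplicon Reference amplicon sequence.
#' @inheritParams call_events
#' @param ... Passed on to [call_events()].
#' @return An `edit_profile`.
#' @export
call_target <- function(reads, amplicon, cut_offset, ...) {
  tab <- table(reads)
  uniq <- names(tab)
  res <- align_reads(uniq, amplicon)
  alignments <- lapply(seq_along(uniq), function(i) {
    structure(list(read = uniq[i], pattern = res$pattern[i],
                   subject = res$subject[i], score = res$score[i],
                   identity = res$identity[i], events = res$events[[i]]),
              class = "read_alignment")
  })
  call_events(alignments, cut_offset, weights = as.integer(tab), ...)
}

#' Compact editing-outcome notation
#'
#' Deletions, insertions and substitutions of length n are written `-n`,
#' `+n` and `/n` respectively; a profile is rendered as comma-joined
#' tokens. `parse_notation()` inverts `format_notation()` (Unicode minus
#' and hyphen variants are accepted).
#'
#' @param events Data.frame with columns `kind` and `length` (or a single
#'   `edit_profile` event row).
#' @return Character vector of tokens.
#' @export
#' @examples
#' format_notation(data.frame(kind = c("deletion", "insertion"), length = c(5, 1)))
#' parse_notation("-5")
format_notation <- function(events) {
  sym <- c(deletion = "-", insertion = "+", substitution = "/")
  bad <- setdiff(unique(events$kind), names(sym))
  if (length(bad)) stop("unknown event kind: ", bad[1], call. = FALSE)
  paste0(sym[events$kind], events$length)
}

#' @rdname format_notation
#' @param token A single notation token such as `"-5"`, `"+1"` or `"/2"`.
#' @export
parse_notation <- function(token) {
  token <- gsub("[−‐–]", "-", trimws(token))
  m <- regmatches(token, regexec("^([-+/])([0-9]+)$", token))[[1]]
  if (length(m) != 3L) stop(sprintf("malformed notation token '%s'", token), call. = FALSE)
  kind <- c(`-` = "deletion", `+` = "insertion", `/` = "substitution")[m[2]]
  list(kind = unname(kind), length = as.integer(m[3]))
}

#' Render a profile's events as a notation string
#'
#' @param profile An `edit_profile`.
#' @return Single string, e.g. `"-5, -1"`; `""` for no events.
#' @export
profile_notation <- function(profile) {
  paste(profile$events$notation, collapse = ", ")
}

#' Editing-outcome spectrum over a cohort
#'
#' Proportions of deletion / insertion / substitution events and per-kind
#' length histograms, counting each distinct retained event once.
#'
#' @param events Data.frame of events (columns `kind`, `length`), e.g. the
#'   row-bound `events` of many profiles.
#' @return List with `proportions` (named, summing to 1) and
#'   `length_hist` (list of tables by kind).
#' @export
classify_spectrum <- function(events) {
  if (nrow(events) == 0L) stop("classify_spectrum() needs at least one event", call. = FALSE)
  kinds <- c("deletion", "insertion", "substitution")
  counts <- vapply(kinds, function(k) sum(events$kind == k), numeric(1))
  list(proportions = counts / sum(counts),
       length_hist = lapply(setNames(kinds, kinds), function(k)
         table(events$length[events$kind == k])))
}

#' Distribution of the number of editing types per edited plant
#'
#' @param profiles List of `edit_profile` objects from edited plants.
#' @return Data.frame with classes `1`, `2`, `3-9`, `>=10`, their counts
#'   and percentages (half-up, 2 decimals) over the profiles given; empty
#'   input returns an empty table.
#' @export
type_count_summary <- function(profiles) {
  if (!length(profiles)) {
    return(data.frame(class = character(0), count = integer(0), pct = numeric(0)))
  }
  n_types <- vapply(profiles, function(p) nrow(p$events), integer(1))
  cls <- ifelse(n_types >= 10L, ">=10",
                ifelse(n_types >= 3L, "3-9", as.character(n_types)))
  levels <- c("1", "2", "3-9", ">=10")
  counts <- vapply(levels, function(l) sum(cls == l), integer(1))
  data.frame(class = levels, count = unname(counts),
             pct = pct2(unname(counts), length(profiles)),
             stringsAsFactors = FALSE)
}
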