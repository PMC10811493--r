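## Cross-generation (T0 -> T1) editing heritability.
##
## An editing type is heritable when a progeny plant carries an event
## identical to one of its parent's (same kind, normalized position,
## length and sequence). Events present in the progeny but absent from the
## parent are novel edits from continued Cas9 activity.

#' Match T1 events against the T0 parent profile
#'
#' Events match iff `(kind, start, length, alt_seq)` are equal (positions
#' are left-normalized, so identity comparison is well-defined).
#'
#' @param t0,t1 `edit_profile` objects for the same target.
#' @return List with `matched` / `novel` event tables (T1 rows),
#'   `n_t0_events`, and `heritability_pct` = 100 * matched / T0 events
#'   (`NA` when the parent has no passing events).
#' @export
match_events <- function(t0, t1) {
  if (!identical(t0$target_id, t1$target_id)) {
    stop("match_events(): profiles target different amplicons", call. = FALSE)
  }
  k0 <- event_key(t0$events)
  k1 <- event_key(t1$events)
  matched <- t1$events[k1 %in% k0, , drop = FALSE]
  novel <- t1$events[!(k1 %in% k0), , drop = FALSE]
  n0 <- nrow(t0$events)
  list(matched = matched, novel = novel, n_t0_events = n0,
       heritability_pct = if (n0 > 0L)
         100 * sum(k0 %in% k1) / n0 else NA_real_)
}

#' Compare T0 and T1 profile sets through a pedigree
#'
#' @param t0_profiles,t1_profiles Named lists of `edit_profile`s keyed
#'   `plant_id|target_id` (as produced by [truth_profiles()] or assembled
#'   from [call_target()] results).
#' @param pedigree Data.frame with `t1_plant_id` and `t0_line_id`.
#' @return List with `per_plant` (plant, line, matched / novel counts,
#'   heritability), `per_line` (unweighted line means) and the
#'   [cohort_summary()] rollup.
#' @export
compare_generations <- function(t0_profiles, t1_profiles, pedigree) {
  split_key <- function(k) strsplit(k, "|", fixed = TRUE)
  t1_ids <- vapply(split_key(names(t1_profiles)), `[`, character(1), 1)
  rows <- list()
  for (i in seq_along(t1_profiles)) {
    p1 <- t1_profiles[[i]]
    line <- pedigree$t0_line_id[match(t1_ids[i], pedigree$t1_plant_id)]
    if (is.na(line)) next
    key0 <- paste(line, p1$target_id, sep = "|")
    p0 <- t0_profiles[[key0]]
    if (is.null(p0)) next
    m <- match_events(p0, p1)
    rows[[length(rows) + 1L]] <- data.frame(
      plant_id = p1$plant_id, line_id = line, target_id = p1$target_id,
      n_t0_events = m$n_t0_events, n_matched = nrow(m$matched),
      n_novel = nrow(m$novel), heritability_pct = m$heritability_pct,
      stringsAsFactors = FALSE)
  }
  per_target <- do.call(rbind, rows)
  # per plant: pool over that plant's targets
  agg <- aggregate(cbind(n_t0_events, n_matched, n_novel) ~ plant_id + line_id,
                   data = per_target, FUN = sum)
  agg$heritability_pct <- ifelse(agg$n_t0_events > 0,
                                 100 * agg$n_matched / agg$n_t0_events, NA_real_)
  per_line <- aggregate(heritability_pct ~ line_id, data = agg,
                        FUN = mean, na.action = stats::na.omit)
  names(per_line)[2] <- "mean_heritability_pct"
  list(per_plant = agg[order(agg$plant_id), ],
       per_line = per_line,
       cohort = cohort_summary(agg, nrow(agg)))
}

#' Cohort heritability rollup
#'
#' @param per_plant Data.frame with `heritability_pct` and `n_novel`
#'   per T1 plant (plants whose parent had no passing events carry `NA`
#'   heritability and are excluded from the mean).
#' @param n_t1 Number of T1 plants assayed (`>= 1`).
#' @return List with `n_t1`, `mean_heritability_pct`,
#'   `faithful_pct` (plants at exactly 100%), `novel_pct` (plants with at
#'   least one novel event); percentages half-up to 2 decimals.
#' @export
#' @examples
#' cohort_summary(data.frame(heritability_pct = c(100, 50), n_novel = c(0, 1)), 2)
cohort_summary <- function(per_plant, n_t1) {
  stopifnot(n_t1 >= 1)
  h <- per_plant$heritability_pct
  list(n_t1 = n_t1,
       mean_heritability_pct = round_half_up(mean(h, na.rm = TRUE), 2),
       faithful_pct = pct2(sum(!is.na(h) & h == 100), n_t1),
       novel_pct = pct2(sum(per_plant$n_novel >= 1L), n_t1))
}

#' Per-line editing-frequency trajectory
#'
#' Flags lines whose editing frequency escalates across generations: a
#' weakly edited T0 parent can yield strongly edited progeny when Cas9
#' keeps cutting.
#'
#' @param t0_freq T0 editing frequency (fraction or percent, consistently).
#' @param t1_freqs Numeric vector of progeny editing frequencies.
#' @return List with `t0`, `t1`, and `escalated` (`TRUE` when
#'   `min(t1_freqs) > t0_freq`).
#' @export
#' @examples
#' frequency_trajectory(0.67, c(99.48, 93.46, 94.11))$escalated
frequency_trajectory <- function(t0_freq, t1_freqs) {
  stopifnot(length(t1_freqs) >= 1)
  list(t0 = t0_freq, t1 = t1_freqs, escalated = min(t1_freqs) > t0_freq)
}
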