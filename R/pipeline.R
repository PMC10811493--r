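## End-to-end genotyping pipeline glue:
## demultiplex -> sgRNA identification -> editing-event calling.

# Assign a plant's target reads to one of its called amplicons. Reads are
# first matched by the amplicon's 5' primer-region prefix (exact); leftovers
# fall back to best global alignment score.
assign_target_reads <- function(reads, candidate_amplicons, prefix_len = 15L) {
  if (length(candidate_amplicons) == 1L) {
    return(setNames(rep(names(candidate_amplicons), length(reads)), NULL))
  }
  prefixes <- substr(candidate_amplicons, 1L, prefix_len)
  hit <- match(substr(reads, 1L, prefix_len), prefixes)
  out <- names(candidate_amplicons)[hit]
  todo <- which(is.na(hit))
  if (length(todo)) {
    uniq <- unique(reads[todo])
    scores <- vapply(candidate_amplicons, function(a)
      align_reads(uniq, a)$score, numeric(length(uniq)))
    if (length(uniq) == 1L) scores <- matrix(scores, nrow = 1L)
    best <- names(candidate_amplicons)[max.col(scores, ties.method = "first")]
    out[todo] <- best[match(reads[todo], uniq)]
  }
  out
}

#' Run the genotyping pipeline on pooled cassette and target reads
#'
#' Demultiplexes both read pools by dual barcode, identifies each plant's
#' sgRNAs from the cassette pool, then calls editing events per plant and
#' called target from the target pool.
#'
#' @param cassette_reads,target_reads Read input accepted by
#'   [demultiplex()] (data.frame, character vector, or FASTQ path).
#' @param scheme A [barcode_scheme()] with a populated sample map.
#' @param library sgRNA manifest.
#' @param amplicons Named character vector of reference amplicons.
#' @param max_mismatch Barcode decoding radius.
#' @param cassette_anchor Protospacer extraction anchor.
#' @param min_reads,min_fraction sgRNA calling thresholds.
#' @param window,min_event_reads,min_event_freq,min_identity Event-calling
#'   parameters (see [call_events()]).
#' @return List with `demux_cassette`, `demux_target`, `sgrna`
#'   ([identify_sgrnas()] result), `profiles` (named `edit_profile` list,
#'   keyed `plant_id|sgrna_id`) and `events` (row-bound retained events
#'   with plant and target columns).
#' @export
run_genotyping <- function(cassette_reads, target_reads, scheme, library,
                           amplicons, max_mismatch = 0L,
                           cassette_anchor = SGRNA_SCAFFOLD_ANCHOR,
                           min_reads = 10L, min_fraction = 0.05,
                           window = 10L, min_event_reads = 2L,
                           min_event_freq = 0.005, min_identity = 0.6) {
  dc <- demultiplex(cassette_reads, scheme, max_mismatch)
  dt <- demultiplex(target_reads, scheme, max_mismatch)
  sg <- identify_sgrnas(dc, library, cassette_anchor,
                        min_reads = min_reads, min_fraction = min_fraction)
  profiles <- list()
  events <- list()
  called_plants <- unique(sg$calls$plant_id)
  for (pid in called_plants) {
    sgids <- sg$calls$sgrna_id[sg$calls$plant_id == pid]
    reads <- dt$reads_by_sample[[pid]]
    if (is.null(reads) || !length(reads)) next
    cand <- setNames(amplicons[library$ref_id[match(sgids, library$sgrna_id)]],
                     sgids)
    amp_of <- assign_target_reads(reads, cand)
    for (sgid in sgids) {
      sub <- reads[amp_of == sgid]
      lib_row <- library[library$sgrna_id == sgid, ]
      prof <- call_target(sub, amplicons[[lib_row$ref_id]], lib_row$cut_offset,
                          window = window, min_event_reads = min_event_reads,
                          min_event_freq = min_event_freq,
                          min_identity = min_identity,
                          plant_id = pid, target_id = sgid)
      profiles[[paste(pid, sgid, sep = "|")]] <- prof
      if (nrow(prof$events)) {
        ev <- prof$events
        ev$plant_id <- pid
        ev$target_id <- sgid
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  list(demux_cassette = dc, demux_target = dt, sgrna = sg,
       profiles = profiles,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

#' Reduce per-target profiles to one profile per plant
#'
#' For plants carrying several guides, cohort editing statistics use the
#' plant's maximum-frequency target.
#'
#' @param profiles Named list of `edit_profile`s keyed `plant_id|target_id`.
#' @return Named list of `edit_profile`s keyed by plant.
#' @export
plant_max_profiles <- function(profiles) {
  pids <- vapply(profiles, function(p) p$plant_id, character(1))
  out <- list()
  for (pid in unique(pids)) {
    ps <- profiles[pids == pid]
    f <- vapply(ps, function(p) p$editing_frequency, numeric(1))
    out[[pid]] <- ps[[which.max(f)]]
  }
  out
}

#' Write pipeline call tables to TSV
#'
#' @param result A [run_genotyping()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_call_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$sgrna$calls, file.path(dir, "sgrna_calls.tsv"))
  profs <- result$profiles
  ptab <- data.frame(
    plant_id = vapply(profs, function(p) p$plant_id, character(1)),
    target_id = vapply(profs, function(p) p$target_id, character(1)),
    total_reads = vapply(profs, function(p) p$total_reads, integer(1)),
    editing_frequency = vapply(profs, function(p) p$editing_frequency, numeric(1)),
    status = vapply(profs, function(p) p$status, character(1)),
    notation = vapply(profs, profile_notation, character(1)),
    stringsAsFactors = FALSE)
  rownames(ptab) <- NULL
  write_tsv(ptab, file.path(dir, "profiles.tsv"))
  if (!is.null(result$events)) write_tsv(result$events, file.path(dir, "events.tsv"))
  invisible(dir)
}
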