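## Cohort-level library summaries.

#' Summarise editing efficiency over a cohort
#'
#' Effective editing means an editing frequency strictly above 1% of
#' reads; high efficiency means strictly above 80%.
#'
#' @param profiles List of `edit_profile` objects (one per analysed plant;
#'   for multi-target plants, pass the per-plant maximum-frequency
#'   profile or one profile per target as appropriate to the design).
#' @param n_analyzed Number of plants analysed (`>= length(profiles)`).
#' @return List with `n_analyzed`, `n_effective`, `pct_effective`,
#'   `n_high_efficiency`, `pct_high_efficiency` (percentages half-up, 2
#'   decimals).
#' @export
#' @examples
#' # 359 of 369 plants above 1%, 279 above 80%
#' profs <- lapply(c(rep(0.9, 279), rep(0.5, 80), rep(0.005, 10)), function(f)
#'   structure(list(editing_frequency = f,
#'                  status = if (f > 0.01) "edited" else "non-edited"),
#'             class = "edit_profile"))
#' summarize_editing(profs, 369)[c("pct_effective", "pct_high_efficiency")]
summarize_editing <- function(profiles, n_analyzed = length(profiles)) {
  if (n_analyzed == 0) stop("n_analyzed must be positive", call. = FALSE)
  stopifnot(n_analyzed >= length(profiles))
  freq <- vapply(profiles, function(p) p$editing_frequency, numeric(1))
  n_eff <- sum(freq > 0.01)
  n_high <- sum(freq > 0.80)
  list(n_analyzed = as.integer(n_analyzed),
       n_effective = as.integer(n_eff),
       pct_effective = pct2(n_eff, n_analyzed),
       n_high_efficiency = as.integer(n_high),
       pct_high_efficiency = pct2(n_high, n_analyzed))
}

#' Gene coverage of the identified sgRNAs
#'
#' @param calls sgRNA call table with an `sgrna_id` column.
#' @param library sgRNA manifest (`sgrna_id`, `gene_id`); must be
#'   non-empty.
#' @return List with `n_sgrnas_seen`, `n_genes_seen`, `n_library_genes`
#'   and `coverage_pct` (half-up, 2 decimals).
#' @export
gene_coverage <- function(calls, library) {
  if (nrow(library) == 0L) stop("library must be non-empty", call. = FALSE)
  seen <- unique(calls$sgrna_id)
  genes_seen <- unique(library$gene_id[library$sgrna_id %in% seen])
  n_lib_genes <- length(unique(library$gene_id))
  list(n_sgrnas_seen = length(seen),
       n_genes_seen = length(genes_seen),
       n_library_genes = n_lib_genes,
       coverage_pct = pct2(length(genes_seen), n_lib_genes))
}

#' Assemble the cohort library summary
#'
#' @param editing Result of [summarize_editing()].
#' @param coverage Result of [gene_coverage()].
#' @param multiplicity Result of [multiplicity_summary()].
#' @param type_counts Result of [type_count_summary()].
#' @return A `library_summary` list combining the four blocks.
#' @export
library_summary <- function(editing, coverage, multiplicity, type_counts) {
  structure(list(editing = editing, coverage = coverage,
                 multiplicity = multiplicity, type_counts = type_counts),
            class = "library_summary")
}

#' Write summary artifacts (JSON + TSV)
#'
#' The JSON round-trips losslessly through [read_summary_json()];
#' tabular blocks are also written as TSVs.
#'
#' @param summary A [library_summary()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_outputs <- function(summary, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir),
                             call. = FALSE)
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  scalars <- c(summary$editing,
               summary$coverage,
               list(single_among_positive_pct = summary$multiplicity$single_among_positive_pct))
  write_tsv(data.frame(metric = names(scalars),
                       value = unlist(scalars, use.names = FALSE)),
            file.path(dir, "summary.tsv"))
  write_tsv(summary$multiplicity$table, file.path(dir, "multiplicity.tsv"))
  write_tsv(summary$type_counts, file.path(dir, "type_counts.tsv"))
  invisible(json_path)
}

#' @rdname write_outputs
#' @param path Path to a summary JSON written by [write_outputs()].
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$multiplicity$table <- as.data.frame(x$multiplicity$table)
  x$type_counts <- as.data.frame(x$type_counts)
  structure(x, class = "library_summary")
}
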