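#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
                             call. = FALSE))
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a 4-line-record FASTQ file.
#' @return A data.frame with columns `read_id` and `seq`. Base qualities are
#'   not retained: all downstream statistics are count-based.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             seq = unname(as.character(ss)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' Writes 4-line FASTQ records with a constant quality character, producing
#' byte-identical output for identical input.
#'
#' @param ids Character vector of read identifiers.
#' @param seqs Character vector of read sequences.
#' @param path Output path.
#' @param qual Quality character used for every base (default `"I"`, Q40).
#' @export
write_fastq <- function(ids, seqs, path, qual = "I") {
  stopifnot(length(ids) == length(seqs))
  quals <- vapply(nchar(seqs), function(n) strrep(qual, n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Plain TSV I/O used for all manifests (sgRNA library, sample sheets,
#' calls, profiles, pedigree).
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `read_tsv()` returns a data.frame with character columns kept as
#'   character.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
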