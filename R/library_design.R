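#' Enumerate candidate Cas9 target sites (20-nt protospacer + NGG PAM)
#'
#' Scans both strands of every reference sequence for 23-nt windows whose
#' last two bases (in target orientation) are `GG`. Coordinates are 0-based
#' on the forward strand: `protospacer_start` is the start of the 23-nt
#' site window, so `protospacer_start + 23 <= nchar(reference)` on either
#' strand. The blunt Cas9 cut falls 3 nt 5' of the PAM; `cut_offset` is the
#' 0-based offset of the base immediately 3' of the cut on the forward
#' strand (`start + 17` on `+`, `start + 6` on `-`).
#'
#' @param genome Named character vector of DNA sequences (A/C/G/T/N), a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param gene_ids Optional named character vector mapping reference names to
#'   gene identifiers; defaults to the reference names themselves.
#' @param max_sites Hard cap on the number of enumerated sites; the
#'   all-vs-all off-target filter downstream is quadratic, so enumeration is
#'   desk-scale by contract.
#' @return A data.frame of candidate sites with columns `sgrna_id`,
#'   `gene_id`, `protospacer`, `pam`, `ref_id`, `strand`,
#'   `protospacer_start`, `cut_offset`, sorted by
#'   (`ref_id`, `protospacer_start`, `strand`).
#' @export
#' @examples
#' enumerate_sites(c(amp1 = "ACGTACGTACGTACGTACGTAGG"))
enumerate_sites <- function(genome, gene_ids = NULL, max_sites = 1e6) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (length(genome) == 0L) return(empty_sites())
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stop("malformed genome: every reference sequence must be named", call. = FALSE)
  }
  genome <- toupper(genome)
  assert_dna(genome, "genome")

  scan_one <- function(seq, ref) {
    L <- nchar(seq)
    if (L < 23L) return(NULL)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    res <- list()
    # + strand: protospacer at s..s+19, PAM at s+20..s+22 (0-based s)
    s <- 0:(L - 23L)
    plus <- s[ch[s + 22L] == "G" & ch[s + 23L] == "G"]
    if (length(plus)) {
      res$plus <- data.frame(
        ref_id = ref, strand = "+",
        protospacer = substring(seq, plus + 1L, plus + 20L),
        pam = substring(seq, plus + 21L, plus + 23L),
        protospacer_start = plus,
        cut_offset = plus + 17L,
        stringsAsFactors = FALSE)
    }
    # - strand: forward-strand window [w, w+23) shows CCN..; the target-
    # orientation protospacer is revcomp(fwd[w+3, w+23))
    minus <- s[ch[s + 1L] == "C" & ch[s + 2L] == "C"]
    if (length(minus)) {
      res$minus <- data.frame(
        ref_id = ref, strand = "-",
        protospacer = revcomp(substring(seq, minus + 4L, minus + 23L)),
        pam = revcomp(substring(seq, minus + 1L, minus + 3L)),
        protospacer_start = minus,
        cut_offset = minus + 6L,
        stringsAsFactors = FALSE)
    }
    if (length(res)) do.call(rbind, res) else NULL
  }

  parts <- Map(scan_one, genome, names(genome))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(empty_sites())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (nrow(out) > max_sites) {
    stop(sprintf("enumerated %d sites, above the cap of %g", nrow(out), max_sites),
         call. = FALSE)
  }
  gid <- if (is.null(gene_ids)) setNames(names(genome), names(genome)) else gene_ids
  out$gene_id <- unname(gid[out$ref_id])
  out <- out[order(out$ref_id, out$protospacer_start, out$strand), ]
  out$sgrna_id <- sprintf("%s:%d%s", out$ref_id, out$protospacer_start, out$strand)
  rownames(out) <- NULL
  out[, c("sgrna_id", "gene_id", "protospacer", "pam", "ref_id", "strand",
          "protospacer_start", "cut_offset")]
}

empty_sites <- function() {
  data.frame(sgrna_id = character(0), gene_id = character(0),
             protospacer = character(0), pam = character(0),
             ref_id = character(0), strand = character(0),
             protospacer_start = integer(0), cut_offset = integer(0),
             stringsAsFactors = FALSE)
}

#' Minimum off-target mismatch count for a candidate site
#'
#' Minimum Hamming distance over the 20-nt protospacer between the candidate
#' and every *other* NGG site in `all_sites`. The PAM is required to be NGG
#' at both sites (guaranteed by enumeration) and contributes no mismatches.
#' `N` never matches any base, including another `N`.
#'
#' @param candidate A single-row data.frame (one enumerated site) or an
#'   `sgrna_id` present in `all_sites`.
#' @param all_sites Site table from [enumerate_sites()]; must contain the
#'   candidate itself.
#' @return Integer: the minimum distance, or the sentinel `21L` ("no other
#'   site": one more than the maximum possible distance, keeping the return
#'   type integral and totally ordered).
#' @export
min_offtarget_mismatch <- function(candidate, all_sites) {
  if (is.character(candidate)) {
    idx <- match(candidate, all_sites$sgrna_id)
    if (is.na(idx)) stop("candidate sgrna_id not found in all_sites", call. = FALSE)
    candidate <- all_sites[idx, ]
  }
  if (nchar(candidate$protospacer) != 20L) {
    stop("invariant violated: protospacer length must be 20", call. = FALSE)
  }
  self <- all_sites$ref_id == candidate$ref_id &
    all_sites$protospacer_start == candidate$protospacer_start &
    all_sites$strand == candidate$strand
  others <- all_sites$protospacer[!self]
  if (!length(others)) return(21L)
  if (any(nchar(others) != 20L)) {
    stop("invariant violated: protospacer length must be 20", call. = FALSE)
  }
  min(hamming(rep(candidate$protospacer, length(others)), others,
              n_mismatches_all = TRUE))
}

# All-candidates version: minimum pairwise protospacer distance per site.
min_offtarget_mismatch_all <- function(sites) {
  n <- nrow(sites)
  if (n == 0L) return(integer(0))
  if (any(nchar(sites$protospacer) != 20L)) {
    stop("invariant violated: protospacer length must be 20", call. = FALSE)
  }
  if (n == 1L) return(21L)
  m <- str_raw_matrix(sites$protospacer, 20L)
  isN <- m == charToRaw("N")
  out <- integer(n)
  for (i in seq_len(n)) {
    d <- colSums(m != m[, i] | isN | isN[, i])
    d[i] <- 21L
    out[i] <- as.integer(min(d, 21L))
  }
  out
}

#' Apply the off-target mismatch filter to candidate sgRNAs
#'
#' A candidate is accepted iff its minimum protospacer mismatch count
#' against every other NGG site is strictly greater than `threshold`
#' (default 2: sites whose nearest neighbour differs at only 1 or 2
#' positions are discarded as off-target-prone).
#'
#' @param candidates Candidate site table (subset of `all_sites`).
#' @param all_sites Full enumerated site table; defaults to `candidates`.
#' @param threshold Non-negative integer mismatch threshold (exclusive).
#' @return `candidates` with added columns `min_offtarget_mm`, `accepted`,
#'   and `reject_reason` (`NA` when accepted).
#' @export
filter_sgrnas <- function(candidates, all_sites = candidates, threshold = 2L) {
  stopifnot(threshold >= 0)
  if (nrow(candidates) == 0L) {
    candidates$min_offtarget_mm <- integer(0)
    candidates$accepted <- logical(0)
    candidates$reject_reason <- character(0)
    return(candidates)
  }
  same <- identical(candidates$sgrna_id, all_sites$sgrna_id)
  mm <- if (same) {
    min_offtarget_mismatch_all(all_sites)
  } else {
    vapply(seq_len(nrow(candidates)), function(i)
      min_offtarget_mismatch(candidates[i, ], all_sites), integer(1))
  }
  candidates$min_offtarget_mm <- mm
  candidates$accepted <- mm > threshold
  candidates$reject_reason <- ifelse(
    candidates$accepted, NA_character_,
    sprintf("min off-target mismatch %d <= threshold %d", mm, threshold))
  candidates
}

#' Partition primer pairs into balanced sub-pools
#'
#' Deterministic balanced partition: pool sizes differ by at most one, with
#' the larger pools first (969 primer pairs over 24 sub-pools gives nine
#' pools of 41 and fifteen of 40).
#'
#' @param n_items Number of items to partition.
#' @param k_pools Number of pools, `1 <= k_pools <= n_items`.
#' @return Integer vector of pool sizes summing to `n_items`.
#' @export
#' @examples
#' partition_pools(969, 24)
partition_pools <- function(n_items, k_pools) {
  if (k_pools < 1 || k_pools > n_items) {
    stop("k_pools must satisfy 1 <= k_pools <= n_items", call. = FALSE)
  }
  base <- n_items %/% k_pools
  rem <- n_items %% k_pools
  c(rep(base + 1L, rem), rep(base, k_pools - rem))
}

# Assign accepted candidates to contiguous sub-pools following
# partition_pools sizes; rejected rows get NA.
assign_pools <- function(filtered, k_pools) {
  filtered$pool_id <- NA_integer_
  idx <- which(filtered$accepted)
  if (length(idx) && k_pools >= 1) {
    sizes <- partition_pools(length(idx), min(k_pools, length(idx)))
    filtered$pool_id[idx] <- rep(seq_along(sizes), sizes)
  }
  filtered
}

#' Amplicon design constraints
#'
#' Sequencing-driven constraints on genotyping amplicons: short-read
#' chemistry caps the product at 280 bp; primers must keep at least a 30 bp
#' gap from the cut site so that typical indels do not destroy a priming
#' site; annealing temperatures are held in a narrow 58-60 degree C band so
#' all pairs amplify under one cycling condition.
#'
#' @param max_amplicon_len Maximum amplicon length in bp.
#' @param min_primer_target_gap Minimum distance (bp) between a primer's
#'   inner edge and the cut site.
#' @param tm_range Numeric length-2: allowed primer melting-temperature
#'   range in degrees Celsius.
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(max_amplicon_len = 280L,
                               min_primer_target_gap = 30L,
                               tm_range = c(58, 60)) {
  stopifnot(max_amplicon_len > 2 * min_primer_target_gap,
            length(tm_range) == 2L, tm_range[1] <= tm_range[2])
  structure(list(max_amplicon_len = as.integer(max_amplicon_len),
                 min_primer_target_gap = as.integer(min_primer_target_gap),
                 tm_range = as.numeric(tm_range)),
            class = "design_constraints")
}

#' Primer melting temperature (salt-free Wallace-type approximation)
#'
#' `Tm = 64.9 + 41 * (G + C - 16.4) / length`.
#'
#' @param primer DNA string(s).
#' @return Numeric Tm in degrees Celsius.
#' @export
primer_tm <- function(primer) {
  assert_dna(primer, "primer", allow_n = FALSE)
  len <- nchar(primer)
  gc <- gc_fraction(primer) * len
  64.9 + 41 * (gc - 16.4) / len
}

#' Validate a genotyping amplicon against design constraints
#'
#' All problems are reported, never raised: the report lists every failed
#' constraint among `"length"` (amplicon too long), `"gap"` (a primer's
#' inner edge closer than the minimum gap to the cut site) and `"tm"` (a
#' primer melting temperature outside the allowed band).
#'
#' @param amplicon_len Amplicon length in bp.
#' @param fwd_primer_end 0-based offset one past the forward primer's last
#'   base (its inner edge).
#' @param rev_primer_start 0-based offset of the reverse primer's first
#'   (innermost) base on the forward strand.
#' @param cut_offset 0-based cut-site offset on the amplicon.
#' @param primer_seqs Character vector of the two primer sequences
#'   (forward, reverse).
#' @param constraints A [design_constraints()] object.
#' @return List with `pass` (logical), `reasons` (character vector),
#'   `gaps` (fwd/rev gap in bp) and `tm` (fwd/rev Tm).
#' @export
validate_amplicon <- function(amplicon_len, fwd_primer_end, rev_primer_start,
                              cut_offset, primer_seqs,
                              constraints = design_constraints()) {
  stopifnot(inherits(constraints, "design_constraints"),
            length(primer_seqs) == 2L)
  reasons <- character(0)
  if (amplicon_len > constraints$max_amplicon_len) reasons <- c(reasons, "length")
  gaps <- c(fwd = cut_offset - fwd_primer_end, rev = rev_primer_start - cut_offset)
  if (any(gaps < constraints$min_primer_target_gap)) reasons <- c(reasons, "gap")
  tm <- setNames(primer_tm(primer_seqs), c("fwd", "rev"))
  if (any(tm < constraints$tm_range[1] | tm > constraints$tm_range[2])) {
    reasons <- c(reasons, "tm")
  }
  list(pass = length(reasons) == 0L, reasons = reasons, gaps = gaps, tm = tm)
}

#' Design an sgRNA library manifest from a genome
#'
#' Convenience wrapper: enumerate sites, apply the off-target mismatch
#' filter, and assign accepted guides to sub-pools. Within a gene, accepted
#' candidates are ranked by position (5'-most first); efficiency scoring is
#' out of scope.
#'
#' @inheritParams enumerate_sites
#' @inheritParams filter_sgrnas
#' @param k_pools Number of primer sub-pools for accepted guides.
#' @return Library manifest data.frame (site columns plus
#'   `min_offtarget_mm`, `accepted`, `reject_reason`, `pool_id`).
#' @export
design_library <- function(genome, threshold = 2L, k_pools = 24L,
                           gene_ids = NULL, max_sites = 1e6) {
  sites <- enumerate_sites(genome, gene_ids = gene_ids, max_sites = max_sites)
  assign_pools(filter_sgrnas(sites, threshold = threshold), k_pools)
}
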