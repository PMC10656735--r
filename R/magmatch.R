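# Cross-validation of MDMS candidates against metagenome assemblies: local
# alignment of each candidate to contigs, the >96% identity match rule, and
# the bin quality filter (completeness >= 50%, contamination <= 10%).

#' Filter bins by completeness and contamination
#'
#' @param bins data.frame with columns bin_id, completeness, contamination
#'   (see [read_bin_metadata()]).
#' @param min_completeness minimum completeness, percent.
#' @param max_contamination maximum contamination, percent.
#' @return the subset of `bins` passing both criteria.
#' @export
filter_bins <- function(bins, min_completeness = 50, max_contamination = 10) {
  bins[bins$completeness >= min_completeness &
       bins$contamination <= max_contamination, , drop = FALSE]
}

# Restrict a long contig to a window around the shared-k-mer region before
# running the full local DP (quadratic in the window, not the contig).
contig_window <- function(query, contig, k, max_full_dp = 20000L) {
  n <- nchar(contig)
  if (n <= max_full_dp) return(c(1L, n))
  kms <- kmer_set(query, k)
  pos <- integer()
  for (km in head(kms, 50)) {
    m <- gregexpr(km, contig, fixed = TRUE)[[1]]
    if (m[1] != -1L) pos <- c(pos, as.integer(m))
  }
  if (length(pos) == 0) return(NULL)
  L <- nchar(query)
  c(max(1L, min(pos) - 2L * L), min(n, max(pos) + 3L * L))
}

#' Screen MDMS candidates against metagenome contigs and bins
#'
#' Each candidate is locally aligned to every contig sharing at least one
#' k-mer with it; the best hit per (candidate, contig) pair is reported with
#' the bin quality of the contig's bin. A hit passes when identity exceeds
#' `min_identity` AND the contig belongs to a bin passing the quality
#' filter. Hits to unbinned contigs are kept as assembly-only evidence
#' (flag ASSEMBLY_ONLY); hits to failing bins are kept with flag BIN_QC;
#' hits covering less than `low_cover_frac` of the candidate are flagged
#' LOW_COVER for manual review rather than rejected.
#'
#' @param mdms named character vector of candidate sequences.
#' @param contigs named character vector of contig sequences.
#' @param bin_info list from [read_bin_metadata()] (or NULL: all contigs
#'   treated as unbinned).
#' @param min_identity percent identity a hit must exceed.
#' @param min_completeness,max_contamination bin filter, see [filter_bins()].
#' @param low_cover_frac overlap_len below this fraction of the candidate
#'   length raises the LOW_COVER flag.
#' @param min_score minimum local alignment score for a reportable hit;
#'   filters the short spurious overlaps that shared k-mers between
#'   unrelated sequences inevitably produce.
#' @param k k-mer size for the contig prefilter.
#' @return data.frame sorted by identity: mdms_id, contig_id, bin_id,
#'   identity, overlap_len, seq_len, node_len, completeness, contamination,
#'   bin_size_bp, passed, flags.
#' @export
match_mdms <- function(mdms, contigs, bin_info = NULL, min_identity = 96,
                       min_completeness = 50, max_contamination = 10,
                       low_cover_frac = 0.5, min_score = 40L, k = 8L) {
  empty <- data.frame(mdms_id = character(), contig_id = character(),
                      bin_id = character(), identity = numeric(),
                      overlap_len = integer(), seq_len = integer(),
                      node_len = integer(), completeness = numeric(),
                      contamination = numeric(), bin_size_bp = numeric(),
                      passed = logical(), flags = character(),
                      stringsAsFactors = FALSE)
  if (length(mdms) == 0 || length(contigs) == 0) return(empty)
  check_seqs(mdms, "MDMS set"); check_seqs(contigs, "contig set")
  membership <- if (!is.null(bin_info)) bin_info$membership else character()
  bins <- if (!is.null(bin_info)) bin_info$bins else
    data.frame(bin_id = character(), completeness = numeric(),
               contamination = numeric(), size_bp = numeric())
  good_bins <- filter_bins(bins, min_completeness, max_contamination)$bin_id
  local_par <- alignment_params(mode = "local")
  rows <- list()
  for (qid in names(mdms)) {
    q <- mdms[[qid]]
    qk <- kmer_set(q, k)
    for (cid in names(contigs)) {
      ctg <- contigs[[cid]]
      if (!any(vapply(qk, function(km) grepl(km, ctg, fixed = TRUE),
                      logical(1))))
        next
      win <- contig_window(q, ctg, k)
      if (is.null(win)) next
      al <- align(mdms[qid], substr(ctg, win[1], win[2]), local_par)
      if (al$aligned_cols == 0 || al$score < min_score) next
      binned <- cid %in% names(membership)
      bin_id <- if (binned) membership[[cid]] else NA_character_
      brow <- if (binned) bins[bins$bin_id == bin_id, ] else NULL
      bin_ok <- binned && bin_id %in% good_bins
      flags <- character()
      if (!binned) flags <- c(flags, "ASSEMBLY_ONLY")
      if (binned && !bin_ok) flags <- c(flags, "BIN_QC")
      if (al$overlap_len < low_cover_frac * nchar(q))
        flags <- c(flags, "LOW_COVER")
      rows[[length(rows) + 1L]] <- data.frame(
        mdms_id = qid, contig_id = cid, bin_id = bin_id,
        identity = al$identity, overlap_len = al$overlap_len,
        seq_len = nchar(q), node_len = nchar(ctg),
        completeness = if (binned) brow$completeness else NA_real_,
        contamination = if (binned) brow$contamination else NA_real_,
        bin_size_bp = if (binned) brow$size_bp else NA_real_,
        passed = al$identity > min_identity && bin_ok,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$identity, out$mdms_id, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
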