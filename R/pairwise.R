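# Pairwise alignment, percent identity / query coverage, and a k-mer
# prefiltered database search that stands in for BLAST at desk scale.

#' Alignment scoring parameters
#'
#' A gap of length L costs `gap_open + (L - 1) * gap_extend`. Ambiguity
#' codes (including N) never match, even against themselves, so identity is
#' conservative.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open cost of opening a gap (<= 0).
#' @param gap_extend cost of extending a gap by one base (<= 0).
#' @param mode "semiglobal" (global with free terminal gaps on both
#'   sequences) or "local" (Smith-Waterman).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(match = 1L, mismatch = -1L, gap_open = -2L,
                             gap_extend = -1L,
                             mode = c("semiglobal", "local")) {
  mode <- match.arg(mode)
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), mode = mode),
            class = "alignment_params")
}

#' Align two sequences
#'
#' Semiglobal mode is a global alignment with free terminal gaps on both
#' sequences; identity is computed over the aligned columns only (terminal
#' gap columns excluded, internal gaps counted as mismatching columns).
#' Query coverage is the percentage of the query spanned by the alignment.
#'
#' @param a query: a single named sequence (or unnamed string).
#' @param b subject: a single named sequence (or unnamed string).
#' @param params an [alignment_params()] object.
#' @return list of class `mdms_alignment` with query_id, subject_id,
#'   identity, query_coverage, matches, aligned_cols, overlap_len, score,
#'   the aligned strings, and 1-based span coordinates.
#' @export
align <- function(a, b, params = alignment_params()) {
  qa <- toupper(as.character(a)[1]); qb <- toupper(as.character(b)[1])
  if (is.na(qa) || is.na(qb) || !nzchar(qa) || !nzchar(qb))
    stop("empty sequence")
  res <- align_cpp(qa, qb, params$match, params$mismatch, params$gap_open,
                   params$gap_extend, params$mode == "local")
  av <- strsplit(res$a_aligned, "", fixed = TRUE)[[1]]
  bv <- strsplit(res$b_aligned, "", fixed = TRUE)[[1]]
  cols <- length(av)
  acgt <- c("A", "C", "G", "T")
  matches <- sum(av == bv & av %in% acgt)
  span_a <- if (cols) res$a_end - res$a_start + 1L else 0L
  span_b <- if (cols) res$b_end - res$b_start + 1L else 0L
  structure(list(
    query_id = if (!is.null(names(a))) names(a)[1] else NA_character_,
    subject_id = if (!is.null(names(b))) names(b)[1] else NA_character_,
    identity = if (cols) 100 * matches / cols else 0,
    query_coverage = 100 * span_a / nchar(qa),
    matches = matches,
    aligned_cols = cols,
    overlap_len = span_b,
    score = res$score,
    a_aligned = res$a_aligned, b_aligned = res$b_aligned,
    a_start = res$a_start, a_end = res$a_end,
    b_start = res$b_start, b_end = res$b_end),
    class = "mdms_alignment")
}

#' @export
print.mdms_alignment <- function(x, ...) {
  cat(sprintf("<alignment %s vs %s: identity %.2f%%, coverage %.1f%%, score %d>\n",
              x$query_id, x$subject_id, x$identity, x$query_coverage,
              x$score))
  invisible(x)
}

hit_row <- function(h) {
  data.frame(query_id = h$query_id, subject_id = h$subject_id,
             identity = h$identity, query_coverage = h$query_coverage,
             matches = h$matches, aligned_cols = h$aligned_cols,
             overlap_len = h$overlap_len, score = h$score,
             stringsAsFactors = FALSE)
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity = numeric(), query_coverage = numeric(),
             matches = integer(), aligned_cols = integer(),
             overlap_len = integer(), score = integer(),
             stringsAsFactors = FALSE)
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Build an indexed reference database
#'
#' @param seqs named character vector of reference sequences.
#' @param lineages character matrix of 7 ranks with row names covering every
#'   sequence id (see [read_lineages()]).
#' @param k k-mer size for the search prefilter.
#' @return list of class `reference_db`.
#' @export
reference_db <- function(seqs, lineages, k = 8L) {
  check_seqs(seqs, "reference db")
  miss <- setdiff(names(seqs), rownames(lineages))
  if (length(miss))
    stop("reference sequence(s) without a lineage: ",
         paste(head(miss, 5), collapse = ", "))
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    for (km in kmer_set(seqs[[i]], k)) idx[[km]] <- c(idx[[km]], i)
  }
  structure(list(seqs = seqs,
                 lineages = lineages[names(seqs), , drop = FALSE],
                 kmer_index = idx, k = as.integer(k)),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db: %d sequences, %d-mer index>\n",
              length(x$seqs), x$k))
  invisible(x)
}

#' Search a query against a reference database
#'
#' Candidate subjects are those sharing at least `min_shared_kmers` k-mers
#' with the query (the whole database when `prefilter = FALSE`, in which
#' case the result provably contains the best-scoring subject). Candidates
#' are aligned semiglobally and ranked by descending alignment score --
#' not identity, because under free-end-gap alignment a short perfect
#' end-overlap between unrelated sequences carries ~100% identity over a
#' handful of columns and would outrank a genuine full-length hit. The
#' identity of the best-scoring alignment is what downstream threshold
#' decisions consume. Ties break by identity, then subject id.
#'
#' @param query single named sequence.
#' @param db a [reference_db()].
#' @param top_n number of hits to return.
#' @param prefilter use the k-mer prefilter.
#' @param min_shared_kmers minimum shared k-mers for a candidate.
#' @param params alignment parameters.
#' @return data.frame of hits (possibly zero rows).
#' @export
search_db <- function(query, db, top_n = 5L, prefilter = TRUE,
                   min_shared_kmers = 1L, params = alignment_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$seqs) == 0) stop("empty reference database")
  q <- toupper(as.character(query)[1])
  cand <- if (prefilter) {
    kms <- kmer_set(q, db$k)
    counts <- table(unlist(lapply(kms, function(km) db$kmer_index[[km]])))
    as.integer(names(counts)[counts >= min_shared_kmers])
  } else seq_along(db$seqs)
  if (length(cand) == 0) return(empty_hit_table())
  hits <- lapply(cand, function(i)
    hit_row(align(query, db$seqs[i], params)))
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$score, -hits$identity, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  head(hits, top_n)
}

#' Best-hit identity of a query against a database
#'
#' The identity of the best-scoring [search_db()] hit.
#'
#' @inheritParams search_db
#' @return percent identity of the top hit, 0 when there is no hit.
#' @export
best_identity <- function(query, db, prefilter = TRUE,
                          params = alignment_params()) {
  h <- search_db(query, db, top_n = 1L, prefilter = prefilter, params = params)
  if (nrow(h) == 0) 0 else h$identity[1]
}
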