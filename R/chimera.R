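# Reference-based bimera screening. A query is modelled as prefix-of-parent-A
# plus suffix-of-parent-B; if the best two-parent model explains materially
# more of the query than the best single parent, the query is flagged
# chimeric. Flagged sequences are annotated, never removed.

# Per-query-position match indicator: TRUE where the query base is aligned
# to an identical unambiguous parent base in the semiglobal alignment.
# Query positions outside the aligned span, opposite a gap, or inserted
# relative to the parent count as mismatches.
match_vector <- function(query, parent, params = alignment_params()) {
  al <- align(query, parent, params)
  L <- nchar(as.character(query)[1])
  m <- logical(L)
  if (al$aligned_cols == 0) return(m)
  av <- strsplit(al$a_aligned, "", fixed = TRUE)[[1]]
  bv <- strsplit(al$b_aligned, "", fixed = TRUE)[[1]]
  qpos <- al$a_start - 1L
  acgt <- c("A", "C", "G", "T")
  for (i in seq_along(av)) {
    if (av[i] != "-") {
      qpos <- qpos + 1L
      m[qpos] <- av[i] == bv[i] && av[i] %in% acgt
    }
  }
  m
}

#' Scan one query for bimeric (two-parent) structure
#'
#' The top `top_k_parents` database hits are taken as candidate parents.
#' For every ordered parent pair (A, B) and breakpoint c (0-based position
#' of the first suffix base, both segments at least `min_segment` bases),
#' the two-parent model scores the A-matches before c plus the B-matches
#' from c on. The query is CHIMERIC when the best two-parent identity
#' exceeds the best single-parent identity by at least `min_delta`
#' percentage points. Pairs with A = B are included, so delta is never
#' negative.
#'
#' @param query single named sequence.
#' @param db a [reference_db()] with at least 2 records.
#' @param top_k_parents number of candidate parents considered.
#' @param min_delta minimum identity gain (percentage points) to call
#'   CHIMERIC.
#' @param min_segment minimum bases in each parental segment.
#' @param prefilter use the k-mer search prefilter.
#' @return one-row data.frame: query_id, parent_a, parent_b, breakpoint,
#'   best_single_identity, chimeric_identity, delta, verdict, reason.
#' @export
bimera_scan <- function(query, db, top_k_parents = 8L, min_delta = 2.0,
                        min_segment = 50L, prefilter = TRUE) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$seqs) < 2) stop("bimera scan needs a database of >= 2 records")
  qid <- names(query)[1] %||% NA_character_
  L <- nchar(as.character(query)[1])
  verdict_row <- function(parent_a = NA_character_, parent_b = NA_character_,
                          breakpoint = NA_integer_, best_single = NA_real_,
                          chimeric = NA_real_, delta = NA_real_,
                          verdict, reason = "") {
    data.frame(query_id = qid, parent_a = parent_a, parent_b = parent_b,
               breakpoint = breakpoint, best_single_identity = best_single,
               chimeric_identity = chimeric, delta = delta,
               verdict = verdict, reason = reason, stringsAsFactors = FALSE)
  }
  if (L < 2L * min_segment)
    return(verdict_row(verdict = "UNDECIDED", reason = "QUERY_TOO_SHORT"))
  hits <- search_db(query, db, top_n = top_k_parents, prefilter = prefilter)
  if (nrow(hits) < 2)
    return(verdict_row(verdict = "UNDECIDED", reason = "TOO_FEW_PARENTS"))
  parents <- hits$subject_id
  mv <- lapply(parents, function(p) match_vector(query, db$seqs[p]))
  names(mv) <- parents
  tot <- vapply(mv, sum, 0L)
  cum <- lapply(mv, cumsum)
  single_best <- max(tot)
  best_single_identity <- 100 * single_best / L

  cps <- min_segment:(L - min_segment)   # prefix lengths = breakpoints
  best <- -1L; best_a <- best_b <- NA_character_; best_c <- NA_integer_
  ord <- sort(parents)                   # lexicographic tie-break
  for (a in ord) {
    for (b in ord) {
      sc <- cum[[a]][cps] + tot[[b]] - cum[[b]][cps]
      mx <- max(sc)
      if (mx > best) {
        # the junction is unidentifiable inside a run of tied breakpoints
        # (where the two parents agree); report the middle of the longest
        # tied run
        ties <- which(sc == mx)
        runs <- split(ties, cumsum(c(1, diff(ties) != 1)))
        run <- runs[[which.max(lengths(runs))]]
        best <- mx; best_a <- a; best_b <- b
        best_c <- cps[run[ceiling(length(run) / 2)]]
      }
    }
  }
  chimeric_identity <- 100 * best / L
  delta <- chimeric_identity - best_single_identity
  verdict <- if (delta >= min_delta && best_a != best_b) "CHIMERIC" else "CLEAN"
  verdict_row(best_a, best_b, best_c, best_single_identity,
              chimeric_identity, delta, verdict)
}

#' Bimera-scan a set of sequences
#'
#' @param seqs named character vector of queries (e.g. MDMS candidates).
#' @inheritParams bimera_scan
#' @return data.frame, one row per query (see [bimera_scan()]).
#' @export
scan_chimeras <- function(seqs, db, top_k_parents = 8L, min_delta = 2.0,
                          min_segment = 50L, prefilter = TRUE) {
  out <- do.call(rbind, lapply(names(seqs), function(id)
    bimera_scan(seqs[id], db, top_k_parents = top_k_parents,
                min_delta = min_delta, min_segment = min_segment,
                prefilter = prefilter)))
  rownames(out) <- NULL
  out
}
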