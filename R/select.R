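# OTU-table normalisation and MDMS candidate selection: retain OTUs with at
# least 50 total reads, convert counts to per-sample relative abundances,
# and keep unassigned OTUs whose relative-abundance summary exceeds 0.5%.

#' Drop OTUs below a minimum total read count
#'
#' @param tab an [otu_table()].
#' @param min_total minimum row sum (reads across all samples) to retain.
#' @return filtered `otu_table`; the sample set is unchanged.
#' @export
filter_min_reads <- function(tab, min_total = 50L) {
  stopifnot(inherits(tab, "otu_table"))
  keep <- rowSums(tab) >= min_total
  out <- unclass(tab)[keep, , drop = FALSE]
  class(out) <- c("otu_table", class(out))
  out
}

#' Convert counts to per-sample relative abundances
#'
#' Each non-empty sample column sums to 1; all-zero columns are left at zero
#' with a warning.
#'
#' @param tab an [otu_table()].
#' @return numeric matrix of the same shape.
#' @export
to_relative <- function(tab) {
  stopifnot(inherits(tab, "otu_table"))
  m <- unclass(tab)
  totals <- colSums(m)
  if (any(totals == 0))
    warning("sample(s) with zero total reads left as all-zero: ",
            paste(colnames(m)[totals == 0], collapse = ", "))
  totals[totals == 0] <- 1
  sweep(m, 2, totals, "/")
}

#' Per-OTU relative-abundance summary
#'
#' Aggregates each OTU's per-sample relative abundances into one percent
#' value. The default aggregate is the sum across samples (so a value of
#' 0.5 means the OTU's relative abundances add up to half a percentage
#' point over the whole survey); mean and max are available.
#'
#' @param tab an [otu_table()].
#' @param summary aggregation across samples: "sum", "mean" or "max".
#' @return named numeric vector, percent units.
#' @export
abundance_summary <- function(tab, summary = c("sum", "mean", "max")) {
  summary <- match.arg(summary)
  rel <- suppressWarnings(to_relative(tab))
  f <- switch(summary, sum = rowSums,
              mean = rowMeans,
              max = function(m) apply(m, 1, max))
  100 * f(rel)
}

#' Select putative MDMS candidates
#'
#' Emits the OTUs flagged unassigned whose relative-abundance summary is
#' strictly greater than `cutoff` percent, sorted by summary descending.
#' The table is expected to be min-read filtered already.
#'
#' @param tab an [otu_table()] (after [filter_min_reads()]).
#' @param rank_calls data.frame from [classify_otus()]; rows for every OTU in
#'   `tab` are required.
#' @param cutoff selection cutoff in percent (strict inequality).
#' @param summary aggregation across samples, see [abundance_summary()].
#' @return data.frame: otu_id, abundance_summary, max_sample_abundance,
#'   unassigned_at ("75", "90", "both" or "none"), best_identity,
#'   novelty_rank.
#' @export
select_mdms <- function(tab, rank_calls, cutoff = 0.5,
                        summary = c("sum", "mean", "max")) {
  summary <- match.arg(summary)
  stopifnot(inherits(tab, "otu_table"))
  empty <- data.frame(otu_id = character(), abundance_summary = numeric(),
                      max_sample_abundance = numeric(),
                      unassigned_at = character(),
                      best_identity = numeric(), novelty_rank = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(empty)
  miss <- setdiff(rownames(tab), rank_calls$otu_id)
  if (length(miss))
    stop("OTU(s) in table without a rank call: ",
         paste(head(miss, 5), collapse = ", "))
  calls <- rank_calls[match(rownames(tab), rank_calls$otu_id), ]
  summ <- abundance_summary(tab, summary)
  rel <- suppressWarnings(to_relative(tab))
  max_ab <- if (ncol(rel)) 100 * apply(rel, 1, max) else rep(0, nrow(rel))
  keep <- calls$unassigned & summ > cutoff
  out <- data.frame(
    otu_id = rownames(tab),
    abundance_summary = summ,
    max_sample_abundance = max_ab,
    unassigned_at = ifelse(calls$unassigned_75 & calls$unassigned_90, "both",
                    ifelse(calls$unassigned_90, "90",
                    ifelse(calls$unassigned_75, "75", "none"))),
    best_identity = calls$best_identity,
    novelty_rank = calls$novelty_rank,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$abundance_summary, out$otu_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
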