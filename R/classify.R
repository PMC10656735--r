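# Unassigned-OTU detection and novelty-rank inference from best-hit
# percent identity, following the 16S identity bands of Yarza-style
# taxonomic threshold proposals: identities at or below 94.5% indicate a
# distinct genus, 86.5% a distinct family, 82% a distinct order, 78.5% a
# distinct class and 75% a distinct phylum.

NOVELTY_LEVELS <- c("NONE", "GENUS", "FAMILY", "ORDER", "CLASS", "PHYLUM",
                    "BEYOND_PHYLUM")

#' Identity thresholds separating taxonomic ranks
#'
#' Boundaries are inclusive on the novel side: a best-hit identity exactly
#' at a threshold is called novel at that rank (94.5% "or lower" means a
#' distinct genus).
#'
#' @param genus,family,order,class_,phylum percent-identity thresholds,
#'   strictly decreasing.
#' @param floor identities below this are flagged `BEYOND_PHYLUM` (likely
#'   artifact rather than biology).
#' @return list of class `rank_thresholds`.
#' @export
rank_thresholds <- function(genus = 94.5, family = 86.5, order = 82.0,
                            class_ = 78.5, phylum = 75.0, floor = 60.0) {
  t <- c(genus = genus, family = family, order = order, class_ = class_,
         phylum = phylum)
  if (any(diff(t) >= 0))
    stop("thresholds must be strictly decreasing genus > ... > phylum")
  if (floor >= phylum) stop("floor must lie below the phylum threshold")
  structure(as.list(c(t, floor = floor)), class = "rank_thresholds")
}

#' Map a best-hit identity to a taxonomic novelty rank
#'
#' @param identity percent identity (vectorised), in [0, 100].
#' @param thresholds a [rank_thresholds()] object.
#' @return character vector over NONE, GENUS, FAMILY, ORDER, CLASS, PHYLUM,
#'   BEYOND_PHYLUM.
#' @export
infer_novelty_rank <- function(identity, thresholds = rank_thresholds()) {
  if (any(is.na(identity)) || any(identity < 0 | identity > 100))
    stop("identity must lie in [0, 100]")
  t <- thresholds
  ifelse(identity > t$genus, "NONE",
  ifelse(identity > t$family, "GENUS",
  ifelse(identity > t$order, "FAMILY",
  ifelse(identity > t$class_, "ORDER",
  ifelse(identity > t$phylum, "CLASS",
  ifelse(identity >= t$floor, "PHYLUM", "BEYOND_PHYLUM"))))))
}

#' Does a query pass an alignment identity threshold?
#'
#' Mirrors reference-alignment screening at the 75% (include in an
#' alignment) and 90% (call a database match) identity thresholds.
#'
#' @param query single named sequence.
#' @param db a [reference_db()].
#' @param threshold percent identity cutoff (canonically 75 or 90).
#' @param prefilter use the k-mer search prefilter.
#' @return TRUE iff the best-hit identity is >= threshold.
#' @export
align_pass <- function(query, db, threshold, prefilter = TRUE) {
  best_identity(query, db, prefilter = prefilter) >= threshold
}

# Number of leading lineage ranks that remain trusted for a novelty rank:
# novelty at rank r means the query is a new r, so the transferred lineage
# keeps everything above r and blanks r and below.
trusted_depth <- function(novelty_rank) {
  c(NONE = 7L, GENUS = 5L, FAMILY = 4L, ORDER = 3L, CLASS = 2L,
    PHYLUM = 1L, BEYOND_PHYLUM = 0L)[novelty_rank]
}

transfer_lineage <- function(lineage_row, novelty_rank) {
  out <- rep(UNKNOWN, 7L)
  names(out) <- colnames(lineage_row) %||% RANK_NAMES
  d <- trusted_depth(novelty_rank)
  if (d > 0) out[seq_len(d)] <- lineage_row[seq_len(d)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify OTU representatives against a reference database
#'
#' For each representative: find the best database hit, map its identity to
#' a novelty rank, transfer the best hit's lineage truncated at the novelty
#' rank (a new genus keeps the lineage through family), and flag the OTU as
#' unassigned at the 75/90 alignment thresholds and at the overall
#' assignment threshold.
#'
#' @param reps named character vector of OTU representative sequences.
#' @param db a [reference_db()].
#' @param thresholds a [rank_thresholds()].
#' @param assign_min_identity best-hit identity below which an OTU counts as
#'   UNASSIGNED (no lineage at any rank).
#' @param align_thresholds the two alignment-screen identity cutoffs.
#' @param prefilter use the k-mer search prefilter.
#' @return data.frame: otu_id, best_subject, best_identity, novelty_rank,
#'   transferred_lineage, unassigned_75, unassigned_90, unassigned.
#' @export
classify_otus <- function(reps, db, thresholds = rank_thresholds(),
                          assign_min_identity = 90,
                          align_thresholds = c(75, 90), prefilter = TRUE) {
  check_seqs(reps, "OTU representatives")
  rows <- lapply(names(reps), function(id) {
    h <- search_db(reps[id], db, top_n = 1L, prefilter = prefilter)
    if (nrow(h) == 0) {
      best_id <- 0; best_subj <- NA_character_
    } else {
      best_id <- h$identity[1]; best_subj <- h$subject_id[1]
    }
    rank <- infer_novelty_rank(best_id, thresholds)
    lin <- if (!is.na(best_subj))
      transfer_lineage(db$lineages[best_subj, , drop = FALSE], rank)
    else rep(UNKNOWN, 7L)
    data.frame(otu_id = id, best_subject = best_subj,
               best_identity = best_id, novelty_rank = rank,
               transferred_lineage = paste(lin, collapse = ";"),
               unassigned_75 = best_id < align_thresholds[1],
               unassigned_90 = best_id < align_thresholds[2],
               unassigned = best_id < assign_min_identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
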