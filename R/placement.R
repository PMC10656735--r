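# Phylogenetic placement of MDMS candidates: gap-frequency masking of a
# reference multiple alignment, reference-coordinate projection of query
# fragments into the masked alignment, Jukes-Cantor distances over shared
# columns, neighbor-joining, and a nearest-reference-lineage report.

msa_char_matrix <- function(rows) {
  if (length(unique(nchar(rows))) != 1)
    stop("alignment rows must all have the same length")
  m <- do.call(rbind, strsplit(unname(as.character(rows)), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Mask alignment columns by gap frequency
#'
#' Columns whose gap fraction exceeds `gap_threshold` are dropped.
#' Masking is idempotent: a `masked_msa` input is re-masked over its
#' already-masked columns.
#'
#' @param msa named character vector of equal-length aligned rows (gap
#'   character `-`), or a `masked_msa`.
#' @param gap_threshold maximum tolerated gap fraction per column.
#' @return list of class `masked_msa`: `rows` (original aligned rows),
#'   `keep` (logical per original column), `masked` (rows over kept
#'   columns), `gap_threshold`.
#' @export
mask_columns <- function(msa, gap_threshold = 0.70) {
  if (inherits(msa, "masked_msa")) {
    inner <- mask_columns(msa$masked, gap_threshold)
    keep <- msa$keep
    keep[keep] <- inner$keep
    return(structure(list(rows = msa$rows, keep = keep,
                          masked = inner$masked,
                          gap_threshold = gap_threshold),
                     class = "masked_msa"))
  }
  m <- msa_char_matrix(msa)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= gap_threshold
  masked <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  structure(list(rows = msa, keep = keep, masked = masked,
                 gap_threshold = gap_threshold),
            class = "masked_msa")
}

#' @export
print.masked_msa <- function(x, ...) {
  cat(sprintf("<masked_msa: %d rows, %d of %d columns kept (gap threshold %.2f)>\n",
              length(x$rows), sum(x$keep), length(x$keep), x$gap_threshold))
  invisible(x)
}

#' Add a query fragment to a masked reference alignment
#'
#' The fragment is aligned (semiglobal) to its best-identity reference
#' sequence in ungapped coordinates, then projected through that reference
#' row's gap pattern into the original alignment columns; insertions in the
#' fragment relative to the reference are discarded, and masked-out or
#' uncovered columns are filled with gaps.
#'
#' @param masked a [mask_columns()] result whose row ids match `db` ids.
#' @param fragment single named sequence.
#' @param db the [reference_db()] used to choose the backbone reference.
#' @param prefilter use the k-mer search prefilter.
#' @return named character of length 1 (the new masked row), or NULL with a
#'   warning when the fragment has no reference hit.
#' @export
add_fragment <- function(masked, fragment, db, prefilter = TRUE) {
  stopifnot(inherits(masked, "masked_msa"))
  hit <- search_db(fragment, db, top_n = 1L, prefilter = prefilter)
  if (nrow(hit) == 0) {
    warning("fragment ", names(fragment)[1],
            " has no reference hit; skipped")
    return(NULL)
  }
  ref_id <- hit$subject_id[1]
  if (!ref_id %in% names(masked$rows))
    stop("reference ", ref_id, " missing from the alignment")
  ref_row <- strsplit(masked$rows[[ref_id]], "", fixed = TRUE)[[1]]
  col_of <- which(ref_row != "-")          # ungapped ref pos -> MSA column
  ref_ungapped <- paste(ref_row[ref_row != "-"], collapse = "")
  al <- align(fragment, ref_ungapped)
  av <- strsplit(al$a_aligned, "", fixed = TRUE)[[1]]
  bv <- strsplit(al$b_aligned, "", fixed = TRUE)[[1]]
  new_row <- rep("-", length(ref_row))
  spos <- al$b_start - 1L
  for (i in seq_along(av)) {
    if (bv[i] != "-") {
      spos <- spos + 1L
      if (av[i] != "-") new_row[col_of[spos]] <- av[i]
    }
  }
  out <- paste(new_row[masked$keep], collapse = "")
  names(out) <- names(fragment)[1]
  out
}

#' Jukes-Cantor distance matrix over shared alignment columns
#'
#' For each pair, columns where both rows carry an unambiguous A/C/G/T base
#' are compared; the p-distance is transformed as d = -3/4 log(1 - 4p/3).
#' Pairs sharing fewer than `min_shared_cols` columns, or whose p-distance
#' is at or beyond the JC saturation point (p >= 0.75), cannot be estimated;
#' they are flagged and filled with 1.1 times the largest finite distance so
#' neighbor-joining sees a complete matrix.
#'
#' @param rows named character vector of equal-length aligned rows.
#' @param min_shared_cols minimum shared ungapped columns per pair.
#' @return symmetric numeric matrix with a logical attribute `flagged`
#'   marking filled-in entries.
#' @export
distance_matrix <- function(rows, min_shared_cols = 50L) {
  m <- msa_char_matrix(rows)
  n <- nrow(m)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  flagged <- matrix(FALSE, n, n, dimnames = dimnames(d))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        shared <- ok[i, ] & ok[j, ]
        ns <- sum(shared)
        if (ns < min_shared_cols) {
          d[i, j] <- d[j, i] <- NA_real_
          flagged[i, j] <- flagged[j, i] <- TRUE
          next
        }
        p <- sum(m[i, shared] != m[j, shared]) / ns
        if (p >= 0.75) {
          d[i, j] <- d[j, i] <- NA_real_
          flagged[i, j] <- flagged[j, i] <- TRUE
        } else {
          d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
        }
      }
    }
  }
  if (any(is.na(d))) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- 1.1 * (if (is.finite(mx) && mx > 0) mx else 1)
  }
  attr(d, "flagged") <- flagged
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via \pkg{ape}); tiny negative
#' branch lengths arising from the least-squares step are clamped to zero.
#'
#' @param d symmetric distance matrix with row/column names.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(as.matrix(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Nearest reference lineage of a placed query leaf
#'
#' The reference leaf minimising path (patristic) distance to the query
#' gives the reported lineage. Exact ties are broken lexicographically and
#' flagged AMBIGUOUS; the caveat flag PHYLUM_CONFLICT is raised when the
#' second-nearest reference disagrees at phylum level.
#'
#' @param tree a `phylo` tree containing `query_leaf`.
#' @param query_leaf tip label of the placed query.
#' @param lineages character matrix of ranks with reference ids as row
#'   names; only tips present here count as references.
#' @return one-row data.frame: mdms_id, nearest_ref, nearest_lineage,
#'   path_distance, flags.
#' @export
nearest_lineage <- function(tree, query_leaf, lineages) {
  if (!query_leaf %in% tree$tip.label) stop("no such leaf: ", query_leaf)
  refs <- intersect(tree$tip.label, rownames(lineages))
  refs <- setdiff(refs, query_leaf)
  if (length(refs) == 0) stop("tree contains no reference leaves")
  dm <- ape::cophenetic.phylo(tree)
  dq <- dm[query_leaf, refs]
  o <- order(dq, refs)
  nearest <- refs[o[1]]
  flags <- character()
  if (length(refs) > 1) {
    second <- refs[o[2]]
    if (dq[o[2]] == dq[o[1]]) flags <- c(flags, "AMBIGUOUS")
    if (lineages[second, "phylum"] != lineages[nearest, "phylum"])
      flags <- c(flags, "PHYLUM_CONFLICT")
  }
  data.frame(mdms_id = query_leaf, nearest_ref = nearest,
             nearest_lineage = format_lineage(lineages[nearest, , drop = FALSE]),
             path_distance = unname(dq[o[1]]),
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Place MDMS fragments on a reference alignment and tree
#'
#' Masks the reference alignment, projects each fragment in, builds one
#' Jukes-Cantor / neighbor-joining tree over references plus fragments, and
#' reports each fragment's nearest reference lineage.
#'
#' @param msa named character vector: the reference multiple alignment.
#' @param fragments named character vector of query fragments.
#' @param db the [reference_db()] (ids must match `msa` rows).
#' @param gap_threshold column mask threshold, see [mask_columns()].
#' @param min_shared_cols see [distance_matrix()].
#' @return list: `tree` (phylo), `report` (data.frame, one row per placed
#'   fragment), `masked` (the masked alignment), `placed` (ids actually
#'   placed).
#' @export
place_mdms <- function(msa, fragments, db, gap_threshold = 0.70,
                       min_shared_cols = 50L) {
  masked <- mask_columns(msa, gap_threshold)
  rows <- masked$masked
  placed <- character()
  for (id in names(fragments)) {
    r <- add_fragment(masked, fragments[id], db)
    if (!is.null(r)) {
      rows[id] <- r
      placed <- c(placed, id)
    }
  }
  if (length(placed) == 0)
    return(list(tree = NULL, report = NULL, masked = masked,
                placed = placed))
  d <- distance_matrix(rows, min_shared_cols)
  tree <- nj_tree(d)
  report <- do.call(rbind, lapply(placed, function(id)
    nearest_lineage(tree, id, db$lineages)))
  rownames(report) <- NULL
  list(tree = tree, report = report, masked = masked, placed = placed)
}
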