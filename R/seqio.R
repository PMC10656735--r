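# Readers and writers for the plain-text formats the pipeline touches.
# Sequences are represented throughout as named character vectors (names =
# unique ids, values = uppercase IUPAC DNA); an optional "desc" attribute
# carries per-record descriptions.

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Sentinel for an unknown rank in a lineage
#' @export
UNKNOWN <- "UNKNOWN"

check_seqs <- function(seqs, what = "sequence set", gapped = FALSE) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    stop(what, ": every record needs a non-empty id")
  if (anyDuplicated(ids))
    stop(what, ": duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(grepl("\\s", ids)))
    stop(what, ": ids must not contain whitespace")
  if (any(!nzchar(seqs)))
    stop(what, ": empty sequence for id ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  alphabet <- c(IUPAC_DNA, if (gapped) "-")
  bad <- grepl(paste0("[^", paste(alphabet, collapse = ""), "]"), seqs)
  if (any(bad))
    stop(what, ": non-IUPAC character in ", paste(ids[bad], collapse = ", "))
  invisible(seqs)
}

#' Read a DNA FASTA file
#'
#' Records are uppercased and validated against the IUPAC DNA alphabet.
#' The first whitespace-delimited token of each header is the id; any
#' remainder is kept in the `desc` attribute.
#'
#' @param path path to a plain (optionally line-wrapped) FASTA file.
#' @param gapped allow the gap character `-` (aligned FASTA).
#' @return named character vector of sequences with a `desc` attribute.
#' @export
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty FASTA: ", path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  attr(seqs, "desc") <- setNames(desc, ids)
  check_seqs(seqs, basename(path), gapped = gapped)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (optionally with a `desc` attribute).
#' @param path output path.
#' @param width line-wrap width.
#' @param gapped allow the gap character `-` (aligned FASTA).
#' @export
write_fasta <- function(seqs, path, width = 70L, gapped = FALSE) {
  check_seqs(seqs, gapped = gapped)
  desc <- attr(seqs, "desc")
  hdr <- names(seqs)
  if (!is.null(desc)) {
    d <- desc[hdr]
    hdr <- ifelse(!is.na(d) & nzchar(d), paste(hdr, d), hdr)
  }
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read an OTU count table
#'
#' Supports a plain TSV (first column `otu_id`, remaining columns one per
#' sample) and the dense BIOM-JSON (format 1.0) dialect. Counts must be
#' non-negative integers.
#'
#' @param path input path.
#' @param dialect "tsv", "biom", or "auto" (by extension / leading brace).
#' @return an `otu_table`: integer matrix, rows = OTUs, columns = samples.
#' @export
read_otu_table <- function(path, dialect = c("auto", "tsv", "biom")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)), 1, 1)
    dialect <- if (first == "{" || grepl("\\.(biom|json)$", path)) "biom"
               else "tsv"
  }
  if (dialect == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("OTU table needs at least one sample column")
    ids <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    mode(counts) <- "numeric"
    rownames(counts) <- ids
  } else {
    b <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (!identical(b$matrix_type, "dense"))
      stop("only dense BIOM-JSON is supported")
    counts <- b$data
    if (is.list(counts)) counts <- do.call(rbind, counts)
    rownames(counts) <- if (is.data.frame(b$rows)) b$rows$id
                        else vapply(b$rows, `[[`, "", "id")
    colnames(counts) <- if (is.data.frame(b$columns)) b$columns$id
                        else vapply(b$columns, `[[`, "", "id")
  }
  otu_table(counts)
}

#' Construct / validate an OTU table
#'
#' @param counts numeric matrix of non-negative integer counts with OTU row
#'   names and sample column names.
#' @return integer matrix of class `otu_table`.
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table needs OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated OTU id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyNA(counts) || !is.numeric(counts))
    stop("non-numeric count in OTU table")
  if (any(counts < 0)) stop("negative count in OTU table")
  if (any(counts != round(counts))) stop("non-integer count in OTU table")
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' Write an OTU table as TSV
#' @param tab an `otu_table`.
#' @param path output path.
#' @export
write_otu_table <- function(tab, path) {
  df <- data.frame(otu_id = rownames(tab), as.data.frame(unclass(tab)),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Parse a `;`-separated lineage string into the 7 canonical ranks
#'
#' Missing trailing ranks and empty fields become `UNKNOWN`. Prefix closure
#' is enforced: once a rank is unknown, every lower rank is truncated to
#' `UNKNOWN` (with a warning when this repairs the input).
#'
#' @param x character vector of lineage strings.
#' @return character matrix, one row per input, columns domain..species.
#' @export
parse_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  out <- matrix(UNKNOWN, nrow = length(x), ncol = 7,
                dimnames = list(NULL, RANK_NAMES))
  repaired <- FALSE
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[seq_len(min(length(p), 7))]
    p[!nzchar(p)] <- UNKNOWN
    out[i, seq_along(p)] <- p
    unk <- which(out[i, ] == UNKNOWN)
    if (length(unk) && unk[1] < 7 && any(out[i, unk[1]:7] != UNKNOWN)) {
      repaired <- TRUE
      out[i, unk[1]:7] <- UNKNOWN
    } else if (length(unk)) {
      out[i, unk[1]:7] <- UNKNOWN
    }
  }
  if (repaired)
    warning("lineage(s) with a named rank below an UNKNOWN rank were ",
            "truncated at the first UNKNOWN")
  out
}

#' Format lineage rows back into `;`-joined strings
#' @param lin character matrix as returned by [parse_lineage()].
#' @export
format_lineage <- function(lin) {
  if (is.null(dim(lin))) lin <- matrix(lin, nrow = 1)
  apply(lin, 1, paste, collapse = ";")
}

#' Read a lineage TSV (`seq_id`, `lineage`)
#'
#' @param path input path.
#' @return character matrix of ranks with `seq_id` row names.
#' @export
read_lineages <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("seq_id", "lineage")
  if (!all(need %in% names(df)))
    stop("lineage TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$seq_id)) stop("duplicated seq_id in lineage TSV")
  lin <- parse_lineage(df$lineage)
  rownames(lin) <- df$seq_id
  lin
}

#' Read bin membership / quality metadata
#'
#' Expects a TSV with columns `bin_id`, `contig_id`, `completeness`,
#' `contamination`, `size_bp` (one row per contig; bin-level fields repeated).
#'
#' @param path input path.
#' @return list with `bins` (one row per bin: bin_id, completeness,
#'   contamination, size_bp) and `membership` (named character vector mapping
#'   contig_id to bin_id).
#' @export
read_bin_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("bin_id", "contig_id", "completeness", "contamination", "size_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bin TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$contig_id))
    stop("contig assigned to more than one bin: ",
         paste(unique(df$contig_id[duplicated(df$contig_id)]), collapse = ", "))
  bins <- unique(df[, c("bin_id", "completeness", "contamination", "size_bp")])
  if (anyDuplicated(bins$bin_id))
    stop("inconsistent quality metadata within a bin")
  if (any(bins$completeness < 0 | bins$completeness > 100))
    stop("completeness must lie in [0, 100]")
  if (any(bins$contamination < 0)) stop("contamination must be >= 0")
  rownames(bins) <- NULL
  list(bins = bins,
       membership = setNames(df$bin_id, df$contig_id))
}

# All tabular outputs share this writer: TSV, header row, no quoting.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
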