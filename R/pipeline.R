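# Pipeline driver: one configuration object holding every threshold, and
# run_all() executing the stages in order (classify -> select -> chimera ->
# verify -> magmatch -> place), writing one TSV per stage plus a summary.

#' Pipeline configuration
#'
#' All thresholds of the pipeline as named keys: the 75/90 alignment
#' screens, the rank identity bands (94.5 / 86.5 / 82 / 78.5 / 75), the
#' 50-read retention minimum, the 0.5% abundance cutoff, the >95% at 100%
#' cover verification rule, the >96% MAG screen, the 50% completeness / 10%
#' contamination bin filter and the 0.70 gap-mask threshold.
#'
#' @param ... overrides of the default keys.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    align_threshold_low = 75, align_threshold_high = 90,
    assign_min_identity = 90,
    rank_genus = 94.5, rank_family = 86.5, rank_order = 82,
    rank_class = 78.5, rank_phylum = 75, rank_floor = 60,
    min_total_reads = 50, abundance_cutoff = 0.5, abundance_summary = "sum",
    chimera_top_k = 8, chimera_min_delta = 2.0, chimera_min_segment = 50,
    pcr_max_mismatches = 2, pcr_three_prime_exact = 3,
    verify_min_identity = 95, verify_review_floor = 94.5,
    mag_min_identity = 96, bin_min_completeness = 50,
    bin_max_contamination = 10, mag_low_cover_frac = 0.5,
    mag_min_score = 40,
    gap_threshold = 0.70, placement_min_shared_cols = 50,
    kmer_k = 8)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline_config key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pct <- c("align_threshold_low", "align_threshold_high",
           "assign_min_identity", "rank_genus", "rank_family", "rank_order",
           "rank_class", "rank_phylum", "rank_floor", "verify_min_identity",
           "verify_review_floor", "mag_min_identity", "bin_min_completeness",
           "bin_max_contamination")
  for (k in pct)
    if (cfg[[k]] < 0 || cfg[[k]] > 100)
      stop(k, " must lie in [0, 100]")
  if (cfg$gap_threshold < 0 || cfg$gap_threshold > 1)
    stop("gap_threshold must lie in [0, 1]")
  if (cfg$min_total_reads < 0) stop("min_total_reads must be >= 0")
  if (!cfg$abundance_summary %in% c("sum", "mean", "max"))
    stop("abundance_summary must be sum, mean or max")
  invisible(cfg)
}

#' Read a pipeline configuration from flat YAML
#'
#' Keys missing from the file keep their defaults; unknown keys error.
#'
#' @param path YAML file with a flat mapping of [pipeline_config()] keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_thresholds <- function(cfg) {
  rank_thresholds(genus = cfg$rank_genus, family = cfg$rank_family,
                  order = cfg$rank_order, class_ = cfg$rank_class,
                  phylum = cfg$rank_phylum, floor = cfg$rank_floor)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the whole MDMS pipeline on an input directory
#'
#' Expects `refs.fasta`, `refs_lineage.tsv`, `otus.fasta` and
#' `otu_table.tsv` in `input_dir`; `refs_aln.fasta`, `contigs.fasta` +
#' `bins.tsv` and `primers.tsv` are optional (their stages are skipped with
#' a warning when absent). Stages run in order classify, select, chimera,
#' verify, magmatch, place; each writes a TSV into `out_dir`, and
#' `summary.json` records the counts at each gate. The run is deterministic:
#' no stage uses random numbers. Finding no MDMS is a clean result, not an
#' error.
#'
#' @param input_dir directory of inputs (see [simulate_community()]).
#' @param out_dir report directory (created).
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list.
#' @export
run_all <- function(input_dir, out_dir, config = pipeline_config()) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(input_dir, f)
  for (f in c("refs.fasta", "refs_lineage.tsv", "otus.fasta",
              "otu_table.tsv"))
    if (!file.exists(path(f))) stop("missing required input: ", f)

  refs <- read_fasta(path("refs.fasta"))
  lineages <- read_lineages(path("refs_lineage.tsv"))
  db <- reference_db(refs, lineages, k = config$kmer_k)
  reps <- read_fasta(path("otus.fasta"))
  tab <- read_otu_table(path("otu_table.tsv"))

  stage_log("classify", length(reps), " OTU representatives vs ",
            length(refs), " references")
  thresholds <- config_thresholds(config)
  calls <- classify_otus(
    reps, db, thresholds,
    assign_min_identity = config$assign_min_identity,
    align_thresholds = c(config$align_threshold_low,
                         config$align_threshold_high))
  write_tsv(calls, file.path(out_dir, "rank_calls.tsv"))

  stage_log("select", "retention >= ", config$min_total_reads,
            " reads; cutoff > ", config$abundance_cutoff, "%")
  kept <- filter_min_reads(tab, config$min_total_reads)
  kept <- kept[intersect(rownames(kept), names(reps)), , drop = FALSE]
  class(kept) <- c("otu_table", "matrix", "array")
  candidates <- select_mdms(kept, calls, cutoff = config$abundance_cutoff,
                            summary = config$abundance_summary)
  write_tsv(candidates, file.path(out_dir, "mdms_candidates.tsv"))
  mdms <- reps[candidates$otu_id]
  if (length(mdms))
    write_fasta(mdms, file.path(out_dir, "mdms_candidates.fasta"))

  stage_log("chimera", length(mdms), " candidates")
  chim <- if (length(mdms))
    scan_chimeras(mdms, db, top_k_parents = config$chimera_top_k,
                  min_delta = config$chimera_min_delta,
                  min_segment = config$chimera_min_segment)
  else NULL
  if (!is.null(chim)) write_tsv(chim, file.path(out_dir, "chimera_report.tsv"))

  verif <- NULL
  contigs <- NULL
  if (file.exists(path("contigs.fasta")))
    contigs <- read_fasta(path("contigs.fasta"))
  if (file.exists(path("primers.tsv")) && length(mdms) && !is.null(contigs)) {
    stage_log("verify", "in-silico PCR against ", length(contigs),
              " templates")
    pairs <- read_primers(path("primers.tsv"))
    verif <- verify_mdms(pairs, contigs, mdms,
                         max_mismatches = config$pcr_max_mismatches,
                         three_prime_exact = config$pcr_three_prime_exact,
                         min_identity = config$verify_min_identity,
                         review_floor = config$verify_review_floor)
    write_tsv(verif, file.path(out_dir, "verification_report.tsv"))
  } else {
    warning("verify stage skipped (primers.tsv, contigs.fasta or ",
            "candidates missing)")
  }

  mags <- NULL
  if (!is.null(contigs) && length(mdms)) {
    stage_log("magmatch", length(mdms), " candidates vs ", length(contigs),
              " contigs")
    bin_info <- if (file.exists(path("bins.tsv")))
      read_bin_metadata(path("bins.tsv")) else NULL
    mags <- match_mdms(mdms, contigs, bin_info,
                       min_identity = config$mag_min_identity,
                       min_completeness = config$bin_min_completeness,
                       max_contamination = config$bin_max_contamination,
                       low_cover_frac = config$mag_low_cover_frac,
                       min_score = config$mag_min_score,
                       k = config$kmer_k)
    write_tsv(mags, file.path(out_dir, "mag_matches.tsv"))
  } else {
    warning("magmatch stage skipped (no contigs.fasta or no candidates)")
  }

  placement <- NULL
  if (file.exists(path("refs_aln.fasta")) && length(mdms)) {
    stage_log("place", length(mdms), " candidates on the reference tree")
    msa <- read_fasta(path("refs_aln.fasta"), gapped = TRUE)
    placement <- place_mdms(msa, mdms, db,
                            gap_threshold = config$gap_threshold,
                            min_shared_cols = config$placement_min_shared_cols)
    if (!is.null(placement$report)) {
      write_tsv(placement$report, file.path(out_dir, "placement_report.tsv"))
      ape::write.tree(placement$tree, file.path(out_dir, "placement.nwk"))
    }
  } else {
    warning("place stage skipped (no refs_aln.fasta or no candidates)")
  }

  summary <- list(
    n_otus = length(reps),
    n_otus_min_reads = nrow(kept),
    n_unassigned = sum(calls$unassigned),
    n_unassigned_75 = sum(calls$unassigned_75),
    n_unassigned_90 = sum(calls$unassigned_90),
    n_mdms_candidates = length(mdms),
    n_chimeric = if (!is.null(chim)) sum(chim$verdict == "CHIMERIC") else 0L,
    n_verified = if (!is.null(verif)) sum(verif$passed) else 0L,
    n_mag_hits = if (!is.null(mags)) nrow(mags) else 0L,
    n_mag_passed = if (!is.null(mags)) sum(mags$passed) else 0L,
    n_placed = if (!is.null(placement)) length(placement$placed) else 0L)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(unclass(config), file.path(out_dir,
                                              "effective_config.yaml"))
  invisible(summary)
}
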