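# Seeded synthetic-community generator: a rank-structured 16S-like reference
# database with a multiple alignment, query sequences at controlled
# divergence bands, bimeras, log-normal OTU count tables, contigs embedding
# candidate sequences, and bins straddling the quality-filter boundaries.
# All randomness uses R's global RNG; callers seed with set.seed().

BASES <- c("A", "C", "G", "T")

#' Random DNA string
#' @param n length in bases.
#' @export
random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

apply_substitutions <- function(v, pos) {
  for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1)
  v
}

#' Evolve a sequence to a target pairwise identity
#'
#' Applies point substitutions (and single-base indels at `indel_rate` of
#' the mutation budget) and re-measures identity with the package's own
#' aligner, adjusting the budget until the realized identity lies within
#' `tol` points of the target. The realized identity is recorded in the
#' `realized_identity` attribute.
#'
#' @param seed_seq a single DNA string.
#' @param target_identity percent identity to aim for.
#' @param indel_rate fraction of mutation events that are indels.
#' @param tol acceptance half-width in identity points.
#' @param max_iter resampling attempts before giving up.
#' @return character(1) with attribute `realized_identity`.
#' @export
evolve <- function(seed_seq, target_identity, indel_rate = 0,
                   tol = 1.0, max_iter = 40L) {
  s <- toupper(as.character(seed_seq)[1])
  L <- nchar(s)
  if (target_identity >= 100)
    return(structure(s, realized_identity = 100))
  k <- max(1L, round(L * (1 - target_identity / 100)))
  for (it in seq_len(max_iter)) {
    k <- max(1L, min(k, L - 1L))
    n_indel <- round(k * indel_rate)
    n_sub <- k - n_indel
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    if (n_sub > 0)
      v <- apply_substitutions(v, sample(L, n_sub))
    if (n_indel > 0) {
      for (e in seq_len(n_indel)) {
        if (runif(1) < 0.5 && length(v) > 1) {
          v <- v[-sample(length(v), 1)]          # deletion
        } else {
          at <- sample(length(v), 1)             # insertion
          v <- append(v, sample(BASES, 1), after = at)
        }
      }
    }
    cand <- paste(v, collapse = "")
    realized <- align(cand, s)$identity
    if (abs(realized - target_identity) <= tol)
      return(structure(cand, realized_identity = realized))
    k <- k + round(L * (realized - target_identity) / 100)
  }
  structure(cand, realized_identity = realized)
}

#' Configuration for the synthetic community
#'
#' Defaults give a 4-phylum x 2 x 2 x 2 x 2 reference hierarchy (64
#' genus-level references) of 450-base sequences (the V3-V4 amplicon scale),
#' 8 samples with log-normal counts at a depth of roughly 15-30k reads per
#' sample (so sub-percent OTUs can still clear the 50-read retention
#' filter, as in a real survey), and a handful of planted novelties,
#' bimeras and contigs.
#'
#' @param ... overrides of the default fields.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_phyla = 4L, classes_per_phylum = 2L, orders_per_class = 2L,
    families_per_order = 2L, genera_per_family = 2L,
    seq_len = 450L,
    # target identity of each rank's ancestor to its parent ancestor
    rank_identity = c(phylum = 78, class = 86, order = 90,
                      family = 93, genus = 96),
    phylum_insert_len = 12L,
    n_samples = 8L, lognormal_meanlog = 7, lognormal_sdlog = 1,
    n_known_otus = 12L,
    plants = c(GENUS = 2L, FAMILY = 2L, ORDER = 2L, CLASS = 2L,
               PHYLUM = 3L),
    n_low_abundance_plants = 2L, low_abundance_summary = 0.3,
    planted_summary_range = c(2, 5),
    n_chimeras = 3L, chimera_summary_range = c(1, 3),
    n_low_count_otus = 3L,
    flank_len = 600L, contig_mutation_rate = 0.005,
    n_decoy_contigs = 3L, n_primer_pairs = 3L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown synth_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synth_config")
}

#' Generate the rank-structured reference database and alignment
#'
#' A root sequence is evolved recursively with per-rank identity targets
#' down to genus-level leaves. Reference evolution is substitution-only, so
#' the alignment is exact by construction; each phylum additionally carries
#' a private insert block whose columns are gapped in the other phyla
#' (75% gap fraction with 4 phyla, i.e. masked at the 0.70 gap threshold).
#'
#' @param cfg a [synth_config()].
#' @return list: `db` (a [reference_db()]), `msa` (named character vector of
#'   aligned rows), `lineages` (rank matrix).
#' @export
make_reference_db <- function(cfg = synth_config()) {
  L <- cfg$seq_len
  root <- random_dna(L)
  t <- cfg$rank_identity
  seqs_base <- character(); lins <- list(); phylum_of <- character()
  for (p in seq_len(cfg$n_phyla)) {
    anc_p <- evolve(root, t[["phylum"]])
    for (cl in seq_len(cfg$classes_per_phylum)) {
      anc_c <- evolve(anc_p, t[["class"]])
      for (o in seq_len(cfg$orders_per_class)) {
        anc_o <- evolve(anc_c, t[["order"]])
        for (f in seq_len(cfg$families_per_order)) {
          anc_f <- evolve(anc_o, t[["family"]])
          for (g in seq_len(cfg$genera_per_family)) {
            leaf <- evolve(anc_f, t[["genus"]])
            id <- sprintf("ref_p%d_c%d_o%d_f%d_g%d", p, cl, o, f, g)
            seqs_base[id] <- as.character(leaf)
            lins[[id]] <- c("Bacteria", sprintf("Phylum%02d", p),
                            sprintf("Class%02d_%d", p, cl),
                            sprintf("Order%02d_%d_%d", p, cl, o),
                            sprintf("Family%02d_%d_%d_%d", p, cl, o, f),
                            sprintf("Genus%02d_%d_%d_%d_%d", p, cl, o, f, g),
                            sprintf("Species_p%d_%d_%d_%d_%d", p, cl, o, f, g))
            phylum_of[id] <- p
          }
        }
      }
    }
  }
  lineages <- do.call(rbind, lins)
  colnames(lineages) <- RANK_NAMES
  # phylum-private insert blocks after evenly spaced base columns
  bl <- cfg$phylum_insert_len
  loci <- round(seq_len(cfg$n_phyla) * L / (cfg$n_phyla + 1))
  blocks <- vapply(seq_len(cfg$n_phyla), function(p) random_dna(bl), "")
  msa <- vapply(names(seqs_base), function(id) {
    v <- strsplit(seqs_base[[id]], "", fixed = TRUE)[[1]]
    out <- character(0)
    prev <- 0L
    for (p in seq_len(cfg$n_phyla)) {
      out <- c(out, v[(prev + 1L):loci[p]],
               if (phylum_of[[id]] == p)
                 strsplit(blocks[p], "", fixed = TRUE)[[1]]
               else rep("-", bl))
      prev <- loci[p]
    }
    paste(c(out, if (prev < L) v[(prev + 1L):L]), collapse = "")
  }, "")
  seqs <- vapply(msa, function(r) gsub("-", "", r, fixed = TRUE), "")
  names(seqs) <- names(msa) <- names(seqs_base)
  list(db = reference_db(seqs, lineages), msa = msa, lineages = lineages)
}

novelty_band <- function(rank, thresholds = rank_thresholds()) {
  t <- thresholds
  switch(rank,
         NONE = c(t$genus, 100),
         GENUS = c(t$family, t$genus),
         FAMILY = c(t$order, t$family),
         ORDER = c(t$class_, t$order),
         CLASS = c(t$phylum, t$class_),
         PHYLUM = c(t$floor, t$phylum),
         stop("no band for rank ", rank))
}

#' Plant a query at a chosen novelty rank
#'
#' Rejection-samples [evolve()] until the query's best database identity
#' (measured with the package's own search) maps to `rank` and lies at
#' least `margin` points inside the rank's identity band.
#'
#' @param db a [reference_db()].
#' @param rank target novelty rank (GENUS .. PHYLUM, or NONE).
#' @param thresholds a [rank_thresholds()].
#' @param margin required distance from the band edges, identity points.
#' @param max_tries attempts before erroring.
#' @return list: seq, seed_ref, best_identity, rank.
#' @export
plant_novel <- function(db, rank, thresholds = rank_thresholds(),
                        margin = 1.0, max_tries = 60L) {
  band <- novelty_band(rank, thresholds)
  lo <- band[1] + margin; hi <- band[2] - if (band[2] < 100) margin else 0
  target <- (lo + hi) / 2
  adj <- target
  for (i in seq_len(max_tries)) {
    seed_ref <- sample(names(db$seqs), 1)
    cand <- evolve(db$seqs[[seed_ref]], adj)
    best <- best_identity(cand, db)
    if (identical(infer_novelty_rank(best, thresholds), rank) &&
        best >= lo && best <= hi)
      return(list(seq = as.character(cand), seed_ref = seed_ref,
                  best_identity = best, rank = rank))
    adj <- max(30, min(99.9, adj - (best - target) * 0.8))
  }
  stop("could not plant a ", rank, "-level query in ", max_tries, " tries")
}

#' Construct a two-parent chimera
#'
#' @param parent_a,parent_b single DNA strings.
#' @param breakpoint_fraction position of the junction as a fraction of the
#'   first parent's length.
#' @return list: seq, breakpoint (0-based position of the first suffix
#'   base).
#' @export
make_chimera <- function(parent_a, parent_b, breakpoint_fraction = 0.5) {
  a <- toupper(as.character(parent_a)[1])
  b <- toupper(as.character(parent_b)[1])
  point <- round(breakpoint_fraction * nchar(a))
  stopifnot(point >= 1, point < nchar(b))
  list(seq = paste0(substr(a, 1, point), substr(b, point + 1, nchar(b))),
       breakpoint = point)
}

#' Build an OTU count table with planted abundance summaries
#'
#' Background OTUs draw log-normal counts per sample; OTUs named in
#' `planted_summary` get per-sample counts tuned so their relative-abundance
#' summary (sum across samples, percent) lands near the requested value;
#' OTUs named in `low_count_ids` total fewer than 50 reads.
#'
#' @param otu_ids character vector of all OTU ids.
#' @param n_samples number of samples.
#' @param meanlog,sdlog log-normal parameters for background counts.
#' @param planted_summary named numeric vector: target percent summaries.
#' @param low_count_ids OTUs forced below the retention threshold.
#' @return an [otu_table()].
#' @export
make_otu_table <- function(otu_ids, n_samples = 8L, meanlog = 3.5,
                           sdlog = 1.2, planted_summary = numeric(),
                           low_count_ids = character()) {
  samples <- sprintf("s%02d", seq_len(n_samples))
  bg_ids <- setdiff(otu_ids, c(names(planted_summary), low_count_ids))
  counts <- matrix(0L, nrow = length(otu_ids), ncol = n_samples,
                   dimnames = list(otu_ids, samples))
  counts[bg_ids, ] <- matrix(
    as.integer(round(rlnorm(length(bg_ids) * n_samples, meanlog, sdlog))) + 1L,
    nrow = length(bg_ids))
  for (id in low_count_ids)
    counts[id, ] <- as.integer(rmultinom(1, sample(10:40, 1),
                                         rep(1, n_samples)))
  base_totals <- colSums(counts)
  for (id in names(planted_summary)) {
    f <- planted_summary[[id]] / (100 * n_samples)  # per-sample rel. abund.
    counts[id, ] <- pmax(1L, as.integer(round(f / (1 - f) * base_totals)))
  }
  otu_table(counts)
}

#' Embed a sequence inside a synthetic contig
#'
#' @param seq the sequence to embed.
#' @param flank_len random flank length on each side.
#' @param mutation_rate per-base substitution rate applied to the embedded
#'   copy.
#' @return list: contig, start (1-based position of the embedded copy),
#'   n_mutations.
#' @export
embed_in_contig <- function(seq, flank_len = 600L, mutation_rate = 0) {
  s <- toupper(as.character(seq)[1])
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n_mut <- rbinom(1, length(v), mutation_rate)
  if (n_mut > 0) v <- apply_substitutions(v, sample(length(v), n_mut))
  list(contig = paste0(random_dna(flank_len), paste(v, collapse = ""),
                       random_dna(flank_len)),
       start = flank_len + 1L, n_mutations = n_mut)
}

#' Assign contigs to bins with a quality spectrum
#'
#' Bin qualities deliberately straddle the completeness >= 50% /
#' contamination <= 10% boundaries; roughly one contig in five is left
#' unbinned (assembly-only).
#'
#' @param contig_ids character vector of contig ids.
#' @return data.frame: bin_id, contig_id, completeness, contamination,
#'   size_bp (one row per binned contig).
#' @export
assign_bins <- function(contig_ids) {
  quality <- data.frame(
    completeness  = c(83.51, 94.64, 54.38, 49.9, 60.0, 96.47),
    contamination = c(0.959, 4.444, 0,     0,    10.1, 0.352),
    size_bp       = c(1528181, 5203795, 529863, 410000, 820000, 2729365))
  n_unbinned <- max(1L, length(contig_ids) %/% 5L)
  binned <- contig_ids[seq_len(length(contig_ids) - n_unbinned)]
  rows <- lapply(seq_along(binned), function(i) {
    q <- quality[((i - 1L) %% nrow(quality)) + 1L, ]
    data.frame(bin_id = sprintf("bin.%d", ((i - 1L) %% nrow(quality)) + 1L),
               contig_id = binned[i], completeness = q$completeness,
               contamination = q$contamination, size_bp = q$size_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a full synthetic input directory
#'
#' Writes every file the pipeline consumes plus machine-readable truth
#' tables: refs.fasta, refs_lineage.tsv, refs_aln.fasta, otus.fasta,
#' otu_table.tsv, contigs.fasta, bins.tsv, primers.tsv and truth/*.tsv.
#'
#' @param out_dir output directory (created).
#' @param seed RNG seed; the whole directory is a deterministic function of
#'   (seed, cfg).
#' @param cfg a [synth_config()].
#' @return invisibly, a list with the truth tables and the paths written.
#' @export
simulate_community <- function(out_dir, seed = 42L, cfg = synth_config()) {
  set.seed(seed)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  ref <- make_reference_db(cfg)
  db <- ref$db
  write_fasta(db$seqs, file.path(out_dir, "refs.fasta"))
  write_tsv(data.frame(seq_id = rownames(ref$lineages),
                       lineage = format_lineage(ref$lineages)),
            file.path(out_dir, "refs_lineage.tsv"))
  write_fasta(ref$msa, file.path(out_dir, "refs_aln.fasta"), gapped = TRUE)

  otus <- character(); truth_plants <- list()
  for (i in seq_len(cfg$n_known_otus)) {
    seed_ref <- sample(names(db$seqs), 1)
    id <- sprintf("otu_known_%02d", i)
    otus[id] <- as.character(evolve(db$seqs[[seed_ref]], 98))
  }
  planted_summary <- numeric()
  for (rank in names(cfg$plants)) {
    for (j in seq_len(cfg$plants[[rank]])) {
      pl <- plant_novel(db, rank)
      id <- sprintf("otu_%s_%d", tolower(rank), j)
      otus[id] <- pl$seq
      summ <- runif(1, cfg$planted_summary_range[1],
                    cfg$planted_summary_range[2])
      planted_summary[id] <- summ
      truth_plants[[id]] <- data.frame(
        otu_id = id, rank = rank, seed_ref = pl$seed_ref,
        best_identity = pl$best_identity, summary_target = summ,
        expected_mdms = pl$best_identity < 90, stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(cfg$n_low_abundance_plants)) {
    pl <- plant_novel(db, "PHYLUM")
    id <- sprintf("otu_lowab_%d", j)
    otus[id] <- pl$seq
    planted_summary[id] <- cfg$low_abundance_summary
    truth_plants[[id]] <- data.frame(
      otu_id = id, rank = "PHYLUM", seed_ref = pl$seed_ref,
      best_identity = pl$best_identity, summary_target = planted_summary[id],
      expected_mdms = FALSE, stringsAsFactors = FALSE)
  }
  truth_plants <- do.call(rbind, truth_plants)

  truth_chim <- list()
  phyla <- unique(db$lineages[, "phylum"])
  for (j in seq_len(cfg$n_chimeras)) {
    pa <- sample(rownames(db$lineages)[db$lineages[, "phylum"] == phyla[1]], 1)
    pb <- sample(rownames(db$lineages)[db$lineages[, "phylum"] == phyla[2]], 1)
    ch <- make_chimera(db$seqs[[pa]], db$seqs[[pb]],
                       runif(1, 0.4, 0.6))
    id <- sprintf("otu_chimera_%d", j)
    otus[id] <- ch$seq
    summ <- runif(1, cfg$chimera_summary_range[1],
                  cfg$chimera_summary_range[2])
    planted_summary[id] <- summ
    best <- best_identity(otus[id], db)
    truth_chim[[id]] <- data.frame(
      otu_id = id, parent_a = pa, parent_b = pb, breakpoint = ch$breakpoint,
      best_identity = best, summary_target = summ,
      expected_mdms = best < 90, stringsAsFactors = FALSE)
  }
  truth_chim <- if (length(truth_chim)) do.call(rbind, truth_chim) else NULL

  low_count_ids <- character()
  for (j in seq_len(cfg$n_low_count_otus)) {
    id <- sprintf("otu_lowcount_%d", j)
    otus[id] <- as.character(evolve(db$seqs[[sample(names(db$seqs), 1)]], 97))
    low_count_ids <- c(low_count_ids, id)
  }

  write_fasta(otus, file.path(out_dir, "otus.fasta"))
  tab <- make_otu_table(names(otus), cfg$n_samples, cfg$lognormal_meanlog,
                        cfg$lognormal_sdlog, planted_summary, low_count_ids)
  write_otu_table(tab, file.path(out_dir, "otu_table.tsv"))

  expected <- c(truth_plants$otu_id[truth_plants$expected_mdms],
                if (!is.null(truth_chim))
                  truth_chim$otu_id[truth_chim$expected_mdms])
  write_tsv(data.frame(otu_id = sort(expected)),
            file.path(out_dir, "truth", "expected_mdms.tsv"))

  # contigs: plants embedded (primer targets verbatim, the rest lightly
  # mutated, one deliberately diverged copy) plus random decoys
  plant_ids <- truth_plants$otu_id[truth_plants$expected_mdms]
  primer_targets <- head(plant_ids, cfg$n_primer_pairs)
  contigs <- character(); truth_contigs <- list()
  for (id in plant_ids) {
    rate <- if (id %in% primer_targets) 0 else cfg$contig_mutation_rate
    emb <- embed_in_contig(otus[[id]], cfg$flank_len, rate)
    cid <- paste0("contig_", id)
    contigs[cid] <- emb$contig
    truth_contigs[[cid]] <- data.frame(
      contig_id = cid, mdms_id = id, start = emb$start,
      n_mutations = emb$n_mutations, stringsAsFactors = FALSE)
  }
  if (length(plant_ids)) {
    # diverged copy of a NON-primer-target plant, so in-silico PCR stays
    # specific for the primer-targeted candidates
    div_id <- plant_ids[length(plant_ids)]
    emb <- embed_in_contig(otus[[div_id]], cfg$flank_len, 0.05)
    contigs["contig_diverged"] <- emb$contig
    truth_contigs[["contig_diverged"]] <- data.frame(
      contig_id = "contig_diverged", mdms_id = div_id,
      start = emb$start, n_mutations = emb$n_mutations,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(cfg$n_decoy_contigs))
    contigs[sprintf("contig_decoy_%d", j)] <- random_dna(1500L)
  write_fasta(contigs, file.path(out_dir, "contigs.fasta"))
  truth_contigs <- do.call(rbind, truth_contigs)
  bins <- assign_bins(names(contigs))
  write_tsv(bins, file.path(out_dir, "bins.tsv"))

  # internal primer sites, so the amplified length is shorter than the
  # original representative (as for re-sequenced fragments)
  primers <- do.call(rbind, lapply(primer_targets, function(id) {
    s <- otus[[id]]; L <- nchar(s)
    data.frame(name = id, fwd = substr(s, 11, 30),
               rev = revcomp(substr(s, L - 29, L - 10)),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(primers))
    write_tsv(primers, file.path(out_dir, "primers.tsv"))

  write_tsv(truth_plants, file.path(out_dir, "truth", "plants.tsv"))
  if (!is.null(truth_chim))
    write_tsv(truth_chim, file.path(out_dir, "truth", "chimeras.tsv"))
  write_tsv(truth_contigs, file.path(out_dir, "truth", "contigs.tsv"))

  invisible(list(dir = out_dir, otus = otus, table = tab, db = db,
                 msa = ref$msa, plants = truth_plants,
                 chimeras = truth_chim, contigs = truth_contigs,
                 expected_mdms = sort(expected), bins = bins))
}
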