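test_that("gap-frequency masking drops columns above 0.70 and is idempotent", {
  msa <- c(a = "ACGT-", b = "AC---", c = "AC-T-", d = "ACGTA")
  # column gap fractions: 0, 0, 0.5, 0.25, 0.75
  m <- mask_columns(msa)
  expect_identical(unname(m$keep), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(unname(m$masked["a"]), "ACGT")
  m2 <- mask_columns(m)
  expect_identical(m2$masked, m$masked)
  gapless <- c(a = "ACGT", b = "TGCA")
  expect_true(all(mask_columns(gapless)$keep))
})

test_that("fragments project through their reference row's gap pattern", {
  ref <- small_db()
  masked <- mask_columns(ref$msa)
  id <- names(ref$db$seqs)[1]
  frag <- setNames(substr(ref$db$seqs[[id]], 40, 320), "frag")
  row <- add_fragment(masked, frag, ref$db)
  expect_identical(unname(nchar(row)), nchar(masked$masked[[1]]))
  ref_row <- strsplit(masked$masked[[id]], "")[[1]]
  new_row <- strsplit(row, "")[[1]]
  covered <- new_row != "-"
  expect_true(any(covered))
  expect_identical(new_row[covered], ref_row[covered])

  # an insertion relative to the reference is discarded by projection
  with_ins <- setNames(paste0(substr(ref$db$seqs[[id]], 40, 150), "GGGGGGGG",
                              substr(ref$db$seqs[[id]], 151, 320)), "ins")
  row2 <- add_fragment(masked, with_ins, ref$db)
  expect_identical(unname(nchar(row2)), nchar(masked$masked[[1]]))

  orphan <- setNames(strrep("GATC", 100), "orphan")
  expect_warning(r <- add_fragment(masked, orphan, ref$db), "no reference hit")
  expect_null(r)
})

test_that("Jukes-Cantor distances match the closed form and ape::dist.dna", {
  rows <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  # one difference in 100 shared columns
  v <- strsplit(rows[["b"]], "")[[1]]; v[1] <- "G"
  rows["b"] <- paste(v, collapse = "")
  d <- distance_matrix(rows)
  expect_equal(d["a", "b"], -0.75 * log(1 - 4 * 0.01 / 3), tolerance = 1e-12)
  expect_equal(d["a", "b"], 0.010067, tolerance = 1e-4)
  expect_identical(d["a", "a"], 0)
  expect_identical(d["a", "b"], d["b", "a"])

  set.seed(73)
  msa <- setNames(vapply(1:5, function(i) random_dna(200), ""),
                  paste0("t", 1:5))
  msa[2] <- as.character(evolve(msa[[1]], 90))
  d2 <- distance_matrix(msa)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(msa), "")))
  ape_d <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                   pairwise.deletion = TRUE))
  ape_d <- ape_d[rownames(d2), colnames(d2)]
  ok <- !attr(d2, "flagged")       # ape yields NaN/Inf at JC saturation
  expect_true(all(abs(d2[ok] - ape_d[ok]) < 1e-9))
})

test_that("pairs with too few shared columns are flagged and filled", {
  rows <- c(a = paste0(strrep("A", 60), strrep("-", 60)),
            b = paste0(strrep("-", 60), strrep("A", 60)),
            c = paste0(strrep("A", 30), strrep("C", 30), strrep("A", 60)))
  d <- distance_matrix(rows)
  fl <- attr(d, "flagged")
  expect_true(fl["a", "b"])            # zero shared columns
  expect_false(fl["a", "c"])
  mx <- max(d[!fl & row(d) != col(d)])
  expect_equal(d["a", "b"], 1.1 * mx)
})

test_that("NJ solves the three-taxon case exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  # three-point formulas: x = (dab + dac - dbc) / 2, etc.
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd["a", "b"], 5)
  expect_equal(cd["a", "c"], 9)
  expect_equal(cd["b", "c"], 10)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["a"]), 2)
  expect_equal(unname(el["b"]), 3)
  expect_equal(unname(el["c"]), 7)
})

test_that("NJ recovers ultrametric four-taxon topologies every time", {
  set.seed(79)
  for (i in 1:10) {
    h <- sort(runif(3, 0.05, 0.5))     # ((a,b),(c,d)) depths
    dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    dm["a", "b"] <- dm["b", "a"] <- 2 * h[1]
    dm["c", "d"] <- dm["d", "c"] <- 2 * h[2]
    for (x in c("a", "b")) for (y in c("c", "d"))
      dm[x, y] <- dm[y, x] <- 2 * h[3]
    tr <- nj_tree(dm)
    truth <- ape::read.tree(text = "((a,b),(c,d));")
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(truth))), 0)
  }
})

test_that("Newick writing round-trips topology and branch lengths", {
  set.seed(83)
  d <- distance_matrix(setNames(vapply(1:6, function(i) random_dna(150), ""),
                                paste0("t", 1:6)))
  tr <- nj_tree(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  tr2 <- ape::read.tree(f)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
  o <- match(paste(tr$tip.label), tr2$tip.label)
  cd1 <- ape::cophenetic.phylo(tr); cd2 <- ape::cophenetic.phylo(tr2)
  expect_equal(cd1, cd2[rownames(cd1), colnames(cd1)], tolerance = 1e-9)
})

test_that("a query grafted next to a reference reports that reference", {
  ref <- small_db()
  db <- ref$db
  frag <- setNames(as.character(evolve(db$seqs[[3]], 97)), "query")
  res <- place_mdms(ref$msa, frag, db)
  expect_identical(res$report$nearest_ref, names(db$seqs)[3])
  expect_identical(res$report$nearest_lineage,
                   unname(format_lineage(db$lineages[3, , drop = FALSE])))
})

test_that("exact ties are flagged AMBIGUOUS and broken lexicographically", {
  d <- matrix(c(0, 2, 1, 1,
                2, 0, 1, 1,
                1, 1, 0, 2,
                1, 1, 2, 0), 4, 4,
              dimnames = list(c("q", "r1", "r2", "r3"),
                              c("q", "r1", "r2", "r3")))
  tr <- nj_tree(d)
  lin <- matrix("X", 3, 7, dimnames = list(c("r1", "r2", "r3"), NULL))
  colnames(lin) <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")
  res <- nearest_lineage(tr, "q", lin)
  cd <- ape::cophenetic.phylo(tr)
  near <- sort(cd["q", c("r1", "r2", "r3")])
  if (near[1] == near[2]) {
    expect_true(grepl("AMBIGUOUS", res$flags))
    expect_identical(res$nearest_ref, names(near)[order(names(near[near == near[1]]))][1])
  }
  expect_identical(res$nearest_ref, names(which.min(cd["q", c("r1", "r2", "r3")])))
})

test_that("community candidates at sub-phylum divergence land in the right phylum", {
  fx <- sim_fixture()
  run <- sim_run()
  rep <- read_out(run, "placement_report.tsv")
  plants <- fx$truth$plants
  sub <- plants[plants$rank %in% c("GENUS", "FAMILY", "ORDER", "CLASS") &
                  plants$expected_mdms, ]
  m <- merge(sub, rep, by.x = "otu_id", by.y = "mdms_id")
  lin_db <- read_lineages(file.path(fx$dir, "refs_lineage.tsv"))
  seed_phy <- lin_db[m$seed_ref, "phylum"]
  got_phy <- vapply(strsplit(m$nearest_lineage, ";"), `[`, "", 2)
  expect_gte(mean(got_phy == seed_phy), 0.9)
})
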