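test_that("a query identical to a database parent is CLEAN with delta 0", {
  db <- small_db()$db
  v <- bimera_scan(setNames(db$seqs[1], "probe"), db)
  expect_identical(v$verdict, "CLEAN")
  expect_equal(v$delta, 0)
  expect_equal(v$chimeric_identity, v$best_single_identity)
})

test_that("a 50/50 bimera of 10%-divergent parents is caught near its junction", {
  set.seed(131)
  pa <- random_dna(400)
  pb <- as.character(evolve(pa, 90))
  seqs <- c(parentA = pa, parentB = pb,
            other1 = random_dna(400), other2 = random_dna(400))
  db <- reference_db(seqs, matrix("X", 4, 7,
                                  dimnames = list(names(seqs), NULL)))
  ch <- make_chimera(pa, pb, 0.5)
  v <- bimera_scan(setNames(ch$seq, "bim"), db)
  expect_identical(v$verdict, "CHIMERIC")
  expect_identical(v$parent_a, "parentA")
  expect_identical(v$parent_b, "parentB")
  expect_gte(v$delta, 2)
  # the junction is identifiable only up to the run between the flanking
  # parent differences; the reported midpoint must stay inside it
  diffs <- which(strsplit(pa, "")[[1]] != strsplit(pb, "")[[1]])
  lo <- max(diffs[diffs <= ch$breakpoint])
  hi <- min(diffs[diffs > ch$breakpoint])
  expect_gte(v$breakpoint, lo)
  expect_lt(v$breakpoint, hi)

  # denser divergence pins the junction more tightly (about half the mean
  # spacing between parent differences)
  set.seed(137)
  pc <- as.character(evolve(pa, 78, tol = 2))
  db2 <- reference_db(c(parentA = pa, parentC = pc),
                      matrix("X", 2, 7,
                             dimnames = list(c("parentA", "parentC"), NULL)))
  ch2 <- make_chimera(pa, pc, 0.5)
  v2 <- bimera_scan(setNames(ch2$seq, "bim2"), db2)
  expect_identical(v2$verdict, "CHIMERIC")
  diffs2 <- which(strsplit(pa, "")[[1]] != strsplit(pc, "")[[1]])
  lo2 <- max(diffs2[diffs2 <= ch2$breakpoint])
  hi2 <- min(diffs2[diffs2 > ch2$breakpoint])
  expect_gte(v2$breakpoint, lo2)
  expect_lt(v2$breakpoint, hi2)
  expect_lte(abs(v2$breakpoint - ch2$breakpoint), (hi2 - lo2))
})

test_that("uniformly spread mutations do not mimic a bimera", {
  db <- small_db()$db
  set.seed(17)
  for (i in 1:5) {
    clean <- evolve(db$seqs[[sample(length(db$seqs), 1)]], 85)
    v <- bimera_scan(setNames(as.character(clean), "clean"), db)
    expect_identical(v$verdict, "CLEAN")
  }
})

test_that("delta is never negative (two parents dominate one)", {
  db <- small_db()$db
  set.seed(23)
  for (i in 1:8) {
    q <- evolve(db$seqs[[sample(length(db$seqs), 1)]],
                sample(c(70, 80, 90), 1))
    v <- bimera_scan(setNames(as.character(q), "q"), db)
    if (v$verdict != "UNDECIDED") expect_gte(v$delta, -1e-9)
  }
})

test_that("scan with all parents equals a brute-force pair/breakpoint search", {
  ref <- small_db()
  db <- ref$db
  set.seed(29)
  pa <- db$seqs[[2]]; pb <- db$seqs[[7]]
  ch <- make_chimera(pa, pb, 0.4)
  q <- setNames(ch$seq, "bim")
  v <- bimera_scan(q, db, top_k_parents = length(db$seqs))

  # independent reconstruction from exported align(): per-parent match
  # vectors projected on query coordinates, exhaustive (A, B, c) scan
  L <- nchar(q[[1]])
  mv <- lapply(names(db$seqs), function(p) {
    al <- align(q, db$seqs[p])
    m <- logical(L)
    av <- strsplit(al$a_aligned, "")[[1]]
    bv <- strsplit(al$b_aligned, "")[[1]]
    qpos <- al$a_start - 1
    for (i in seq_along(av)) {
      if (av[i] != "-") {
        qpos <- qpos + 1
        m[qpos] <- av[i] == bv[i] && av[i] %in% c("A", "C", "G", "T")
      }
    }
    m
  })
  names(mv) <- names(db$seqs)
  best <- -1
  for (a in names(mv)) for (b in names(mv)) {
    ca <- cumsum(mv[[a]]); cb <- cumsum(mv[[b]])
    for (cp in 50:(L - 50)) {
      sc <- ca[cp] + sum(mv[[b]]) - cb[cp]
      if (sc > best) best <- sc
    }
  }
  expect_equal(v$chimeric_identity, 100 * best / L)
})

test_that("degenerate inputs yield UNDECIDED with a reason", {
  db <- small_db()$db
  short <- setNames(substr(db$seqs[[1]], 1, 80), "short")
  v <- bimera_scan(short, db)
  expect_identical(v$verdict, "UNDECIDED")
  expect_identical(v$reason, "QUERY_TOO_SHORT")
  lonely <- setNames(strrep("GATT", 120), "lonely")  # no k-mer in common
  v2 <- bimera_scan(lonely, db)
  expect_identical(v2$verdict, "UNDECIDED")
  expect_identical(v2$reason, "TOO_FEW_PARENTS")
})

test_that("planted bimeras in the community are flagged, plants are not", {
  fx <- sim_fixture()
  run <- sim_run()
  chim <- read_out(run, "chimera_report.tsv")
  truth <- fx$truth$chimeras
  flagged <- chim$query_id[chim$verdict == "CHIMERIC"]
  expect_true(all(truth$otu_id %in% flagged))
  hits <- merge(chim, truth, by.x = "query_id", by.y = "otu_id")
  expect_true(all(abs(hits$breakpoint.x - hits$breakpoint.y) <= 5))
})
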