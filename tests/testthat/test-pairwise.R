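test_that("alignment identity and coverage behave on canonical cases", {
  al <- align(c(q = "ACGTACGT"), c(s = "ACGTACGT"))
  expect_equal(al$identity, 100)
  expect_equal(al$query_coverage, 100)

  # exact substring as query: full coverage, full identity in semiglobal mode
  al2 <- align(c(q = "ACGT"), c(s = "TTACGTTT"))
  expect_equal(al2$identity, 100)
  expect_equal(al2$query_coverage, 100)
  expect_equal(al2$overlap_len, 4L)

  expect_error(align(c(q = ""), c(s = "ACGT")), "empty")
})

test_that("a 30-mer with 3 substitutions aligns at exactly 90% identity", {
  set.seed(11)
  x <- random_dna(30)
  v <- strsplit(x, "")[[1]]
  for (p in sample(30, 3)) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  y <- paste(v, collapse = "")
  al <- align(c(q = x), c(s = y))
  expect_equal(al$identity, 90)
  orc <- oracle_align(x, y)
  expect_identical(al$score, as.integer(orc$score))
  expect_equal(al$identity, orc$identity)
})

test_that("aligner equals the independent DP oracle on 200 random pairs", {
  set.seed(2024)
  for (i in 1:200) {
    a <- random_dna(sample(8:40, 1))
    b <- random_dna(sample(8:40, 1))
    al <- align(c(q = a), c(s = b))
    orc <- oracle_align(a, b)
    expect_identical(al$score, as.integer(orc$score))
    expect_equal(al$identity, orc$identity)
  }
})

test_that("local mode equals the oracle and never scores below zero", {
  set.seed(77)
  par <- alignment_params(mode = "local")
  for (i in 1:50) {
    a <- random_dna(sample(10:40, 1)); b <- random_dna(sample(10:40, 1))
    al <- align(c(q = a), c(s = b), par)
    orc <- oracle_align(a, b, local = TRUE)
    expect_identical(al$score, as.integer(orc$score))
    expect_equal(al$identity, orc$identity)
    expect_gte(al$score, 0)
  }
})

test_that("identity is symmetric under query/subject swap", {
  set.seed(5)
  for (i in 1:25) {
    a <- random_dna(40); b <- as.character(evolve(a, sample(75:99, 1)))
    expect_equal(align(c(q = a), c(s = b))$identity,
                 align(c(q = b), c(s = a))$identity)
  }
})

test_that("mutating a matched position degrades score; identity within slack", {
  # Mutating a position that the optimal alignment pairs as a match always
  # lowers the alignment score. Identity is matches over aligned columns of
  # the new score-optimal alignment, whose column count can shift by a gap,
  # so it is non-increasing only up to one column's worth of slack.
  set.seed(13)
  for (i in 1:60) {
    a <- random_dna(60)
    bs <- as.character(evolve(a, 92))
    al0 <- align(c(q = a), c(s = bs))
    av <- strsplit(al0$a_aligned, "")[[1]]
    bv <- strsplit(al0$b_aligned, "")[[1]]
    bpos <- cumsum(bv != "-") + al0$b_start - 1
    matched <- unique(bpos[av == bv & av %in% c("A", "C", "G", "T")])
    b <- strsplit(bs, "")[[1]]
    p <- sample(matched, 1)
    b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
    al1 <- align(c(q = a), c(s = paste(b, collapse = "")))
    expect_lt(al1$score, al0$score)
    expect_lte(al1$identity, al0$identity + 100 / al1$aligned_cols)
  }
})

test_that("ambiguity codes never count as matches", {
  al <- align(c(q = "ACGTNNNN"), c(s = "ACGTNNNN"))
  expect_equal(al$matches, 4L)   # the N block scores as mismatch even vs N
  expect_lt(al$identity, 100)
})

test_that("database search equals exhaustive align-all ranking", {
  set.seed(303)
  seqs <- setNames(vapply(1:20, function(i) random_dna(120), ""),
                   sprintf("s%02d", 1:20))
  # make a couple of near-duplicates so ranking is non-trivial
  q <- c(q1 = as.character(evolve(seqs[[3]], 95)))
  lin <- matrix("X", nrow = 20, ncol = 7,
                dimnames = list(names(seqs), NULL))
  db <- reference_db(seqs, lin)
  hits <- search_db(q, db, top_n = 20, prefilter = FALSE)
  brute <- do.call(rbind, lapply(names(seqs), function(id) {
    al <- align(q, seqs[id])
    data.frame(subject_id = id, identity = al$identity, score = al$score)
  }))
  brute <- brute[order(-brute$score, -brute$identity, brute$subject_id), ]
  expect_identical(hits$subject_id, brute$subject_id)
  expect_equal(hits$identity, brute$identity)
  expect_identical(hits$subject_id[1], "s03")
})

test_that("prefilter returns nothing without a shared k-mer; best_identity 0", {
  db <- reference_db(c(r1 = strrep("AC", 30)),
                     matrix("X", 1, 7, dimnames = list("r1", NULL)))
  q <- c(q = strrep("GT", 30))  # shares no 8-mer with r1
  expect_identical(nrow(search_db(q, db)), 0L)
  expect_equal(best_identity(q, db), 0)
})

test_that("identical query ranks its database twin first at 100%", {
  ref <- small_db()
  id <- names(ref$db$seqs)[3]
  hits <- search_db(setNames(ref$db$seqs[id], "probe"), ref$db, top_n = 3)
  expect_identical(hits$subject_id[1], id)
  expect_equal(hits$identity[1], 100)
})
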