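test_that("GC content is the plain percentage", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GCGC"), 100)
})

test_that("nearest-neighbor Tm matches the frozen independent oracle", {
  # reference values computed once with an independently coded
  # nearest-neighbor implementation (same unified parameter set, 0.5 uM
  # total strand, 50 mM Na+); frozen here at 0.1 C tolerance
  expect_equal(melting_temp("GCAAGTCAAACCCCGCTTAT"), 56.2063, tolerance = 0.1)
  expect_equal(melting_temp("ACGTACGTACGTACGTACGT"), 57.0595,
               tolerance = 0.1)  # self-complementary: symmetry term + C/1
  expect_equal(melting_temp("ATATATATATATATATATAT"), 28.2122, tolerance = 0.1)
  expect_equal(melting_temp("GAATTCGAATTCGAATTC"), 45.6992, tolerance = 0.1)
  # GC raises Tm at equal length; calls are deterministic
  expect_gt(melting_temp(strrep("ACGT", 5)), melting_temp(strrep("ATAT", 5)))
  expect_identical(melting_temp("GCAAGTCAAACCCCGCTTAT"),
                   melting_temp("GCAAGTCAAACCCCGCTTAT"))
  expect_error(melting_temp("ACGTACG"), "at least 8")
  expect_error(melting_temp("ACGTACGTN"), "unambiguous")
})

test_that("self-dimer run length agrees with a brute-force slide", {
  expect_identical(self_dimer("AAAAAA"), 0L)    # rc is TTTTTT, nothing equal
  expect_identical(self_dimer("GAATTC"), 6L)    # palindrome
  brute <- function(s) {
    x <- strsplit(s, "")[[1]]
    y <- strsplit(revcomp(s), "")[[1]]
    n <- length(x); best <- 0
    for (d in (-(n - 1)):(n - 1)) {
      run <- 0
      for (i in 1:n) {
        j <- i + d
        if (j >= 1 && j <= n && x[i] == y[j]) {
          run <- run + 1
          best <- max(best, run)
        } else run <- 0
      }
    }
    as.integer(best)
  }
  set.seed(41)
  for (i in 1:25) {
    s <- random_dna(20)
    expect_identical(self_dimer(s), brute(s))
  }
})

test_that("in-silico PCR amplifies a verbatim template slice once", {
  set.seed(43)
  tmpl <- random_dna(400)
  fwd <- substr(tmpl, 51, 70)
  rev <- revcomp(substr(tmpl, 301, 320))
  pair <- primer_pair("p1", fwd, rev)
  res <- in_silico_pcr(pair, c(t = tmpl))
  expect_identical(res$reason, "OK")
  expect_identical(unname(res$amplicon), substr(tmpl, 51, 320))

  # three mismatches in the forward primer kill the site
  fv <- strsplit(fwd, "")[[1]]
  for (p in c(2, 5, 8)) fv[p] <- setdiff(c("A", "C", "G", "T"), fv[p])[1]
  bad <- primer_pair("p2", paste(fv, collapse = ""), rev)
  expect_identical(in_silico_pcr(bad, c(t = tmpl))$reason, "NO_PRODUCT")

  # a duplicated locus makes amplification non-specific
  dup <- paste0(tmpl, tmpl)
  expect_identical(in_silico_pcr(pair, c(t = dup))$reason,
                   "MULTIPLE_PRODUCTS")
})

test_that("a mismatch at the primer 3' end is rejected, upstream tolerated", {
  set.seed(47)
  tmpl <- random_dna(300)
  fwd <- substr(tmpl, 21, 40)
  rev <- revcomp(substr(tmpl, 241, 260))
  mod <- function(s, p) {
    v <- strsplit(s, "")[[1]]
    v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  ok <- primer_pair("up", mod(fwd, 5), rev)          # one internal mismatch
  expect_identical(in_silico_pcr(ok, c(t = tmpl))$reason, "OK")
  bad <- primer_pair("end", mod(fwd, 20), rev)       # 3'-terminal mismatch
  expect_identical(in_silico_pcr(bad, c(t = tmpl))$reason, "NO_PRODUCT")
})

test_that("amplicon comparison enforces similarity > 95 at 100% cover", {
  set.seed(53)
  rep <- setNames(random_dna(300), "mdms1")
  # exact internal amplicon: pass
  amp <- setNames(substr(rep[[1]], 21, 280), "amp")
  r <- compare_amplicon(amp, rep)
  expect_true(r$passed)
  expect_equal(r$identity, 100)
  expect_equal(r$query_cover, 100)
  expect_lt(r$amplified_len, r$original_len)

  # exactly 95.0% identity at full cover: fail (strict >) but flag review
  v <- strsplit(substr(rep[[1]], 1, 200), "")[[1]]
  for (p in seq(10, 190, length.out = 10))
    v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  amp95 <- setNames(paste(v, collapse = ""), "amp95")
  r95 <- compare_amplicon(amp95, rep)
  expect_equal(r95$identity, 95)
  expect_false(r95$passed)
  expect_true(r95$review)

  # full identity but incomplete cover: fail regardless
  ampx <- setNames(paste0(substr(rep[[1]], 21, 280), strrep("A", 40)), "ampx")
  rx <- compare_amplicon(ampx, rep)
  expect_lt(rx$query_cover, 100)
  expect_false(rx$passed)
})

test_that("primer QC reports out-of-window GC / Tm and missing 3' clamp", {
  pr <- primer_report(primer_pair("at", strrep("AT", 10), strrep("TA", 10)))
  expect_true(grepl("GC_OUT_OF_RANGE", pr$warnings[1]))
  expect_true(grepl("TM_OUT_OF_RANGE", pr$warnings[1]))
  expect_true(grepl("NO_3PRIME_CLAMP", pr$warnings[1]))
  expect_error(primer_pair("bad", "ACGT", strrep("A", 20)), "length")
  expect_error(primer_pair("amb", strrep("ACGTN", 4), strrep("ACGT", 5)),
               "unambiguous")
})

test_that("a perfect primer pair round-trips any community candidate", {
  fx <- sim_fixture()
  reps <- fx$truth$otus[fx$truth$expected_mdms][1:2]
  set.seed(59)
  for (id in names(reps)) {
    s <- reps[[id]]; L <- nchar(s)
    pair <- primer_pair(id, substr(s, 11, 30), revcomp(substr(s, L - 29, L - 10)))
    tmpl <- setNames(paste0(random_dna(150), s, random_dna(150)), "ctg")
    res <- in_silico_pcr(pair, tmpl)
    expect_identical(res$reason, "OK")
    cmp <- compare_amplicon(res$amplicon, reps[id])
    expect_true(cmp$passed)
    expect_lte(cmp$amplified_len, cmp$original_len)
  }
})
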