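# Existence verification of MDMS candidates: primer quality control,
# in-silico PCR against template sequences, and comparison of the recovered
# amplicon to the original candidate (pass rule: similarity > 95% at 100%
# query cover; identities in (94.5, 95] are flagged for review since they
# may still indicate the same genus).

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                    B = "V", D = "H", H = "D", V = "B")

#' Reverse complement of a DNA string
#' @param seq a single DNA string (IUPAC alphabet).
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  s <- toupper(as.character(seq)[1])
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(DNA_COMPLEMENT[v])), collapse = "")
}

#' GC content of a sequence
#' @param seq a single DNA string.
#' @return percent of G+C bases.
#' @export
gc_content <- function(seq) {
  v <- strsplit(toupper(as.character(seq)[1]), "", fixed = TRUE)[[1]]
  100 * sum(v %in% c("G", "C")) / length(v)
}

# Nearest-neighbor duplex parameters (unified oligonucleotide set of
# Allawi & SantaLucia 1997, Biochemistry 36:10581): dH in kcal/mol,
# dS in cal/(mol K), keyed by the top-strand dinucleotide.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)    # terminal A-T pair initiation
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)   # terminal G-C pair initiation
NN_SYM_DS <- -1.4                      # self-complementary symmetry term

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex Tm from the unified nearest-neighbor parameter set (Allawi &
#' SantaLucia 1997): Tm = dH / (dS + R ln k) - 273.15, where k is the total
#' strand concentration divided by 4 (or by 1 for a self-complementary
#' oligo, which also receives the symmetry entropy term). Salt is corrected
#' on the entropy as dS + 0.368 (N-1) ln[Na+].
#'
#' @param seq a single unambiguous DNA string, length >= 8.
#' @param conc_m total strand concentration, mol/L.
#' @param na_mm monovalent cation concentration, mM.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temp <- function(seq, conc_m = 5e-7, na_mm = 50) {
  s <- toupper(as.character(seq)[1])
  n <- nchar(s)
  if (n < 8) stop("nearest-neighbor model needs at least 8 bases")
  if (grepl("[^ACGT]", s))
    stop("melting_temp requires an unambiguous A/C/G/T sequence")
  steps <- substring(s, 1:(n - 1), 2:n)
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (end in c(substr(s, 1, 1), substr(s, n, n))) {
    init <- if (end %in% c("A", "T")) NN_INIT_AT else NN_INIT_GC
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  selfcomp <- identical(s, revcomp(s))
  if (selfcomp) dS <- dS + NN_SYM_DS
  dS <- dS + 0.368 * (n - 1) * log(na_mm / 1000)
  k <- if (selfcomp) conc_m else conc_m / 4
  R <- 1.987
  dH * 1000 / (dS + R * log(k)) - 273.15
}

#' Longest self-complementary run of a primer
#'
#' Slides the sequence against its own reverse complement over all ungapped
#' offsets and returns the longest contiguous run of matching characters
#' (i.e. the longest perfectly self-annealing stretch).
#'
#' @param seq a single DNA string.
#' @return integer run length (0 when nothing anneals).
#' @export
self_dimer <- function(seq) {
  s <- toupper(as.character(seq)[1])
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  y <- strsplit(revcomp(s), "", fixed = TRUE)[[1]]
  n <- length(x)
  best <- 0L
  for (d in (-(n - 1L)):(n - 1L)) {
    i <- max(1L, 1L - d):min(n, n - d)
    eq <- x[i] == y[i + d]
    run <- 0L
    for (e in eq) {
      run <- if (e) run + 1L else 0L
      if (run > best) best <- run
    }
  }
  best
}

#' Construct / validate a primer pair
#'
#' Both primers are given 5'->3' (the reverse primer on the reverse
#' strand), 15-30 nt, unambiguous bases only.
#'
#' @param name pair name (conventionally the target MDMS id).
#' @param fwd,rev primer sequences.
#' @return list of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  for (p in c(fwd, rev)) {
    if (nchar(p) < 15 || nchar(p) > 30)
      stop("primer length must be 15-30 nt: ", p)
    if (grepl("[^ACGT]", p))
      stop("primers must contain unambiguous A/C/G/T only: ", p)
  }
  structure(list(name = name, fwd = fwd, rev = rev), class = "primer_pair")
}

#' Read a primer TSV (`name`, `fwd`, `rev`)
#' @param path input path.
#' @return list of [primer_pair()] objects.
#' @export
read_primers <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "fwd", "rev")
  if (!all(need %in% names(df)))
    stop("primer TSV must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$name[i], df$fwd[i], df$rev[i]))
}

#' Quality-control report for a primer pair
#'
#' Checks GC content, nearest-neighbor Tm, the longest self-complementary
#' run, the 3' clamp (terminal G/C) and the Tm difference within the pair.
#' Acceptance windows are conventional primer-design defaults and are fully
#' configurable.
#'
#' @param pair a [primer_pair()].
#' @param gc_range acceptable GC window, percent.
#' @param tm_range acceptable Tm window, degrees C.
#' @param max_tm_diff maximum |Tm(fwd) - Tm(rev)|, degrees C.
#' @param max_self_dimer longest tolerated self-complementary run, bases.
#' @return data.frame with one row per primer plus pair-level fields
#'   `tm_difference` and `warnings` (";"-joined, empty when all checks pass).
#' @export
primer_report <- function(pair, gc_range = c(40, 60), tm_range = c(57, 63),
                          max_tm_diff = 3, max_self_dimer = 4) {
  stopifnot(inherits(pair, "primer_pair"))
  per <- lapply(c(fwd = pair$fwd, rev = pair$rev), function(p) {
    list(gc = gc_content(p), tm = melting_temp(p), dimer = self_dimer(p),
         clamp = substr(p, nchar(p), nchar(p)) %in% c("G", "C"))
  })
  tm_diff <- abs(per$fwd$tm - per$rev$tm)
  warn <- character()
  for (side in c("fwd", "rev")) {
    q <- per[[side]]
    if (q$gc < gc_range[1] || q$gc > gc_range[2])
      warn <- c(warn, paste0(side, ":GC_OUT_OF_RANGE"))
    if (q$tm < tm_range[1] || q$tm > tm_range[2])
      warn <- c(warn, paste0(side, ":TM_OUT_OF_RANGE"))
    if (q$dimer > max_self_dimer)
      warn <- c(warn, paste0(side, ":SELF_DIMER"))
    if (!q$clamp) warn <- c(warn, paste0(side, ":NO_3PRIME_CLAMP"))
  }
  if (tm_diff > max_tm_diff) warn <- c(warn, "pair:TM_DIFFERENCE")
  data.frame(name = pair$name, primer = c("fwd", "rev"),
             sequence = c(pair$fwd, pair$rev),
             gc = c(per$fwd$gc, per$rev$gc),
             tm = c(per$fwd$tm, per$rev$tm),
             self_dimer_run = c(per$fwd$dimer, per$rev$dimer),
             three_prime_clamp = c(per$fwd$clamp, per$rev$clamp),
             tm_difference = tm_diff,
             warnings = paste(warn, collapse = ";"),
             stringsAsFactors = FALSE)
}

# All start positions (1-based) where `primer` anneals to `template` on the
# plus strand with <= max_mm mismatches; the bases at the primer's 3' side
# (given by three_prime, a vector of primer positions) must match exactly.
primer_sites <- function(primer, template, max_mm, three_prime) {
  lp <- nchar(primer); lt <- nchar(template)
  if (lt < lp) return(integer())
  pv <- strsplit(primer, "", fixed = TRUE)[[1]]
  tv <- strsplit(template, "", fixed = TRUE)[[1]]
  starts <- 1:(lt - lp + 1)
  keep <- vapply(starts, function(s) {
    w <- tv[s:(s + lp - 1)]
    sum(w != pv) <= max_mm && all(w[three_prime] == pv[three_prime])
  }, logical(1))
  starts[keep]
}

#' In-silico PCR of a primer pair against one template
#'
#' The forward primer is matched on the plus strand and the reverse
#' complement of the reverse primer downstream of it; each site tolerates at
#' most `max_mismatches` mismatches but the `three_prime_exact` bases at the
#' primer 3' end must match exactly. The amplicon spans from the forward
#' primer's 5' base to the reverse primer's 5' base inclusive. Amplification
#' must be specific: zero or more than one product returns no amplicon.
#'
#' @param pair a [primer_pair()].
#' @param template a single (named) template sequence.
#' @param max_mismatches tolerated mismatches per primer site.
#' @param three_prime_exact number of exact 3'-end bases per primer.
#' @return list with `amplicon` (named character of length 1, or NULL) and
#'   `reason` ("OK", "NO_PRODUCT" or "MULTIPLE_PRODUCTS").
#' @export
in_silico_pcr <- function(pair, template, max_mismatches = 2L,
                          three_prime_exact = 3L) {
  stopifnot(inherits(pair, "primer_pair"))
  tmpl <- toupper(as.character(template)[1])
  lf <- nchar(pair$fwd)
  rc_rev <- revcomp(pair$rev)
  lr <- nchar(rc_rev)
  f_sites <- primer_sites(pair$fwd, tmpl, max_mismatches,
                          (lf - three_prime_exact + 1L):lf)
  # the reverse primer's 3' end maps to the LEFTMOST plus-strand base of
  # its site, so the exact bases are the first ones of the rc site
  r_sites <- primer_sites(rc_rev, tmpl, max_mismatches,
                          1L:three_prime_exact)
  products <- list()
  for (f in f_sites) {
    for (r in r_sites) {
      if (r > f + lf - 1L)  # reverse site strictly downstream of forward site
        products[[length(products) + 1L]] <- c(f, r + lr - 1L)
    }
  }
  if (length(products) == 0)
    return(list(amplicon = NULL, reason = "NO_PRODUCT"))
  if (length(products) > 1)
    return(list(amplicon = NULL, reason = "MULTIPLE_PRODUCTS"))
  span <- products[[1]]
  amp <- substr(tmpl, span[1], span[2])
  names(amp) <- paste0(pair$name, "_amplicon")
  list(amplicon = amp, reason = "OK")
}

#' Compare a recovered amplicon to the original MDMS representative
#'
#' The amplicon is the query of a semiglobal alignment against the
#' representative. Verification passes when identity exceeds
#' `min_identity` percent at 100% query cover; identities in
#' (`review_floor`, `min_identity`] at full cover are flagged for review
#' (same-genus relevance).
#'
#' @param amplicon single named sequence (from [in_silico_pcr()]).
#' @param mdms_rep single named sequence, the original representative.
#' @param min_identity strict pass threshold, percent.
#' @param review_floor lower edge of the review band, percent.
#' @return one-row data.frame: mdms_id, original_len, amplified_len,
#'   identity, query_cover, passed, review.
#' @export
compare_amplicon <- function(amplicon, mdms_rep, min_identity = 95,
                             review_floor = 94.5) {
  al <- align(amplicon, mdms_rep)
  full_cover <- al$query_coverage >= 100 - 1e-9
  passed <- al$identity > min_identity && full_cover
  review <- !passed && full_cover &&
    al$identity > review_floor && al$identity <= min_identity
  data.frame(mdms_id = names(mdms_rep)[1] %||% NA_character_,
             original_len = nchar(as.character(mdms_rep)[1]),
             amplified_len = nchar(as.character(amplicon)[1]),
             identity = al$identity,
             query_cover = al$query_coverage,
             passed = passed, review = review, stringsAsFactors = FALSE)
}

#' Verify MDMS candidates by in-silico PCR and re-sequencing comparison
#'
#' Each primer pair (named after its target MDMS) is amplified against every
#' template; amplification must yield exactly one product across the whole
#' template set, which is then compared to the original representative.
#'
#' @param pairs list of [primer_pair()] objects.
#' @param templates named character vector of template sequences (e.g.
#'   metagenome contigs standing in for the re-sequenced sample).
#' @param reps named character vector of MDMS representatives.
#' @param max_mismatches,three_prime_exact see [in_silico_pcr()].
#' @param min_identity,review_floor see [compare_amplicon()].
#' @return data.frame with one row per primer pair: mdms_id, original_len,
#'   amplified_len, identity, query_cover, passed, review, reason.
#' @export
verify_mdms <- function(pairs, templates, reps, max_mismatches = 2L,
                        three_prime_exact = 3L, min_identity = 95,
                        review_floor = 94.5) {
  rows <- lapply(pairs, function(pair) {
    fail <- function(reason)
      data.frame(mdms_id = pair$name,
                 original_len = if (pair$name %in% names(reps))
                   nchar(reps[[pair$name]]) else NA_integer_,
                 amplified_len = NA_integer_, identity = NA_real_,
                 query_cover = NA_real_, passed = FALSE, review = FALSE,
                 reason = reason, stringsAsFactors = FALSE)
    if (!pair$name %in% names(reps)) return(fail("NO_SUCH_MDMS"))
    amps <- list()
    multiple <- FALSE
    for (t in names(templates)) {
      res <- in_silico_pcr(pair, templates[t], max_mismatches,
                           three_prime_exact)
      if (identical(res$reason, "MULTIPLE_PRODUCTS")) multiple <- TRUE
      if (!is.null(res$amplicon)) amps[[length(amps) + 1L]] <- res$amplicon
    }
    if (multiple || length(amps) > 1) return(fail("MULTIPLE_PRODUCTS"))
    if (length(amps) == 0) return(fail("NO_PRODUCT"))
    out <- compare_amplicon(amps[[1]], reps[pair$name],
                            min_identity = min_identity,
                            review_floor = review_floor)
    out$reason <- "OK"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
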