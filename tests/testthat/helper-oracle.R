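# Independent full-matrix Gotoh oracle, written against the documented
# alignment contract: same scoring (match only for equal unambiguous
# A/C/G/T; gap of length L costs gap_open + (L-1)*gap_extend), same end-cell
# rule (max over last row/column, ties prefer larger i+j then larger i) and
# same traceback tie-break (diagonal > gap-in-b > gap-in-a; gap states
# prefer closing over extending). Deliberately plain R matrices, no shared
# code with the package.
oracle_align <- function(a, b, match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1, local = FALSE) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a, consumes b
  F <- matrix(NEG, n + 1, m + 1)  # gap in b, consumes a
  acgt <- c("A", "C", "G", "T")
  s_of <- function(x, y) if (x == y && x %in% acgt) match else mismatch
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open, F[i - 1, j] + gap_extend)
      h <- max(H[i - 1, j - 1] + s_of(av[i - 1], bv[j - 1]), E[i, j], F[i, j])
      if (local && h < 0) h <- 0
      H[i, j] <- h
    }
  }
  best <- if (local) 0 else NEG
  bi <- 0; bj <- 0
  cells <- if (local) {
    expand.grid(i = 0:n, j = 0:m)
  } else {
    rbind(data.frame(i = n, j = 0:m), data.frame(i = 0:n, j = m))
  }
  for (r in seq_len(nrow(cells))) {
    i <- cells$i[r]; j <- cells$j[r]
    h <- H[i + 1, j + 1]
    if (h > best || (h == best &&
                     (i + j > bi + bj || (i + j == bi + bj && i > bi)))) {
      best <- h; bi <- i; bj <- j
    }
  }
  # traceback
  aa <- character(); bb <- character()
  i <- bi; j <- bj; state <- "H"
  repeat {
    if (state == "H") {
      if (local && H[i + 1, j + 1] == 0) break
      if (i == 0 || j == 0) break
      sc <- s_of(av[i], bv[j])
      if (H[i + 1, j + 1] == H[i, j] + sc) {
        aa <- c(av[i], aa); bb <- c(bv[j], bb); i <- i - 1; j <- j - 1
      } else if (H[i + 1, j + 1] == F[i + 1, j + 1]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "F") {
      aa <- c(av[i], aa); bb <- c("-", bb)
      open <- F[i + 1, j + 1] == H[i, j + 1] + gap_open
      i <- i - 1
      state <- if (open) "H" else "F"
    } else {
      aa <- c("-", aa); bb <- c(bv[j], bb)
      open <- E[i + 1, j + 1] == H[i + 1, j] + gap_open
      j <- j - 1
      state <- if (open) "H" else "E"
    }
  }
  cols <- length(aa)
  matches <- sum(aa == bb & aa %in% acgt)
  list(score = best,
       identity = if (cols) 100 * matches / cols else 0,
       matches = matches, aligned_cols = cols)
}
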