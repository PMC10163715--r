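# Independent oracles and small fixture builders used across the suite.

# Full affine-gap local Smith-Waterman in plain R (O(nm); for short
# sequences).  Gap of length L costs go + ge * L.  Returns the score and
# the matched-position map (a-position, b-position) of one optimal
# alignment.  Written independently of the package's aligner.
swOracle <- function(a, b, match = 1, mismatch = -2, go = 5, ge = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in a (move left)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in b (move up)
  ptr <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 1L; bj <- 1L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ge, H[i, j - 1] - go - ge)
      F[i, j] <- max(F[i - 1, j] - ge, H[i - 1, j] - go - ge)
      d <- H[i - 1, j - 1] + if (A[i - 1] == B[j - 1]) match else mismatch
      h <- max(0, d, E[i, j], F[i, j])
      H[i, j] <- h
      ptr[i, j] <- if (h == 0) 0L else if (h == d) 1L else
        if (h == E[i, j]) 3L else 2L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  map <- NULL
  i <- bi; j <- bj
  while (i > 1 && j > 1 && H[i, j] > 0 && ptr[i, j] > 0L) {
    if (ptr[i, j] == 1L) {
      map <- rbind(c(i - 1L, j - 1L), map)
      i <- i - 1L; j <- j - 1L
    } else if (ptr[i, j] == 3L) {
      k <- j - 1L
      while (k > 1L && H[i, k] - (go + ge * (j - k)) < H[i, j]) k <- k - 1L
      j <- k
    } else {
      k <- i - 1L
      while (k > 1L && H[k, j] - (go + ge * (i - k)) < H[i, j]) k <- k - 1L
      i <- k
    }
  }
  colnames(map) <- c("a", "b")
  list(score = best, map = map)
}

# Brute-force permutation scan: rebuilds the match test per assignment
# directly from the call matrix, independent of permutationNull().
bruteForceNull <- function(calls, k, individuals) {
  cmb <- utils::combn(length(individuals), k)
  vapply(seq_len(ncol(cmb)), function(j) {
    cc <- individuals[cmb[, j]]
    ss <- setdiff(individuals, cc)
    sum(vapply(rownames(calls), function(g) {
      v <- calls[g, individuals]
      all(!is.na(v[cc]) & v[cc] == "CC") &&
        all(!is.na(v[ss]) & v[ss] == "S_")
    }, logical(1)))
  }, integer(1))
}

# One-sample Wilcoxon signed-rank (normal approximation, continuity
# correction, average ranks for ties, zeros dropped) written from the
# textbook formula, independent of stats::wilcox.test.
signedRankOracle <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  EV <- n * (n + 1) / 4
  ties <- table(r)
  varV <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- V - EV
  z <- (z - sign(z) * 0.5) / sqrt(varV)
  2 * stats::pnorm(-abs(z))
}

# random nucleotide string
randSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                    replace = TRUE), collapse = "")

# AlleleCounts from two matrices plus generations
makeAC <- function(zc, zs, generation, stage = NULL) {
  cd <- data.frame(generation = generation,
                   row.names = colnames(zc))
  cd$stage <- if (is.null(stage)) rep("late", ncol(zc)) else stage
  AlleleCounts(zc, zs, colData = cd)
}

# small study configuration used by several integration tests
smallStudyConfig <- function(seed = 11L, ...) {
  SimConfig(seed = seed, nGenes = 12L, lengthRange = c(500L, 1200L),
            meanDepth = 600,
            aseGenes = data.frame(gene = 1:2, caveFraction = 0.8),
            deGenes = data.frame(gene = 1:4,
                                 log2fc = c(3, 3, -3, -3),
                                 stage = "both"),
            linkedBlocks = list(list(phenotype = "unpigmented",
                                     genes = 5:6, marker = "M1")),
            f2PhenotypeSpec = c(unpigmented = 3L), ...)
}
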