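# Independent oracles used across the suite.  These deliberately share no
# code with the package implementation paths they check.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

randomPeptide <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Brute-force affine-gap global alignment score (Gotoh, full three-state
# recursion).  A gap of length L costs open + L * ext, matching the
# convention of the alignment wrapper under test.
affineGapScoreOracle <- function(a, b, submat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # av[i] aligned to bv[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes av[i])
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes bv[j])
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Grid-scan isoelectric-point oracle: recomputes the Henderson-Hasselbalch
# net charge from the published Bjellqvist constants on a fine pH grid and
# returns the pH of minimal absolute charge.
gridScanPiOracle <- function(seq, step = 1e-3) {
  chars <- strsplit(toupper(seq), "")[[1]]
  nK <- sum(chars == "K"); nR <- sum(chars == "R"); nH <- sum(chars == "H")
  nD <- sum(chars == "D"); nE <- sum(chars == "E"); nC <- sum(chars == "C")
  nY <- sum(chars == "Y")
  ph <- seq(0, 14, by = step)
  pos <- 10^7.5 / (10^7.5 + 10^ph) +
    nK * 10^10 / (10^10 + 10^ph) +
    nR * 10^12 / (10^12 + 10^ph) +
    nH * 10^5.98 / (10^5.98 + 10^ph)
  neg <- 10^ph / (10^3.55 + 10^ph) +
    nD * 10^ph / (10^4.05 + 10^ph) +
    nE * 10^ph / (10^4.45 + 10^ph) +
    nC * 10^ph / (10^9 + 10^ph) +
    nY * 10^ph / (10^10 + 10^ph)
  ph[which.min(abs(pos - neg))]
}

# Random additive distance matrix from a random tree with known topology.
randomAdditiveCase <- function(nTaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(nTaxa, br = function(n) runif(n, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
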