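test_that("EM recovers a planted motif with its sites", {
  set.seed(1)
  base <- vapply(1:30, function(i) randomPeptide(80), character(1))
  names(base) <- sprintf("s%02d", 1:30)
  planted <- plantMotif(base, "WWHHKKDDEEYY", occurrenceProb = 1, seed = 2)
  mods <- discoverMotifs(planted$seqs, nMotifs = 1, wMin = 10, wMax = 14,
                         seed = 3)
  expect_length(mods, 1L)
  m <- mods[[1]]
  expect_identical(motifConsensus(m), substr("WWHHKKDDEEYY", 1, m@width))
  # >= 90% of the 30 planted sites recovered at exact offsets
  truth <- setNames(planted$spans$start, planted$spans$seq_id)
  found <- motifSites(m)
  hits <- sum(truth[found$seq_id] == found$start)
  expect_gte(hits / nrow(planted$spans), 0.9)
})

test_that("letter-probability rows are stochastic and floored", {
  set.seed(4)
  base <- setNames(vapply(1:12, function(i) randomPeptide(60), character(1)),
                   sprintf("s%d", 1:12))
  pl <- plantMotif(base, "AAWWAAWWAA", seed = 5)
  mods <- discoverMotifs(pl$seqs, nMotifs = 1, wMin = 10, wMax = 10, seed = 6)
  m <- mods[[1]]
  expect_equal(rowSums(motifPpm(m)), rep(1, motifWidth(m)), tolerance = 1e-9)
  expect_true(all(motifPpm(m) > 0))
  expect_true(all(motifIc(m) >= 0 & motifIc(m) <= log2(20) + 1e-9))
})

test_that("the EM objective is monotone non-decreasing", {
  set.seed(7)
  base <- setNames(vapply(1:15, function(i) randomPeptide(70), character(1)),
                   sprintf("s%d", 1:15))
  pl <- plantMotif(base, "MMGGPPLLWW", subRate = 0.2, seed = 8)
  mods <- discoverMotifs(pl$seqs, nMotifs = 1, wMin = 10, wMax = 10, seed = 9)
  tr <- mods[[1]]@trace
  expect_gte(length(tr), 2L)
  expect_true(all(diff(tr) > -1e-8 * (1 + abs(tr[-length(tr)]))))
})

test_that("pure-noise input yields no motif above the signal threshold", {
  set.seed(10)
  noise <- setNames(vapply(1:30, function(i) randomPeptide(80),
                           character(1)), sprintf("n%d", 1:30))
  mods <- discoverMotifs(noise, nMotifs = 3, wMin = 8, wMax = 16, seed = 11)
  expect_length(mods, 0L)
})

test_that("discovery is deterministic for a fixed seed", {
  set.seed(12)
  base <- setNames(vapply(1:15, function(i) randomPeptide(60), character(1)),
                   sprintf("s%d", 1:15))
  pl <- plantMotif(base, "CCNNCCQQEE", seed = 13)
  m1 <- discoverMotifs(pl$seqs, nMotifs = 2, wMin = 8, wMax = 12, seed = 14)
  m2 <- discoverMotifs(pl$seqs, nMotifs = 2, wMin = 8, wMax = 12, seed = 14)
  expect_identical(lapply(m1, motifPpm), lapply(m2, motifPpm))
  expect_identical(lapply(m1, motifSites), lapply(m2, motifSites))
})

test_that("scanning finds the consensus with maximal score", {
  set.seed(15)
  base <- setNames(vapply(1:12, function(i) randomPeptide(60), character(1)),
                   sprintf("s%d", 1:12))
  pl <- plantMotif(base, "WWDDWWKKWW", seed = 16)
  m <- discoverMotifs(pl$seqs, nMotifs = 1, wMin = 10, wMax = 10,
                      seed = 17)[[1]]
  host <- paste0(randomPeptide(25), motifConsensus(m), randomPeptide(25))
  hits <- scanMotif(m, host)
  expect_identical(hits$start[which.max(hits$score)], 26L)
  # shorter than the motif: empty result
  expect_identical(nrow(scanMotif(m, "ACDEF")), 0L)
  # scan recovers at least the EM site list on the training set
  pres <- motifPresenceTable(list(m), pl$seqs)
  expect_true(all(pres[unique(motifSites(m)$seq_id), 1] == 1L))
})

test_that("presence table is block-structured for disjoint planted motifs", {
  set.seed(18)
  gA <- setNames(vapply(1:10, function(i) randomPeptide(70), character(1)),
                 sprintf("a%02d", 1:10))
  gB <- setNames(vapply(1:10, function(i) randomPeptide(70), character(1)),
                 sprintf("b%02d", 1:10))
  pA <- plantMotif(gA, "WWHHKKDDEEYY", seed = 19)
  pB <- plantMotif(gB, "MMGGPPLLCCNN", seed = 20)
  allSeqs <- c(pA$seqs, pB$seqs)
  mA <- discoverMotifs(pA$seqs, nMotifs = 1, wMin = 12, wMax = 12,
                       seed = 21)[[1]]
  mB <- discoverMotifs(pB$seqs, nMotifs = 1, wMin = 12, wMax = 12,
                       seed = 22)[[1]]
  pres <- motifPresenceTable(list(mA, mB), allSeqs, pValue = 1e-6)
  expect_identical(dim(pres), c(20L, 2L))
  expect_true(all(pres[sprintf("a%02d", 1:10), 1] == 1L))
  expect_true(all(pres[sprintf("b%02d", 1:10), 2] == 1L))
  expect_true(all(pres[sprintf("a%02d", 1:10), 2] == 0L))
  expect_true(all(pres[sprintf("b%02d", 1:10), 1] == 0L))
})

test_that("a motif planted only in group-2 tails marks only group-2 rows", {
  dat <- twoClusterData(nPer = 4, seed = 23, ctermLenE = 120L)
  g2 <- grep("^g2_", names(dat$seqs))
  tailStart <- dat$truthE$asp_pos + 1L
  region <- cbind(rep(1L, length(dat$seqs)), nchar(dat$seqs))
  region[g2, 1] <- tailStart
  # restrict planting to group-2 rows by zero-width regions elsewhere
  region[-g2, ] <- 0L
  pl <- plantMotif(dat$seqs, "WWHHKKDDEEYY", occurrenceProb = 1,
                   region = region, seed = 24)
  expect_identical(sort(pl$spans$seq_id),
                   sort(names(dat$seqs)[g2]))
  m <- discoverMotifs(pl$seqs[g2], nMotifs = 1, wMin = 12, wMax = 12,
                      seed = 25)[[1]]
  pres <- motifPresenceTable(list(m), pl$seqs, pValue = 1e-6)
  expect_true(all(pres[g2, 1] == 1L))
  expect_true(all(pres[-g2, 1] == 0L))
})
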