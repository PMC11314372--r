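test_that("scaffold generation round-trips its ground truth", {
  out <- generatePcsSequence(scaffoldSpec("N", includeThr7 = TRUE, seed = 1))
  tri <- detectTriad(out$seq, mode = "scan")
  expect_equal(cysPos(tri), out$truth$cys_pos)
  call <- classifyIsoform(out$seq, tri)
  expect_identical(subtype(call), "N")

  out2 <- generatePcsSequence(scaffoldSpec("E", seed = 2))
  expect_identical(out2$truth$asp_pos - out2$truth$his_pos - 1L, 17L)

  out3 <- generatePcsSequence(scaffoldSpec("D", includeThr7 = FALSE, seed = 3))
  tri3 <- detectTriad(out3$seq, mode = "scan")
  expect_false(checkCk2Context(out3$seq, tri3))
})

test_that("scaffold spec invariants are enforced", {
  expect_error(scaffoldSpec("N", chSpacing = 5), "chSpacing")
  expect_error(scaffoldSpec("E", chSpacing = 10, includeCC = TRUE),
               "CC/CXXXC")
  expect_error(scaffoldSpec("E", ctermCysFrac = 1.5), "ctermCysFrac")
  bg <- rep(0.05, 20); bg[1] <- 0.06
  expect_error(scaffoldSpec("N", background = bg), "simplex")
})

test_that("dataset generation is sized, unique and deterministic", {
  d1 <- generatePcsDataset(5, seed = 11)
  expect_length(d1$seqs, 15L)
  expect_identical(anyDuplicated(names(d1$seqs)), 0L)
  expect_identical(nrow(d1$truth), 15L)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeFasta(d1$seqs, f1)
  writeFasta(generatePcsDataset(5, seed = 11)$seqs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  d2 <- generatePcsDataset(1, seed = 12)
  tris <- annotateTriads(d2$seqs, mode = "scan")
  subs <- vapply(seq_along(d2$seqs), function(i)
    subtype(classifyIsoform(as.character(d2$seqs[[i]]), tris[[i]])),
    character(1))
  expect_identical(subs, d2$truth$subtype)
})

test_that("planted motif spans follow the occurrence probability", {
  set.seed(1)
  base <- vapply(1:20, function(i) randomPeptide(80), character(1))
  all <- plantMotif(base, "WWHHKKDDEEYY", occurrenceProb = 1, seed = 5)
  expect_identical(nrow(all$spans), 20L)
  # planted copies really sit at the recorded offsets
  for (r in 1:5) {
    got <- substr(all$seqs[[all$spans$seq_id[r]]],
                  all$spans$start[r], all$spans$end[r])
    expect_identical(got, "WWHHKKDDEEYY")
  }

  base200 <- vapply(1:200, function(i) randomPeptide(60), character(1))
  half <- plantMotif(base200, "WWHHKKDDEEYY", occurrenceProb = 0.5, seed = 6)
  # 99% binomial interval for n = 200, p = 0.5
  expect_gte(nrow(half$spans), qbinom(0.005, 200, 0.5))
  expect_lte(nrow(half$spans), qbinom(0.995, 200, 0.5))

  expect_error(plantMotif(c(a = "ACDEF"), "WWHHKKDDEEYY"), "shortest")
  expect_error(plantMotif(base, "ACD"), "width")
})

test_that("JTT pair simulation matches the model's expected divergence", {
  p0 <- evolvePair(100, t = 0, seed = 1)
  expect_identical(p0$ancestor, p0$descendant)

  expect_error(evolvePair(100, t = -1), "non-negative")

  p1 <- evolvePair(10000, t = 0.1, seed = 2)
  obs <- mean(strsplit(p1$ancestor, "")[[1]] != strsplit(p1$descendant, "")[[1]])
  pid <- sum(jttEquilibrium() * diag(jttProbMatrix(0.1)))
  expExp <- 1 - pid
  se <- sqrt(expExp * (1 - expExp) / 10000)
  expect_lt(abs(obs - expExp), 3 * se)

  expect_identical(evolvePair(500, 0.3, seed = 9),
                   evolvePair(500, 0.3, seed = 9))
})

test_that("site-difference fraction grows with divergence", {
  diffFrac <- vapply(c(0.01, 0.1, 0.5, 1.0), function(t) {
    p <- evolvePair(10000, t, seed = 42)
    mean(strsplit(p$ancestor, "")[[1]] != strsplit(p$descendant, "")[[1]])
  }, numeric(1))
  expect_true(all(diff(diffFrac) > 0))
})

test_that("no generated scaffold hides a better-scoring competing triad", {
  for (s in 1:100) {
    sub <- c("N", "E", "D")[(s %% 3) + 1]
    out <- generatePcsSequence(scaffoldSpec(sub, chSpacing = 94L + (s %% 62L),
                                            seed = s))
    hit <- detectTriad(out$seq, mode = "scan")
    expect_identical(c(cysPos(hit), hisPos(hit), aspPos(hit)),
                     c(out$truth$cys_pos, out$truth$his_pos,
                       out$truth$asp_pos))
  }
})
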