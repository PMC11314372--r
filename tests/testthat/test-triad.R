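test_that("identical sequences align gap-free with the diagonal score", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  aln <- alignGlobal(s, s)
  expect_identical(aln$alignedQuery, s)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  b62 <- BLOSUM62
  expect_equal(aln$score,
               sum(diag(b62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))
})

test_that("alignment scores match the brute-force affine-gap oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  b62 <- BLOSUM62
  set.seed(7)
  for (k in 1:50) {
    a <- randomPeptide(sample(5:40, 1))
    b <- randomPeptide(sample(5:40, 1))
    expect_equal(alignGlobal(a, b)$score,
                 affineGapScoreOracle(a, b, b62),
                 info = sprintf("pair %d: %s vs %s", k, a, b))
  }
})

test_that("a single gap is opened when the gap penalty dominates", {
  aln <- alignGlobal("ACD", "AD")
  expect_identical(aln$alignedReference, "A-D")
})

test_that("position mapping handles identity, deletions and round trips", {
  s <- "ACDEFGHIKL"
  aln <- alignGlobal(s, s)
  expect_identical(mapPositions(aln, 1:10), 1:10)

  # reference position falling inside a query deletion maps to NA
  alnDel <- list(alignedQuery = "AC---HIKL", alignedReference = "ACDEFHIKL")
  expect_identical(mapPositions(alnDel, c(2L, 4L, 6L)), c(2L, NA, 3L))
  expect_error(mapPositions(alnDel, 10L), "out of range")

  # round trip through the reverse alignment where ungapped
  q <- "MKVACDEFGHIKLMNPQRST"
  r <- "ACDEFGHIKLMNPQRST"
  fwd <- alignGlobal(q, r)
  rev <- list(alignedQuery = fwd$alignedReference,
              alignedReference = fwd$alignedQuery)
  mapped <- mapPositions(fwd, 1:17)
  back <- mapPositions(rev, mapped[!is.na(mapped)])
  expect_identical(back, (1:17)[!is.na(mapped)])
})

test_that("constrained scan recovers scaffolds across the spacing range", {
  ok <- 0L; n <- 0L
  for (s in 1:60) {
    spacing <- 94L + ((s * 7L) %% 62L)
    sub <- c("N", "E", "D")[(s %% 3) + 1]
    out <- generatePcsSequence(scaffoldSpec(sub, chSpacing = spacing,
                                            seed = 1000L + s))
    hit <- detectTriad(out$seq, mode = "scan")
    n <- n + 1L
    ok <- ok + as.integer(triadFound(hit) &&
                            cysPos(hit) == out$truth$cys_pos &&
                            hisPos(hit) == out$truth$his_pos &&
                            aspPos(hit) == out$truth$asp_pos)
  }
  expect_identical(ok, n)
})

test_that("reference alignment recovers triads in homologous queries", {
  ref <- pcsReference()
  truthPos <- c(ref$cys, ref$his, ref$asp)
  protect <- unique(c(truthPos, (ref$cys - 7):(ref$cys + 1),
                      ref$his - 1, ref$his + 1, ref$asp - 1, ref$asp + 1))
  refs <- list(ref)
  for (k in 1:20) {
    q <- mutateSequence(ref$seq, subRate = 0.10, protect = protect,
                        seed = 500L + k)
    # shift all coordinates by a random N-terminal extension
    ext <- 3L + (k %% 9L)
    set.seed(600L + k)
    q <- paste0(randomPeptide(ext, setdiff(AA20, "C")), q)
    hit <- detectTriad(q, references = refs, mode = "align")
    expect_true(triadFound(hit))
    expect_identical(hit@method, "reference_alignment")
    expect_identical(c(cysPos(hit), hisPos(hit), aspPos(hit)),
                     as.integer(truthPos + ext))
  }
})

test_that("spacing accessors equal position differences minus one", {
  # anchored by the canonical triad coordinates 56/162/180: 105 and 17
  tri <- new("TriadAnnotation", found = TRUE, cysPos = 56L, hisPos = 162L,
             aspPos = 180L, context7 = "QVCACYC", method = "constrained_scan",
             score = 2)
  expect_identical(chDistance(tri), 162L - 56L - 1L)
  expect_identical(chDistance(tri), 105L)
  expect_identical(hdDistance(tri), 17L)
})

test_that("sequences without an acceptable triad are flagged, not dropped", {
  set.seed(11)
  junk <- randomPeptide(200, setdiff(AA20, c("C", "H", "D")))
  hit <- detectTriad(junk, mode = "scan")
  expect_false(triadFound(hit))
  expect_identical(hit@method, "none")
  expect_error(detectTriad("ACDEF"), "too short")
  expect_warning(annotateTriads(c(x = junk), mode = "scan"), "x")
})
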