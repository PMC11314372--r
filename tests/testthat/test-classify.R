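# Helper: build a minimal sequence with a chosen 7-mer context at the
# catalytic Cys, a His after `spacing` residues and an Asp 18 after the His.
contextScaffold <- function(context7, spacing = 100L, segment = NULL) {
  stopifnot(nchar(context7) == 7L, endsWith(context7, "C"))
  set.seed(99)
  if (is.null(segment))
    segment <- randomPeptide(spacing, setdiff(AA20, c("C", "H")))
  paste0(randomPeptide(49, setdiff(AA20, "C")), context7, segment, "H",
         randomPeptide(17, setdiff(AA20, c("H", "D"))), "D",
         randomPeptide(30))
}

triadOf <- function(s) detectTriad(s, mode = "scan")

test_that("the residue at Cys-4 drives the subtype and group", {
  sN <- contextScaffold("QNNQAYC")
  callN <- classifyIsoform(sN, triadOf(sN))
  expect_identical(subtype(callN), "N")
  expect_identical(isoformGroup(callN), 1L)

  sD <- contextScaffold("QSDPAYC")
  callD <- classifyIsoform(sD, triadOf(sD))
  expect_identical(subtype(callD), "D")
  expect_identical(isoformGroup(callD), 2L)

  sE <- contextScaffold("QEEPQYC")
  callE <- classifyIsoform(sE, triadOf(sE))
  expect_identical(subtype(callE), "E")
  expect_identical(isoformGroup(callE), 2L)

  # any other residue at -4 stays unclassified with no group
  sQ <- contextScaffold("QSQPAYC")
  callQ <- classifyIsoform(sQ, triadOf(sQ))
  expect_identical(subtype(callQ), "unclassified")
  expect_true(is.na(isoformGroup(callQ)))
})

test_that("the CK2 call needs S/T at -7 and D/E at -4", {
  sYes <- contextScaffold("AAEPAYC")
  sYes <- paste0(substr(sYes, 1, 48), "T", substr(sYes, 50, nchar(sYes)))
  expect_true(checkCk2Context(sYes, triadOf(sYes)))

  sNo1 <- contextScaffold("AANQAYC")   # N at -4
  sNo1 <- paste0(substr(sNo1, 1, 48), "T", substr(sNo1, 50, nchar(sNo1)))
  expect_false(checkCk2Context(sNo1, triadOf(sNo1)))

  # the diatom "D" case: D at -4 but Asn instead of Thr at -7
  sNo2 <- contextScaffold("AADPAYC")
  sNo2 <- paste0(substr(sNo2, 1, 48), "N", substr(sNo2, 50, nchar(sNo2)))
  expect_false(checkCk2Context(sNo2, triadOf(sNo2)))
})

test_that("CC and CXXXC hits are found only between catalytic Cys and His", {
  seg <- strsplit(randomPeptide(100, setdiff(AA20, c("C", "H"))), "")[[1]]
  seg[c(34, 35)] <- "C"          # CC at offsets 34-35 after the Cys
  seg[c(53, 57)] <- "C"          # CXXXC at 53..57
  s <- contextScaffold("QEEPQYC", segment = paste(seg, collapse = ""))
  tri <- triadOf(s)
  hits <- findConservedCys(s, tri)
  expect_identical(hits$cc, cysPos(tri) + 34L)
  expect_identical(hits$cxxxc, cysPos(tri) + 53L)
  expect_identical(hits$conservedCount, 4L)

  sNone <- contextScaffold("QNNQAYC")
  hits0 <- findConservedCys(sNone, triadOf(sNone))
  expect_length(hits0$cc, 0L)
  expect_length(hits0$cxxxc, 0L)
  expect_identical(hits0$conservedCount, 0L)
})

test_that("cysteine counting and tail length are exact", {
  expect_identical(countCys("ACCA"), 2L)
  s <- contextScaffold("QNNQAYC")
  tri <- triadOf(s)
  expect_identical(ctermTail(s, tri), nchar(s) - aspPos(tri))
  sEnd <- substr(s, 1, aspPos(tri))
  expect_identical(ctermTail(sEnd, triadOf(sEnd)), 0L)
})

test_that("subtype recovery is exact on a mixed synthetic dataset", {
  d <- generatePcsDataset(34, seed = 21)   # 102 scaffolds
  tris <- annotateTriads(d$seqs, mode = "scan")
  calls <- lapply(seq_along(d$seqs), function(i)
    classifyIsoform(as.character(d$seqs[[i]]), tris[[i]]))
  expect_identical(vapply(calls, subtype, character(1)), d$truth$subtype)
  grp <- vapply(calls, isoformGroup, integer(1))
  expect_identical(grp, ifelse(d$truth$subtype == "N", 1L, 2L))
  # CK2 dichotomy: E scaffolds (Thr planted) competent, N scaffolds never
  ck2 <- vapply(calls, ck2Competent, logical(1))
  expect_true(all(ck2[d$truth$subtype == "E"]))
  expect_false(any(ck2[d$truth$subtype == "N"]))
})

test_that("column information content matches closed-form cases", {
  expect_equal(columnInformation(c("C", "C", "C"))$ic, log2(20))
  block20 <- AA20
  expect_equal(columnInformation(block20)$ic, 0)
  halfhalf <- c(rep("A", 10), rep("V", 10))
  expect_equal(columnInformation(halfhalf)$ic, log2(20) - 1)
  expect_error(columnInformation(character(0)), "empty")
  expect_error(columnInformation(c("A-", "AA")), "gaps")
})
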