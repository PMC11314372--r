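test_that("JTT ML distance is zero for identical sequences and symmetric", {
  set.seed(2)
  s <- randomPeptide(200)
  expect_identical(jttMlDistance(s, s)$distance, 0)
  p <- evolvePair(500, 0.4, seed = 3)
  d1 <- jttMlDistance(p$ancestor, p$descendant)$distance
  d2 <- jttMlDistance(p$descendant, p$ancestor)$distance
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("JTT ML distance recovers the simulated divergence", {
  p <- evolvePair(10000, 0.2, seed = 5)
  fit <- jttMlDistance(p$ancestor, p$descendant)
  expect_lt(abs(fit$distance - 0.2), 3 * fit$se)
})

test_that("the fitted distance is a local likelihood optimum", {
  pi0 <- jttEquilibrium()
  loglik <- function(a, b, t) {
    ai <- match(strsplit(a, "")[[1]], names(pi0))
    bi <- match(strsplit(b, "")[[1]], names(pi0))
    p <- jttProbMatrix(t)
    sum(log(pi0[ai] * p[cbind(ai, bi)]))
  }
  for (k in 1:50) {
    p <- evolvePair(300, runif(1, 0.05, 1.5), seed = 100 + k)
    t_hat <- jttMlDistance(p$ancestor, p$descendant)$distance
    ll <- loglik(p$ancestor, p$descendant, t_hat)
    expect_gte(ll + 1e-7, loglik(p$ancestor, p$descendant, t_hat + 0.01))
    expect_gte(ll + 1e-7, loglik(p$ancestor, p$descendant,
                                 max(t_hat - 0.01, 1e-8)))
  }
})

test_that("JTT ML distances agree with an established implementation", {
  skip_if_not_installed("phangorn")
  for (k in 1:5) {
    p <- evolvePair(1000, c(0.05, 0.2, 0.5, 1, 2)[k], seed = 50 + k)
    mine <- jttMlDistance(p$ancestor, p$descendant)$distance
    pd <- phangorn::phyDat(rbind(a = strsplit(p$ancestor, "")[[1]],
                                 b = strsplit(p$descendant, "")[[1]]),
                           type = "AA")
    ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))["a", "b"]
    expect_equal(mine, ref, tolerance = 0.02 * max(ref, 0.05))
  }
})

test_that("gapped and X columns are removed pairwise", {
  a <- "AC-DXF"
  b <- "ACWD-F"
  fit <- jttMlDistance(a, b)
  expect_identical(fit$sites, 4L)   # positions 1, 2, 4, 6
  expect_warning(out <- jttMlDistance("---", "AAA"), "no overlapping")
  expect_true(is.na(out$distance))
})

test_that("NJ on a 3-taxon matrix uses the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  # external branches: (d_AB + d_AC - d_BC)/2 etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 1)
  expect_equal(unname(bl["B"]), 2)
  expect_equal(unname(bl["C"]), 3)
  expect_error(njTree(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ reproduces random additive trees exactly", {
  skip_if_not_installed("phangorn")
  for (k in 1:50) {
    nTaxa <- 5 + (k %% 8)
    case <- randomAdditiveCase(nTaxa, seed = 300 + k)
    rec <- njTree(case$d)
    expect_identical(phangorn::RF.dist(rec, case$tree), 0L)
    # branch lengths: patristic distances match the generating matrix
    expect_equal(ape::cophenetic.phylo(rec)[rownames(case$d),
                                            colnames(case$d)],
                 case$d, tolerance = 1e-9)
  }
})

test_that("bootstrap supports are reproducible and bounded", {
  d <- generatePcsDataset(2, seed = 31, ctermLen = 0L)
  aln <- stackAlignment(d$seqs)
  t1 <- bootstrapSupports(aln, nReplicates = 20, seed = 9)
  t2 <- bootstrapSupports(aln, nReplicates = 20, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  sup <- t1$node.label[!is.na(t1$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_setequal(t1$tip.label, names(d$seqs))
})

test_that("two groups evolved from distinct ancestors split cleanly", {
  tr <- twoClusterTree(nPer = 4, bootstrap = 50, seed = 77)
  ids1 <- grep("^g1_", tr$tip.label, value = TRUE)
  expect_length(ids1, 4L)
  sup <- splitSupport(tr, ids1)
  expect_gte(sup, 95)
})
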