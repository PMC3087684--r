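test_that("BM simulation honors rate, root and seed contracts", {
  tr <- simulateYuleTree(16, seed = 1)
  expect_equal(unname(simulateBM(tr, 0, 3.5, seed = 2)), rep(3.5, 16))
  x1 <- simulateBM(tr, 1, 0, seed = 7)
  x2 <- simulateBM(tr, 1, 0, seed = 7)
  expect_identical(x1, x2)
  expect_false(identical(x1, simulateBM(tr, 1, 0, seed = 8)))
  trm <- parseNewick("((A,B),C);")
  expect_error(simulateBM(trm, 1, 0, seed = 1), "missing branch lengths")
})

test_that("BM marginal tip variance on a star equals sigma2 x depth", {
  st <- starTree(paste0("t", 1:10000), branchLength = 2.5)
  x <- simulateBM(st, sigma2 = 3, rootValue = 1, seed = 42)
  expect_equal(var(x), 3 * 2.5, tolerance = 0.05 * 3 * 2.5)
  expect_equal(mean(x), 1, tolerance = 0.1)
})

test_that("correlated BM recovers the trait correlation through contrasts", {
  tr <- simulateYuleTree(64, seed = 3)
  Sigma <- matrix(c(1, 0.8, 0.8, 1), 2)
  rs <- vapply(1:100, function(b) {
    X <- simulateCorrelatedBM(tr, Sigma, seed = b)
    picCorrelation(
      computeContrasts(tr, setNames(X[, 1], rownames(X))),
      computeContrasts(tr, setNames(X[, 2], rownames(X))))$r
  }, numeric(1))
  expect_equal(mean(rs), 0.8, tolerance = 0.05)
  # perfectly correlated traits: every replicate r = 1 to machine precision
  Sp <- matrix(1, 2, 2)
  X <- simulateCorrelatedBM(tr, Sp, seed = 5)
  r1 <- picCorrelation(
    computeContrasts(tr, setNames(X[, 1], rownames(X))),
    computeContrasts(tr, setNames(X[, 2], rownames(X))))$r
  expect_equal(r1, 1, tolerance = 1e-10)
  expect_error(simulateCorrelatedBM(tr, matrix(c(1, 2, 2, 1), 2), seed = 1),
               "positive semi-definite")
})

test_that("nested generator reproduces its design and components contract", {
  d0 <- simulateNestedDataset(c(2, 2, 2, 3), rep(0, 4), grandMean = 4.2,
                              seed = 1)
  expect_true(all(d0$value == 4.2))
  expect_equal(nrow(d0), 2 * 2 * 2 * 3)
  d <- simulateNestedDataset(c(3, 4, 3, 4), c(0.175, 0.066, 0.019, 0.003),
                             grandMean = 5, seed = 9)
  expect_equal(nrow(d), 144)
  expect_equal(length(unique(d$clade)), 3)
  expect_equal(length(unique(d$species)), 12)
  expect_equal(length(unique(d$clone)), 36)
  expect_identical(d, simulateNestedDataset(c(3, 4, 3, 4),
                                            c(0.175, 0.066, 0.019, 0.003),
                                            grandMean = 5, seed = 9))
  # unbalanced skeleton passes through unchanged
  skel <- data.frame(clade = c("A", "A", "B"), species = c("s1", "s1", "s2"),
                     clone = c("k1", "k1", "k2"))
  du <- simulateNestedDataset(skel, c(1, 1, 1, 1), seed = 2)
  expect_equal(du[, 1:3], skel)
})

test_that("histogram generator and peak detector round-trip", {
  h <- simulateHistogram(data.frame(mean = 200, cv = 4, events = 7000),
                         noiseEvents = 100, seed = 11)
  expect_equal(sum(h$count), 7100)
  expect_true(all(diff(h$channel) == 1))
  p <- detectPeaks(h)
  expect_equal(p$mean_channel, 200, tolerance = 1)
  expect_equal(p$cv, 4, tolerance = 0.5)
  # two-peak ratio chain reproduces the calibration arithmetic
  h2 <- simulateHistogram(data.frame(mean = c(340, 1000), cv = c(3, 3),
                                     events = c(7000, 8000)),
                          nChannels = 1100, seed = 12)
  p2 <- detectPeaks(h2)
  est <- genomeSizeFromPeaks(p2[1, ], p2[2, ])
  expect_equal(est$pg, 0.119, tolerance = 0.002)
})

test_that("the bundled summary fixture matches the published table", {
  fx <- table1Fixture()
  expect_equal(nrow(fx$table), 33)
  expect_equal(length(unique(fx$table$species)), 12)
  expect_setequal(unique(fx$table$clade), c("A", "B", "C"))
  adr <- fx$table[fx$table$clone == "Adriatic2", ]
  expect_equal(adr$mean_mbp, 55.1)
  expect_equal(adr$sem, 0.3)
  expect_equal(adr$n, 4)
  expect_equal(fx$table$mean_mbp[fx$table$clone == "MNCHU008"], 407.0)
  expect_true(ape::is.binary.phylo(fx$tree))
  expect_setequal(fx$tree$tip.label, fx$table$clone)
})

test_that("simulated signal vanishes after contrasts on the fixture tree", {
  fx <- table1Fixture()
  tr <- fx$tree
  sig <- vapply(1:40, function(b) {
    x <- simulateBM(tr, 1, 0, seed = 500 + b)
    ptip <- pValue(tfsiTest(tr, x, "tips", 50, 99, seed = 600 + b))
    cs <- computeContrasts(tr, x)
    pcon <- pValue(tfsiTest(tr, cs, "contrasts", 50, 99, seed = 700 + b))
    c(ptip <= 0.05, pcon <= 0.05)
  }, logical(2))
  expect_gt(mean(sig[1, ]), 0.5)    # strong signal in the tip data
  expect_lt(mean(sig[2, ]), 0.3)    # near-nominal after contrasts
})
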