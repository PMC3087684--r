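test_that("contrasts follow the pruning recursion on worked examples", {
  # two tips: single standardized difference
  cs <- computeContrasts(parseNewick("(A:1,B:1);"), c(A = 0, B = 2))
  expect_equal(nContrasts(cs), 1)
  expect_equal(unname(contrastValues(cs)), -2 / sqrt(2), tolerance = 1e-12)

  # three tips: contrasts, ancestral state and branch adjustment by hand
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  cs <- computeContrasts(tr, c(A = 1, B = 3, C = 6))
  df <- as.data.frame(cs)
  expect_equal(sort(abs(df$contrast)), c(sqrt(2), 4 / sqrt(3.5)),
               tolerance = 1e-6)
  expect_equal(sort(abs(df$contrast)), c(1.4142, 2.1381), tolerance = 1e-4)
  cherry <- df[df$variance == 2, ]
  expect_equal(cherry$ancestor_state, 2.0)       # equal-branch mean of A,B
  expect_equal(cherry$adjusted_length, 1.5)      # 1 + 1*1/(1+1)

  # equal tip values give all-zero contrasts
  cs0 <- computeContrasts(tr, c(A = 5, B = 5, C = 5))
  expect_equal(unname(contrastValues(cs0)), c(0, 0))
})

test_that("contrasts match the ape::pic oracle on random BM data", {
  for (seed in 1:6) {
    tr <- randomTestTree(sample(5:40, 1), seed)
    x <- simulateBM(tr, sigma2 = 2, rootValue = 1, seed = seed + 100)
    mine <- computeContrasts(tr, x)
    oracle <- ape::pic(x[tr$tip.label], tr, var.contrasts = TRUE)
    expect_equal(sort(abs(contrastValues(mine))),
                 sort(abs(oracle[, "contrasts"])), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sort(contrastVariances(mine)),
                 sort(oracle[, "variance"]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("contrast count and input validation behave as specified", {
  tr <- randomTestTree(10, 1)
  x <- simulateBM(tr, 1, 0, seed = 1)
  expect_equal(nContrasts(computeContrasts(tr, x)), 9)
  expect_error(computeContrasts(tr, x[-1]), "no trait value")
  poly <- parseNewick("(A:1,B:1,C:1);")
  expect_error(computeContrasts(poly, c(A = 1, B = 2, C = 3)),
               "not bifurcating")
})

test_that("zero-branch policies keep contrasts finite or fail loudly", {
  tr <- parseNewick("((A:0,B:0):1,C:2);")
  expect_error(computeContrasts(tr, c(A = 1, B = 2, C = 3),
                                zeroBranchPolicy = "raw"),
               "zero contrast variance at node")
  cs <- computeContrasts(tr, c(A = 1, B = 2, C = 3))  # epsilon default
  expect_true(all(is.finite(contrastValues(cs))))
  expect_true(all(contrastVariances(cs) > 0))
  # missing branch lengths: only all_one substitutes
  trm <- parseNewick("((A,B),C);")
  expect_error(computeContrasts(trm, c(A = 1, B = 2, C = 3)), "missing branch")
  cs1 <- computeContrasts(trm, c(A = 1, B = 2, C = 3),
                          zeroBranchPolicy = "all_one")
  expect_equal(unname(contrastVariances(cs1)), c(2, 2.5),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("child-order rotation flips signs but not magnitudes or r", {
  trA <- parseNewick("((A:1,B:1):1,C:2);")
  trB <- parseNewick("(C:2,(B:1,A:1):1);")   # rotated at both nodes
  x <- c(A = 0.3, B = 1.9, C = -1)
  y <- c(A = 2.0, B = 0.1, C = 0.7)
  csA <- computeContrasts(trA, x); csB <- computeContrasts(trB, x)
  expect_equal(sort(abs(contrastValues(csA))), sort(abs(contrastValues(csB))),
               ignore_attr = TRUE)
  rA <- picCorrelation(csA, computeContrasts(trA, y))
  rB <- picCorrelation(csB, computeContrasts(trB, y))
  expect_equal(rA$r^2, rB$r^2, tolerance = 1e-12)
  expect_equal(rA$p, rB$p, tolerance = 1e-12)
})

test_that("through-origin correlation hits the exact degenerate cases", {
  tr <- randomTestTree(12, 3)
  x <- simulateBM(tr, 1, 0, seed = 9)
  cs <- computeContrasts(tr, x)
  double <- cs; double@contrast <- 2 * cs@contrast
  expect_equal(picCorrelation(cs, double)$r, 1)
  neg <- cs; neg@contrast <- -cs@contrast
  expect_equal(picCorrelation(cs, neg)$r, -1)
  zero <- cs; zero@contrast <- rep(0, nContrasts(cs))
  expect_error(
    picCorrelation(cs, new("ContrastSet", node = cs@node,
                           contrast = rep(0, nContrasts(cs)),
                           variance = cs@variance,
                           ancestorState = cs@ancestorState,
                           adjustedLength = cs@adjustedLength,
                           trait = "z", tipLabels = cs@tipLabels)),
    "undefined")
})

test_that("star-tree contrasts reproduce the Pearson correlation exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:30, 1)
    st <- resolvePolytomies(starTree(paste0("t", 1:n), 1.7))
    x <- setNames(rnorm(n), paste0("t", 1:n))
    y <- setNames(rnorm(n), paste0("t", 1:n))
    r <- picCorrelation(computeContrasts(st, x), computeContrasts(st, y))$r
    expect_equal(r, cor(x, y), tolerance = 1e-12)
  }
})

test_that("independent BM traits give near-zero mean contrast correlation", {
  tr <- simulateYuleTree(64, seed = 11)
  rs <- vapply(1:200, function(b) {
    x <- simulateBM(tr, 1, 0, seed = 2 * b)
    y <- simulateBM(tr, 1, 0, seed = 2 * b + 100001)
    picCorrelation(computeContrasts(tr, x), computeContrasts(tr, y))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("BM contrasts are standard normal after rate standardization", {
  tr <- simulateYuleTree(32, seed = 5)
  sigma2 <- 3
  pooled <- unlist(lapply(1:30, function(b)
    contrastValues(computeContrasts(tr, simulateBM(tr, sigma2, 0,
                                                   seed = 2000 + b)))))
  z <- pooled / sqrt(sigma2)
  expect_equal(var(z), 1, tolerance = 0.1)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})
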