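test_that("pg/Mbp conversion uses the 978 factor exactly", {
  expect_equal(pgToMbp(1), 978)
  expect_equal(pgToMbp(0), 0)
  expect_equal(roundHalfAway(pgToMbp(0.416)), 407)
  expect_equal(roundHalfAway(mbpToPg(256.3), 3), 0.262)
  expect_error(pgToMbp(-1), "non-negative")
  # inverses to machine precision
  v <- c(0.056, 0.12, 0.416, 2.5)
  expect_equal(mbpToPg(pgToMbp(v)), v, tolerance = 1e-15)
})

test_that("genome size from peaks is the calibrated channel ratio", {
  p <- list(mean_channel = 500)
  expect_equal(genomeSizeFromPeaks(p, p)$pg, 0.35)
  est <- genomeSizeFromPeaks(list(mean_channel = 340),
                             list(mean_channel = 1000))
  expect_equal(est$pg, 0.119)
  expect_equal(est$mbp, 0.119 * 978)
  # scale invariance of the ratio
  est2 <- genomeSizeFromPeaks(list(mean_channel = 340 * 3.7),
                              list(mean_channel = 1000 * 3.7))
  expect_equal(est2$pg, est$pg, tolerance = 1e-12)
  expect_error(genomeSizeFromPeaks(list(mean_channel = 340), NULL), "missing")
})

test_that("replicate aggregation reports mean, sem and n", {
  a <- aggregateReplicates(c(110, 112, 114, 116))
  expect_equal(a$mean, 113)
  expect_equal(a$sem, sd(c(110, 112, 114, 116)) / 2)
  expect_equal(a$sem, 1.291, tolerance = 1e-3)
  expect_equal(a$n, 4L)
  one <- aggregateReplicates(42)
  expect_equal(one$mean, 42)
  expect_equal(one$sem, 0)
  expect_false(one$sem_defined)
  expect_equal(aggregateReplicates(rep(7, 5))$sem, 0)
})

test_that("species means reproduce the published summary rows", {
  expect_equal(speciesSummary(c(111.7, 116.7, 114.5, 128.8, 123.0)), 118.9)
  expect_equal(speciesSummary(c(217.6, 407.0, 340.0, 221.5, 216.6,
                                229.5, 256.3)), 269.8)
  expect_equal(speciesSummary(58.8), 58.8)
})

test_that("peak detection recovers synthetic Gaussian peaks", {
  h1 <- simulateHistogram(data.frame(mean = 200, cv = 4, events = 7000),
                          seed = 101)
  p1 <- detectPeaks(h1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$mean_channel, 200, tolerance = 1)
  expect_equal(p1$cv, 4, tolerance = 0.5)

  h2 <- simulateHistogram(data.frame(mean = c(200, 570), cv = c(4, 3),
                                     events = c(7000, 8000)),
                          noiseEvents = 300, seed = 102)
  p2 <- detectPeaks(h2)
  expect_equal(nrow(p2), 2)
  expect_true(all(diff(p2$mean_channel) > 0))  # sorted by mean channel
  expect_equal(p2$mean_channel, c(200, 570), tolerance = 2)

  expect_error(detectPeaks(data.frame(channel = 0:10, count = 0)), "no events")
  # degenerate peak: all events in one bin
  h3 <- data.frame(channel = 0:10, count = c(rep(0, 5), 500, rep(0, 5)))
  p3 <- detectPeaks(h3)
  expect_true(p3$degenerate[1])
  expect_equal(p3$cv[1], 0)
})

test_that("noise-only histograms yield no qualifying peak", {
  h <- simulateHistogram(data.frame(mean = numeric(0), cv = numeric(0),
                                    events = numeric(0)),
                         noiseEvents = 2000, seed = 103)
  expect_equal(nrow(detectPeaks(h)), 0)
})

test_that("ploidy fit finds exact multiples and flags outliers", {
  pf <- fitPloidyMultiples(c(100, 200, 300), baseGrid = c(50, 150, 0.5))
  expect_equal(ploidyBase(pf), 100)
  expect_equal(unname(ploidyMultipliers(pf)), c(1L, 2L, 3L))
  expect_equal(pf@score, 0)

  austria <- c(Bogoria1 = 217.6, MNCHU008 = 407.0, MNCHU024 = 340.0,
               Nakuru1 = 221.5, Nakuru2 = 216.6, OHJ1 = 229.5, OHJ4 = 256.3)
  pa <- fitPloidyMultiples(austria, fixedBase = 117, labels = names(austria))
  expect_equal(unname(ploidyMultipliers(pa)), c(2L, 3L, 3L, 2L, 2L, 2L, 2L))
  worst <- names(which.max(abs(ploidyResiduals(pa))))
  expect_equal(worst, "MNCHU008")
  expect_equal(407 / 117, 3.48, tolerance = 0.01)  # below the "expected" 4

  single <- fitPloidyMultiples(5, fixedBase = 5)
  expect_equal(unname(ploidyMultipliers(single)), 1L)
  expect_equal(single@score, 0)
  expect_error(fitPloidyMultiples(numeric(0), fixedBase = 1), "no sizes")
})

test_that("fixture genome sizes span the published seven-fold range", {
  fx <- table1Fixture()
  expect_equal(roundHalfAway(max(fx$table$mean_mbp) / min(fx$table$mean_mbp)),
               7)
})
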