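test_that("restructuring matches the hand-worked 5-bin fixture", {
  lfq <- tinyLFQ(matrix(c(0L, 0L, 10L, 0L, 0L), ncol = 1))
  r <- restructure(lfq, 5)
  # worked by hand: truncated-window MAs are (10/3, 2.5, 2, 2.5, 10/3);
  # deviations (-1, -1, 4, -1, -1); the isolated peak (two empty neighbours)
  # is divided by 3; negatives scaled by (4/3)/4 to balance the column
  expect_equal(as.vector(r@values), c(-1/3, -1/3, 4/3, -1/3, -1/3),
               tolerance = 1e-12)
  expect_equal(r@asp, 4/3, tolerance = 1e-12)
  expect_equal(sum(r@values), 0, tolerance = 1e-12)
})

test_that("flat, empty and rescaled columns restructure as required", {
  # identical counts carry no modal structure
  r <- restructure(tinyLFQ(matrix(rep(5L, 5), ncol = 1)), 3)
  expect_true(all(abs(r@values) < 1e-12))
  # an all-zero column contributes nothing to ASP
  two <- tinyLFQ(cbind(c(0L, 0L, 10L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L)))
  r2 <- restructure(two, 5)
  expect_true(all(r2@values[, 2] == 0))
  expect_equal(r2@asp, 4/3, tolerance = 1e-12)
  # count-scale invariance: the deviation step is a ratio
  set.seed(5)
  col <- as.integer(rpois(7, 6))
  a <- restructure(tinyLFQ(matrix(col, ncol = 1)), 3)
  b <- restructure(tinyLFQ(matrix(col * 3L, ncol = 1)), 3)
  expect_equal(a@values, b@values, tolerance = 1e-10)
  # balanced columns sum to zero whenever both signs occur
  set.seed(11)
  m <- matrix(as.integer(rpois(36, 4)), nrow = 6)
  rb <- restructure(tinyLFQ(m), 3)
  for (j in 1:ncol(m))
    if (any(rb@values[, j] > 0) && any(rb@values[, j] < 0))
      expect_equal(sum(rb@values[, j]), 0, tolerance = 1e-10)
})

test_that("restructuring rejects invalid moving-average windows", {
  lfq <- tinyLFQ(matrix(c(0L, 0L, 10L, 0L, 0L), ncol = 1))
  expect_error(restructure(lfq, 4), "odd")
  expect_error(restructure(lfq, 1), "odd|>= 3")
  expect_error(restructure(lfq, 7), "exceed")
})

test_that("the goodness score hits its limits at full and zero explanation", {
  # bins [14,18) [18,22) [22,26) [26,30); two dates three months apart
  lfq <- tinyLFQ(matrix(c(1L, 5L, 1L, 1L, 1L, 1L, 5L, 1L), nrow = 4),
                 dates = as.Date(c("2016-03-15", "2016-06-15")))
  # scores fixed by hand: one positive peak per column, zeros elsewhere
  vals <- cbind(c(0, 2, 0, 0), c(0, 0, 1.5, 0))
  r <- madeRestructured(lfq, vals)
  expect_equal(r@asp, 3.5)
  # worked geometry: anchor a = 2015.7 gives ages 0.504 and 0.755 at the two
  # dates, so linf = 26, k = 2.754 predicts 19.5 mm (bin 2) then 22.8 mm
  # (bin 3); the 3/K age cap (1.089 yr) rules out any older anchor
  hit <- VBGFParams(linf = 26, k = 2.754, tAnchor = 0.7)
  sc <- scoreGrowthCurve(r, hit)
  expect_equal(sc$esp, r@asp)
  expect_equal(sc$rn, 1)
  # a family kept below the scored classes explains nothing
  vals2 <- cbind(c(0, 0, 0, 2), c(0, 0, 0, 1.5))
  r2 <- madeRestructured(lfq, vals2)
  low <- VBGFParams(linf = 17, k = 0.5, tAnchor = 0)
  sc2 <- scoreGrowthCurve(r2, low)
  expect_equal(sc2$esp, 0)
  expect_equal(sc2$rn, 0.1)
  # rn = 10^(esp/asp)/10 by definition
  expect_equal(sc$rn, 10^(sc$esp / sc$asp) / 10)
  # unscorable data (ASP = 0) is an error
  r0 <- madeRestructured(lfq, matrix(0, 4, 2), asp = 0)
  expect_error(scoreGrowthCurve(r0, hit), "unscorable")
})

test_that("both searches find the clean global optimum and agree on it", {
  # the same two-peak geometry, restructured for real: the perfect
  # trajectory explains every peak without crossing a trough, so Rn = 1 is
  # attainable and both optimizers must reach it (and so agree within 0.05)
  lfq <- tinyLFQ(matrix(c(1L, 5L, 1L, 1L, 1L, 1L, 5L, 1L), nrow = 4),
                 dates = as.Date(c("2016-03-15", "2016-06-15")))
  bounds <- list(linf = c(24, 28), k = c(2.4, 3.1), tAnchor = c(0.6, 0.8))
  sa <- fitELEFAN(lfq, "sa", bounds = bounds, maWindow = 3, seed = 2)
  ga <- fitELEFAN(lfq, "ga", bounds = bounds, maWindow = 3, seed = 2,
                  control = list(popSize = 20L, generations = 30L))
  expect_equal(sa@rn, 1)
  expect_equal(ga@rn, 1)
  expect_lt(abs(sa@rn - ga@rn), 0.05)
})

test_that("ESP equals an independent exhaustive enumeration on small grids", {
  set.seed(17)
  for (rep in 1:8) {
    nr <- sample(4:6, 1)
    nc <- sample(2:3, 1)
    lfq <- tinyLFQ(matrix(as.integer(rpois(nr * nc, 5)), nrow = nr))
    r <- restructure(lfq, 3)
    if (r@asp <= 0) next
    linf <- runif(1, 20, 45)
    k <- runif(1, 0.4, 1.5)
    ta <- runif(1)
    sc <- scoreGrowthCurve(r, VBGFParams(linf, k, tAnchor = ta))
    oracle <- bruteESP(lfq, r@values, linf, k, ta)
    expect_equal(sc$esp, oracle, tolerance = 1e-9)
  }
})

test_that("both optimizers recover a single simulated cohort within tolerance", {
  sim <- simulatePopulation(singleCohortConfig(), seed = 4)
  lfq <- binLFQ(sim$records, sex = "male")
  bounds <- list(linf = c(54, 66), k = c(0.55, 1.1), tAnchor = c(0, 1))
  sa <- fitELEFAN(lfq, "sa", bounds = bounds, seed = 21)
  ga <- fitELEFAN(lfq, "ga", bounds = bounds, seed = 21,
                  control = list(popSize = 30L, generations = 40L))
  for (fit in list(sa, ga)) {
    p <- vbgfParams(fit)
    expect_lt(abs(p@k - 0.8) / 0.8, 0.15)
    expect_lt(abs(p@linf - 60) / 60, 0.10)
  }
  # the reported score is the maximum of the trace, and traces are monotone
  expect_equal(sa@rn, max(sa@trace))
  expect_equal(ga@rn, max(ga@trace))
  expect_true(all(diff(sa@trace) >= 0))
  expect_true(all(diff(ga@trace) >= 0))
})

test_that("fits are deterministic for a fixed seed and exact at a point", {
  lfq <- tinyLFQ(matrix(as.integer(rpois(24, 4)), nrow = 6) +
                   diag(6)[, 1:4] * 8L)
  ctl <- list(iterations = 60L, probes = 10L)
  f1 <- fitELEFAN(lfq, "sa", seed = 9, control = ctl)
  f2 <- fitELEFAN(lfq, "sa", seed = 9, control = ctl)
  expect_equal(vbgfParams(f1), vbgfParams(f2))
  expect_identical(f1@trace, f2@trace)
  g1 <- fitELEFAN(lfq, "ga", seed = 9,
                  control = list(popSize = 10L, generations = 10L))
  g2 <- fitELEFAN(lfq, "ga", seed = 9,
                  control = list(popSize = 10L, generations = 10L))
  expect_equal(vbgfParams(g1), vbgfParams(g2))

  # bounds collapsed to a point return that point with its exact score
  pt <- list(linf = 30, k = 0.9, tAnchor = 0.25)
  fp <- fitELEFAN(lfq, "sa", bounds = pt, seed = 1,
                  control = list(iterations = 20L, probes = 3L))
  expect_equal(vbgfParams(fp)@linf, 30)
  expect_equal(vbgfParams(fp)@k, 0.9)
  direct <- scoreGrowthCurve(restructure(lfq, 5),
                             VBGFParams(30, 0.9, tAnchor = 0.25))
  expect_equal(fp@rn, direct$rn)
  # a GA with one individual and no variation degenerates to its start point
  gp <- fitELEFAN(lfq, "ga", bounds = pt, seed = 1,
                  control = list(popSize = 1L, generations = 5L,
                                 mutation = 0, crossover = 0))
  expect_equal(vbgfParams(gp)@linf, 30)
  expect_equal(gp@rn, direct$rn)
})

test_that("cohort tracks match the population structure", {
  # the default crayfish-like population shows five cohorts per sex
  sim <- simulatePopulation(simConfig(), seed = 1)
  lfq <- binLFQ(sim$records, sex = "male")
  # reference male growth, anchored mid-season between the two pulses
  truthParams <- VBGFParams(linf = 60.93, k = 0.81, tAnchor = 0.6)
  co <- identifyCohorts(lfq, truthParams)
  expect_equal(co$nCohorts, 5L)
  # tracks advance monotonically once recruited
  for (i in unique(co$tracks$cohort)) {
    L <- na.omit(co$tracks$predLength[co$tracks$cohort == i])
    if (length(L) > 1) expect_true(all(diff(L) > 0))
  }
  # an asymptote below the smallest class supports no track
  none <- identifyCohorts(lfq, VBGFParams(linf = 10, k = 0.8, tAnchor = 0.5))
  expect_equal(none$nCohorts, 0L)
  # fast growth over a single year of data: one or two tracks at most
  short <- tinyLFQ(matrix(as.integer(rpois(18, 3)), nrow = 6),
                   binLower = seq(14, 34, 4))
  few <- identifyCohorts(short, VBGFParams(linf = 40, k = 1.8, tAnchor = 0.2))
  expect_lte(few$nCohorts, 2L)
  expect_gte(few$nCohorts, 1L)
  # maxCohorts keeps the youngest tracks
  capped <- identifyCohorts(lfq, truthParams, maxCohorts = 2)
  expect_equal(capped$nCohorts, 2L)
  allAnchors <- sort(unique(co$tracks$anchorTime))
  expect_equal(sort(unique(capped$tracks$anchorTime)),
               allAnchors[(length(allAnchors) - 1):length(allAnchors)])
})
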