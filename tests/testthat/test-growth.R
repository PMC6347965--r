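test_that("the growth curve passes through its defining points", {
  p <- VBGFParams(linf = 60.93, k = 0.81, t0 = -0.29)
  expect_equal(vbgfLength(p@t0, p), 0)
  expect_lt(abs(vbgfLength(50, p) - 60.93), 1e-8)
  # strictly increasing and bounded by the asymptote
  tt <- seq(-0.29, 10, by = 0.05)
  L <- vbgfLength(tt, p)
  expect_true(all(diff(L) > 0))
  expect_true(all(L <= p@linf))
  # degenerate seasonality: C = 0 variant equals the plain curve
  ps <- VBGFParams(linf = 60.93, k = 0.81, t0 = -0.29, C = 0, ts = 0.3)
  expect_equal(vbgfLength(tt, ps), L)
  # seasonal curve oscillates around the plain one but shares annual marks
  posc <- VBGFParams(linf = 60.93, k = 0.81, t0 = -0.29, C = 0.5, ts = 0.2)
  expect_false(isTRUE(all.equal(vbgfLength(1.3, posc), vbgfLength(1.3, p))))
})

test_that("asymptotic length from the maximum observed length", {
  expect_equal(linfFromLmax(95), 100)
  expect_equal(round(linfFromLmax(57.8835), 2), 60.93)
  expect_equal(round(linfFromLmax(55.214), 2), 58.12)
  expect_error(linfFromLmax(-1), "positive")
})

test_that("growth performance index reproduces the published values", {
  expect_equal(round(phiPrime(0.81, 60.93), 2), 8.01)
  expect_equal(round(phiPrime(0.86, 58.12), 2), 7.97)
  expect_equal(phiPrime(1, 1), 0)
  expect_equal(phiPrime(1, 1, base = "decimal"), 0)
  # decimal base gives the conventional Munro-Pauly index
  expect_equal(phiPrime(0.81, 60.93, base = "decimal"),
               log10(0.81) + 2 * log10(60.93))
  # strictly increasing in both arguments
  ks <- seq(0.2, 1.6, by = 0.2)
  expect_true(all(diff(phiPrime(ks, 60)) > 0))
  expect_true(all(diff(phiPrime(0.8, seq(40, 80, 5))) > 0))
  expect_error(phiPrime(-1, 60), "positive")
})

test_that("empirical t0 matches the published regression and is negative", {
  expect_equal(round(empiricalT0(0.81, 60.93), 2), -0.29)
  expect_equal(round(empiricalT0(0.86, 58.12), 2), -0.27)
  grid <- expand.grid(k = seq(0.2, 1.8, by = 0.2), linf = seq(30, 90, 10))
  t0s <- empiricalT0(grid$k, grid$linf)
  expect_true(all(t0s < 0))
  expect_true(all(empiricalT0(grid$k, grid$linf, "classic") < 0))
  # monotone toward zero in both k and linf
  expect_true(all(diff(empiricalT0(seq(0.2, 1.8, 0.1), 60)) > 0))
  expect_true(all(diff(empiricalT0(0.8, seq(30, 90, 5))) > 0))
  # the classic decimal-log variant is a different curve
  expect_false(isTRUE(all.equal(empiricalT0(0.81, 60.93),
                                empiricalT0(0.81, 60.93, "classic"))))
})

test_that("expected longevity follows t_max = 3/K + t0", {
  expect_equal(round(tMax(0.81, -0.29), 2), 3.41)
  expect_equal(round(tMax(0.86, -0.27), 2), 3.22)
  expect_equal(tMax(3, 0), 1)
  expect_error(tMax(0, 0), "positive")
})

test_that("the derived-growth chain reports at 2 dp from the rounded t0", {
  dg <- deriveGrowth(0.81, 60.93, roundTo = 2)
  expect_equal(dg$phiPrime, 8.01)
  expect_equal(dg$t0, -0.29)
  expect_equal(dg$tMax, 3.41)
  full <- deriveGrowth(0.81, 60.93)
  expect_equal(full$tMax, 3 / 0.81 + full$t0)
})

test_that("growth parameters serialize to the flat key-value form and back", {
  p <- VBGFParams(linf = 60.93, k = 0.81, t0 = -0.29, C = 0.2, ts = 0.4,
                  tAnchor = 0.7)
  l <- vbgfToList(p)
  expect_named(l, c("linf", "k", "t0", "c", "ts", "t_anchor"))
  q <- vbgfFromList(l)
  for (s in slotNames(p)) expect_equal(slot(q, s), slot(p, s))
  # missing optional keys default to zero
  m <- vbgfFromList(list(linf = 60, k = 0.8))
  expect_equal(m@t0, 0)
  expect_equal(m@cAmplitude, 0)
})

test_that("parameter validity is enforced", {
  expect_error(VBGFParams(linf = -5, k = 0.8), "linf")
  expect_error(VBGFParams(linf = 60, k = 0), "k")
  expect_error(VBGFParams(linf = 60, k = 0.8, C = 2), "C")
  expect_error(VBGFParams(linf = 60, k = 0.8, tAnchor = 1), "tAnchor")
})
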