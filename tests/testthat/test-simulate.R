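smallConfig <- function(...) simConfig(recruitsPerYear = 800, ...)

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- smallConfig()
  a <- simulatePopulation(cfg, seed = 42)
  b <- simulatePopulation(cfg, seed = 42)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- simulatePopulation(cfg, seed = 43)
  expect_false(identical(a$records, c$records))
})

test_that("emitted records respect the biology and the effort schedule", {
  sim <- simulatePopulation(smallConfig(), seed = 7)
  rec <- sim$records
  expect_true(all(rec$ctl_mm > 0))
  expect_true(all(rec$weight_g > 0))
  expect_true(all(rec$sex %in% c("female", "male")))
  # organ weights and eggs only on females, eggs only in the berried season
  males <- rec[rec$sex == "male", ]
  expect_true(all(is.na(males$gonad_g)))
  expect_true(all(is.na(males$egg_count)))
  eggs <- rec[!is.na(rec$egg_count), ]
  expect_true(all(eggs$sex == "female"))
  expect_true(all(as.integer(format(eggs$date, "%m")) %in% c(9L, 10L, 11L, 12L)))
  fem <- rec[rec$sex == "female" & !is.na(rec$gonad_g), ]
  expect_true(all(fem$gonad_g <= fem$weight_g))
  # effort metadata follows the monthly schedule (3 days Nov-Feb, 1 Jun-Sep)
  m <- as.integer(format(rec$date, "%m"))
  expect_true(all(rec$trap_days[m %in% c(11, 12, 1, 2)] == 3))
  expect_true(all(rec$trap_days[m %in% 6:9] == 1))
  expect_true(all(rec$traps == 8))
})

test_that("trap selectivity truncates the catch near its L50", {
  sim <- simulatePopulation(simConfig(recruitsPerYear = 4000, selL50 = 15),
                            seed = 11)
  expect_lt(abs(min(sim$records$ctl_mm) - 15), 3.5)
  # harsh mortality leaves no old animals: the catch stays far below Linf
  harsh <- simulatePopulation(smallConfig(z = c(female = 8, male = 8)),
                              seed = 11)
  expect_lt(max(harsh$records$ctl_mm), 0.8 * 60.93)
})

test_that("the deterministic expected matrix matches its degenerate cases", {
  # effectively unselective gear catches nothing
  off <- smallConfig(selL50 = 1e6)
  E0 <- expectedLFQ(off, sex = "male")
  expect_true(all(E0 < 1e-6))
  # a single cohort with no growth variability occupies one bin per date
  cfg1 <- simConfig(recruitsPerYear = 1000, cvLinf = 0, cvK = 0,
                    pulseMonths = 10L, pulseWeights = 1, burnYears = 0,
                    sampleDates = seq(as.Date("2016-12-15"), by = "month",
                                      length.out = 6))
  E1 <- expectedLFQ(cfg1, sex = "male")
  occupied <- colSums(E1 > 1e-9)
  expect_true(all(occupied <= 1))
  # and the occupied bin advances along the growth curve
  rows <- apply(E1, 2, function(col) if (any(col > 1e-9)) which(col > 1e-9) else NA)
  expect_true(all(diff(na.omit(rows)) >= 0))
})

test_that("replicate means converge on the expected matrix", {
  cfg <- simConfig(recruitsPerYear = 600, burnYears = 2,
                   sampleDates = seq(as.Date("2016-03-15"), by = "month",
                                     length.out = 6))
  E <- expectedLFQ(cfg, sex = "female", binWidth = 4, anchor = 0)
  nrep <- 80
  acc <- array(0, c(nrow(E), ncol(E), nrep))
  edges <- as.numeric(rownames(E))
  for (r in seq_len(nrep)) {
    rec <- simulatePopulation(cfg, seed = 1000 + r)$records
    rec <- rec[rec$sex == "female", ]
    bin <- floor(rec$ctl_mm / 4) + 1
    day <- match(format(rec$date), colnames(E))
    ok <- bin >= 1 & bin <= nrow(E) & !is.na(day)
    for (i in which(ok)) acc[bin[i], day[i], r] <- acc[bin[i], day[i], r] + 1
  }
  mu <- apply(acc, c(1, 2), mean)
  se <- apply(acc, c(1, 2), sd) / sqrt(nrep)
  dev <- abs(mu - E)
  expect_true(all(dev <= 4 * se + 0.15))
})

test_that("truth records carry the configuration and cohort bookkeeping", {
  cfg <- smallConfig()
  sim <- simulatePopulation(cfg, seed = 5)
  expect_equal(sim$truth$seed, 5L)
  expect_equal(sim$truth$params$male$linf, 60.93)
  expect_equal(sim$truth$params$female$z, 1.93)
  expect_equal(sim$truth$nRecords, nrow(sim$records))
  expect_setequal(unique(sim$truth$cohorts$month), c(10L, 11L, 3L, 4L, 5L))
  # pulse magnitudes are honoured in the realized cohort sizes
  oct <- sim$truth$cohorts$n[sim$truth$cohorts$month == 10L][1]
  mar <- sim$truth$cohorts$n[sim$truth$cohorts$month == 3L][1]
  expect_equal(oct / mar, 3.5)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(pulseWeights = c(0.5, 0.2)), "equal length|sum to 1")
  expect_error(simConfig(pulseMonths = c(10L, 3L), pulseWeights = c(0.7, 0.2)),
               "sum to 1")
  expect_error(simConfig(z = c(female = -1, male = 2)), "positive")
  expect_error(simConfig(trapDaysByMonth = rep(1, 5)), "12")
  expect_error(simConfig(berriedProb = 1.5), "berriedProb")
})
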