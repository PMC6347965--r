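#' @include AllClasses.R
NULL

#' Configuration of the synthetic crayfish population
#'
#' Full parameterization of the individual-based simulator. The defaults
#' emulate a commercially trapped red swamp crayfish pond population sampled
#' monthly for a year: two recruitment pulses per year (major October to
#' November, minor March to May), sex-specific von Bertalanffy growth and
#' total mortality, logistic trap size-selectivity that truncates animals
#' below about 15 mm cephalothorax length, and a seasonal monthly trapping
#' effort (8 traps; 1 day June-September, 2 days March-May and October, 3
#' days November-February).
#'
#' @slot sampleDates monthly sampling dates.
#' @slot burnYears years of recruitment history simulated before the first
#'   sample, so that all surviving cohorts are present.
#' @slot pulseMonths,pulseWeights recruitment pulse months (1-12) and their
#'   relative magnitudes (sum to 1).
#' @slot recruitsPerYear annual number of recruits per sex.
#' @slot linf,k named numeric (`female`, `male`): mean VBGF parameters.
#' @slot cvLinf,cvK lognormal individual CVs on Linf and K.
#' @slot z named numeric (`female`, `male`): total mortality (1/year).
#' @slot selL50,selSlope logistic trap selectivity: length at 50% retention
#'   (mm) and slope (1/mm).
#' @slot catchability per-trap-day catch rate of a fully selected animal.
#' @slot traps traps per sampling event.
#' @slot trapDaysByMonth days fished in each calendar month (length 12).
#' @slot alphaW,betaW,cvW weight allometry `W = alphaW * L^betaW` (g, mm) with
#'   lognormal noise; plumbing defaults, not taken from any field study.
#' @slot gsiMonthly,hsiMonthly,cvIndex monthly mean GSI/HSI (%) for females
#'   and their lognormal CV; shaped to peak in the spawning season.
#' @slot berriedMonths,berriedProb,eggMean,eggSD,eggMin,eggMax months in which
#'   berried females occur, the probability a female is berried then, and the
#'   truncated-normal egg-count model.
#' @slot femaleCatchMult optional month-specific female catchability
#'   multiplier (burrowing berried females); default all 1.
#' @seealso [simConfig()], [simulatePopulation()], [expectedLFQ()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(sampleDates = "Date", burnYears = "numeric",
                 pulseMonths = "integer", pulseWeights = "numeric",
                 recruitsPerYear = "numeric", linf = "numeric", k = "numeric",
                 cvLinf = "numeric", cvK = "numeric", z = "numeric",
                 selL50 = "numeric", selSlope = "numeric",
                 catchability = "numeric", traps = "numeric",
                 trapDaysByMonth = "numeric", alphaW = "numeric",
                 betaW = "numeric", cvW = "numeric", gsiMonthly = "numeric",
                 hsiMonthly = "numeric", cvIndex = "numeric",
                 berriedMonths = "integer", berriedProb = "numeric",
                 eggMean = "numeric", eggSD = "numeric", eggMin = "numeric",
                 eggMax = "numeric", femaleCatchMult = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (length(object@pulseMonths) != length(object@pulseWeights))
    msg <- c(msg, "pulseMonths and pulseWeights must have equal length")
  if (abs(sum(object@pulseWeights) - 1) > 1e-8)
    msg <- c(msg, "pulseWeights must sum to 1")
  if (any(object@pulseWeights < 0)) msg <- c(msg, "pulseWeights must be >= 0")
  for (s in c("linf", "k", "z"))
    if (!all(c("female", "male") %in% names(slot(object, s))) ||
        any(slot(object, s) <= 0))
      msg <- c(msg, sprintf("%s must be positive and named female/male", s))
  if (any(c(object@cvLinf, object@cvK, object@cvW, object@cvIndex) < 0))
    msg <- c(msg, "CVs must be >= 0")
  if (object@selL50 <= 0 || object@selSlope <= 0)
    msg <- c(msg, "selectivity parameters must be positive")
  if (object@catchability <= 0) msg <- c(msg, "catchability must be positive")
  if (object@traps < 1) msg <- c(msg, "traps must be at least 1")
  if (length(object@trapDaysByMonth) != 12L || any(object@trapDaysByMonth < 0))
    msg <- c(msg, "trapDaysByMonth must be 12 non-negative values")
  if (length(object@femaleCatchMult) != 12L || any(object@femaleCatchMult < 0))
    msg <- c(msg, "femaleCatchMult must be 12 non-negative values")
  if (object@berriedProb < 0 || object@berriedProb > 1)
    msg <- c(msg, "berriedProb must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@sampleDates), "sampling dates,",
      format(object@recruitsPerYear), "recruits/year/sex\n")
  cat("  pulses: months", paste(object@pulseMonths, collapse = ","),
      "weights", paste(format(object@pulseWeights), collapse = ","), "\n")
  cat("  growth: Linf F/M =", object@linf[["female"]], "/",
      object@linf[["male"]], "mm, K F/M =", object@k[["female"]], "/",
      object@k[["male"]], "/yr\n")
  cat("  mortality Z F/M =", object@z[["female"]], "/", object@z[["male"]],
      "/yr; selectivity L50 =", object@selL50, "mm\n")
})

#' Build a simulator configuration
#'
#' All arguments have crayfish-pond defaults; see [SimConfig-class] for their
#' meaning and units.
#'
#' @param sampleDates monthly sampling dates (default: the 15th of each month,
#'   March 2016 to February 2017).
#' @param burnYears,pulseMonths,pulseWeights,recruitsPerYear,linf,k,cvLinf,cvK
#'   see [SimConfig-class].
#' @param z,selL50,selSlope,catchability,traps,trapDaysByMonth see
#'   [SimConfig-class].
#' @param alphaW,betaW,cvW,gsiMonthly,hsiMonthly,cvIndex see
#'   [SimConfig-class].
#' @param berriedMonths,berriedProb,eggMean,eggSD,eggMin,eggMax,femaleCatchMult
#'   see [SimConfig-class].
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(recruitsPerYear = 1000)
#' cfg
#' @export
simConfig <- function(
    sampleDates = seq(as.Date("2016-03-15"), by = "month", length.out = 12L),
    burnYears = 4,
    pulseMonths = c(10L, 11L, 3L, 4L, 5L),
    pulseWeights = c(0.35, 0.35, 0.10, 0.10, 0.10),
    recruitsPerYear = 6000,
    linf = c(female = 58.12, male = 60.93),
    k = c(female = 0.86, male = 0.81),
    cvLinf = 0.08, cvK = 0.08,
    z = c(female = 1.93, male = 2.32),
    selL50 = 17, selSlope = 3,
    catchability = 0.005,
    traps = 8,
    trapDaysByMonth = c(3, 3, 2, 2, 2, 1, 1, 1, 1, 2, 3, 3),
    alphaW = 9e-4, betaW = 3, cvW = 0.05,
    gsiMonthly = c(0.5, 0.8, 0.6, 0.5, 0.5, 0.8, 1.5, 4, 6, 4, 1, 0.6),
    hsiMonthly = c(4, 4, 4.5, 6, 6, 6, 6, 5, 4.5, 4, 4, 4),
    cvIndex = 0.3,
    berriedMonths = c(9L, 10L, 11L, 12L),
    berriedProb = 0.25,
    eggMean = 429, eggSD = 65, eggMin = 250, eggMax = 650,
    femaleCatchMult = rep(1, 12)) {
  new("SimConfig", sampleDates = as.Date(sampleDates),
      burnYears = burnYears, pulseMonths = as.integer(pulseMonths),
      pulseWeights = pulseWeights, recruitsPerYear = recruitsPerYear,
      linf = linf, k = k, cvLinf = cvLinf, cvK = cvK, z = z,
      selL50 = selL50, selSlope = selSlope, catchability = catchability,
      traps = traps, trapDaysByMonth = trapDaysByMonth, alphaW = alphaW,
      betaW = betaW, cvW = cvW, gsiMonthly = gsiMonthly,
      hsiMonthly = hsiMonthly, cvIndex = cvIndex,
      berriedMonths = as.integer(berriedMonths), berriedProb = berriedProb,
      eggMean = eggMean, eggSD = eggSD, eggMin = eggMin, eggMax = eggMax,
      femaleCatchMult = femaleCatchMult)
}

# recruitment pulses (absolute mid-month times and cohort sizes) covering
# burnYears before the first sample up to the last sample
.pulseTable <- function(config) {
  ty <- dateToYearFrac(config@sampleDates)
  years <- seq.int(floor(min(ty)) - ceiling(config@burnYears), floor(max(ty)))
  tab <- expand.grid(year = years, i = seq_along(config@pulseMonths))
  tab$month <- config@pulseMonths[tab$i]
  tab$weight <- config@pulseWeights[tab$i]
  tab$t <- tab$year + (tab$month - 0.5) / 12
  tab$n <- round(config@recruitsPerYear * tab$weight)
  tab <- tab[tab$t < max(ty) & tab$n > 0, c("year", "month", "t", "n")]
  tab[order(tab$t), , drop = FALSE]
}

.lnorm_pars <- function(cv) {
  sdlog <- sqrt(log(1 + cv^2))
  c(meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean-1 lognormal
}

.selectivity <- function(L, config) stats::plogis(config@selSlope * (L - config@selL50))

#' Simulate a trapped crayfish population
#'
#' Individual-based simulation: cohorts are recruited at the configured pulse
#' times, each individual carries lognormal multipliers on Linf and K, dies
#' at an exponentially distributed age (rate z), and at each sampling date a
#' live animal is retained with probability
#' `1 - exp(-catchability x traps x days x selectivity(L))`. Retained animals
#' are emitted as catch records with allometric body weight, female gonad and
#' hepatopancreas weights following the seasonal GSI/HSI schedules, egg
#' counts for berried females in season, and the effort metadata of the
#' sampling event. Trapping is non-lethal in the simulation: fishing deaths
#' are already part of z.
#'
#' Identical `(config, seed)` pairs give identical record tables.
#'
#' @param config a [SimConfig-class] object.
#' @param seed integer RNG seed.
#' @return a list with `records` (catch-record data.frame as documented in
#'   [readCatchRecords()]) and `truth` (list: the configuration as a flat
#'   list, the realized cohort table with recruit counts, and per-sex true
#'   parameter values).
#' @examples
#' sim <- simulatePopulation(simConfig(recruitsPerYear = 500), seed = 1)
#' head(sim$records)
#' @export
simulatePopulation <- function(config, seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(as.integer(seed))
  pulses <- .pulseTable(config)
  ty <- dateToYearFrac(config@sampleDates)
  months <- as.integer(format(config@sampleDates, "%m"))
  recs <- vector("list", 2L)
  names(recs) <- c("female", "male")
  for (sx in c("female", "male")) {
    nTot <- sum(pulses$n)
    birth <- rep(pulses$t, pulses$n)
    lp <- .lnorm_pars(config@cvLinf)
    kp <- .lnorm_pars(config@cvK)
    linf_i <- config@linf[[sx]] *
      stats::rlnorm(nTot, lp["meanlog"], lp["sdlog"])
    k_i <- config@k[[sx]] * stats::rlnorm(nTot, kp["meanlog"], kp["sdlog"])
    deathAge <- stats::rexp(nTot, rate = config@z[[sx]])
    out <- vector("list", length(ty))
    for (j in seq_along(ty)) {
      age <- ty[j] - birth
      alive <- age > 0 & age < deathAge
      if (!any(alive)) next
      L <- linf_i[alive] * (1 - exp(-k_i[alive] * age[alive]))
      effort <- config@traps * config@trapDaysByMonth[months[j]]
      q <- config@catchability *
        if (sx == "female") config@femaleCatchMult[months[j]] else 1
      pCatch <- 1 - exp(-q * effort * .selectivity(L, config))
      caught <- stats::runif(length(L)) < pCatch
      if (!any(caught)) next
      Lc <- L[caught]
      nC <- length(Lc)
      w <- config@alphaW * Lc^config@betaW *
        stats::rlnorm(nC, .lnorm_pars(config@cvW)["meanlog"],
                      .lnorm_pars(config@cvW)["sdlog"])
      gonad <- hep <- rep(NA_real_, nC)
      eggs <- rep(NA_real_, nC)
      if (sx == "female") {
        ip <- .lnorm_pars(config@cvIndex)
        gonad <- pmin(w * (config@gsiMonthly[months[j]] / 100) *
                        stats::rlnorm(nC, ip["meanlog"], ip["sdlog"]),
                      0.4 * w)
        hep <- pmin(w * (config@hsiMonthly[months[j]] / 100) *
                      stats::rlnorm(nC, ip["meanlog"], ip["sdlog"]),
                    0.4 * w)
        if (months[j] %in% config@berriedMonths) {
          berried <- stats::runif(nC) < config@berriedProb
          ne <- sum(berried)
          if (ne > 0)
            eggs[berried] <- round(pmin(pmax(
              stats::rnorm(ne, config@eggMean, config@eggSD),
              config@eggMin), config@eggMax))
        }
      }
      out[[j]] <- data.frame(
        date = config@sampleDates[j], sex = sx, ctl_mm = round(Lc, 2),
        weight_g = round(w, 2), gonad_g = round(gonad, 3),
        hepatopancreas_g = round(hep, 3), egg_count = eggs,
        traps = config@traps,
        trap_days = config@trapDaysByMonth[months[j]],
        stringsAsFactors = FALSE)
    }
    recs[[sx]] <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$date, records$sex, records$ctl_mm), ,
                     drop = FALSE]
  rownames(records) <- NULL
  truth <- list(
    seed = as.integer(seed),
    cohorts = pulses,
    params = list(
      female = list(linf = config@linf[["female"]], k = config@k[["female"]],
                    z = config@z[["female"]]),
      male = list(linf = config@linf[["male"]], k = config@k[["male"]],
                  z = config@z[["male"]])),
    eggMean = config@eggMean, eggSD = config@eggSD,
    selL50 = config@selL50,
    nRecords = nrow(records))
  list(records = records, truth = truth)
}

#' Deterministic expected length-frequency matrix
#'
#' Noise-free oracle for [simulatePopulation()]: integrates the cohort
#' trajectories, exponential survival, trap selectivity and the monthly
#' effort schedule over the individual-growth distribution (lognormal
#' multipliers on Linf and K, handled by quantile quadrature) to give the
#' expected count in each length class at each sampling date. Column means
#' of simulated counts converge to this matrix as replicates accumulate.
#'
#' @param config a [SimConfig-class] object.
#' @param dates sampling dates (default: the config's).
#' @param sex `"female"` or `"male"`.
#' @param binWidth,anchor bin grid (defaults: width 4 mm, anchored at 0).
#' @param nQuad quadrature points per growth-multiplier dimension.
#' @return matrix of expected counts (classes x dates) with the bin lower
#'   edges as rownames.
#' @export
expectedLFQ <- function(config, dates = NULL, sex = c("female", "male"),
                        binWidth = 4, anchor = 0, nQuad = 32L) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  sex <- match.arg(sex)
  if (is.null(dates)) dates <- config@sampleDates
  dates <- as.Date(dates)
  ty <- dateToYearFrac(dates)
  months <- as.integer(format(dates, "%m"))
  pulses <- .pulseTable(config)
  maxL <- config@linf[[sex]] * (1 + 5 * config@cvLinf)
  nclass <- ceiling((maxL - anchor) / binWidth)
  edges <- anchor + binWidth * (0:(nclass - 1L))
  # quadrature nodes over the two lognormal growth multipliers
  qgrid <- function(cv) {
    if (cv <= 0) return(1)
    p <- .lnorm_pars(cv)
    stats::qlnorm((seq_len(nQuad) - 0.5) / nQuad, p["meanlog"], p["sdlog"])
  }
  ul <- qgrid(config@cvLinf)
  uk <- qgrid(config@cvK)
  grid <- expand.grid(ul = ul, uk = uk)
  wgt <- 1 / nrow(grid)
  out <- matrix(0, nclass, length(ty),
                dimnames = list(sprintf("%g", edges), format(dates)))
  for (j in seq_along(ty)) {
    effort <- config@traps * config@trapDaysByMonth[months[j]]
    q <- config@catchability *
      if (sex == "female") config@femaleCatchMult[months[j]] else 1
    for (ci in seq_len(nrow(pulses))) {
      age <- ty[j] - pulses$t[ci]
      if (age <= 0) next
      nAlive <- pulses$n[ci] * exp(-config@z[[sex]] * age)
      L <- config@linf[[sex]] * grid$ul * (1 - exp(-config@k[[sex]] * grid$uk * age))
      pCatch <- 1 - exp(-q * effort * .selectivity(L, config))
      bin <- floor((L - anchor) / binWidth) + 1
      ok <- bin >= 1 & bin <= nclass
      if (!any(ok)) next
      contrib <- vapply(split(pCatch[ok] * wgt * nAlive, bin[ok]), sum,
                        numeric(1))
      ix <- as.integer(names(contrib))
      out[ix, j] <- out[ix, j] + contrib
    }
  }
  out
}
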