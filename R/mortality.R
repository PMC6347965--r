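#' @include AllClasses.R
NULL

#' Powell-Wetherall estimation of Linf and Z/K
#'
#' For a series of length cutoffs L' the mean length of animals at or above
#' L', minus L', is regressed on L' by ordinary least squares. Under a
#' steady-state population with von Bertalanffy growth and constant total
#' mortality above the selection length, the regression line `a + b L'`
#' yields \eqn{L_\infty = -a/b} and \eqn{Z/K = -(1+b)/b}; a valid geometry
#' has slope in (-1, 0).
#'
#' Cutoffs are the lower edges of a bin grid of width `binWidth`, starting at
#' the global modal class (taken as the first fully selected length) and
#' extending to the largest class with at least `minAbove` animals at or
#' above it, so that sparse upper tails do not destabilise the means.
#'
#' @param lengths a [LengthSample-class] object or a numeric vector of
#'   lengths (mm).
#' @param binWidth cutoff spacing in mm (default 4).
#' @param minAbove smallest number of animals at or above a cutoff for it to
#'   be used (default 5).
#' @return a [PWFit-class] object.
#' @examples
#' set.seed(1)
#' # steady-state lengths with Linf = 60, Z/K = 2, full selection above 20 mm
#' u <- runif(5000)
#' L <- 60 - (60 - 20) * (1 - u)^(1 / 2)
#' powellWetherall(L, binWidth = 4)
#' @export
powellWetherall <- function(lengths, binWidth = 4, minAbove = 5) {
  if (is(lengths, "LengthSample")) lengths <- lengths@lengths
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) < 3L) stop("need at least 3 lengths")
  if (diff(range(lengths)) <= 2 * binWidth)
    stop("lengths must span more than 2 bins")
  anchor <- floor(min(lengths))
  edges <- seq(anchor, max(lengths), by = binWidth)
  counts <- vapply(edges, function(e)
    sum(lengths >= e & lengths < e + binWidth), numeric(1))
  modal <- edges[which.max(counts)]
  nAbove <- vapply(edges, function(e) sum(lengths >= e), numeric(1))
  use <- edges >= modal & nAbove >= minAbove
  cutoffs <- edges[use]
  if (length(cutoffs) < 3L) stop("fewer than 3 usable cutoffs")
  meanExcess <- vapply(cutoffs, function(e)
    mean(lengths[lengths >= e]) - e, numeric(1))
  fit <- stats::lm(meanExcess ~ cutoffs)
  a <- unname(stats::coef(fit)[1])
  bb <- unname(stats::coef(fit)[2])
  if (!is.finite(bb) || bb >= 0 || bb <= -1)
    stop("invalid PW geometry: slope ", format(bb, digits = 4),
         " outside (-1, 0)")
  new("PWFit", cutoffs = cutoffs, meanExcess = meanExcess,
      nAbove = as.integer(nAbove[use]), slope = bb, intercept = a,
      linf = -a / bb, zOverK = -(1 + bb) / bb,
      r2 = summary(fit)$r.squared, nPoints = length(cutoffs))
}

#' Total mortality from a Powell-Wetherall fit
#'
#' Z = (Z/K) x K, combining the Powell-Wetherall slope with an externally
#' estimated growth coefficient (typically from ELEFAN).
#'
#' @param pwFit a [PWFit-class] object.
#' @param k growth coefficient (1/year), positive.
#' @return total mortality Z (1/year).
#' @export
zFromPW <- function(pwFit, k) {
  stopifnot(is(pwFit, "PWFit"))
  validObject(pwFit)
  if (k <= 0) stop("k must be positive")
  pwFit@zOverK * k
}

#' Empirical natural-mortality estimators
#'
#' Named empirical estimators of the natural mortality rate M:
#' \describe{
#'   \item{`"pauly"`}{Pauly's temperature regression
#'     `log10 M = -0.0066 - 0.279 log10(Linf) + 0.6543 log10(K) +
#'     0.4634 log10(T)`, with `Linf` in cm (lengths supplied in mm are
#'     converted) and `T` the mean annual water temperature in Celsius.}
#'   \item{`"hoenig"`}{Hoenig's longevity regression
#'     `ln Z = 1.44 - 0.982 ln(t_max)`, used as M for an unfished stock;
#'     decreasing in `t_max`.}
#' }
#' These are coarse cross-species regressions; the analysis pipeline never
#' picks one silently — M is a user decision there.
#'
#' @param method `"pauly"` or `"hoenig"`.
#' @param k growth coefficient (1/year), for `"pauly"`.
#' @param linfMM asymptotic length in mm, for `"pauly"`.
#' @param meanTempC mean annual water temperature (Celsius), for `"pauly"`.
#' @param tMaxYear expected longevity (years), for `"hoenig"`.
#' @return natural mortality M (1/year).
#' @examples
#' naturalMortality("pauly", k = 0.81, linfMM = 60.93, meanTempC = 19.75)
#' naturalMortality("hoenig", tMaxYear = 3.41)
#' @export
naturalMortality <- function(method = c("pauly", "hoenig"), k = NULL,
                             linfMM = NULL, meanTempC = NULL, tMaxYear = NULL) {
  method <- match.arg(method)
  if (method == "pauly") {
    if (is.null(k) || is.null(linfMM) || is.null(meanTempC))
      stop("pauly method needs k, linfMM and meanTempC")
    if (k <= 0 || linfMM <= 0) stop("k and linfMM must be positive")
    if (meanTempC <= 0) stop("meanTempC must be positive")
    10^(-0.0066 - 0.279 * log10(linfMM / 10) + 0.6543 * log10(k) +
          0.4634 * log10(meanTempC))
  } else {
    if (is.null(tMaxYear) || tMaxYear <= 0) stop("hoenig method needs tMaxYear > 0")
    exp(1.44 - 0.982 * log(tMaxYear))
  }
}

#' Decompose total mortality into fishing and natural components
#'
#' F = Z - M and E = F/Z. A stock is flagged overexploited when E exceeds
#' 0.5, the conventional optimum-exploitation reference. When M > Z the
#' decomposition is still reported (F negative, E raw) with a warning.
#'
#' @param z total mortality (1/year), positive.
#' @param m natural mortality (1/year), non-negative.
#' @return a [MortalityEstimates-class] object.
#' @examples
#' decomposeMortality(2.32, 0.93)  # F = 1.39, E = 0.60
#' @export
decomposeMortality <- function(z, m) {
  if (!is.numeric(z) || z <= 0) stop("z must be positive")
  if (!is.numeric(m) || m < 0) stop("m must be non-negative")
  if (m > z) warning("M exceeds Z; F is negative and E reported raw")
  f <- z - m
  e <- f / z
  new("MortalityEstimates", z = z, m = m, f = f, e = e,
      overexploited = e > 0.5)
}
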