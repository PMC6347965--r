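#' @include AllClasses.R
NULL

#' Von Bertalanffy growth function
#'
#' Length at (fractional) age `t` under the VBGF
#' \eqn{L(t) = L_\infty(1 - e^{-K(t - t_0)})}; with seasonal amplitude
#' `C > 0` the standard oscillating variant
#' \eqn{L(t) = L_\infty(1 - e^{-K(t-t_0) - S(t) + S(t_0)})},
#' \eqn{S(t) = (CK/2\pi)\sin(2\pi(t - t_s))}, is used. For `t < t0` the
#' returned length is negative (the curve's analytic continuation); lengths
#' never exceed `linf` for `t >= t0`.
#'
#' @param t numeric vector of times (years).
#' @param params a [VBGFParams-class] object.
#' @return predicted lengths (mm), same shape as `t`.
#' @examples
#' vbgfLength(c(0.5, 1, 2), VBGFParams(linf = 60.93, k = 0.81, t0 = -0.29))
#' @export
vbgfLength <- function(t, params) {
  stopifnot(is(params, "VBGFParams"))
  validObject(params)
  S <- function(x) (params@cAmplitude * params@k / (2 * pi)) * sin(2 * pi * (x - params@ts))
  params@linf * (1 - exp(-params@k * (t - params@t0) - S(t) + S(params@t0)))
}

#' Asymptotic length from the maximum observed length
#'
#' The asymptotic length is taken as `lmax / 0.95`, the conventional rule
#' that the largest animal observed has reached 95% of the asymptote.
#'
#' @param lmaxMM maximum observed length (mm), positive.
#' @return asymptotic length (mm).
#' @examples
#' linfFromLmax(57.8835)  # 60.93
#' @export
linfFromLmax <- function(lmaxMM) {
  if (!is.numeric(lmaxMM) || any(lmaxMM <= 0)) stop("lmaxMM must be positive")
  lmaxMM / 0.95
}

#' Growth performance index
#'
#' The growth performance index combines the growth coefficient and the
#' asymptotic length, `phi' = log(K) + 2 log(Linf)`. The default uses natural
#' logarithms; `base = "decimal"` gives the conventional Munro-Pauly index on
#' base-10 logs.
#'
#' @param k growth coefficient (1/year), positive.
#' @param linf asymptotic length (mm), positive.
#' @param base `"natural"` (default) or `"decimal"`.
#' @return the index value.
#' @examples
#' phiPrime(0.81, 60.93)              # 8.01 on natural logs
#' phiPrime(0.81, 60.93, "decimal")   # the Munro-Pauly convention
#' @export
phiPrime <- function(k, linf, base = c("natural", "decimal")) {
  base <- match.arg(base)
  if (any(k <= 0) || any(linf <= 0)) stop("k and linf must be positive")
  lg <- if (base == "natural") log else log10
  lg(k) + 2 * lg(linf)
}

#' Empirical initial-condition parameter t0
#'
#' Estimates `t0` from `K` and `Linf` via the empirical regression
#' `ln(-t0) = -0.3922 - 0.2752 ln(Linf) - 1.308 ln(K)` (the default,
#' `variant = "as-printed"`). The classic Pauly form on decimal logs,
#' `log10(-t0) = -0.3922 - 0.2752 log10(Linf) - 1.038 log10(K)`, is available
#' as `variant = "classic"`. The result is always negative.
#'
#' @inheritParams phiPrime
#' @param variant which regression to evaluate; see Details.
#' @return `t0` in years (negative).
#' @examples
#' empiricalT0(0.81, 60.93)  # about -0.29
#' @export
empiricalT0 <- function(k, linf, variant = c("as-printed", "classic")) {
  variant <- match.arg(variant)
  if (any(k <= 0) || any(linf <= 0)) stop("k and linf must be positive")
  if (variant == "as-printed")
    -exp(-0.3922 - 0.2752 * log(linf) - 1.308 * log(k))
  else
    -10^(-0.3922 - 0.2752 * log10(linf) - 1.038 * log10(k))
}

#' Expected longevity
#'
#' Longevity approximated as `t_max = 3/K + t0`, the age at which about 95%
#' of the asymptotic length is reached.
#'
#' @inheritParams phiPrime
#' @param t0 initial-condition parameter (years).
#' @return expected longevity (years).
#' @examples
#' tMax(0.81, -0.29)  # 3.41
#' @export
tMax <- function(k, t0) {
  if (any(k <= 0)) stop("k must be positive")
  3 / k + t0
}

#' All derived growth quantities from (K, Linf)
#'
#' Convenience wrapper: growth performance index (natural logs), empirical
#' `t0`, and expected longevity. With `roundTo = 2` the chain is computed the
#' way summary tables are usually assembled: `t0` is rounded first and
#' `t_max` computed from the rounded value.
#'
#' @inheritParams phiPrime
#' @param roundTo decimal places for reporting, or `NULL` for full precision.
#' @return a list with `phiPrime`, `t0`, `tMax`.
#' @examples
#' deriveGrowth(0.81, 60.93, roundTo = 2)
#' @export
deriveGrowth <- function(k, linf, roundTo = NULL) {
  phi <- phiPrime(k, linf)
  t0 <- empiricalT0(k, linf)
  if (!is.null(roundTo)) {
    phi <- round(phi, roundTo)
    t0 <- round(t0, roundTo)
    tm <- round(tMax(k, t0), roundTo)
  } else tm <- tMax(k, t0)
  list(phiPrime = phi, t0 = t0, tMax = tm)
}

#' Serialize / deserialize growth parameters
#'
#' Flat key-value form (keys `linf`, `k`, `t0`, `c`, `ts`, `t_anchor`)
#' suitable for YAML/JSON configs.
#'
#' @param params a [VBGFParams-class] object.
#' @return `vbgfToList` a named list; `vbgfFromList` a
#'   [VBGFParams-class].
#' @export
vbgfToList <- function(params) {
  list(linf = params@linf, k = params@k, t0 = params@t0,
       c = params@cAmplitude, ts = params@ts, t_anchor = params@tAnchor)
}

#' @param x a named list as produced by `vbgfToList`.
#' @rdname vbgfToList
#' @export
vbgfFromList <- function(x) {
  g <- function(key, default = 0) if (is.null(x[[key]])) default else x[[key]]
  VBGFParams(linf = x$linf, k = x$k, t0 = g("t0"), C = g("c"),
             ts = g("ts"), tAnchor = g("t_anchor"))
}
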