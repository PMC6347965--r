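#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setOldClass("Date")

#' LFQData: a length-frequency dataset
#'
#' Container for a binned length-frequency dataset: a matrix of counts with
#' length classes as rows and sampling dates as columns, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with assay `"counts"`,
#' `rowData` column `binLower` (lower edge of each half-open length class, mm)
#' and `colData` columns `date` and `tYear` (the date as a fractional year).
#' Bin width (mm), the sex label and the maximum observed length are kept in
#' `metadata()`.
#'
#' Bins are half-open `[lower, lower + width)`: a length exactly on an edge
#' belongs to the class whose lower edge it equals.
#'
#' @slot . see Description; all content lives in the inherited
#'   `SummarizedExperiment` slots.
#' @seealso [LFQData()] the constructor, [binLFQ()], [restructure()]
#' @exportClass LFQData
setClass("LFQData", contains = "SummarizedExperiment")

setValidity("LFQData", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
  }
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!"binLower" %in% colnames(rd)) msg <- c(msg, "rowData$binLower is required")
  if (!all(c("date", "tYear") %in% colnames(cd)))
    msg <- c(msg, "colData needs 'date' and 'tYear'")
  w <- metadata(object)$binWidth
  if (is.null(w) || !is.numeric(w) || w <= 0)
    msg <- c(msg, "metadata$binWidth must be a positive number")
  if ("binLower" %in% colnames(rd) && nrow(rd) > 1L) {
    d <- diff(rd$binLower)
    if (any(d <= 0)) msg <- c(msg, "bin lower edges must be strictly increasing")
    if (!is.null(w) && is.numeric(w) &&
        any(abs(d - w) > 1e-8)) msg <- c(msg, "bin spacing must equal binWidth")
  }
  if ("date" %in% colnames(cd) && ncol(object) > 1L &&
      is.unsorted(cd$date, strictly = FALSE))
    msg <- c(msg, "sampling dates must be ordered")
  if (is.null(msg)) TRUE else msg
})

#' Construct an LFQData object
#'
#' @param counts integer matrix, length classes (rows) by sampling dates
#'   (columns).
#' @param binLower numeric vector of lower bin edges (mm), ascending, uniform
#'   spacing.
#' @param binWidth bin width in mm.
#' @param dates sampling dates (`Date` or ISO strings), one per column.
#' @param sexLabel label for the sex analysed (`"female"`, `"male"` or
#'   `"pooled"`).
#' @param lmax maximum observed length (mm); defaults to the upper edge of the
#'   last non-empty class.
#' @return an [LFQData-class] object.
#' @examples
#' cts <- matrix(c(2L, 5L, 1L, 0L, 4L, 3L), nrow = 3)
#' lfq <- LFQData(cts, binLower = c(14, 18, 22), binWidth = 4,
#'                dates = c("2016-03-15", "2016-04-15"))
#' binLower(lfq)
#' @export
LFQData <- function(counts, binLower, binWidth, dates,
                    sexLabel = "pooled", lmax = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  dates <- as.Date(dates)
  if (length(binLower) != nrow(counts))
    stop("length(binLower) must equal nrow(counts)")
  if (length(dates) != ncol(counts))
    stop("length(dates) must equal ncol(counts)")
  if (is.null(lmax)) {
    occ <- which(rowSums(counts) > 0)
    lmax <- if (length(occ)) binLower[max(occ)] + binWidth else max(binLower) + binWidth
  }
  dimnames(counts) <- list(sprintf("%g", binLower), format(dates))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(binLower = as.numeric(binLower)),
    colData = DataFrame(date = dates, tYear = dateToYearFrac(dates),
                        row.names = format(dates)),
    metadata = list(binWidth = as.numeric(binWidth),
                    sexLabel = sexLabel, lmax = as.numeric(lmax)))
  new("LFQData", se)
}

#' Von Bertalanffy growth parameters
#'
#' Parameters of the (optionally seasonally oscillating) von Bertalanffy
#' growth function
#' \deqn{L(t) = L_\infty (1 - e^{-K (t - t_0) - S(t) + S(t_0)}),}
#' where \eqn{S(t) = (CK/2\pi)\sin(2\pi(t - t_s))}. With `C = 0` this is the
#' standard VBGF. `tAnchor` locates the recruitment origin within the calendar
#' year for length-frequency curve scoring (fraction of a year in `[0, 1)`).
#'
#' @slot linf asymptotic length \eqn{L_\infty} (mm).
#' @slot k growth coefficient \eqn{K} (1/year).
#' @slot t0 initial-condition parameter \eqn{t_0} (year).
#' @slot cAmplitude amplitude `C` of the seasonal oscillation, in `[0, 1]`.
#' @slot ts onset of the growth season (fraction of year).
#' @slot tAnchor recruitment anchor within the year, in `[0, 1)`.
#' @seealso [VBGFParams()], [vbgfLength()]
#' @exportClass VBGFParams
setClass("VBGFParams",
  representation(linf = "numeric", k = "numeric", t0 = "numeric",
                 cAmplitude = "numeric", ts = "numeric", tAnchor = "numeric"),
  prototype(t0 = 0, cAmplitude = 0, ts = 0, tAnchor = 0))

setValidity("VBGFParams", function(object) {
  msg <- NULL
  for (s in c("linf", "k", "t0", "cAmplitude", "ts", "tAnchor"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("slot '%s' must be a single finite number", s))
  if (is.null(msg)) {
    if (object@linf <= 0) msg <- c(msg, "linf must be > 0")
    if (object@k <= 0) msg <- c(msg, "k must be > 0")
    if (object@cAmplitude < 0 || object@cAmplitude > 1) msg <- c(msg, "C must be in [0, 1]")
    if (object@tAnchor < 0 || object@tAnchor >= 1)
      msg <- c(msg, "tAnchor must be in [0, 1)")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param linf,k,t0,C,ts,tAnchor see the class slots.
#' @return a [VBGFParams-class] object.
#' @examples
#' p <- VBGFParams(linf = 60.93, k = 0.81, t0 = -0.29)
#' vbgfLength(1, p)
#' @rdname VBGFParams-class
#' @export
VBGFParams <- function(linf, k, t0 = 0, C = 0, ts = 0, tAnchor = 0) {
  new("VBGFParams", linf = as.numeric(linf), k = as.numeric(k),
      t0 = as.numeric(t0), cAmplitude = as.numeric(C), ts = as.numeric(ts),
      tAnchor = as.numeric(tAnchor))
}

#' Restructured length-frequency data
#'
#' ELEFAN peak scores obtained from an [LFQData-class] object by
#' [restructure()]: a signed score matrix of the same shape as the counts, the
#' moving-average window used, and the available sum of peaks (ASP).
#'
#' @slot values signed score matrix (classes x dates).
#' @slot maWindow moving-average window width (odd integer).
#' @slot asp available sum of peaks: the summed per-column maxima of runs of
#'   positive scores.
#' @slot lfq the source [LFQData-class] object.
#' @exportClass RestructuredLFQ
setClass("RestructuredLFQ",
  representation(values = "matrix", maWindow = "integer",
                 asp = "numeric", lfq = "LFQData"))

setValidity("RestructuredLFQ", function(object) {
  msg <- NULL
  if (!identical(dim(object@values), dim(object@lfq)))
    msg <- c(msg, "score matrix shape must match the source counts")
  if (any(object@values > 0) && object@asp <= 0)
    msg <- c(msg, "asp must be > 0 when positive scores exist")
  if (is.null(msg)) TRUE else msg
})

#' ELEFAN fit result
#'
#' The best von Bertalanffy parameter set found by an ELEFAN optimizer, its
#' goodness score Rn = 10^(ESP/ASP) / 10, the trace of the best score by
#' iteration, and the seed used.
#'
#' @slot params the fitted [VBGFParams-class].
#' @slot esp explained sum of peaks at the optimum.
#' @slot asp available sum of peaks of the restructured data.
#' @slot rn goodness score in (0, 1].
#' @slot trace best Rn by iteration (SA) or generation (GA).
#' @slot seed RNG seed used for the search.
#' @slot method `"sa"` or `"ga"`.
#' @exportClass ELEFANFit
setClass("ELEFANFit",
  representation(params = "VBGFParams", esp = "numeric", asp = "numeric",
                 rn = "numeric", trace = "numeric", seed = "integer",
                 method = "character"))

#' Powell-Wetherall regression fit
#'
#' For cutoffs L' the mean length of animals at or above L' minus L' is
#' regressed on L'. Under steady state with von Bertalanffy growth the fit
#' line has intercept `a` and slope `b` with
#' \eqn{L_\infty = -a/b} and \eqn{Z/K = -(1+b)/b}.
#'
#' @slot cutoffs the L' values used (mm).
#' @slot meanExcess mean length above each cutoff minus the cutoff (mm).
#' @slot nAbove number of animals at or above each cutoff.
#' @slot slope,intercept OLS coefficients.
#' @slot linf,zOverK derived quantities.
#' @slot r2 coefficient of determination of the regression.
#' @slot nPoints number of cutoffs used.
#' @exportClass PWFit
setClass("PWFit",
  representation(cutoffs = "numeric", meanExcess = "numeric",
                 nAbove = "integer", slope = "numeric", intercept = "numeric",
                 linf = "numeric", zOverK = "numeric", r2 = "numeric",
                 nPoints = "integer"))

setValidity("PWFit", function(object) {
  msg <- NULL
  if (object@slope >= 0 || object@slope <= -1)
    msg <- c(msg, "slope must lie in (-1, 0)")
  if (object@zOverK <= 0) msg <- c(msg, "zOverK must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Mortality decomposition
#'
#' Total mortality Z split into natural (M) and fishing (F = Z - M)
#' components, with the exploitation rate E = F/Z. A stock is flagged
#' overexploited when E > 0.5.
#'
#' @slot z,m,f,e instantaneous rates (1/year) and the exploitation rate.
#' @slot overexploited logical flag, `e > 0.5`.
#' @exportClass MortalityEstimates
setClass("MortalityEstimates",
  representation(z = "numeric", m = "numeric", f = "numeric",
                 e = "numeric", overexploited = "logical"))

#' A pooled sample of individual lengths
#'
#' @slot lengths individual lengths (mm), all positive.
#' @slot sexLabel sex analysed.
#' @slot dateRange first and last sampling date contributing.
#' @exportClass LengthSample
setClass("LengthSample",
  representation(lengths = "numeric", sexLabel = "character",
                 dateRange = "Date"))

setValidity("LengthSample", function(object) {
  if (length(object@lengths) == 0L) return("lengths must be non-empty")
  if (any(object@lengths <= 0)) return("all lengths must be > 0")
  TRUE
})
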