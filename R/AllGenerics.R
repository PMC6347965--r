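#' @include AllClasses.R
NULL

#' Accessors for length-frequency and fit objects
#'
#' `lfqCounts()` returns the counts matrix; `binLower()` the lower bin edges
#' (mm); `binWidth()` the bin width (mm); `sampleDates()` the sampling dates;
#' `sampleTimes()` the dates as fractional years; `sexLabel()` the sex label;
#' `lmax()` the maximum observed length (mm). On an [ELEFANFit-class],
#' `vbgfParams()` returns the fitted parameters and `rnScore()` the goodness
#' score.
#'
#' @param object an [LFQData-class], [RestructuredLFQ-class],
#'   [ELEFANFit-class], [PWFit-class] or [MortalityEstimates-class] object as
#'   appropriate.
#' @return the accessed component.
#' @name accessors
#' @examples
#' cts <- matrix(c(2L, 5L, 1L, 0L, 4L, 3L), nrow = 3)
#' lfq <- LFQData(cts, binLower = c(14, 18, 22), binWidth = 4,
#'                dates = c("2016-03-15", "2016-04-15"))
#' lfqCounts(lfq); binWidth(lfq); sampleTimes(lfq)
NULL

#' @rdname accessors
#' @export
setGeneric("lfqCounts", function(object) standardGeneric("lfqCounts"))
#' @rdname accessors
#' @export
setGeneric("binLower", function(object) standardGeneric("binLower"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("sampleDates", function(object) standardGeneric("sampleDates"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("sexLabel", function(object) standardGeneric("sexLabel"))
#' @rdname accessors
#' @export
setGeneric("lmax", function(object) standardGeneric("lmax"))
#' @rdname accessors
#' @export
setGeneric("vbgfParams", function(object) standardGeneric("vbgfParams"))
#' @rdname accessors
#' @export
setGeneric("rnScore", function(object) standardGeneric("rnScore"))

#' @rdname restructure
#' @export
setGeneric("restructure", function(lfq, maWindow = 5L) standardGeneric("restructure"))

#' @rdname scoreGrowthCurve
#' @export
setGeneric("scoreGrowthCurve", function(restructured, params)
  standardGeneric("scoreGrowthCurve"))

setMethod("lfqCounts", "LFQData", function(object)
  SummarizedExperiment::assay(object, "counts"))
setMethod("binLower", "LFQData", function(object)
  SummarizedExperiment::rowData(object)$binLower)
setMethod("binWidth", "LFQData", function(object) metadata(object)$binWidth)
setMethod("sampleDates", "LFQData", function(object)
  SummarizedExperiment::colData(object)$date)
setMethod("sampleTimes", "LFQData", function(object)
  SummarizedExperiment::colData(object)$tYear)
setMethod("sexLabel", "LFQData", function(object) metadata(object)$sexLabel)
setMethod("lmax", "LFQData", function(object) metadata(object)$lmax)

setMethod("binLower", "RestructuredLFQ", function(object) binLower(object@lfq))
setMethod("binWidth", "RestructuredLFQ", function(object) binWidth(object@lfq))
setMethod("sampleTimes", "RestructuredLFQ", function(object) sampleTimes(object@lfq))

setMethod("vbgfParams", "ELEFANFit", function(object) object@params)
setMethod("rnScore", "ELEFANFit", function(object) object@rn)

setMethod("show", "VBGFParams", function(object) {
  cat("VBGFParams: Linf =", format(object@linf, digits = 5),
      "mm, K =", format(object@k, digits = 4), "/yr, t0 =",
      format(object@t0, digits = 4), "yr\n")
  if (object@cAmplitude > 0)
    cat("  seasonal: C =", object@cAmplitude, ", ts =", object@ts, "\n")
  cat("  recruitment anchor t_anchor =", format(object@tAnchor, digits = 4), "\n")
})

setMethod("show", "RestructuredLFQ", function(object) {
  cat("RestructuredLFQ:", nrow(object@values), "classes x",
      ncol(object@values), "dates; MA =", object@maWindow,
      "; ASP =", format(object@asp, digits = 5), "\n")
})

setMethod("show", "ELEFANFit", function(object) {
  cat("ELEFANFit (", toupper(object@method), "), seed ", object@seed, "\n",
      sep = "")
  show(object@params)
  cat("  ESP/ASP =", format(object@esp, digits = 5), "/",
      format(object@asp, digits = 5), " -> Rn =",
      format(object@rn, digits = 4), "\n")
})

setMethod("show", "PWFit", function(object) {
  cat("Powell-Wetherall fit on", object@nPoints, "cutoffs\n")
  cat("  a =", format(object@intercept, digits = 5),
      ", b =", format(object@slope, digits = 5),
      " (R^2 =", format(object@r2, digits = 3), ")\n")
  cat("  Linf =", format(object@linf, digits = 5),
      "mm, Z/K =", format(object@zOverK, digits = 4), "\n")
})

setMethod("show", "MortalityEstimates", function(object) {
  cat("Mortality: Z =", format(object@z, digits = 4),
      ", M =", format(object@m, digits = 4),
      ", F =", format(object@f, digits = 4),
      ", E =", format(object@e, digits = 4), "\n")
  if (isTRUE(object@overexploited))
    cat("  E > 0.5: overexploited\n")
})

setMethod("show", "LengthSample", function(object) {
  cat("LengthSample:", length(object@lengths), object@sexLabel,
      "lengths,", format(object@dateRange[1]), "to",
      format(object@dateRange[2]), "\n")
})
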