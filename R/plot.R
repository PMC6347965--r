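#' @include AllClasses.R elefan.R
NULL

#' Plot a length-frequency dataset with optional growth curves
#'
#' Draws the monthly length-frequency histograms (or the restructured scores,
#' positive bars filled and negative bars open) side by side along the time
#' axis, optionally overlaying the von Bertalanffy trajectory family of a
#' fit.
#'
#' @param lfq an [LFQData-class] object.
#' @param fit optional [ELEFANFit-class] or [VBGFParams-class] whose cohort
#'   trajectories are overlaid.
#' @param restructured logical; plot restructured scores instead of counts.
#' @param maWindow moving-average width when `restructured = TRUE`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotLFQ <- function(lfq, fit = NULL, restructured = FALSE, maWindow = 5L, ...) {
  ty <- sampleTimes(lfq)
  edges <- binLower(lfq)
  w <- binWidth(lfq)
  vals <- if (restructured) restructure(lfq, maWindow)@values else lfqCounts(lfq)
  xspan <- diff(range(ty))
  halfw <- if (length(ty) > 1L) 0.4 * min(diff(sort(ty))) else 0.04
  scale <- halfw / max(abs(vals), 1e-9)
  graphics::plot(NA, xlim = range(ty) + c(-halfw, halfw) * 2,
                 ylim = c(min(edges), max(edges) + w),
                 xlab = "time (year)", ylab = "length (mm)", ...)
  for (j in seq_along(ty)) {
    v <- vals[, j] * scale
    for (i in seq_along(edges)) {
      if (v[i] == 0) next
      graphics::rect(ty[j], edges[i], ty[j] + v[i], edges[i] + w,
                     col = if (v[i] > 0) "grey40" else "white",
                     border = "grey20")
    }
  }
  if (!is.null(fit)) {
    params <- if (is(fit, "ELEFANFit")) vbgfParams(fit) else fit
    anchors <- .anchorTimes(lfq, params)
    tt <- seq(min(ty) - 0.05, max(ty) + 0.05, length.out = 200)
    for (a in anchors) {
      L <- .trajLength(tt[tt >= a], params, a)
      graphics::lines(tt[tt >= a], L, col = "steelblue", lwd = 1.5)
    }
  }
  invisible(NULL)
}
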