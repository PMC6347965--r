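#' @include AllClasses.R
NULL

#' Gonadosomatic index
#'
#' GSI = 100 x gonad weight / body weight, in percent.
#'
#' @param wGonad gonad weight (g), in `[0, wTotal]`.
#' @param wTotal body weight (g), positive.
#' @return percentage, vectorised.
#' @examples
#' gsi(0.37, 25)   # 1.48
#' @export
gsi <- function(wGonad, wTotal) {
  if (any(wTotal <= 0, na.rm = TRUE)) stop("wTotal must be positive")
  if (any(wGonad < 0, na.rm = TRUE)) stop("wGonad must be non-negative")
  if (any(wGonad > wTotal, na.rm = TRUE)) stop("wGonad must not exceed wTotal")
  100 * wGonad / wTotal
}

#' Hepatosomatic index
#'
#' HSI = 100 x hepatopancreas weight / body weight, in percent.
#'
#' @param wHep hepatopancreas weight (g), in `[0, wTotal]`.
#' @inheritParams gsi
#' @return percentage, vectorised.
#' @examples
#' hsi(1.11, 30)   # 3.70
#' @export
hsi <- function(wHep, wTotal) {
  if (any(wTotal <= 0, na.rm = TRUE)) stop("wTotal must be positive")
  if (any(wHep < 0, na.rm = TRUE)) stop("wHep must be non-negative")
  if (any(wHep > wTotal, na.rm = TRUE)) stop("wHep must not exceed wTotal")
  100 * wHep / wTotal
}

#' Catch per unit effort
#'
#' Daily number of animals per trap: `n / (traps x days)`.
#'
#' @param nCaught number caught during the sampling event.
#' @param nTraps traps deployed, at least 1.
#' @param nDays days fished, at least 1.
#' @return catch per trap per day.
#' @examples
#' cpue(48, 8, 2)  # 3
#' @export
cpue <- function(nCaught, nTraps, nDays) {
  if (any(nTraps < 1) || any(nDays < 1)) stop("effort must be at least 1 trap-day")
  if (any(nCaught < 0)) stop("nCaught must be non-negative")
  nCaught / (nTraps * nDays)
}

#' Chi-squared test of a balanced sex ratio
#'
#' Goodness-of-fit test of observed female/male counts against 1:1, df = 1.
#' By default no continuity correction is applied; `correct = TRUE` applies
#' the Yates correction (which can only lower the statistic).
#'
#' @param nFemale,nMale observed counts, not both zero.
#' @param correct apply the Yates continuity correction?
#' @return a list with `chi2`, `p`, `df`.
#' @examples
#' sexRatioChi2(1012, 1039)  # chi2 = 0.36, p = 0.55
#' @export
sexRatioChi2 <- function(nFemale, nMale, correct = FALSE) {
  n <- nFemale + nMale
  if (n <= 0) stop("counts must not both be zero")
  expd <- n / 2
  dev <- abs(c(nFemale, nMale) - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expd)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L)
}

#' Fecundity summary of berried females
#'
#' Mean, standard error (sd/sqrt(n); 0 with a warning for a single female),
#' minimum, maximum and count of egg numbers.
#'
#' @param eggCounts non-negative egg counts, non-empty.
#' @return a list with `n`, `mean`, `se`, `min`, `max`.
#' @examples
#' fecunditySummary(c(290, 610))
#' @export
fecunditySummary <- function(eggCounts) {
  eggCounts <- eggCounts[!is.na(eggCounts)]
  if (length(eggCounts) == 0L) stop("no egg counts supplied")
  if (any(eggCounts < 0)) stop("egg counts must be non-negative")
  n <- length(eggCounts)
  se <- if (n == 1L) {
    warning("single berried female: SE reported as 0")
    0
  } else stats::sd(eggCounts) / sqrt(n)
  list(n = n, mean = mean(eggCounts), se = se,
       min = min(eggCounts), max = max(eggCounts))
}

#' Monthly summaries of reproductive and effort indices
#'
#' Computes per-animal GSI or HSI, or per-sampling-event CPUE, from a catch
#' record table and summarises by month: median, quartiles, mean, SE and n
#' (matching the usual box-plot presentation of reproductive phenology).
#'
#' @param records catch-record data.frame (see [readCatchRecords()]).
#' @param statistic `"gsi"`, `"hsi"` or `"cpue"`.
#' @param sex `"female"`, `"male"` or `"pooled"`.
#' @return a data.frame with one row per month present in the data, columns
#'   `month`, `n`, `median`, `q25`, `q75`, `mean`, `se`.
#' @export
monthlyIndices <- function(records, statistic = c("gsi", "hsi", "cpue"),
                           sex = c("female", "male", "pooled")) {
  statistic <- match.arg(statistic)
  sex <- match.arg(sex)
  records <- .filterSex(records, sex)
  if (nrow(records) == 0L) stop("no records for sex '", sex, "'")
  month <- as.integer(format(records$date, "%m"))
  vals <- switch(statistic,
    gsi = {
      ok <- !is.na(records$gonad_g) & !is.na(records$weight_g) &
        records$weight_g > 0
      data.frame(month = month[ok],
                 value = gsi(records$gonad_g[ok], records$weight_g[ok]))
    },
    hsi = {
      ok <- !is.na(records$hepatopancreas_g) & !is.na(records$weight_g) &
        records$weight_g > 0
      data.frame(month = month[ok],
                 value = hsi(records$hepatopancreas_g[ok], records$weight_g[ok]))
    },
    cpue = {
      # one value per sampling event: daily catch per trap
      ev <- unique(records[c("date", "traps", "trap_days")])
      ev <- ev[!is.na(ev$traps) & !is.na(ev$trap_days), , drop = FALSE]
      if (nrow(ev) == 0L) stop("no effort metadata in records")
      nc <- vapply(seq_len(nrow(ev)), function(i)
        sum(records$date == ev$date[i]), numeric(1))
      data.frame(month = as.integer(format(ev$date, "%m")),
                 value = cpue(nc, ev$traps, ev$trap_days))
    })
  if (nrow(vals) == 0L) stop("no usable values for statistic '", statistic, "'")
  agg <- lapply(split(vals$value, vals$month), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(n = length(v), median = q[2], q25 = q[1], q75 = q[3], mean = mean(v),
      se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  })
  out <- data.frame(month = as.integer(names(agg)),
                    do.call(rbind, agg), row.names = NULL)
  names(out) <- c("month", "n", "median", "q25", "q75", "mean", "se")
  out[order(out$month), , drop = FALSE]
}
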