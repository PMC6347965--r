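#' @include AllClasses.R
NULL

#' Convert calendar dates to fractional years
#'
#' Dates are mapped to `year + (day_of_year - 0.5) / days_in_year`, so a date
#' sits at the midpoint of its day and leap years are handled exactly.
#'
#' @param dates `Date` vector or ISO strings.
#' @return numeric vector of fractional years.
#' @examples
#' dateToYearFrac("2016-07-01")
#' @export
dateToYearFrac <- function(dates) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  diy <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366L, 365L)
  yr + (doy - 0.5) / diy
}

.recordCols <- c("date", "sex", "ctl_mm", "weight_g", "gonad_g",
                 "hepatopancreas_g", "egg_count", "traps", "trap_days")

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read and validate individual catch records
#'
#' Reads a delimited text file of individual catch records (one row per
#' animal) with a header. Required columns: `date`, `sex`, `ctl_mm`
#' (cephalothorax length, mm). Optional columns: `weight_g`, `gonad_g`,
#' `hepatopancreas_g`, `egg_count`, `traps`, `trap_days`. Rows violating the
#' record invariants (non-positive length, negative weights, organ weight
#' exceeding body weight, egg counts on males, unparseable dates or numbers)
#' are rejected with a per-row reason; valid rows are returned with dates
#' normalised to `Date`.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return a list with elements `records` (data.frame of valid rows) and
#'   `rejects` (data.frame with columns `line` and `reason`; zero rows when
#'   all input is clean).
#' @seealso [binLFQ()], [poolLengths()], [writeValidationReport()]
#' @export
readCatchRecords <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty records file: ", path)
  missing_req <- setdiff(c("date", "sex", "ctl_mm"), names(raw))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  for (cc in setdiff(.recordCols, names(raw))) raw[[cc]] <- NA_character_
  raw <- raw[.recordCols]
  n <- nrow(raw)

  blank <- function(x) is.na(x) | !nzchar(x) | x == "NA"
  dt <- as.Date(ifelse(blank(raw$date), NA, raw$date), format = "%Y-%m-%d")
  sex <- tolower(raw$sex)
  sex[sex %in% c("f", "female")] <- "female"
  sex[sex %in% c("m", "male")] <- "male"
  num <- lapply(raw[c("ctl_mm", "weight_g", "gonad_g", "hepatopancreas_g",
                      "egg_count", "traps", "trap_days")], .num_or_na)

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason <<- ifelse(is.na(reason) & bad, why, reason)
  flag(is.na(dt), "unparseable date")
  flag(!sex %in% c("female", "male"), "unknown sex code")
  flag(blank(raw$ctl_mm) | is.na(num$ctl_mm), "unparseable length")
  flag(!is.na(num$ctl_mm) & num$ctl_mm <= 0, "nonpositive length")
  for (wcol in c("weight_g", "gonad_g", "hepatopancreas_g")) {
    bad_parse <- !blank(raw[[wcol]]) & is.na(num[[wcol]])
    flag(bad_parse, paste("unparseable", wcol))
    flag(!is.na(num[[wcol]]) & num[[wcol]] < 0, paste("negative", wcol))
  }
  flag(!is.na(num$gonad_g) & !is.na(num$weight_g) &
         num$gonad_g > num$weight_g, "gonad weight exceeds body weight")
  flag(!is.na(num$hepatopancreas_g) & !is.na(num$weight_g) &
         num$hepatopancreas_g > num$weight_g,
       "hepatopancreas weight exceeds body weight")
  flag(!blank(raw$egg_count) & is.na(num$egg_count), "unparseable egg_count")
  flag(!is.na(num$egg_count) &
         (num$egg_count < 0 | num$egg_count != round(num$egg_count)),
       "invalid egg_count")
  flag(!is.na(num$egg_count) & sex == "male", "egg count on male")

  ok <- is.na(reason)
  records <- data.frame(date = dt[ok], sex = sex[ok], ctl_mm = num$ctl_mm[ok],
                        weight_g = num$weight_g[ok], gonad_g = num$gonad_g[ok],
                        hepatopancreas_g = num$hepatopancreas_g[ok],
                        egg_count = num$egg_count[ok], traps = num$traps[ok],
                        trap_days = num$trap_days[ok],
                        stringsAsFactors = FALSE)
  # header is line 1, so data row i sits on file line i + 1
  rejects <- data.frame(line = which(!ok) + 1L, reason = reason[!ok],
                        stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

#' Write a machine-readable validation report
#'
#' @param validated the list returned by [readCatchRecords()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeValidationReport <- function(validated, path) {
  rep <- list(n_valid = nrow(validated$records),
              n_rejected = nrow(validated$rejects),
              rejects = validated$rejects)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

.filterSex <- function(records, sex) {
  sex <- match.arg(sex, c("female", "male", "pooled"))
  if (sex != "pooled") records <- records[records$sex == sex, , drop = FALSE]
  records
}

#' Bin catch records into a length-frequency dataset
#'
#' Assigns each record's length to a half-open bin `[lower, lower + width)`
#' on a uniform grid anchored at `anchor` and tabulates counts per sampling
#' date. Sexes are analysed separately by default; `sex = "pooled"` combines
#' them.
#'
#' @param records data.frame of catch records (as from [readCatchRecords()]).
#' @param binWidth bin width in mm (default 4).
#' @param anchor lower edge of the first bin (mm); default: the minimum
#'   observed length floored to the nearest integer mm.
#' @param sex `"female"`, `"male"` or `"pooled"`.
#' @return an [LFQData-class] object; column sums equal the number of binned
#'   records per date and `lmax()` is the maximum observed length.
#' @examples
#' rec <- data.frame(date = as.Date("2016-03-15"), sex = "female",
#'                   ctl_mm = c(15.2, 18, 19.9))
#' lfqCounts(binLFQ(rec, binWidth = 4, anchor = 14, sex = "female"))
#' @export
binLFQ <- function(records, binWidth = 4, anchor = NULL,
                   sex = c("female", "male", "pooled")) {
  sex <- match.arg(sex)
  if (binWidth <= 0) stop("binWidth must be > 0")
  records <- .filterSex(records, sex)
  if (nrow(records) == 0L) stop("no records for sex '", sex, "'")
  len <- records$ctl_mm
  if (any(is.na(len) | len <= 0)) stop("records contain invalid lengths")
  if (is.null(anchor)) anchor <- floor(min(len))
  if (min(len) < anchor) stop("anchor must not exceed the minimum length")
  nclass <- max(1L, ceiling((max(len) - anchor) / binWidth))
  if (max(len) >= anchor + nclass * binWidth) nclass <- nclass + 1L  # edge case
  edges <- anchor + binWidth * (0:(nclass - 1L))
  idx <- findInterval(len, c(edges, anchor + nclass * binWidth),
                      rightmost.closed = FALSE, left.open = FALSE)
  dates <- sort(unique(records$date))
  counts <- vapply(dates, function(d) {
    tabulate(idx[records$date == d], nbins = nclass)
  }, integer(nclass))
  counts <- matrix(counts, nrow = nclass, ncol = length(dates))
  LFQData(counts, binLower = edges, binWidth = binWidth, dates = dates,
          sexLabel = sex, lmax = max(len))
}

#' Pool individual lengths across sampling dates
#'
#' Collects all lengths for one sex within a date range, e.g. to feed the
#' Powell-Wetherall estimator with a full year of samples.
#'
#' @inheritParams binLFQ
#' @param dateRange length-2 vector (`Date` or ISO strings) of inclusive
#'   bounds, or `NULL` for all dates.
#' @return a [LengthSample-class] object.
#' @export
poolLengths <- function(records, sex = c("female", "male", "pooled"),
                        dateRange = NULL) {
  sex <- match.arg(sex)
  records <- .filterSex(records, sex)
  if (!is.null(dateRange)) {
    dateRange <- as.Date(dateRange)
    records <- records[records$date >= dateRange[1] &
                         records$date <= dateRange[2], , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records in the requested selection")
  new("LengthSample", lengths = records$ctl_mm, sexLabel = sex,
      dateRange = range(records$date))
}

#' Write / read an LFQ matrix as CSV
#'
#' Layout: first column `bin_lower`, remaining columns one per sampling date
#' (ISO header), cells are counts.
#'
#' @param lfq an [LFQData-class] object.
#' @param path CSV path.
#' @return `writeLFQ` returns `path` invisibly; `readLFQ` an
#'   [LFQData-class] object.
#' @export
writeLFQ <- function(lfq, path) {
  df <- data.frame(bin_lower = binLower(lfq), lfqCounts(lfq),
                   check.names = FALSE)
  colnames(df) <- c("bin_lower", format(sampleDates(lfq)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param binWidth bin width in mm; for `readLFQ` inferred from the edge
#'   spacing when `NULL`.
#' @param sexLabel sex label to attach when reading.
#' @rdname writeLFQ
#' @export
readLFQ <- function(path, binWidth = NULL, sexLabel = "pooled") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "bin_lower") stop("first column must be 'bin_lower'")
  edges <- df[[1]]
  if (is.null(binWidth)) {
    if (length(edges) < 2L) stop("cannot infer binWidth from one class")
    binWidth <- diff(edges)[1]
  }
  cts <- as.matrix(df[-1])
  LFQData(cts, binLower = edges, binWidth = binWidth,
          dates = as.Date(names(df)[-1]), sexLabel = sexLabel)
}
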