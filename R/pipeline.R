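#' @include AllClasses.R records.R growth.R elefan.R mortality.R repro.R
NULL

#' Assemble a pipeline configuration
#'
#' @param records path to a catch-record CSV, or a records data.frame.
#' @param outDir output directory for the report bundle.
#' @param sexes sexes to analyse separately.
#' @param binWidth,anchor length-class grid (mm); `anchor = NULL` floors the
#'   minimum observed length.
#' @param maWindow ELEFAN moving-average width.
#' @param method `"sa"` or `"ga"`.
#' @param bounds optimizer bounds (see [fitELEFAN()]), or `NULL` for the
#'   defaults derived from the data.
#' @param control optimizer control overrides.
#' @param seed RNG seed, recorded in every output.
#' @param pwMinAbove Powell-Wetherall cutoff rule: smallest tail count.
#' @param m named numeric of user-supplied natural mortality per sex (the
#'   recommended route), or `NULL` to use `mMethod`.
#' @param mMethod,meanTempC empirical M estimator (see [naturalMortality()])
#'   and its temperature input, used only when `m` is `NULL`; the choice is
#'   recorded in the run log.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(records, outDir, sexes = c("female", "male"),
                           binWidth = 4, anchor = NULL, maWindow = 5L,
                           method = c("sa", "ga"), bounds = NULL,
                           control = list(), seed = 1L, pwMinAbove = 5,
                           m = NULL, mMethod = NULL, meanTempC = NULL) {
  method <- match.arg(method)
  if (is.character(records) && !file.exists(records))
    stop("records file not found: ", records)
  if (is.null(m) && is.null(mMethod))
    stop("natural mortality must be chosen explicitly: supply 'm' ",
         "(per-sex values) or 'mMethod' (empirical estimator)")
  structure(list(records = records, outDir = outDir, sexes = sexes,
                 binWidth = binWidth, anchor = anchor, maWindow = maWindow,
                 method = method, bounds = bounds, control = control,
                 seed = as.integer(seed), pwMinAbove = pwMinAbove, m = m,
                 mMethod = mMethod, meanTempC = meanTempC),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()].
#'
#' @param path YAML file path.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipelineConfig)))]
  if (!is.null(args$m)) args$m <- unlist(args$m)
  do.call(pipelineConfig, args)
}

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

#' Run the full length-frequency assessment pipeline
#'
#' Per sex: bins the records into a length-frequency matrix, restructures it,
#' fits the growth curve by ELEFAN, derives the growth quantities (growth
#' performance index, empirical t0, longevity), runs Powell-Wetherall on the
#' pooled lengths, combines Z/K with the fitted K into Z, decomposes Z into M
#' and F with the exploitation rate, and computes reproductive and effort
#' index tables. All intermediates are written as CSV/JSON into `outDir`
#' together with a summary table (one row per sex: K, Linf, t0, t_max, phi',
#' Z, M, F, E), a sex-ratio test, a fecundity summary, and a run log
#' capturing the seed and every decision flag. A failing stage aborts with
#' the stage name; outputs written so far are preserved.
#'
#' @param config a `pipelineConfig` list (see [pipelineConfig()]) or a path
#'   to a YAML file for [readPipelineConfig()].
#' @return invisibly, a list with per-sex results and the summary data.frame.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "run_log.txt")
  logLines <- c(sprintf("lfqfit pipeline run %s", format(Sys.time())),
                sprintf("R version: %s", R.version.string),
                sprintf("seed: %d", config$seed),
                sprintf("method: %s, MA = %d, binWidth = %g",
                        config$method, as.integer(config$maWindow),
                        config$binWidth))
  say <- function(...) logLines <<- c(logLines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(logLines, sprintf("FAILED at stage '%s': %s", name,
                                     conditionMessage(e))), logPath)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("read_records", {
    if (is.character(config$records)) {
      v <- readCatchRecords(config$records)
      say("input: %s (%d valid, %d rejected rows)", config$records,
          nrow(v$records), nrow(v$rejects))
      writeValidationReport(v, file.path(config$outDir, "validation.json"))
      v$records
    } else config$records
  })

  nF <- sum(records$sex == "female")
  nM <- sum(records$sex == "male")
  sr <- stage("sex_ratio", sexRatioChi2(nF, nM, correct = FALSE))
  say("sex ratio %d F / %d M: chi2 = %.4f, p = %.4f (uncorrected)",
      nF, nM, sr$chi2, sr$p)
  .writeJSON(c(list(n_female = nF, n_male = nM), sr),
             file.path(config$outDir, "sex_ratio.json"))

  eggs <- records$egg_count[!is.na(records$egg_count)]
  fec <- NULL
  if (length(eggs)) {
    fec <- stage("fecundity", fecunditySummary(eggs))
    say("fecundity: n = %d, mean = %.1f +/- %.1f (SE), range %g-%g",
        fec$n, fec$mean, fec$se, fec$min, fec$max)
    .writeJSON(fec, file.path(config$outDir, "fecundity.json"))
  }

  perSex <- list()
  summary <- NULL
  for (sx in config$sexes) {
    lfq <- stage(paste0("bin_lfq_", sx),
                 binLFQ(records, binWidth = config$binWidth,
                        anchor = config$anchor, sex = sx))
    writeLFQ(lfq, file.path(config$outDir, paste0("lfq_", sx, ".csv")))
    say("%s: %d records in %d classes x %d dates, Lmax = %.2f mm", sx,
        sum(lfqCounts(lfq)), nrow(lfq), ncol(lfq), lmax(lfq))

    rlfq <- stage(paste0("restructure_", sx),
                  restructure(lfq, config$maWindow))
    utils::write.csv(
      data.frame(bin_lower = binLower(lfq), rlfq@values, check.names = FALSE),
      file.path(config$outDir, paste0("restructured_", sx, ".csv")),
      row.names = FALSE)

    fit <- stage(paste0("elefan_", sx),
                 fitELEFAN(lfq, method = config$method, bounds = config$bounds,
                           maWindow = config$maWindow, control = config$control,
                           seed = config$seed))
    p <- vbgfParams(fit)
    say("%s ELEFAN_%s: Linf = %.2f, K = %.3f, t_anchor = %.3f, Rn = %.4f",
        sx, toupper(config$method), p@linf, p@k, p@tAnchor, fit@rn)
    .writeJSON(list(params = vbgfToList(p), esp = fit@esp, asp = fit@asp,
                    rn = fit@rn, seed = fit@seed, method = fit@method),
               file.path(config$outDir, paste0("fit_", sx, ".json")))

    dg <- deriveGrowth(p@k, p@linf, roundTo = 2)
    pw <- stage(paste0("powell_wetherall_", sx),
                powellWetherall(poolLengths(records, sex = sx),
                                binWidth = config$binWidth,
                                minAbove = config$pwMinAbove))
    z <- zFromPW(pw, p@k)
    .writeJSON(list(cutoffs = pw@cutoffs, meanExcess = pw@meanExcess,
                    slope = pw@slope, intercept = pw@intercept,
                    linf = pw@linf, zOverK = pw@zOverK, r2 = pw@r2),
               file.path(config$outDir, paste0("pw_", sx, ".json")))

    m <- stage(paste0("natural_mortality_", sx), {
      if (!is.null(config$m)) {
        if (!sx %in% names(config$m))
          stop("no user M supplied for sex '", sx, "'")
        say("%s: M = %.3f (user-supplied)", sx, config$m[[sx]])
        config$m[[sx]]
      } else {
        mv <- naturalMortality(config$mMethod, k = p@k, linfMM = p@linf,
                               meanTempC = config$meanTempC,
                               tMaxYear = dg$tMax)
        say("%s: M = %.3f (%s estimator)", sx, mv, config$mMethod)
        mv
      }
    })
    mort <- stage(paste0("decompose_", sx), decomposeMortality(z, m))
    .writeJSON(list(z = mort@z, m = mort@m, f = mort@f, e = mort@e,
                    overexploited = mort@overexploited),
               file.path(config$outDir, paste0("mortality_", sx, ".json")))
    say("%s: Z = %.3f, F = %.3f, E = %.3f%s", sx, mort@z, mort@f, mort@e,
        if (mort@overexploited) " (overexploited)" else "")

    for (st in c("gsi", "hsi", "cpue")) {
      tb <- tryCatch(monthlyIndices(records, st, sex = sx),
                     error = function(e) NULL)
      if (!is.null(tb))
        utils::write.csv(tb, file.path(config$outDir,
                                       sprintf("indices_%s_%s.csv", st, sx)),
                         row.names = FALSE)
    }

    summary <- rbind(summary, data.frame(
      sex = sx, k = p@k, linf = p@linf, t0 = dg$t0, t_max = dg$tMax,
      phi_prime = dg$phiPrime, z = z, m = m, f = mort@f, e = mort@e,
      rn = fit@rn, stringsAsFactors = FALSE))
    perSex[[sx]] <- list(lfq = lfq, restructured = rlfq, fit = fit,
                         derived = dg, pw = pw, mortality = mort)
  }

  utils::write.csv(summary, file.path(config$outDir, "summary.csv"),
                   row.names = FALSE)
  .writeJSON(summary, file.path(config$outDir, "summary.json"))
  writeLines(logLines, logPath)
  invisible(list(summary = summary, perSex = perSex,
                 sexRatio = sr, fecundity = fec))
}
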