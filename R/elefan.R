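#' @include AllClasses.R AllGenerics.R growth.R
NULL

# maximal runs of strictly positive scores in a column; returns a list of
# index vectors (each one contiguous)
.posRuns <- function(sc) {
  pos <- sc > 0
  if (!any(pos)) return(list())
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) starts[i]:ends[i])
}

#' Restructure a length-frequency dataset into peak scores
#'
#' Implements the ELEFAN restructuring of a length-frequency matrix, column
#' (sampling date) by column:
#' \enumerate{
#'   \item centred moving average of width `maWindow` over length classes
#'     (edge classes use the truncated window);
#'   \item relative deviation `count / MA - 1` (zero where the moving average
#'     is zero);
#'   \item isolated-peak de-emphasis: each positive score is divided by one
#'     plus the number of adjacent zero-count classes, so a spike flanked by
#'     empty classes is down-weighted;
#'   \item balancing: negative scores are rescaled so that, per column, the
#'     sum of positive scores equals the absolute sum of negative scores
#'     (columns sum to zero whenever both signs occur).
#' }
#' The available sum of peaks (ASP) is the sum over columns of the maxima of
#' each run of consecutive positive scores.
#'
#' A column of identical counts restructures to all-zero scores, and scores
#' are invariant to rescaling all counts in a column by a positive constant.
#'
#' @param lfq an [LFQData-class] object.
#' @param maWindow odd moving-average width, at least 3 and smaller than the
#'   number of length classes (the study setting is 5).
#' @return a [RestructuredLFQ-class] object.
#' @examples
#' lfq <- LFQData(matrix(c(0L, 0L, 10L, 0L, 0L), ncol = 1),
#'                binLower = seq(14, 30, 4), binWidth = 4, dates = "2016-03-15")
#' restructure(lfq, maWindow = 5)@values
#' @rdname restructure
#' @aliases restructure,LFQData-method
#' @export
setMethod("restructure", "LFQData", function(lfq, maWindow = 5L) {
  ma <- as.integer(maWindow)
  cts <- lfqCounts(lfq)
  n <- nrow(cts)
  if (ma %% 2L == 0L || ma < 3L) stop("maWindow must be odd and >= 3")
  if (ma > n) stop("maWindow must not exceed the number of classes")
  half <- (ma - 1L) %/% 2L
  vals <- matrix(0, n, ncol(cts), dimnames = dimnames(cts))
  for (j in seq_len(ncol(cts))) {
    x <- as.numeric(cts[, j])
    mavg <- vapply(seq_len(n), function(i)
      mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
    sc <- ifelse(mavg > 0, x / mavg - 1, 0)
    for (i in which(sc > 0)) {
      nz <- (i > 1L && x[i - 1L] == 0) + (i < n && x[i + 1L] == 0)
      sc[i] <- sc[i] / (1 + nz)
    }
    pos <- sum(sc[sc > 0])
    neg <- -sum(sc[sc < 0])
    if (pos > 0 && neg > 0) sc[sc < 0] <- sc[sc < 0] * (pos / neg)
    vals[, j] <- sc
  }
  asp <- sum(vapply(seq_len(ncol(vals)), function(j) {
    runs <- .posRuns(vals[, j])
    if (!length(runs)) 0 else sum(vapply(runs, function(ix) max(vals[ix, j]),
                                         numeric(1)))
  }, numeric(1)))
  new("RestructuredLFQ", values = vals, maWindow = ma, asp = asp, lfq = lfq)
})

# length along a cohort trajectory anchored (length zero) at absolute time a
.trajLength <- function(t, params, a) {
  S <- function(x) (params@cAmplitude * params@k / (2 * pi)) * sin(2 * pi * (x - params@ts))
  params@linf * (1 - exp(-params@k * (t - a) - S(t) + S(a)))
}

# cohorts older than the longevity implied by the candidate (t_max = 3/K,
# the age of ~95% asymptotic length) are no longer alive; the cap also
# bounds the age at which the curve outgrows the largest class
.ageCap <- function(lfq, params) {
  hiEdge <- max(binLower(lfq)) + binWidth(lfq)
  min(3 / params@k,
      if (hiEdge < params@linf)
        -log(1 - hiEdge / params@linf) / params@k else Inf)
}

# candidate anchor times (one per calendar year) whose trajectory can
# intersect the observed length range during the sampling window
.anchorTimes <- function(lfq, params) {
  ty <- sampleTimes(lfq)
  loEdge <- min(binLower(lfq))
  hiEdge <- max(binLower(lfq)) + binWidth(lfq)
  ageTop <- .ageCap(lfq, params)
  years <- seq.int(floor(min(ty) - ageTop) - 1L, floor(max(ty)))
  a <- years + params@tAnchor
  keep <- vapply(a, function(ai) {
    tt <- ty[ty >= ai & ty - ai <= ageTop]
    if (!length(tt)) return(FALSE)
    L <- .trajLength(tt, params, ai)
    any(L >= loEdge & L < hiEdge)
  }, logical(1))
  a[keep]
}

# cells (row, col) hit by the trajectory family; one row per hit
.hitCells <- function(lfq, params) {
  ty <- sampleTimes(lfq)
  edges <- binLower(lfq)
  w <- binWidth(lfq)
  nclass <- length(edges)
  anchors <- .anchorTimes(lfq, params)
  if (!length(anchors))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  ageTop <- .ageCap(lfq, params)
  hits <- NULL
  for (a in anchors) {
    ok <- ty >= a & ty - a <= ageTop
    if (!any(ok)) next
    L <- .trajLength(ty[ok], params, a)
    row <- floor((L - edges[1]) / w) + 1
    j <- which(ok)
    valid <- row >= 1 & row <= nclass
    if (any(valid))
      hits <- rbind(hits, cbind(row = as.integer(row[valid]),
                                col = as.integer(j[valid])))
  }
  if (is.null(hits))
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
  else hits  # one row per trajectory crossing; duplicates intended
}

#' Score a growth-curve family against restructured data
#'
#' Evaluates the explained sum of peaks (ESP) of the von Bertalanffy
#' trajectory family defined by `params` (one trajectory per calendar year,
#' anchored at `tAnchor`): a trajectory hits a (class, date) cell when its
#' predicted length at that date falls in the cell's half-open length
#' interval. Each run of positive scores contributes its maximum once, on
#' first hit (the peak is then flagged out); cells with non-positive score
#' contribute their value at every trajectory crossing, so families dense
#' enough to sweep the whole grid pay for every trough they cross.
#' The goodness score is `Rn = 10^(ESP/ASP) / 10`, in (0, 1], equal to 1
#' exactly when every peak is explained and no negative cell is crossed.
#'
#' @param restructured a [RestructuredLFQ-class] object.
#' @param params a [VBGFParams-class] object (with `tAnchor` set).
#' @return a list with `esp`, `asp`, `rn`.
#' @rdname scoreGrowthCurve
#' @aliases scoreGrowthCurve,RestructuredLFQ-method
#' @export
setMethod("scoreGrowthCurve", "RestructuredLFQ", function(restructured, params) {
  validObject(params)
  if (restructured@asp <= 0) stop("unscorable dataset: ASP is zero")
  vals <- restructured@values
  hits <- .hitCells(restructured@lfq, params)
  esp <- 0
  for (j in unique(hits[, "col"])) {
    rows <- hits[hits[, "col"] == j, "row"]
    sc <- vals[, j]
    runs <- .posRuns(sc)
    credited <- logical(length(runs))
    for (i in rows) {
      if (sc[i] > 0) {
        ri <- which(vapply(runs, function(ix) i %in% ix, logical(1)))
        if (!credited[ri]) {
          esp <- esp + max(sc[runs[[ri]]])
          credited[ri] <- TRUE
        }
      } else esp <- esp + sc[i]
    }
  }
  esp <- unname(esp)
  list(esp = esp, asp = restructured@asp,
       rn = 10^(esp / restructured@asp) / 10)
})

#' Enumerate cohort growth tracks
#'
#' Lists the growth trajectories (one per recruitment year, all sharing
#' `linf`, `k` and `tAnchor`) that intersect the observed length range during
#' the sampling window, with predicted mean length per sampling date.
#'
#' @param lfq an [LFQData-class] object.
#' @param params fitted [VBGFParams-class].
#' @param maxCohorts keep at most this many tracks (the youngest are kept).
#' @return a list with `nCohorts` and `tracks`, a data.frame with columns
#'   `cohort` (1 = oldest), `anchorTime`, `date`, `tYear`, `predLength`
#'   (NA before the cohort's recruitment).
#' @export
identifyCohorts <- function(lfq, params, maxCohorts = Inf) {
  validObject(params)
  anchors <- .anchorTimes(lfq, params)
  if (length(anchors) > maxCohorts)
    anchors <- sort(anchors)[seq.int(length(anchors) - maxCohorts + 1,
                                     length(anchors))]
  anchors <- sort(anchors)
  ty <- sampleTimes(lfq)
  if (!length(anchors))
    return(list(nCohorts = 0L,
                tracks = data.frame(cohort = integer(0), anchorTime = numeric(0),
                                    date = as.Date(character(0)),
                                    tYear = numeric(0), predLength = numeric(0))))
  tracks <- do.call(rbind, lapply(seq_along(anchors), function(i) {
    a <- anchors[i]
    L <- ifelse(ty >= a, .trajLength(ty, params, a), NA_real_)
    data.frame(cohort = i, anchorTime = a, date = sampleDates(lfq),
               tYear = ty, predLength = L)
  }))
  list(nCohorts = length(anchors), tracks = tracks)
}

.defaultBounds <- function(lfq) {
  # an asymptote below the largest observed animal is inconsistent with the
  # data, so the box is [Lmax, 1.2 * Lmax/0.95]
  linf0 <- linfFromLmax(lmax(lfq))
  list(linf = c(lmax(lfq), 1.2 * linf0), k = c(0.1, 2.0), tAnchor = c(0, 1))
}

.boundsMatrix <- function(bounds) {
  nm <- c("linf", "k", "tAnchor")
  if (!all(nm %in% names(bounds)))
    stop("bounds must name linf, k and tAnchor")
  b <- vapply(nm, function(p) {
    v <- bounds[[p]]
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || any(!is.finite(v)) || v[2] < v[1])
      stop("invalid bounds for ", p)
    v
  }, numeric(2))
  rownames(b) <- c("lo", "hi")
  b
}

.mkParams <- function(x) {
  ta <- min(max(x[3], 0), 1 - 1e-9)
  VBGFParams(linf = x[1], k = x[2], tAnchor = ta)
}

#' Fit von Bertalanffy growth to length-frequency data by ELEFAN
#'
#' Restructures the length-frequency data and searches the (Linf, K,
#' t_anchor) box for the trajectory family maximising the ELEFAN goodness
#' score Rn, by generalized simulated annealing (`method = "sa"`) or by a
#' real-coded genetic algorithm (`method = "ga"`). Both searches are fully
#' seeded and reproducible.
#'
#' Simulated annealing: the initial temperature is the Rn range over 50
#' random probes of the box, cooling is geometric (`cooling`, default 0.95
#' per iteration; set `epoch` > 1 to cool only every `epoch` proposals for a
#' slower anneal), proposals are Gaussian steps scaled by the current
#' temperature and reflected into the bounds. Genetic algorithm: tournament
#' selection (size 2), blend crossover, Gaussian mutation, elitism of one.
#'
#' @param lfq an [LFQData-class] object.
#' @param method `"sa"` or `"ga"`.
#' @param bounds list with elements `linf`, `k`, `tAnchor`, each `c(lo, hi)`
#'   (a single value fixes the parameter). Default: `Linf` in
#'   `[lmax, 1.2 * lmax/0.95]` (the asymptote cannot be below the largest
#'   observed animal), `K` in `[0.1, 2]`, `tAnchor` in `[0, 1)`.
#' @param maWindow moving-average width for restructuring (default 5).
#' @param control optional overrides: SA `iterations` (1000), `cooling`
#'   (0.95), `epoch` (1), `probes` (50); GA `popSize` (50), `generations`
#'   (100), `crossover` (0.8), `mutation` (0.1).
#' @param seed integer RNG seed; two runs with the same seed return identical
#'   results.
#' @return an [ELEFANFit-class] object.
#' @examples
#' \donttest{
#' cfg <- simConfig(recruitsPerYear = 2000)
#' lfq <- binLFQ(simulatePopulation(cfg, seed = 7)$records, sex = "male")
#' fit <- fitELEFAN(lfq, method = "sa", seed = 1,
#'                  control = list(iterations = 200))
#' vbgfParams(fit)
#' }
#' @export
fitELEFAN <- function(lfq, method = c("sa", "ga"), bounds = NULL,
                      maWindow = 5L, control = list(), seed = 1L) {
  method <- match.arg(method)
  if (is.null(bounds)) bounds <- .defaultBounds(lfq)
  b <- .boundsMatrix(bounds)
  rlfq <- restructure(lfq, maWindow)
  if (rlfq@asp <= 0) stop("unscorable dataset: ASP is zero")
  obj <- function(x) scoreGrowthCurve(rlfq, .mkParams(x))$rn
  seed <- as.integer(seed)
  set.seed(seed)
  res <- if (method == "sa") .optimSA(obj, b, control) else .optimGA(obj, b, control)
  best <- .mkParams(res$par)
  sc <- scoreGrowthCurve(rlfq, best)
  new("ELEFANFit", params = best, esp = sc$esp, asp = sc$asp, rn = sc$rn,
      trace = res$trace, seed = seed, method = method)
}

.runif_box <- function(n, b) {
  np <- ncol(b)
  m <- matrix(stats::runif(n * np), n, np)
  sweep(sweep(m, 2, b["hi", ] - b["lo", ], "*"), 2, b["lo", ], "+")
}

.reflect <- function(x, lo, hi) {
  w <- hi - lo
  out <- x
  free <- w > 0
  if (any(free)) {
    y <- (x[free] - lo[free]) %% (2 * w[free])
    out[free] <- lo[free] + ifelse(y > w[free], 2 * w[free] - y, y)
  }
  out[!free] <- lo[!free]
  out
}

.optimSA <- function(obj, b, control) {
  ctl <- utils::modifyList(list(iterations = 1000L, cooling = 0.95,
                                epoch = 1L, probes = 50L), control)
  lo <- b["lo", ]; hi <- b["hi", ]
  probes <- .runif_box(ctl$probes, b)
  pscore <- apply(probes, 1, obj)
  cur <- probes[which.max(pscore), ]
  curScore <- max(pscore)
  best <- cur; bestScore <- curScore
  T0 <- max(diff(range(pscore)), 1e-6)
  temp <- T0
  stepScale <- 0.2 * (hi - lo)
  trace <- numeric(ctl$iterations)
  for (it in seq_len(ctl$iterations)) {
    relT <- max(temp / T0, 0.05)
    prop <- .reflect(cur + stats::rnorm(length(cur)) * stepScale * relT, lo, hi)
    propScore <- obj(prop)
    if (propScore >= curScore ||
        stats::runif(1) < exp((propScore - curScore) / temp)) {
      cur <- prop; curScore <- propScore
    }
    if (curScore > bestScore) { best <- cur; bestScore <- curScore }
    trace[it] <- bestScore
    # geometric cooling once per epoch so the chain explores at each level
    if (it %% ctl$epoch == 0L) temp <- temp * ctl$cooling
  }
  list(par = best, score = bestScore, trace = trace)
}

.optimGA <- function(obj, b, control) {
  ctl <- utils::modifyList(list(popSize = 50L, generations = 100L,
                                crossover = 0.8, mutation = 0.1), control)
  lo <- b["lo", ]; hi <- b["hi", ]
  np <- ncol(b)
  pop <- .runif_box(ctl$popSize, b)
  if (np == 1L) pop <- matrix(pop, ncol = 1L)
  fit <- apply(pop, 1, obj)
  mutSD <- 0.1 * (hi - lo)
  trace <- numeric(ctl$generations)
  for (g in seq_len(ctl$generations)) {
    elite <- pop[which.max(fit), ]
    eliteFit <- max(fit)
    sel <- function() {
      # tournament of two
      i <- sample.int(nrow(pop), 2L, replace = TRUE)
      pop[i[which.max(fit[i])], ]
    }
    newPop <- matrix(NA_real_, nrow(pop), np)
    i <- 1L
    while (i <= nrow(pop)) {
      p1 <- sel()
      p2 <- if (nrow(pop) > 1L) sel() else p1
      if (stats::runif(1) < ctl$crossover && nrow(pop) > 1L) {
        u <- stats::runif(np)  # blend crossover
        c1 <- u * p1 + (1 - u) * p2
        c2 <- (1 - u) * p1 + u * p2
      } else { c1 <- p1; c2 <- p2 }
      newPop[i, ] <- c1
      if (i + 1L <= nrow(pop)) newPop[i + 1L, ] <- c2
      i <- i + 2L
    }
    if (ctl$mutation > 0) {
      mut <- matrix(stats::runif(length(newPop)) < ctl$mutation, nrow(pop), np)
      pert <- matrix(stats::rnorm(length(newPop)), nrow(pop), np) *
        rep(mutSD, each = nrow(pop))
      newPop[mut] <- newPop[mut] + pert[mut]
    }
    newPop <- t(apply(newPop, 1, .reflect, lo = lo, hi = hi))
    if (np == 1L) newPop <- matrix(newPop, ncol = 1L)
    pop <- newPop
    fit <- apply(pop, 1, obj)
    # elitism: preserve the previous best
    if (eliteFit > max(fit)) {
      worst <- which.min(fit)
      pop[worst, ] <- elite
      fit[worst] <- eliteFit
    }
    trace[g] <- max(fit)
  }
  best <- which.max(fit)
  list(par = pop[best, ], score = fit[best], trace = trace)
}
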