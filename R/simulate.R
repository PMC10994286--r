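#' Strategy configuration for whole-field testing
#'
#' @param meta meta-strategy: `"sors"` (plan-driven order, priors seeded
#'   from the running reconstruction), `"quadrant"` (quadrant-center growth
#'   seeding) or `"independent"` (every location tested with the unshifted
#'   empirical prior).
#' @param stopAfter number of locations to test (<= grid size; e.g. 36, 46
#'   or 54).
#' @param batchSize locations per reconstruction update (default 4; the
#'   running estimate is refreshed after each completed batch).
#' @param thresholding `"zest"` or `"staircase"`.
#' @param substitute keep measured values at tested locations in estimates.
#' @return an object of class `vfStrategy`.
#' @export
strategyConfig <- function(meta = c("sors", "quadrant", "independent"),
                           stopAfter = 54L, batchSize = 4L,
                           thresholding = c("zest", "staircase"),
                           substitute = TRUE) {
  meta <- match.arg(meta)
  thresholding <- match.arg(thresholding)
  stopifnot(batchSize >= 1L, stopAfter >= 1L)
  structure(list(meta = meta, stopAfter = as.integer(stopAfter),
                 batchSize = as.integer(batchSize),
                 thresholding = thresholding, substitute = substitute),
            class = "vfStrategy")
}

# current full-field estimate given the measured values so far
.currentEstimate <- function(strategy, plan, measured, substitute = TRUE) {
  k <- length(measured)
  if (k == 0L) {
    return(plan@hill)
  }
  if (strategy$meta == "independent") {
    est <- plan@hill
    idx <- as.integer(names(measured))
    if (substitute) est[idx] <- measured
    return(est)
  }
  if (plan@kind == "quadrant") {
    # the growth estimate substitutes measured values by construction
    return(.growthEstimate(plan@grid, measured, plan@hill))
  }
  planEstimate(plan, measured, k, substitute = substitute)
}

#' Simulate a full visual field test
#'
#' Opens locations in plan order in batches of `batchSize`. Each opened
#' location runs its thresholding procedure with a prior seeded from the
#' current whole-field reconstruction (`meta = "sors"`), from the quadrant
#' growth rule (`meta = "quadrant"`; the four centers use the unshifted
#' prior), or from the unshifted empirical prior (`meta =
#' "independent"`). After each completed batch the running estimate is
#' refreshed; testing stops after `stopAfter` locations, and untested
#' locations keep the final reconstruction value. Locations within a batch
#' are tested sequentially to completion.
#'
#' @param strategy a [strategyConfig()].
#' @param plan a [SORSPlan-class] consistent with the strategy (any kind
#'   for sors; a [quadrantPlan()] for quadrant; any plan supplies the order
#'   and hill for independent).
#' @param truth numeric true threshold vector (the simulated patient's
#'   field).
#' @param zcfg a [zestConfig()] holding the empirical prior and estimator
#'   settings (also used for staircase start values via the prior mean).
#' @param fp,fn,rampHalfwidth responder reliability parameters.
#' @param seed integer seed; per-location streams are derived with
#'   [childSeed()].
#' @return list of class `vfTestResult`: `finalEstimate`,
#'   `finalEstimateModelOnly` (no measured-value substitution), `measured`
#'   (named vector), `presentations` (per-location counts), `totalTrials`,
#'   `trajectory` (data.frame: locations tested, cumulative trials, RMSE
#'   with and without substitution) and the per-trial `log`.
#' @export
runFieldTest <- function(strategy, plan, truth, zcfg,
                         fp = 0.03, fn = 0.03, rampHalfwidth = 2,
                         seed = 1) {
  d <- length(plan@order)
  .checkFieldVector(truth, d, "truth")
  ord <- plan@order[seq_len(strategy$stopAfter)]
  batches <- split(ord, ceiling(seq_along(ord) / strategy$batchSize))
  measured <- numeric(0)
  pres <- integer(d)
  co <- gridCoords(plan@grid)
  centers <- which(abs(co[, 1]) == 9 & abs(co[, 2]) == 9)
  traj <- data.frame(locations = integer(0), trials = integer(0),
                     rmse = numeric(0), rmse_model_only = numeric(0))
  log <- data.frame(location = integer(0), stimulus = numeric(0),
                    seen = logical(0))
  for (b in seq_along(batches)) {
    est <- .currentEstimate(strategy, plan, measured,
                            substitute = strategy$substitute)
    for (loc in batches[[b]]) {
      prior <- switch(strategy$meta,
        independent = zcfg$prior,
        sors = seedPrior(zcfg$prior, est[loc], zcfg$domain),
        quadrant = if (loc %in% centers) zcfg$prior else
          seedPrior(zcfg$prior,
                    quadrantGrowthSeed(plan@grid, measured, plan@hill, loc),
                    zcfg$domain)
      )
      locCfg <- zestConfig(prior, domain = zcfg$domain,
                           terminateSd = zcfg$terminateSd,
                           fp = zcfg$fp, fn = zcfg$fn,
                           rampHalfwidth = zcfg$rampHalfwidth,
                           maxPresentations = zcfg$maxPresentations)
      model <- responder(truth[loc], fp = fp, fn = fn,
                         rampHalfwidth = rampHalfwidth)
      set.seed(childSeed(seed, 3L, loc))
      res <- if (strategy$thresholding == "zest") {
        runZEST(locCfg, model)
      } else {
        start <- sum(prior * zcfg$domain)
        runStaircase(start, model)
      }
      measured[as.character(loc)] <- res$estimate
      pres[loc] <- res$n
      if (res$n > 0) {
        log <- rbind(log, data.frame(location = loc,
                                     stimulus = res$history$stimulus,
                                     seen = res$history$seen))
      }
    }
    estSub <- .currentEstimate(strategy, plan, measured, substitute = TRUE)
    estRaw <- .currentEstimate(strategy, plan, measured, substitute = FALSE)
    traj <- rbind(traj, data.frame(
      locations = length(measured), trials = sum(pres),
      rmse = pointwiseRMSE(truth, estSub),
      rmse_model_only = pointwiseRMSE(truth, estRaw)))
  }
  structure(list(
    finalEstimate = .currentEstimate(strategy, plan, measured,
                                     substitute = TRUE),
    finalEstimateModelOnly = .currentEstimate(strategy, plan, measured,
                                              substitute = FALSE),
    measured = measured, presentations = pres,
    totalTrials = sum(pres), trajectory = traj, log = log
  ), class = "vfTestResult")
}

# partition eyes into fold groups, balanced sizes, deterministic under seed
.eyeFolds <- function(eyes, nFolds, seed) {
  u <- unique(eyes)
  set.seed(childSeed(seed, 4L))
  u <- sample(u)
  split(u, rep_len(seq_len(nFolds), length(u)))
}

#' Cross-validated Monte Carlo evaluation
#'
#' Eyes (not fields) are partitioned into folds. Under the `"small"` scheme
#' (5 folds), each fold trains on one group (20% of eyes) and tests on the
#' remaining 80%; under `"large"` (10 folds) each fold trains on nine
#' groups (90%) and tests on one. Per fold, plans, the empirical prior and
#' the normative hill are fitted on the training split only, every test
#' field is simulated with [runFieldTest()], and mean RMSE / trials are
#' aggregated at each batch checkpoint.
#'
#' @param dataset a [VFDataset-class] with at least 10 eyes.
#' @param strategies named list; each element is a list with elements
#'   `strategy` (a [strategyConfig()]) and `kind` (plan kind for sors:
#'   `"lr"`, `"ttpcr"`, `"pls"`, `"mean"`) and optional `n` (embedding
#'   dimension).
#' @param scheme `"small"` (5-fold, 20/80) or `"large"` (10-fold, 90/10).
#' @param seed master seed.
#' @param maxTestFieldsPerFold cap on simulated test fields per fold (keeps
#'   Monte Carlo cost controllable; `Inf` simulates all).
#' @param fp,fn responder reliability.
#' @return list of class `vfEvaluation`: `checkpoints` (data.frame of
#'   per-strategy, per-fold, per-checkpoint mean RMSE and trials), `fields`
#'   (per-field final RMSE, trials and MD) and `folds` (eye assignments).
#' @export
crossValidate <- function(dataset, strategies, scheme = c("small", "large"),
                          seed = 1, maxTestFieldsPerFold = Inf,
                          fp = 0.03, fn = 0.03) {
  scheme <- match.arg(scheme)
  if (!methods::is(dataset, "VFDataset")) {
    stop("dataset must be a VFDataset (eye identifiers are required ",
         "for group-wise splitting)")
  }
  eyes <- eyeIds(dataset)
  if (length(unique(eyes)) < 10L) stop("need at least 10 eyes")
  nFolds <- if (scheme == "small") 5L else 10L
  folds <- .eyeFolds(eyes, nFolds, seed)
  X <- dbValues(dataset)
  grid <- fieldGrid(dataset)
  cps <- NULL
  flds <- NULL
  for (f in seq_len(nFolds)) {
    trainEyes <- if (scheme == "small") folds[[f]] else
      unlist(folds[-f], use.names = FALSE)
    testEyes <- setdiff(unique(eyes), trainEyes)
    trainX <- X[, eyes %in% trainEyes, drop = FALSE]
    testIdx <- which(eyes %in% testEyes)
    if (is.finite(maxTestFieldsPerFold) &&
        length(testIdx) > maxTestFieldsPerFold) {
      set.seed(childSeed(seed, 5L, f))
      testIdx <- sort(sample(testIdx, maxTestFieldsPerFold))
    }
    prior <- buildPrior(trainX)
    zcfg <- zestConfig(prior)
    normative <- normativeHill(trainX)
    for (sname in names(strategies)) {
      sp <- strategies[[sname]]
      strat <- sp$strategy
      plan <- if (strat$meta == "quadrant") {
        quadrantPlan(trainX, grid = grid)
      } else if (strat$meta == "independent" ||
                 identical(sp$kind, "mean")) {
        trainSORS(trainX, kind = "mean", grid = grid)
      } else {
        trainSORS(trainX, kind = sp$kind,
                  n = if (is.null(sp$n)) 8 else sp$n, grid = grid)
      }
      for (j in testIdx) {
        truth <- X[, j]
        res <- runFieldTest(strat, plan, truth, zcfg, fp = fp, fn = fn,
                            seed = childSeed(seed, 6L, f, j))
        cps <- rbind(cps, cbind(
          data.frame(strategy = sname, fold = f, field = j),
          res$trajectory))
        flds <- rbind(flds, data.frame(
          strategy = sname, fold = f, field = j,
          eye_id = eyes[j],
          md = meanDeviation(truth, normative, grid),
          rmse = pointwiseRMSE(truth, res$finalEstimate),
          trials = res$totalTrials))
      }
    }
  }
  structure(list(checkpoints = cps, fields = flds, folds = folds,
                 scheme = scheme, seed = seed),
            class = "vfEvaluation")
}

#' Severity-stratified summary of an evaluation
#'
#' Splits the per-field results into mild (MD > -6 dB), moderate
#' (-12 < MD <= -6 dB) and severe (MD <= -12 dB) groups and summarizes
#' RMSE and trials per strategy and group.
#'
#' @param report a `vfEvaluation` from [crossValidate()], or any data.frame
#'   with columns `strategy`, `md`, `rmse`, `trials`.
#' @return data.frame with per-strategy, per-severity mean/median RMSE and
#'   trials and group sizes.
#' @export
severityStratify <- function(report) {
  df <- if (inherits(report, "vfEvaluation")) report$fields else report
  df$severity <- severityClass(df$md)
  out <- do.call(rbind, lapply(split(df, list(df$strategy, df$severity),
                                     drop = TRUE), function(g) {
    data.frame(strategy = g$strategy[1],
               severity = as.character(g$severity[1]),
               n = nrow(g),
               mean_rmse = mean(g$rmse), median_rmse = stats::median(g$rmse),
               mean_trials = mean(g$trials))
  }))
  rownames(out) <- NULL
  out
}

#' Embedding-dimension sweep
#'
#' For each embedding dimension `n`, trains a SORS plan with the requested
#' reconstructor on the training fields and reports whole-field
#' reconstruction RMSE on the training and held-out fields after
#' `checkpoint` tested locations. By default the tested locations take
#' their true values (isolating the reconstruction model from thresholding
#' noise); `measurement = "zest"` simulates the full ZEST procedure
#' instead.
#'
#' @param trainX,testX training and held-out [VFDataset-class] or matrices.
#' @param nValues embedding dimensions to sweep.
#' @param checkpoint number of tested locations (default 36).
#' @param kind `"ttpcr"` or `"pls"`.
#' @param measurement `"exact"` or `"zest"`.
#' @param substitute keep measured values at tested locations.
#' @param fp,fn,seed responder reliability and seed (zest measurement
#'   only).
#' @return data.frame with columns n, train_rmse, test_rmse.
#' @export
embeddingSweep <- function(trainX, testX, nValues = c(2, 4, 8, 12, 24, 54),
                           checkpoint = 36, kind = c("ttpcr", "pls"),
                           measurement = c("exact", "zest"),
                           substitute = TRUE, fp = 0.03, fn = 0.03,
                           seed = 1) {
  kind <- match.arg(kind)
  measurement <- match.arg(measurement)
  Xtr <- .asMatrixX(trainX)
  Xte <- .asMatrixX(testX)
  grid <- if (methods::is(trainX, "VFDataset")) fieldGrid(trainX) else
    vfGrid242()
  rmseAt <- function(plan, X, zcfg) {
    prefix <- plan@order[seq_len(checkpoint)]
    errs <- vapply(seq_len(ncol(X)), function(j) {
      truth <- X[, j]
      if (measurement == "exact") {
        measured <- stats::setNames(truth[prefix], prefix)
        est <- planEstimate(plan, measured, checkpoint,
                            substitute = substitute)
      } else {
        strat <- strategyConfig("sors", stopAfter = checkpoint)
        res <- runFieldTest(strat, plan, truth, zcfg, fp = fp, fn = fn,
                            seed = childSeed(seed, 7L, j))
        est <- res$finalEstimate
      }
      pointwiseRMSE(truth, est)
    }, numeric(1))
    mean(errs)
  }
  zcfg <- zestConfig(buildPrior(Xtr))
  out <- lapply(nValues, function(n) {
    plan <- trainSORS(Xtr, kind = kind, n = n, grid = grid)
    data.frame(n = n,
               train_rmse = rmseAt(plan, Xtr, zcfg),
               test_rmse = rmseAt(plan, Xte, zcfg))
  })
  do.call(rbind, out)
}
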