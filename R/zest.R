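#' Simulated responder (psychometric model)
#'
#' Piecewise-linear frequency-of-seeing curve. With true threshold `t`,
#' ramp half-width `w` and stimulus `s` (all dB), the base probability of
#' seeing is `clip(0.5 + (t - s) / (2 w), 0, 1)` — a symmetric linear ramp
#' from 1 at `s = t - w` to 0 at `s = t + w` — and the reported probability
#' is `fp + (1 - fp - fn) * base`, bounded in `\[fp, 1 - fn\]`. `w = 0` is
#' the deterministic limit: the stimulus is seen exactly when `s <= t`.
#'
#' @param threshold true threshold in dB.
#' @param fp false-positive rate (response "seen" to an unseeable
#'   stimulus).
#' @param fn false-negative rate.
#' @param rampHalfwidth ramp half-width `w` in dB (default 2, approximating
#'   a cumulative Gaussian of SD about 1.6 dB); 0 gives a step function.
#' @return an object of class `responder`.
#' @export
responder <- function(threshold, fp = 0.03, fn = 0.03, rampHalfwidth = 2) {
  stopifnot(fp >= 0, fn >= 0, fp + fn <= 1, rampHalfwidth >= 0)
  structure(list(threshold = threshold, fp = fp, fn = fn,
                 rampHalfwidth = rampHalfwidth),
            class = "responder")
}

#' Probability of seeing a stimulus
#'
#' @param model a [responder()].
#' @param stimulus stimulus intensity in dB (vectorized).
#' @return probability in `\[fp, 1 - fn\]`; monotonically non-increasing in
#'   the stimulus dB (dimmer stimuli are seen less often).
#' @examples
#' pSeen(responder(30, fp = 0, fn = 0), 29)  # 0.75
#' @export
pSeen <- function(model, stimulus) {
  w <- model$rampHalfwidth
  base <- if (w == 0) {
    as.numeric(stimulus <= model$threshold)
  } else {
    pmin(pmax(0.5 + (model$threshold - stimulus) / (2 * w), 0), 1)
  }
  model$fp + (1 - model$fp - model$fn) * base
}

#' Draw a seen/not-seen response
#'
#' Bernoulli draw at [pSeen()]; uses the current RNG state, so set a seed
#' for reproducibility.
#'
#' @param model a [responder()].
#' @param stimulus stimulus in dB.
#' @return `TRUE` (seen) or `FALSE` (not seen).
#' @export
simulateResponse <- function(model, stimulus) {
  stats::runif(1) < pSeen(model, stimulus)
}

# ---------------------------------------------------------------------------
# ZEST

#' ZEST configuration
#'
#' @param prior probability mass function over `domain` (normalized
#'   internally).
#' @param domain threshold grid in dB (default 0..40 in 1-dB steps).
#' @param terminateSd terminate once the posterior SD falls below this
#'   (default 2.0 dB).
#' @param fp,fn false-positive / false-negative rates assumed by the
#'   estimator's likelihood (default 3% each, independent of the simulated
#'   responder's actual rates).
#' @param rampHalfwidth likelihood ramp half-width in dB.
#' @param maxPresentations safety cap on presentations per location.
#' @return an object of class `zestConfig`.
#' @export
zestConfig <- function(prior, domain = 0:40, terminateSd = 2.0,
                       fp = 0.03, fn = 0.03, rampHalfwidth = 2,
                       maxPresentations = 30L) {
  stopifnot(length(prior) == length(domain), all(prior >= 0),
            terminateSd > 0)
  s <- sum(prior)
  if (abs(s - 1) > 1e-12) prior <- prior / s
  structure(list(domain = domain, prior = prior,
                 terminateSd = terminateSd, fp = fp, fn = fn,
                 rampHalfwidth = rampHalfwidth,
                 maxPresentations = as.integer(maxPresentations)),
            class = "zestConfig")
}

#' Empirical threshold prior from training data
#'
#' Histogram of all training thresholds (pooled over locations and fields)
#' on the domain grid, additively smoothed and normalized.
#'
#' @param x a [VFDataset-class] or matrix of thresholds.
#' @param smoothing additive count per bin (default 1e-3).
#' @param domain threshold grid in dB.
#' @return normalized probability mass function over `domain`.
#' @export
buildPrior <- function(x, smoothing = 1e-3, domain = 0:40) {
  v <- as.vector(.asMatrixX(x))
  bins <- vapply(domain, function(t) sum(round(v) == t), numeric(1))
  p <- bins + smoothing
  if (sum(p) == 0) p <- rep(1, length(domain))
  p / sum(p)
}

#' Translate a prior to a target mean
#'
#' Shifts the PMF along the domain by the integer offset nearest to
#' `targetMean - mean(prior)`; mass shifted past a boundary accumulates in
#' the edge bin, and the result is renormalized. Used to seed a location's
#' ZEST procedure from a reconstruction estimate.
#'
#' @param prior PMF over `domain`.
#' @param targetMean desired prior mean in dB.
#' @param domain threshold grid.
#' @return shifted PMF.
#' @export
seedPrior <- function(prior, targetMean, domain = 0:40) {
  m <- sum(prior * domain) / sum(prior)
  shift <- round(targetMean - m)
  if (shift == 0) return(prior / sum(prior))
  n <- length(domain)
  idx <- seq_len(n) + shift
  out <- numeric(n)
  low <- idx < 1L
  high <- idx > n
  ok <- !low & !high
  out[idx[ok]] <- prior[ok]
  out[1] <- out[1] + sum(prior[low])
  out[n] <- out[n] + sum(prior[high])
  out / sum(out)
}

#' Initialize / update / query a ZEST state
#'
#' `zestInit` starts a state from the config's prior. `zestStep` applies a
#' Bayes update: the posterior is proportional to the current PMF times the
#' likelihood of the observed response, where the likelihood is the
#' config's assumed psychometric function evaluated at every candidate
#' threshold. `zestNextStimulus` is the posterior mean rounded to the 1-dB
#' grid, `zestSd` the posterior SD, `zestEstimate` the unrounded posterior
#' mean, and `zestDone` tests the stopping rule (posterior SD below
#' `terminateSd`, or the presentation cap reached).
#'
#' @param config a [zestConfig()].
#' @param state a ZEST state as returned by `zestInit`/`zestStep`.
#' @param stimulus presented stimulus in dB.
#' @param seen logical response.
#' @return `zestInit`/`zestStep` return a state (list with `pmf` and
#'   `history`); the query helpers return scalars.
#' @export
zestInit <- function(config) {
  list(pmf = config$prior,
       history = data.frame(stimulus = numeric(0), seen = logical(0)))
}

#' @rdname zestInit
#' @export
zestStep <- function(state, config, stimulus, seen) {
  # vectorized over candidate thresholds: same curve as pSeen()
  w <- config$rampHalfwidth
  base <- if (w == 0) {
    as.numeric(stimulus <= config$domain)
  } else {
    pmin(pmax(0.5 + (config$domain - stimulus) / (2 * w), 0), 1)
  }
  p <- config$fp + (1 - config$fp - config$fn) * base
  lik <- if (seen) p else 1 - p
  post <- state$pmf * lik
  z <- sum(post)
  if (z <= 0) stop("zero posterior mass; check likelihood fp/fn settings")
  list(pmf = post / z,
       history = rbind(state$history,
                       data.frame(stimulus = stimulus, seen = seen)))
}

#' @rdname zestInit
#' @export
zestEstimate <- function(state, config) {
  sum(state$pmf * config$domain)
}

#' @rdname zestInit
#' @export
zestSd <- function(state, config) {
  m <- zestEstimate(state, config)
  sqrt(sum(state$pmf * (config$domain - m)^2))
}

#' @rdname zestInit
#' @export
zestNextStimulus <- function(state, config) {
  s <- round(zestEstimate(state, config))
  min(max(s, min(config$domain)), max(config$domain))
}

#' @rdname zestInit
#' @export
zestDone <- function(state, config) {
  zestSd(state, config) < config$terminateSd ||
    nrow(state$history) >= config$maxPresentations
}

#' Run a full ZEST procedure at one location
#'
#' Loops next-stimulus, simulated response, Bayes update until the stopping
#' rule fires; the estimate is the posterior mean. If the prior already
#' satisfies the stopping rule no stimulus is presented.
#'
#' @param config a [zestConfig()].
#' @param model a [responder()] simulating the patient at this location.
#' @return list with `estimate` (dB), `n` (presentations) and the per-trial
#'   `history` data.frame.
#' @export
runZEST <- function(config, model) {
  state <- zestInit(config)
  while (!zestDone(state, config)) {
    s <- zestNextStimulus(state, config)
    seen <- simulateResponse(model, s)
    state <- zestStep(state, config, s, seen)
  }
  list(estimate = zestEstimate(state, config),
       n = nrow(state$history),
       history = state$history)
}

# ---------------------------------------------------------------------------
# 4-2 staircase

#' Run a 4-2 staircase procedure at one location
#'
#' Classic full-threshold convention: the stimulus steps by 4 dB (dimmer
#' after "seen", brighter after "not seen") until the first response
#' reversal, then by 2 dB until the second reversal. The estimate is the
#' level of the last seen stimulus (the range floor if nothing was seen).
#' Levels are clamped to \[0, 40\] dB; two consecutive identical responses at
#' a range extreme count as a reversal.
#'
#' @param start starting level in dB.
#' @param model a [responder()].
#' @param steps coarse and fine step sizes in dB (default `c(4, 2)`).
#' @param maxPresentations safety cap.
#' @return list with `estimate`, `n` and `history`.
#' @export
runStaircase <- function(start, model, steps = c(4, 2),
                         maxPresentations = 30L) {
  level <- min(max(round(start), .DB_MIN), .DB_MAX)
  reversals <- 0L
  lastSeen <- NA_real_
  prevResp <- NA
  atExtremeRun <- 0L
  hist <- data.frame(stimulus = numeric(0), seen = logical(0))
  while (reversals < 2L && nrow(hist) < maxPresentations) {
    seen <- simulateResponse(model, level)
    hist <- rbind(hist, data.frame(stimulus = level, seen = seen))
    if (seen) lastSeen <- level
    if (!is.na(prevResp) && seen != prevResp) {
      reversals <- reversals + 1L
      atExtremeRun <- 0L
    }
    atExtreme <- (level == .DB_MIN && !seen) || (level == .DB_MAX && seen)
    if (atExtreme) {
      atExtremeRun <- atExtremeRun + 1L
      if (atExtremeRun >= 2L) {
        reversals <- reversals + 1L
        atExtremeRun <- 0L
      }
    } else {
      atExtremeRun <- 0L
    }
    prevResp <- seen
    if (reversals >= 2L) break
    step <- if (reversals == 0L) steps[1] else steps[2]
    level <- level + if (seen) step else -step  # seen -> dimmer (higher dB)
    level <- min(max(level, .DB_MIN), .DB_MAX)
  }
  est <- if (is.na(lastSeen)) .DB_MIN else lastSeen
  list(estimate = est, n = nrow(hist), history = hist)
}
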