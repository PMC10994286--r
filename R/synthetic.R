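#' Normal hill of vision
#'
#' Smooth eccentricity-dependent sensitivity surface,
#' `peak - slope * (x^2 + y^2)^power` dB (defaults 33 - 0.07 r^1.6, about
#' 32 dB paracentrally declining to about 26 dB at the field edge), with
#' blind-spot locations forced to a low floor.
#'
#' @param grid a [VFGrid-class].
#' @param peak foveal peak sensitivity (dB).
#' @param slope,power radial decline parameters.
#' @param superiorDrop fixed offset subtracted in the superior hemifield
#'   (dB; the superior field is slightly less sensitive than the
#'   inferior).
#' @param blindSpotDb value at blind-spot locations (dB).
#' @return numeric per-location sensitivity (dB).
#' @export
hillOfVision <- function(grid, peak = 33, slope = 0.07, power = 0.8,
                         superiorDrop = 1, blindSpotDb = 3) {
  co <- gridCoords(grid)
  h <- peak - slope * (co[, 1]^2 + co[, 2]^2)^power -
    superiorDrop * (co[, 2] > 0)
  h[blindSpot(grid)] <- blindSpotDb
  h
}

#' Archetypical glaucomatous loss patterns
#'
#' Non-negative unit-maximum patterns with spatially contiguous support,
#' used as the latent factors of the synthetic generator: a global
#' depression, superior and inferior arcuate defects (mid-peripheral bands
#' confined to one hemifield), superior and inferior nasal steps, and a
#' temporal wedge. Hemifield confinement mirrors the horizontal-midline
#' asymmetry of glaucomatous loss.
#'
#' @param grid a [VFGrid-class].
#' @return named list of per-location numeric patterns.
#' @export
makeArchetypes <- function(grid) {
  co <- gridCoords(grid)
  x <- co[, 1]
  y <- co[, 2]
  r <- sqrt(x^2 + y^2)
  sup <- y > 0
  inf <- y < 0
  pat <- list(
    global = rep(1, nrow(co)),
    sup_arcuate = as.numeric(sup & r >= 10 & r <= 24),
    inf_arcuate = as.numeric(inf & r >= 10 & r <= 24),
    sup_nasal_step = as.numeric(sup & x <= -9 & y <= 9),
    inf_nasal_step = as.numeric(inf & x <= -9 & y >= -9),
    temporal_wedge = as.numeric(x >= 9 & abs(y) <= 9)
  )
  lapply(pat, function(p) if (max(p) > 0) p / max(p) else p)
}

#' Synthetic generator configuration
#'
#' Defaults describe a mixed glaucomatous population: severity mixture
#' 0.35 normal / 0.30 mild / 0.20 moderate / 0.15 severe, focal archetype
#' amplitudes scaled per severity so that the induced mean deviation spans
#' the mild (> -6 dB), moderate and severe (<= -12 dB) staging bands, a
#' N(0, 1.5) dB eye-level hill offset, 1 dB visit-level residual noise, and
#' five visits per eye (repeated measurements of one eye share its
#' eye-level parameters).
#'
#' @param nEyes number of eyes.
#' @param visitsPerEye repeated visits per eye (default 5).
#' @param severityMix named probabilities over normal/mild/moderate/severe.
#' @param amplitude named list of `c(lo, hi)` uniform ranges (dB) for the
#'   focal-archetype amplitude per severity class.
#' @param offsetSd SD of the eye-level hill-height offset (dB).
#' @param noiseSd SD of the visit-level residual noise (dB).
#' @param archetypes optional character vector restricting the focal
#'   archetype set (names from [makeArchetypes()], `"global"` excluded);
#'   `NULL` uses all focal patterns.
#' @param globalFrac upper bound on the diffuse (global depression)
#'   amplitude, as a fraction of the severity class's focal amplitude cap.
#' @return an object of class `vfGeneratorConfig`.
#' @export
generatorConfig <- function(nEyes = 278, visitsPerEye = 5,
                            severityMix = c(normal = 0.35, mild = 0.30,
                                            moderate = 0.20, severe = 0.15),
                            amplitude = list(normal = c(0, 1),
                                             mild = c(2, 8),
                                             moderate = c(8, 16),
                                             severe = c(16, 30)),
                            offsetSd = 1.5, noiseSd = 1.0,
                            archetypes = NULL, globalFrac = 0.3) {
  stopifnot(abs(sum(severityMix) - 1) < 1e-9, noiseSd >= 0, nEyes >= 1)
  structure(list(nEyes = as.integer(nEyes),
                 visitsPerEye = as.integer(visitsPerEye),
                 severityMix = severityMix, amplitude = amplitude,
                 offsetSd = offsetSd, noiseSd = noiseSd,
                 archetypes = archetypes, globalFrac = globalFrac),
            class = "vfGeneratorConfig")
}

#' Generate a synthetic visual field dataset
#'
#' Each eye draws a severity class, an eye-level hill offset, one to three
#' focal archetypes with severity-scaled amplitudes (plus a severity-scaled
#' global depression), and each visit adds independent Gaussian residual
#' noise before clipping to \[0, 40\] dB. Fields of one eye share the
#' eye-level parameters, so group-wise (per-eye) cross-validation splits
#' are meaningful. Deterministic given `seed`; eye-level and visit-level
#' draws use disjoint seed streams derived with [childSeed()].
#'
#' @param config a [generatorConfig()].
#' @param grid a [VFGrid-class].
#' @param seed integer master seed.
#' @return a [VFDataset-class] with `nEyes * visitsPerEye` fields.
#' @examples
#' d <- generateFields(generatorConfig(nEyes = 20, visitsPerEye = 1), seed = 1)
#' range(dbValues(d))
#' @export
generateFields <- function(config = generatorConfig(), grid = vfGrid242(),
                           seed = 1) {
  arch <- makeArchetypes(grid)
  focal <- arch[setdiff(names(arch), "global")]
  if (!is.null(config$archetypes)) {
    focal <- focal[intersect(names(focal), config$archetypes)]
    if (!length(focal)) stop("no valid archetype names in config")
  }
  hill <- hillOfVision(grid)
  d <- nLocations(grid)
  n <- config$nEyes * config$visitsPerEye
  vals <- matrix(NA_real_, d, n)
  eye <- character(n)
  visit <- integer(n)
  col <- 0L
  classes <- names(config$severityMix)
  for (e in seq_len(config$nEyes)) {
    set.seed(childSeed(seed, 1L, e))
    sev <- sample(classes, 1, prob = config$severityMix)
    offset <- stats::rnorm(1, 0, config$offsetSd)
    amp_rng <- config$amplitude[[sev]]
    nFocal <- sample(seq_len(min(3L, length(focal))), 1)
    which_focal <- sample(names(focal), nFocal)
    amps <- stats::runif(nFocal, amp_rng[1], amp_rng[2])
    # diffuse loss accompanies focal loss in the damaged classes
    global_amp <- if (sev == "normal") 0 else
      stats::runif(1, 0, config$globalFrac * amp_rng[2])
    deficit <- global_amp * arch$global
    for (i in seq_len(nFocal)) {
      deficit <- deficit + amps[i] * focal[[which_focal[i]]]
    }
    base <- hill + offset - deficit
    for (v in seq_len(config$visitsPerEye)) {
      set.seed(childSeed(seed, 2L, e, v))
      col <- col + 1L
      vals[, col] <- .clipDb(base + stats::rnorm(d, 0, config$noiseSd))
      eye[col] <- sprintf("eye%04d", e)
      visit[col] <- v
    }
  }
  VFDataset(vals, eyeId = eye, visit = visit, grid = grid)
}
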