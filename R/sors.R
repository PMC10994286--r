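#' A sequentially optimized testing plan
#'
#' `SORSPlan` pairs an ordered test sequence with one fitted reconstructor
#' per prefix length: model `k` reconstructs the whole field from the first
#' `k` locations of the order. Plans are produced by greedy training
#' ([trainSORS()]) for the lr/ttpcr/pls kinds, by descending training
#' variance for the mean baseline, and by quadrant-center growth ordering
#' for the quadrant baseline ([quadrantPlan()], which carries no regression
#' models — its reconstruction propagates measured deviations to
#' neighbors).
#'
#' @slot order integer permutation of the location indices (test sequence).
#' @slot models list of [VFReconstructor-class], one per prefix length
#'   (empty for the quadrant baseline).
#' @slot kind one of `"lr"`, `"ttpcr"`, `"pls"`, `"mean"`, `"quadrant"`.
#' @slot hyper list of hyperparameters (e.g. embedding dimension `n`).
#' @slot trainingCurve per-prefix-length training MSE (dB^2).
#' @slot hill the training hill of vision (per-location mean, dB).
#' @slot grid the [VFGrid-class] the plan was trained for.
#' @export
setClass("SORSPlan",
  slots = c(
    order = "integer",
    models = "list",
    kind = "character",
    hyper = "list",
    trainingCurve = "numeric",
    hill = "numeric",
    grid = "VFGrid"
  )
)

setValidity("SORSPlan", function(object) {
  d <- nLocations(object@grid)
  msg <- character(0)
  if (!setequal(object@order, seq_len(d)) || length(object@order) != d) {
    msg <- c(msg, "order must be a permutation of the location indices")
  }
  if (!object@kind %in% c("lr", "ttpcr", "pls", "mean", "quadrant")) {
    msg <- c(msg, "unknown plan kind")
  }
  if (object@kind != "quadrant") {
    if (length(object@models) != d) {
      msg <- c(msg, "need one model per prefix length")
    } else {
      for (k in seq_len(d)) {
        if (!identical(measuredSubset(object@models[[k]]),
                       object@order[seq_len(k)]) &&
            object@kind != "mean") {
          msg <- c(msg, sprintf("model %d subset must equal order[1..%d]",
                                k, k))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SORSPlan-class the test-location order
#' @param x,object a `SORSPlan`.
#' @export
setGeneric("planOrder", function(x) standardGeneric("planOrder"))
setMethod("planOrder", "SORSPlan", function(x) x@order)

#' @describeIn SORSPlan-class per-prefix training MSE (dB^2)
#' @export
setGeneric("trainingCurve", function(x) standardGeneric("trainingCurve"))
setMethod("trainingCurve", "SORSPlan", function(x) x@trainingCurve)

#' @describeIn SORSPlan-class plan kind
#' @export
setGeneric("planKind", function(x) standardGeneric("planKind"))
setMethod("planKind", "SORSPlan", function(x) x@kind)

setMethod("show", "SORSPlan", function(object) {
  cat(sprintf("SORSPlan (%s) over %d locations; first four: %s\n",
              object@kind, length(object@order),
              paste(object@order[1:4], collapse = ", ")))
})

.fitKind <- function(X, subset, kind, n = NULL, basis = NULL) {
  switch(kind,
    lr = fitLR(X, subset),
    ttpcr = fitTTPCR(X, subset, basis),
    pls = fitPLS(X, subset, min(n, length(subset), ncol(X) - 1L)),
    stop("unknown reconstructor kind: ", kind)
  )
}

#' Train a sequentially optimized testing plan
#'
#' Greedy forward selection: at each step, every remaining candidate
#' location is added to the measured subset, a reconstructor is fitted, and
#' the candidate whose model attains the lowest whole-field training MSE is
#' appended (ties broken by lowest location index). For `kind = "ttpcr"`
#' the PCA basis is fitted once on the training fields before the loop and
#' frozen for every subset. `kind = "mean"` skips the greedy search and
#' orders locations by descending training variance (its reconstruction
#' ignores measurements).
#'
#' The greedy search does not guarantee a globally optimal sequence; an
#' exhaustive search over permutations is infeasible.
#'
#' @param x training [VFDataset-class] or locations x fields matrix
#'   (>= 2 fields).
#' @param kind reconstructor kind: `"lr"`, `"ttpcr"`, `"pls"` or `"mean"`.
#' @param n embedding dimension for ttpcr/pls (default 8).
#' @param grid the [VFGrid-class] (default 24-2; must match `nrow(x)`).
#' @param verbose print progress.
#' @return a [SORSPlan-class].
#' @export
trainSORS <- function(x, kind = c("ttpcr", "lr", "pls", "mean"), n = 8,
                      grid = NULL, verbose = FALSE) {
  kind <- match.arg(kind)
  X <- .asMatrixX(x)
  if (is.null(grid)) {
    grid <- if (methods::is(x, "VFDataset")) fieldGrid(x) else vfGrid242()
  }
  d <- nrow(X)
  if (nLocations(grid) != d) stop("grid size must match the field dimension")
  if (ncol(X) < 2L) stop("need at least two training fields")
  if (all(apply(X, 1, stats::var) < 1e-12)) {
    warning("degenerate training set: all fields are identical")
  }
  hill <- rowMeans(X)
  if (kind == "mean") {
    ord <- order(-apply(X, 1, stats::var), seq_len(d))
    mdl <- fitMean(X)
    return(methods::new("SORSPlan", order = as.integer(ord),
                        models = rep(list(mdl), d), kind = "mean",
                        hyper = list(), trainingCurve = rep(mdl@trainMSE, d),
                        hill = hill, grid = grid))
  }
  basis <- if (kind == "ttpcr") fitPCA(X, n) else NULL
  chosen <- integer(0)
  models <- vector("list", d)
  curve <- numeric(d)
  for (k in seq_len(d)) {
    cand <- setdiff(seq_len(d), chosen)
    best <- NULL
    bestMSE <- Inf
    for (j in cand) {
      m <- .fitKind(X, c(chosen, j), kind, n = n, basis = basis)
      if (trainingMSE(m) < bestMSE) {
        bestMSE <- trainingMSE(m)
        best <- m
      }
    }
    chosen <- measuredSubset(best)
    models[[k]] <- best
    curve[k] <- bestMSE
    if (verbose) {
      message(sprintf("step %2d: location %2d, training MSE %.4f",
                      k, chosen[k], bestMSE))
    }
  }
  methods::new("SORSPlan", order = chosen, models = models, kind = kind,
               hyper = list(n = as.integer(n)), trainingCurve = curve,
               hill = hill, grid = grid)
}

#' Quadrant growth testing plan
#'
#' Orders the four quadrant centers at (+/-9, +/-9) degrees first, then
#' grows outward breadth-first by grid adjacency within each quadrant (ties
#' by location index). Its reconstruction carries the measured deviation
#' from the normative hill to neighboring locations (see
#' [quadrantGrowthSeed()]).
#'
#' @param x training [VFDataset-class] or matrix (for the normative hill).
#' @param grid the [VFGrid-class].
#' @return a [SORSPlan-class] with `kind = "quadrant"`.
#' @export
quadrantPlan <- function(x, grid = NULL) {
  X <- .asMatrixX(x)
  if (is.null(grid)) {
    grid <- if (methods::is(x, "VFDataset")) fieldGrid(x) else vfGrid242()
  }
  d <- nLocations(grid)
  co <- gridCoords(grid)
  centers <- sort(which(abs(co[, 1]) == 9 & abs(co[, 2]) == 9))
  if (length(centers) != 4L) stop("grid lacks the four quadrant centers")
  ord <- centers
  # breadth-first within quadrants, layer by layer over all four at once
  frontier <- centers
  while (length(ord) < d) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- neighborsOf(grid, i)
      nb <- nb[quadrantOf(grid, nb) == quadrantOf(grid, i)]
      nxt <- c(nxt, setdiff(nb, c(ord, nxt)))
    }
    if (!length(nxt)) {
      nxt <- setdiff(seq_len(d), ord)  # disconnected leftovers, if any
    }
    nxt <- sort(nxt)
    ord <- c(ord, nxt)
    frontier <- nxt
  }
  methods::new("SORSPlan", order = as.integer(ord), models = list(),
               kind = "quadrant", hyper = list(),
               trainingCurve = numeric(0), hill = rowMeans(X), grid = grid)
}

#' Seeding value for a quadrant-growth neighbor
#'
#' The start value for a not-yet-tested location is its own normative value
#' plus the mean deviation (measured minus normative) of the already
#' determined locations among its within-quadrant neighbors.
#'
#' @param grid the [VFGrid-class].
#' @param determined named numeric vector of determined thresholds (names
#'   are location indices).
#' @param normative normative hill vector.
#' @param loc location index to seed.
#' @return start value in dB.
#' @export
quadrantGrowthSeed <- function(grid, determined, normative, loc) {
  co <- gridCoords(grid)
  if (abs(co[loc, 1]) == 9 && abs(co[loc, 2]) == 9) {
    stop("quadrant centers are tested with the unshifted prior, not seeded")
  }
  nb <- neighborsOf(grid, loc)
  nb <- nb[quadrantOf(grid, nb) == quadrantOf(grid, loc)]
  det_idx <- intersect(nb, as.integer(names(determined)))
  if (!length(det_idx)) {
    stop("no determined within-quadrant neighbor for location ", loc)
  }
  dev <- mean(determined[as.character(det_idx)] - normative[det_idx])
  normative[loc] + dev
}

# growth reconstruction for the quadrant baseline: propagate deviations
# outward from the measured set, BFS over within-quadrant adjacency
.growthEstimate <- function(grid, measured, normative) {
  d <- nLocations(grid)
  est <- normative
  det <- measured
  idx <- as.integer(names(measured))
  est[idx] <- measured
  todo <- setdiff(seq_len(d), idx)
  while (length(todo)) {
    progressed <- FALSE
    for (loc in todo) {
      nb <- neighborsOf(grid, loc)
      nb <- nb[quadrantOf(grid, nb) == quadrantOf(grid, loc)]
      src <- intersect(nb, as.integer(names(det)))
      if (length(src)) {
        val <- normative[loc] +
          mean(det[as.character(src)] - normative[src])
        est[loc] <- val
        det[as.character(loc)] <- val
        todo <- setdiff(todo, loc)
        progressed <- TRUE
      }
    }
    if (!progressed) break  # isolated locations keep the normative value
  }
  est
}

#' Whole-field estimate from a plan prefix
#'
#' Applies the plan's prefix-`k` reconstructor to the measured values. By
#' default the measured values themselves are substituted back at tested
#' locations (matching perimetric reporting practice; substitution can only
#' reduce error there); set `substitute = FALSE` for the pure model output
#' at every location.
#'
#' @param plan a [SORSPlan-class].
#' @param measured named numeric vector of measured thresholds; names must
#'   be exactly the location indices `planOrder(plan)[1:k]`.
#' @param k prefix length (>= 1).
#' @param substitute keep measured values at tested locations (default
#'   TRUE).
#' @param clip clip model output to \[0, 40\] dB.
#' @return numeric full-field estimate.
#' @export
planEstimate <- function(plan, measured, k, substitute = TRUE, clip = TRUE) {
  d <- length(plan@order)
  if (k < 1L || k > d) stop("k must be between 1 and ", d)
  prefix <- plan@order[seq_len(k)]
  idx <- as.integer(names(measured))
  if (length(measured) != k || !setequal(idx, prefix)) {
    stop("measured must cover exactly the first k locations of the plan")
  }
  s <- measured[as.character(prefix)]
  est <- switch(plan@kind,
    quadrant = .growthEstimate(plan@grid, measured, plan@hill),
    mean = reconstruct(plan@models[[k]], numeric(0), clip = clip),
    as.numeric(reconstruct(plan@models[[k]], s, clip = clip))
  )
  if (substitute) est[prefix] <- s
  est
}

#' Render the test order on the grid
#'
#' @param plan a [SORSPlan-class].
#' @param grid the [VFGrid-class] (defaults to the plan's grid).
#' @return data.frame with columns x, y, rank (1 = tested first) and band
#'   (`"1-4"`, `"5-20"`, `"21-36"`, `"37+"`).
#' @export
sequenceMap <- function(plan, grid = NULL) {
  if (is.null(grid)) grid <- plan@grid
  co <- gridCoords(grid)
  rank <- match(seq_len(nrow(co)), plan@order)  # position of i in the order
  band <- cut(rank, breaks = c(0, 4, 20, 36, Inf),
              labels = c("1-4", "5-20", "21-36", "37+"))
  data.frame(x = co[, 1], y = co[, 2], rank = rank, band = band)
}

#' Plot the test order map
#'
#' Fig-style ordering map: locations annotated with their test rank,
#' colored by band (first 4 red, 5-20 blue, 21-36 green, rest grey).
#'
#' @param plan a [SORSPlan-class].
#' @param file optional png path; when given the plot is written there.
#' @return the [sequenceMap()] data.frame, invisibly.
#' @export
plotSequenceMap <- function(plan, file = NULL) {
  sm <- sequenceMap(plan)
  cols <- c("1-4" = "red3", "5-20" = "blue3", "21-36" = "green4",
            "37+" = "grey50")
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(sm$x, sm$y, type = "n", asp = 1,
                 xlab = "x (deg, temporal +)", ylab = "y (deg, superior +)",
                 main = sprintf("Test order (%s)", plan@kind))
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::text(sm$x, sm$y, labels = sm$rank,
                 col = cols[as.character(sm$band)], font = 2)
  invisible(sm)
}
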