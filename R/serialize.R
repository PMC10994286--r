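# JSON serialization of fitted models and plans.

.modelToList <- function(m) {
  kind <- reconstructorKind(m)
  out <- list(kind = kind, subset = m@subset, d = m@d,
              train_mse = m@trainMSE)
  if (kind == "mean") {
    out$hill <- m@hill
  } else if (kind == "lr") {
    out$D <- m@D
    out$beta <- m@beta
  } else if (kind == "ttpcr") {
    out$D <- m@D
    out$beta <- m@beta
    out$mu <- m@basis@mu
    out$W <- m@basis@components
    out$eigenvalues <- m@basis@eigenvalues
    out$all_eigenvalues <- m@basis@allEigenvalues
  } else if (kind == "pls") {
    out$W <- m@W
    out$D <- m@D
    out$beta <- m@beta
    out$n <- m@n
    out$converged <- m@converged
  }
  out
}

.modelFromList <- function(l) {
  subset <- as.integer(l$subset)
  d <- as.integer(l$d)
  asmat <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
  switch(l$kind,
    mean = methods::new("MeanReconstructor", subset = subset, d = d,
                        hill = as.numeric(l$hill),
                        trainMSE = l$train_mse),
    lr = methods::new("LRReconstructor", subset = subset, d = d,
                      D = asmat(l$D), beta = as.numeric(l$beta),
                      trainMSE = l$train_mse),
    ttpcr = methods::new("TTPCRReconstructor", subset = subset, d = d,
                         D = asmat(l$D), beta = as.numeric(l$beta),
                         basis = methods::new("PCABasis",
                           mu = as.numeric(l$mu), components = asmat(l$W),
                           eigenvalues = as.numeric(l$eigenvalues),
                           allEigenvalues = as.numeric(l$all_eigenvalues)),
                         trainMSE = l$train_mse),
    pls = methods::new("PLSReconstructor", subset = subset, d = d,
                       W = asmat(l$W), D = asmat(l$D),
                       beta = as.numeric(l$beta), n = as.integer(l$n),
                       converged = as.logical(l$converged),
                       trainMSE = l$train_mse),
    stop("unknown model kind in archive: ", l$kind)
  )
}

#' Serialize a plan to a JSON archive
#'
#' Writes the order, kind, hyperparameters, training curve, hill, grid and
#' every prefix model to a single JSON file; [planFromJSON()] restores an
#' equivalent [SORSPlan-class] (predictions agree to numerical precision).
#'
#' @param plan a [SORSPlan-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
planToJSON <- function(plan, path) {
  obj <- list(
    order = plan@order, kind = plan@kind, hyper = plan@hyper,
    training_curve = plan@trainingCurve, hill = plan@hill,
    grid = jsonlite::fromJSON(gridToJSON(plan@grid)),
    models = lapply(plan@models, .modelToList)
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname planToJSON
#' @export
planFromJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  grid <- VFGrid(cbind(obj$grid$x, obj$grid$y),
                 blindSpot = as.integer(obj$grid$blind_spot))
  methods::new("SORSPlan",
               order = as.integer(obj$order),
               models = lapply(obj$models, .modelFromList),
               kind = obj$kind,
               hyper = if (length(obj$hyper)) obj$hyper else list(),
               trainingCurve = as.numeric(obj$training_curve),
               hill = as.numeric(obj$hill),
               grid = grid)
}
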