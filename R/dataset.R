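#' A dataset of visual fields
#'
#' `VFDataset` extends [SummarizedExperiment::SummarizedExperiment] with rows
#' as grid locations and columns as individual visual fields. The single
#' assay `"dB"` holds the threshold matrix (locations x fields, decibels of
#' stimulus attenuation, range 0-40). `rowData` carries the grid geometry
#' (x, y, quadrant, blind-spot flag); `colData` carries `eye_id`,
#' `laterality` and `visit`. The full [VFGrid-class] lives in
#' `metadata(x)$grid`. All fields are stored in right-eye (OD) convention.
#'
#' @export
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
setClass("VFDataset", contains = "SummarizedExperiment")

setValidity("VFDataset", function(object) {
  msg <- character(0)
  if (!"dB" %in% SummarizedExperiment::assayNames(object)) {
    return("VFDataset must carry an assay named 'dB'")
  }
  v <- SummarizedExperiment::assay(object, "dB")
  if (any(!is.finite(v))) msg <- c(msg, "thresholds must be finite")
  if (any(v < .DB_MIN - 1e-9) || any(v > .DB_MAX + 1e-9)) {
    msg <- c(msg, sprintf("thresholds must lie in [%d, %d] dB",
                          .DB_MIN, .DB_MAX))
  }
  if (!"eye_id" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain eye_id")
  }
  g <- S4Vectors::metadata(object)$grid
  if (is.null(g) || !methods::is(g, "VFGrid")) {
    msg <- c(msg, "metadata(x)$grid must be a VFGrid")
  } else if (nLocations(g) != nrow(object)) {
    msg <- c(msg, "assay row count must equal the grid's location count")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VFDataset
#'
#' @param values numeric matrix of thresholds, locations x fields (dB).
#' @param eyeId character/integer vector of eye identifiers, one per field
#'   (column); used for group-wise cross-validation splits.
#' @param laterality `"OD"` or `"OS"` per field (values must already be in
#'   OD convention; laterality is carried as metadata only).
#' @param visit optional visit index per field.
#' @param grid a [VFGrid-class]; defaults to the 24-2 pattern.
#' @return a [VFDataset-class].
#' @examples
#' g <- vfGrid242()
#' m <- matrix(30, nLocations(g), 3)
#' d <- VFDataset(m, eyeId = c("a", "a", "b"))
#' nFields(d)
#' @export
VFDataset <- function(values, eyeId, laterality = "OD", visit = NULL,
                      grid = vfGrid242()) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (length(eyeId) != n) stop("eyeId must have one entry per field")
  laterality <- rep_len(laterality, n)
  if (is.null(visit)) {
    visit <- stats::ave(seq_len(n), eyeId, FUN = seq_along)
  }
  co <- gridCoords(grid)
  rd <- S4Vectors::DataFrame(
    x = co[, "x"], y = co[, "y"],
    quadrant = quadrantOf(grid, seq_len(nLocations(grid))),
    blind_spot = seq_len(nLocations(grid)) %in% blindSpot(grid)
  )
  cd <- S4Vectors::DataFrame(eye_id = as.character(eyeId),
                             laterality = laterality,
                             visit = as.integer(visit))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dB = values), rowData = rd, colData = cd,
    metadata = list(grid = grid)
  )
  methods::new("VFDataset", se)
}

#' @describeIn VFDataset-class the locations x fields threshold matrix (dB)
#' @param x a `VFDataset`.
#' @export
setGeneric("dbValues", function(x) standardGeneric("dbValues"))

#' @rdname VFDataset-class
#' @export
setMethod("dbValues", "VFDataset", function(x) {
  unname(SummarizedExperiment::assay(x, "dB"))
})

#' @describeIn VFDataset-class eye identifiers, one per field
#' @export
setGeneric("eyeIds", function(x) standardGeneric("eyeIds"))

#' @rdname VFDataset-class
#' @export
setMethod("eyeIds", "VFDataset", function(x) {
  SummarizedExperiment::colData(x)$eye_id
})

#' @describeIn VFDataset-class the associated [VFGrid-class]
#' @export
setGeneric("fieldGrid", function(x) standardGeneric("fieldGrid"))

#' @rdname VFDataset-class
#' @export
setMethod("fieldGrid", "VFDataset", function(x) {
  S4Vectors::metadata(x)$grid
})

#' @describeIn VFDataset-class number of fields (columns)
#' @export
setGeneric("nFields", function(x) standardGeneric("nFields"))

#' @rdname VFDataset-class
#' @export
setMethod("nFields", "VFDataset", function(x) ncol(x))

# ---------------------------------------------------------------------------
# Metrics

#' Point-wise root-mean-square error between two fields
#'
#' `sqrt(mean((truth - estimate)^2))` over all grid locations (blind-spot
#' locations included).
#'
#' @param truth,estimate numeric threshold vectors of equal length (dB).
#' @return RMSE in dB.
#' @examples
#' pointwiseRMSE(rep(30, 54), rep(32, 54))  # 2
#' @export
pointwiseRMSE <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have the same length")
  }
  sqrt(mean((truth - estimate)^2))
}

#' Mean deviation of a field from normative values
#'
#' Unweighted mean of (value - normative) over the non-blind-spot locations.
#' Used for severity stratification; see [severityClass()].
#'
#' @param values numeric threshold vector (dB).
#' @param normative normative threshold vector of the same length (dB),
#'   typically [normativeHill()] of a training set.
#' @param grid the [VFGrid-class]; its blind-spot locations are excluded.
#' @return mean deviation (MD) in dB.
#' @export
meanDeviation <- function(values, normative, grid = vfGrid242()) {
  n <- nLocations(grid)
  .checkFieldVector(values, n, "values")
  .checkFieldVector(normative, n, "normative")
  keep <- setdiff(seq_len(n), blindSpot(grid))
  mean(values[keep] - normative[keep])
}

#' Severity class from mean deviation
#'
#' Standard glaucoma staging cutoffs: mild `MD > -6` dB, moderate
#' `-12 < MD <= -6` dB, severe `MD <= -12` dB.
#'
#' @param md numeric vector of mean deviations (dB).
#' @return factor with levels mild, moderate, severe.
#' @export
severityClass <- function(md) {
  cut(md, breaks = c(-Inf, -12, -6, Inf),
      labels = c("severe", "moderate", "mild"),
      right = TRUE)
}

#' Normative hill of vision from a training set
#'
#' Per-location arithmetic mean of the training thresholds; the "mean"
#' baseline reconstructor returns exactly this surface.
#'
#' @param x a [VFDataset-class] or a locations x fields matrix.
#' @return numeric vector of per-location mean thresholds (dB).
#' @export
normativeHill <- function(x) {
  m <- if (methods::is(x, "VFDataset")) dbValues(x) else as.matrix(x)
  if (ncol(m) < 1L) stop("need at least one training field")
  rowMeans(m)
}

# ---------------------------------------------------------------------------
# I/O

.wideCols <- function(n) sprintf("loc_%02d", seq_len(n))

#' Read a visual field dataset from CSV
#'
#' Two dialects are supported. `"wide"`: one row per field with columns
#' `eye_id`, optional `laterality` and `visit`, and `loc_01 .. loc_NN`
#' threshold columns in canonical grid order (anatomical order, so OS rows
#' need no mirroring). `"long"`: one row per location with columns `eye_id`,
#' `x`, `y`, `db` and optional `laterality`, `visit`; coordinates are in the
#' eye's own convention and OS records are mirrored into OD convention on
#' load (logged via `message`). Out-of-range thresholds are clipped to
#' \[0, 40\] and the number of clipped cells reported.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @param grid target [VFGrid-class] (default 24-2).
#' @return a [VFDataset-class].
#' @export
readFields <- function(path, dialect = c("wide", "long"),
                       grid = vfGrid242()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  n <- nLocations(grid)
  if (dialect == "wide") {
    need <- c("eye_id", .wideCols(n))
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("wide CSV is missing required columns: ",
           paste(miss, collapse = ", "))
    }
    vals <- t(as.matrix(df[, .wideCols(n)]))
    lat <- if ("laterality" %in% names(df)) df$laterality else "OD"
    vis <- if ("visit" %in% names(df)) df$visit else NULL
    eye <- df$eye_id
  } else {
    need <- c("eye_id", "x", "y", "db")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("long CSV is missing required columns: ",
           paste(miss, collapse = ", "))
    }
    if (!"visit" %in% names(df)) df$visit <- 1L
    if (!"laterality" %in% names(df)) df$laterality <- "OD"
    os <- df$laterality == "OS"
    if (any(os)) {
      df$x[os] <- -df$x[os]
      message(sum(os), " OS rows mirrored into OD convention")
    }
    recs <- split(df, list(df$eye_id, df$visit), drop = TRUE)
    vals <- matrix(NA_real_, n, length(recs))
    eye <- lat <- character(length(recs))
    vis <- integer(length(recs))
    co <- gridCoords(grid)
    for (r in seq_along(recs)) {
      rec <- recs[[r]]
      idx <- locationIndex(grid, rec$x, rec$y)
      if (anyNA(idx) || length(idx) != n || anyDuplicated(idx)) {
        missing_co <- co[setdiff(seq_len(n), idx[!is.na(idx)]), ,
                         drop = FALSE]
        stop(sprintf(
          "record eye_id=%s visit=%s does not cover the grid (missing: %s)",
          rec$eye_id[1], rec$visit[1],
          paste(sprintf("(%g,%g)", missing_co[, 1], missing_co[, 2]),
                collapse = " ")))
      }
      vals[idx, r] <- rec$db
      eye[r] <- as.character(rec$eye_id[1])
      lat[r] <- rec$laterality[1]
      vis[r] <- as.integer(rec$visit[1])
    }
  }
  out <- vals
  nclip <- sum(out < .DB_MIN | out > .DB_MAX)
  if (nclip > 0) {
    message(nclip, " threshold cells clipped to [0, 40] dB")
    out <- .clipDb(out)
  }
  VFDataset(out, eyeId = eye, laterality = lat, visit = vis, grid = grid)
}

#' Write a visual field dataset to CSV
#'
#' Inverse of [readFields()]; round-trips in-range data exactly (values are
#' written with full precision).
#'
#' @param x a [VFDataset-class].
#' @param path output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
writeFields <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  vals <- dbValues(x)
  cd <- SummarizedExperiment::colData(x)
  n <- nrow(vals)
  if (dialect == "wide") {
    wide <- as.data.frame(t(vals))
    names(wide) <- .wideCols(n)
    df <- cbind(data.frame(eye_id = cd$eye_id,
                           laterality = cd$laterality,
                           visit = cd$visit), wide)
  } else {
    co <- gridCoords(fieldGrid(x))
    df <- do.call(rbind, lapply(seq_len(ncol(vals)), function(j) {
      # stored values are OD-convention; write OS records back in their
      # native convention so that readFields' mirroring round-trips
      xx <- if (identical(cd$laterality[j], "OS")) -co[, 1] else co[, 1]
      data.frame(eye_id = cd$eye_id[j], laterality = cd$laterality[j],
                 visit = cd$visit[j], x = xx, y = co[, 2],
                 db = vals[, j])
    }))
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
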