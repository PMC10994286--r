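#' Test-location grid for perimetry
#'
#' `VFGrid` holds the geometry of a perimetric test pattern: location
#' coordinates in degrees of visual angle (right-eye convention, temporal
#' positive x, superior positive y), the quadrant of each location, the
#' axis-aligned neighbor relation, and which locations sit on the
#' physiological blind spot.
#'
#' @slot coords numeric matrix, one row per location, columns `x` and `y`
#'   (degrees of visual angle).
#' @slot quadrant character vector, one of `"superotemporal"`,
#'   `"superonasal"`, `"inferotemporal"`, `"inferonasal"` per location.
#' @slot neighbors list of integer vectors; `neighbors[[i]]` are the
#'   locations one grid step (axis-aligned) away from location `i`.
#' @slot blindSpot integer indices of blind-spot locations.
#'
#' @seealso [vfGrid242()] for the standard 24-2 pattern.
#' @export
setClass("VFGrid",
  slots = c(
    coords = "matrix",
    quadrant = "character",
    neighbors = "list",
    blindSpot = "integer"
  )
)

setValidity("VFGrid", function(object) {
  co <- object@coords
  msg <- character(0)
  if (!is.numeric(co) || ncol(co) != 2L) {
    return("coords must be a numeric matrix with columns x, y")
  }
  n <- nrow(co)
  if (anyDuplicated(paste(co[, 1], co[, 2]))) {
    msg <- c(msg, "coordinates must be unique")
  }
  if (any(co == 0)) {
    msg <- c(msg, "no location may lie on an axis (x or y equal to 0)")
  }
  if (length(object@quadrant) != n ||
      !all(object@quadrant %in% c("superotemporal", "superonasal",
                                  "inferotemporal", "inferonasal"))) {
    msg <- c(msg, "quadrant labels invalid")
  }
  if (length(object@neighbors) != n) {
    msg <- c(msg, "neighbors must have one entry per location")
  } else {
    for (i in seq_len(n)) {
      for (j in object@neighbors[[i]]) {
        if (!(i %in% object@neighbors[[j]])) {
          msg <- c(msg, "neighbor relation must be symmetric")
          break
        }
      }
    }
  }
  if (length(object@blindSpot) &&
      (any(object@blindSpot < 1L) || any(object@blindSpot > n))) {
    msg <- c(msg, "blindSpot indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a test grid from coordinates
#'
#' Quadrants are derived from coordinate signs and neighbors from
#' axis-aligned offsets of `spacing` degrees. Intended for custom or toy
#' grids; the shipped clinical pattern is [vfGrid242()].
#'
#' @param coords numeric matrix (or 2-column data.frame) of x, y coordinates
#'   in degrees, right-eye convention.
#' @param blindSpot integer indices of blind-spot locations (may be empty).
#' @param spacing grid step in degrees used to define adjacency (default 6).
#' @return a [VFGrid-class] object.
#' @export
VFGrid <- function(coords, blindSpot = integer(0), spacing = 6) {
  co <- as.matrix(coords)
  dimnames(co) <- list(NULL, c("x", "y"))
  storage.mode(co) <- "double"
  n <- nrow(co)
  quad <- ifelse(co[, "y"] > 0,
                 ifelse(co[, "x"] > 0, "superotemporal", "superonasal"),
                 ifelse(co[, "x"] > 0, "inferotemporal", "inferonasal"))
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    dx <- abs(co[, "x"] - co[i, "x"])
    dy <- abs(co[, "y"] - co[i, "y"])
    nb[[i]] <- which((dx == spacing & dy == 0) | (dx == 0 & dy == spacing))
  }
  methods::new("VFGrid", coords = co, quadrant = quad,
               neighbors = nb, blindSpot = as.integer(blindSpot))
}

#' The standard 24-2 test grid
#'
#' Builds the canonical 54-location 24-2 pattern in right-eye (OD) field
#' convention: all points with `|x|, |y| in {3, 9, 15, 21}` and
#' `|x| + |y| <= 30` (52 points) plus the two nasal extension points at
#' `(-27, +/-3)`. Temporal is positive x, superior positive y. Locations are
#' ordered row-major from superior to inferior, nasal to temporal within a
#' row (sorted by decreasing y then increasing x), and the two locations
#' covering the physiological blind spot at `(+15, +/-3)` are flagged.
#'
#' @return a [VFGrid-class] with 54 locations.
#' @examples
#' g <- vfGrid242()
#' nLocations(g)
#' gridCoords(g)[blindSpot(g), ]
#' @export
vfGrid242 <- function() {
  v <- c(-21, -15, -9, -3, 3, 9, 15, 21)
  co <- expand.grid(x = v, y = v)
  co <- co[abs(co$x) + abs(co$y) <= 30, ]
  co <- rbind(co, data.frame(x = c(-27, -27), y = c(3, -3)))
  co <- co[order(-co$y, co$x), ]
  bs <- which(co$x == 15 & abs(co$y) == 3)
  VFGrid(co, blindSpot = bs, spacing = 6)
}

#' @describeIn VFGrid-class number of test locations
#' @param x,object a `VFGrid`.
#' @export
setGeneric("nLocations", function(x) standardGeneric("nLocations"))

#' @rdname VFGrid-class
#' @export
setMethod("nLocations", "VFGrid", function(x) nrow(x@coords))

#' @describeIn VFGrid-class coordinate matrix (degrees, OD convention)
#' @export
setGeneric("gridCoords", function(x) standardGeneric("gridCoords"))

#' @rdname VFGrid-class
#' @export
setMethod("gridCoords", "VFGrid", function(x) x@coords)

#' @describeIn VFGrid-class quadrant label of location(s) `i`
#' @param i integer location index (vectorized).
#' @export
setGeneric("quadrantOf", function(x, i) standardGeneric("quadrantOf"))

#' @rdname VFGrid-class
#' @export
setMethod("quadrantOf", "VFGrid", function(x, i) x@quadrant[i])

#' @describeIn VFGrid-class indices of the axis-aligned neighbors of `i`
#' @export
setGeneric("neighborsOf", function(x, i) standardGeneric("neighborsOf"))

#' @rdname VFGrid-class
#' @export
setMethod("neighborsOf", "VFGrid", function(x, i) x@neighbors[[i]])

#' @describeIn VFGrid-class indices of blind-spot locations
#' @export
setGeneric("blindSpot", function(x) standardGeneric("blindSpot"))

#' @rdname VFGrid-class
#' @export
setMethod("blindSpot", "VFGrid", function(x) x@blindSpot)

#' @rdname VFGrid-class
#' @export
setMethod("show", "VFGrid", function(object) {
  cat(sprintf("VFGrid with %d locations (%d blind-spot)\n",
              nLocations(object), length(object@blindSpot)))
  cat("  x range:", paste(range(object@coords[, "x"]), collapse = " .. "),
      " y range:", paste(range(object@coords[, "y"]), collapse = " .. "),
      "\n")
})

#' Locate grid indices by coordinate
#'
#' @param grid a [VFGrid-class].
#' @param x,y coordinate vectors in degrees.
#' @return integer indices (NA where no location matches).
#' @export
locationIndex <- function(grid, x, y) {
  co <- gridCoords(grid)
  key <- paste(co[, 1], co[, 2])
  match(paste(x, y), key)
}

#' Mirror coordinates between left- and right-eye field conventions
#'
#' Left-eye (OS) fields are stored in right-eye (OD) convention by negating
#' the horizontal coordinate; applying the mirror twice is the identity.
#'
#' @param xy 2-column matrix of x, y coordinates.
#' @return matrix with x negated.
#' @export
mirrorCoords <- function(xy) {
  xy <- as.matrix(xy)
  xy[, 1] <- -xy[, 1]
  xy
}

#' Serialize / deserialize a grid to JSON
#'
#' @param grid a [VFGrid-class].
#' @param path file path; for `gridToJSON`, `NULL` returns the JSON string.
#' @return `gridFromJSON` returns a [VFGrid-class].
#' @export
gridToJSON <- function(grid, path = NULL) {
  co <- gridCoords(grid)
  obj <- list(
    x = unname(co[, 1]), y = unname(co[, 2]),
    blind_spot = as.integer(blindSpot(grid))
  )
  js <- jsonlite::toJSON(obj, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname gridToJSON
#' @export
gridFromJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  VFGrid(cbind(obj$x, obj$y), blindSpot = as.integer(obj$blind_spot))
}
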