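#' Build a camera grid with embedded corral traps
#'
#' Lays out \code{rows x cols} cameras on a rectangular lattice with the
#' given spacing, and places \code{n_traps} corral traps inside the camera
#' bounding box by deterministic stratified sampling: an overlay grid of
#' strata is drawn over the box, one trap is placed per selected stratum at
#' its centre plus a seeded uniform jitter. This mirrors a spatially
#' balanced trap design nested within a camera array.
#'
#' @param rows,cols Camera lattice dimensions (rows along x).
#' @param spacing_km Lattice spacing in km.
#' @param n_traps Number of corral traps.
#' @param seed Integer seed controlling the trap jitter.
#' @param strata Optional integer pair (nx, ny) of overlay-grid dimensions;
#'   derived from the box aspect ratio when omitted. It is an error for
#'   \code{n_traps} to exceed the number of strata.
#'
#' @return A \code{detector_array}: data frame with columns \code{id},
#'   \code{x}, \code{y} (km) and \code{type} (\code{"camera"} or
#'   \code{"trap"}).
#' @export
build_detector_grid <- function(rows = 5L, cols = 4L, spacing_km = 0.75,
                                n_traps = 10L, seed = 1L, strata = NULL) {
  stopifnot(rows >= 1, cols >= 1, n_traps >= 1, spacing_km > 0)
  cam <- expand.grid(x = (seq_len(rows) - 1) * spacing_km,
                     y = (seq_len(cols) - 1) * spacing_km)
  n_cam <- nrow(cam)
  width <- max(cam$x) - min(cam$x)
  height <- max(cam$y) - min(cam$y)

  if (is.null(strata)) {
    ny <- max(1L, round(sqrt(n_traps * max(height, spacing_km) /
                               max(width, spacing_km))))
    nx <- ceiling(n_traps / ny)
    strata <- c(nx, ny)
  }
  n_strata <- prod(strata)
  if (n_traps > n_strata)
    stop("n_traps (", n_traps, ") exceeds number of strata (", n_strata, ")")

  # evenly spread stratum selection, then seeded jitter within each stratum
  sel <- unique(round(seq(1, n_strata, length.out = n_traps)))
  ix <- (sel - 1) %% strata[1]
  iy <- (sel - 1) %/% strata[1]
  sw <- width / strata[1]
  sh <- height / strata[2]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  tx <- min(cam$x) + (ix + 0.5) * sw + stats::runif(n_traps, -0.35, 0.35) * sw
  ty <- min(cam$y) + (iy + 0.5) * sh + stats::runif(n_traps, -0.35, 0.35) * sh
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tx <- pmin(pmax(tx, min(cam$x)), max(cam$x))
  ty <- pmin(pmax(ty, min(cam$y)), max(cam$y))

  det <- data.frame(
    id = c(sprintf("C%02d", seq_len(n_cam)), sprintf("T%02d", seq_len(n_traps))),
    x = c(cam$x, tx),
    y = c(cam$y, ty),
    type = c(rep("camera", n_cam), rep("trap", n_traps)),
    stringsAsFactors = FALSE
  )
  class(det) <- c("detector_array", "data.frame")
  det
}

#' Convex hull of a detector array
#'
#' @param detectors A \code{detector_array} or any data frame with
#'   \code{x}, \code{y} columns.
#' @param type Optional detector type filter.
#' @return Matrix of hull vertices (counter-clockwise), columns x, y.
#' @export
detector_hull <- function(detectors, type = NULL) {
  if (!is.null(type)) detectors <- detectors[detectors$type %in% type, ]
  pts <- unique(cbind(detectors$x, detectors$y))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[rev(h), , drop = FALSE]   # chull is clockwise; reverse to CCW
}

# Landscape = bounding box of all detectors expanded by the margin.
landscape_extent <- function(detectors, margin_km) {
  list(xmin = min(detectors$x) - margin_km,
       xmax = max(detectors$x) + margin_km,
       ymin = min(detectors$y) - margin_km,
       ymax = max(detectors$y) + margin_km)
}

#' Landscape area implied by a detector array and margin
#'
#' @param detectors Detector array.
#' @param margin_km Margin added on every side of the detector bounding box.
#' @return Area in km^2.
#' @export
landscape_area <- function(detectors, margin_km) {
  ext <- landscape_extent(detectors, margin_km)
  (ext$xmax - ext$xmin) * (ext$ymax - ext$ymin)
}
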