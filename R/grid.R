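#' Discretise a lake outline into a regular modelling grid
#'
#' Builds the discrete spatial domain of the fusion model: a regular grid of
#' square cells covering the bounding box of a lake outline, with a logical
#' water mask marking the cells whose centers lie inside the outline after an
#' inward shoreline buffer has been removed. The buffer excludes shallow
#' near-shore water where satellite retrievals are unreliable.
#'
#' A cell center belongs to the domain when it is inside the outline polygon
#' and at least \code{buffer_distance} metres from the polygon boundary
#' (morphological erosion of the polygon).
#'
#' @param lake_outline two-column matrix of polygon vertices (metres, projected
#'   coordinates). The polygon is closed implicitly; it must be simple
#'   (non-self-intersecting).
#' @param cell_size cell side length in metres (60 m at operational
#'   resolution; coarser values keep desk-scale experiments fast).
#' @param buffer_distance inward shoreline buffer in metres (default 500).
#' @param bounds optional rectangle \code{c(xmin, ymin, xmax, ymax)}; defaults
#'   to the outline bounding box.
#' @return an object of class \code{lake_grid}: a list with
#'   \item{cell_centers}{n_cells x 2 matrix of water-cell center coordinates}
#'   \item{n_cells}{number of water cells}
#'   \item{cell_size}{cell side (m)}
#'   \item{nx, ny, origin}{raster layout of the underlying pixel lattice}
#'   \item{mask}{logical nx x ny matrix, TRUE for water cells}
#'   \item{cell_of_pixel}{integer nx x ny matrix mapping pixels to water-cell
#'     ids (NA outside the domain)}
#' @examples
#' g <- make_grid(square_outline(6000), cell_size = 600)
#' g$n_cells  # 8 x 8 interior once the 500-m buffer strips the outer ring
#' @export
make_grid <- function(lake_outline, cell_size, buffer_distance = 500,
                      bounds = NULL) {
  lake_outline <- as.matrix(lake_outline)
  stopifnot(ncol(lake_outline) == 2, nrow(lake_outline) >= 3)
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (buffer_distance < 0) stop("buffer_distance must be >= 0")

  if (is.null(bounds)) {
    bounds <- c(min(lake_outline[, 1]), min(lake_outline[, 2]),
                max(lake_outline[, 1]), max(lake_outline[, 2]))
  }
  nx <- max(1L, ceiling((bounds[3] - bounds[1]) / cell_size))
  ny <- max(1L, ceiling((bounds[4] - bounds[2]) / cell_size))
  xs <- bounds[1] + (seq_len(nx) - 0.5) * cell_size
  ys <- bounds[2] + (seq_len(ny) - 0.5) * cell_size
  centers <- cbind(rep(xs, times = ny), rep(ys, each = nx))

  inside <- pracma::inpolygon(centers[, 1], centers[, 2],
                              lake_outline[, 1], lake_outline[, 2],
                              boundary = FALSE)
  keep <- inside
  if (buffer_distance > 0) {
    d <- dist_to_polygon(centers, lake_outline)
    keep <- inside & d >= buffer_distance
  }
  if (!any(keep)) {
    stop("empty domain: the buffer distance removes every cell; ",
         "reduce buffer_distance or use a larger outline")
  }

  mask <- matrix(keep, nrow = nx, ncol = ny)
  cell_of_pixel <- matrix(NA_integer_, nx, ny)
  cell_of_pixel[mask] <- seq_len(sum(mask))

  structure(list(
    cell_centers = centers[keep, , drop = FALSE],
    n_cells = sum(keep),
    cell_size = cell_size,
    nx = nx, ny = ny,
    origin = bounds[1:2],
    mask = mask,
    cell_of_pixel = cell_of_pixel
  ), class = "lake_grid")
}

#' @export
print.lake_grid <- function(x, ...) {
  cat(sprintf("lake_grid: %d water cells of %g m on a %d x %d lattice\n",
              x$n_cells, x$cell_size, x$nx, x$ny))
  invisible(x)
}

#' Square lake outline helper
#'
#' Convenience polygon for synthetic experiments: an axis-aligned rectangle
#' (square by default) with its lower-left corner at \code{origin}.
#'
#' @param side side length in metres, or a length-2 vector \code{c(sx, sy)}.
#' @param origin lower-left corner, default \code{c(0, 0)}.
#' @return a 4 x 2 matrix of vertices.
#' @export
square_outline <- function(side, origin = c(0, 0)) {
  side <- rep_len(side, 2)
  cbind(origin[1] + c(0, side[1], side[1], 0),
        origin[2] + c(0, 0, side[2], side[2]))
}

# Minimum distance from each point to the polygon boundary (segments).
dist_to_polygon <- function(points, poly) {
  v1 <- poly
  v2 <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  d <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(v1))) {
    a <- v1[s, ]; b <- v2[s, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      ds <- sqrt((points[, 1] - a[1])^2 + (points[, 2] - a[2])^2)
    } else {
      t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      px <- a[1] + t * ab[1]
      py <- a[2] + t * ab[2]
      ds <- sqrt((points[, 1] - px)^2 + (points[, 2] - py)^2)
    }
    d <- pmin(d, ds)
  }
  d
}

#' Map planar coordinates to the nearest water cell
#'
#' Observations and satellite pixels are tied to state cells by nearest cell
#' center, which keeps the 60 m vs 300 m resampling rule deterministic.
#'
#' @param grid a \code{lake_grid}.
#' @param xy two-column matrix (or length-2 vector) of coordinates in metres.
#' @return integer vector of water-cell indices.
#' @export
nearest_cell <- function(grid, xy) {
  stopifnot(inherits(grid, "lake_grid"))
  xy <- matrix(xy, ncol = 2)
  vapply(seq_len(nrow(xy)), function(i) {
    d2 <- (grid$cell_centers[, 1] - xy[i, 1])^2 +
          (grid$cell_centers[, 2] - xy[i, 2])^2
    which.min(d2)
  }, integer(1))
}

#' Expand per-cell values onto the pixel lattice
#'
#' Returns an \code{nx x ny} matrix with water cells filled from \code{values}
#' and everything outside the domain set to NA. This is the exchange format
#' for map layers (written to and read from plain-text grids).
#'
#' @param grid a \code{lake_grid}.
#' @param values numeric vector of length \code{grid$n_cells}.
#' @return numeric matrix of dimension \code{c(nx, ny)}.
#' @export
field_matrix <- function(grid, values) {
  stopifnot(inherits(grid, "lake_grid"), length(values) == grid$n_cells)
  m <- matrix(NA_real_, grid$nx, grid$ny)
  m[grid$mask] <- values[grid$cell_of_pixel[grid$mask]]
  m
}

#' Collapse a pixel-lattice matrix back to per-cell values
#'
#' Inverse of \code{\link{field_matrix}} on the water mask.
#'
#' @param grid a \code{lake_grid}.
#' @param m numeric matrix of dimension \code{c(nx, ny)}.
#' @return numeric vector of length \code{grid$n_cells}.
#' @export
field_values <- function(grid, m) {
  stopifnot(inherits(grid, "lake_grid"),
            nrow(m) == grid$nx, ncol(m) == grid$ny)
  v <- rep(NA_real_, grid$n_cells)
  idx <- grid$cell_of_pixel[grid$mask]
  v[idx] <- m[grid$mask]
  v
}
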