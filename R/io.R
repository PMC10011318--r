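#' Write / read an observation table as CSV
#'
#' The exchange format carries coordinates rather than internal cell ids:
#' columns \code{day}, \code{source}, \code{x}, \code{y}, \code{value_ugL},
#' \code{rel_sd}. On reading, coordinates are snapped back to the nearest
#' water-cell center.
#'
#' @param observations observation data frame (\code{day}, \code{cell},
#'   \code{value}, \code{source}, \code{rel_sd}).
#' @param grid the \code{lake_grid} the cell indices refer to.
#' @param path CSV file path.
#' @return \code{read_observations_csv} returns the internal observation data
#'   frame.
#' @export
write_observations_csv <- function(observations, grid, path) {
  stopifnot(inherits(grid, "lake_grid"))
  out <- data.frame(
    day = observations$day,
    source = observations$source,
    x = grid$cell_centers[observations$cell, 1],
    y = grid$cell_centers[observations$cell, 2],
    value_ugL = observations$value,
    rel_sd = observations$rel_sd
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path, grid) {
  stopifnot(inherits(grid, "lake_grid"))
  raw <- utils::read.csv(path)
  data.frame(
    day = raw$day,
    cell = nearest_cell(grid, cbind(raw$x, raw$y)),
    value = raw$value_ugL,
    source = raw$source,
    rel_sd = raw$rel_sd
  )
}

#' Write / read a map layer as a plain-text grid
#'
#' Map layers (daily mean, SD, relative SD, truth snapshots, raw satellite
#' scenes) are exchanged as long-format CSV with one row per water cell:
#' \code{x}, \code{y}, \code{value}. Plain text keeps the products
#' inspectable and portable; values round-trip at full double precision.
#'
#' @param grid a \code{lake_grid}.
#' @param values per-cell values (length \code{n_cells}).
#' @param path CSV file path.
#' @return \code{read_field_csv} returns the per-cell value vector, ordered
#'   by the grid's cell index.
#' @export
write_field_csv <- function(grid, values, path) {
  stopifnot(inherits(grid, "lake_grid"), length(values) == grid$n_cells)
  out <- data.frame(x = grid$cell_centers[, 1], y = grid$cell_centers[, 2],
                    value = values)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, grid) {
  stopifnot(inherits(grid, "lake_grid"))
  raw <- utils::read.csv(path)
  values <- rep(NA_real_, grid$n_cells)
  values[nearest_cell(grid, cbind(raw$x, raw$y))] <- raw$value
  values
}

#' Write a fusion product as CSV
#'
#' One row per day and cell with the posterior mean, log-SD, interval bounds
#' and linear SD.
#'
#' @param product a fusion product data frame.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_product_csv <- function(product, path) {
  utils::write.csv(product, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' Records seed, configuration, stream combinations and station cells so a
#' product set can be reproduced exactly.
#'
#' @param manifest the \code{manifest} element of a \code{fusion_experiment}.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
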