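#' Orthogonal P1 unit cell
#'
#' Constructs a unit cell with 90 degree angles. Only primitive orthogonal
#' cells are supported; the cell volume is \code{a * b * c}.
#'
#' @param a,b,c Edge lengths in Angstrom. \code{b} and \code{c} default to
#'   \code{a} (cubic cell).
#' @return An object of class \code{unit_cell} with fields \code{a}, \code{b},
#'   \code{c} and \code{volume} (Angstrom^3).
#' @export
#' @examples
#' cell <- unit_cell(10)
#' cell$volume # 1000
unit_cell <- function(a, b = a, c = a) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), length(a) == 1L)
  if (a <= 0 || b <= 0 || c <= 0) {
    stop("unit cell edges must be positive", call. = FALSE)
  }
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         volume = as.numeric(a) * as.numeric(b) * as.numeric(c)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell P1: %.3f x %.3f x %.3f A, 90/90/90, V = %.2f A^3>\n",
              x$a, x$b, x$c, x$volume))
  invisible(x)
}

#' Voxel sampling of a unit cell
#'
#' A periodic grid over a unit cell. Voxel index \code{i} (0-based) on the x
#' axis corresponds to fractional coordinate \code{i / nx}; the grid is
#' periodic so index \code{nx} wraps to 0. Sampling is therefore half-open on
#' \code{[0, 1)} along every axis.
#'
#' @param cell A [unit_cell()].
#' @param nx,ny,nz Positive voxel counts per axis; \code{ny}, \code{nz}
#'   default to \code{nx}.
#' @return A \code{map_grid} object with the cell, counts and per-axis
#'   spacings in Angstrom.
#' @export
map_grid <- function(cell, nx, ny = nx, nz = nx) {
  stopifnot(inherits(cell, "unit_cell"))
  n <- c(nx, ny, nz)
  if (any(n < 1) || any(n != round(n))) {
    stop("voxel counts must be positive integers", call. = FALSE)
  }
  structure(
    list(cell = cell, nx = as.integer(nx), ny = as.integer(ny),
         nz = as.integer(nz),
         spacing = c(cell$a / nx, cell$b / ny, cell$c / nz)),
    class = "map_grid"
  )
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map_grid %d x %d x %d over %.2f x %.2f x %.2f A (spacing %.3f/%.3f/%.3f A)>\n",
              x$nx, x$ny, x$nz, x$cell$a, x$cell$b, x$cell$c,
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Grid for a dataset configuration
#'
#' Voxel counts are derived as \code{round(edge / spacing)} and forced to be
#' even (the U-net's 2x pooling requires even axes). A 20 A cell at 0.5 A
#' spacing gives a 40^3 grid; 10 A / 0.5 A and 12 A / 0.6 A both give 20^3.
#'
#' @param cell A [unit_cell()].
#' @param spacing Target grid spacing in Angstrom.
#' @return A [map_grid()].
#' @export
grid_from_spacing <- function(cell, spacing) {
  stopifnot(spacing > 0)
  n <- round(c(cell$a, cell$b, cell$c) / spacing)
  n <- ifelse(n %% 2 == 1, n + 1, n)
  map_grid(cell, n[1], n[2], n[3])
}

#' Periodic 3D map of real values
#'
#' @param grid A [map_grid()].
#' @param values Numeric 3D array with dim \code{c(nx, ny, nz)}.
#' @param role Either \code{"density"} or \code{"patterson"}.
#' @return A \code{voxel_map} object.
#' @export
voxel_map <- function(grid, values, role = c("density", "patterson")) {
  role <- match.arg(role)
  stopifnot(inherits(grid, "map_grid"))
  values <- as.array(values)
  if (!identical(dim(values), c(grid$nx, grid$ny, grid$nz))) {
    stop("values shape does not match grid counts", call. = FALSE)
  }
  structure(list(grid = grid, values = values, role = role),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map [%s] %d x %d x %d, range [%.4g, %.4g]>\n",
              x$role, x$grid$nx, x$grid$ny, x$grid$nz,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Rescale a map linearly onto [-1, 1]
#'
#' Per-map affine min-max normalization: the minimum value maps to -1 and the
#' maximum to +1. A constant map (zero range) normalizes to all zeros rather
#' than erroring, so degenerate fixtures pass through the pipeline. The
#' operation is idempotent.
#'
#' @param map A [voxel_map()].
#' @param mode \code{"minmax"} for the affine map above, or \code{"maxabs"}
#'   for symmetric division by \code{max(abs(values))} (keeps zero at zero).
#' @return A [voxel_map()] with values in \code{[-1, 1]}.
#' @export
normalize_map <- function(map, mode = c("minmax", "maxabs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "voxel_map"))
  v <- map$values
  if (any(!is.finite(v))) stop("map contains non-finite values", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (mode == "minmax") {
    if (hi - lo <= 0) {
      v[] <- 0
    } else {
      v <- 2 * (v - lo) / (hi - lo) - 1
    }
  } else {
    m <- max(abs(v))
    if (m <= 0) v[] <- 0 else v <- v / m
  }
  voxel_map(map$grid, v, map$role)
}
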