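#' Regular grid geometry
#'
#' Defines the discretised study window: a regular lattice of `nx` by `ny`
#' square cells of side `cell_size`, anchored at the lower-left corner
#' `origin`. Cells are indexed row-major with x fastest, so cell `k`
#' (1-based) sits at column `i = ((k - 1) %% nx) + 1` and row
#' `j = ((k - 1) %/% nx) + 1`, with centre
#' `origin + (i - 0.5, j - 0.5) * cell_size`. All distances elsewhere in the
#' package are expressed in the same length units as `cell_size`.
#'
#' @param nx,ny Number of cells along x and y (each at least 2).
#' @param cell_size Length of a cell edge (positive).
#' @param origin Numeric length-2, coordinates of the lower-left corner of
#'   the lower-left cell.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(100, 100)
#' n_cells(g)
#' @export
grid_geometry <- function(nx, ny, cell_size = 1, origin = c(0, 0)) {
  nx <- as.integer(nx)
  ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L)
    stop("grid must have nx >= 2 and ny >= 2 cells")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar")
  if (!is.numeric(origin) || length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be two finite coordinates")
  structure(
    list(nx = nx, ny = ny, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells, cell_size %g, origin (%g, %g)\n",
              x$nx, x$ny, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A `grid_geometry`.
#' @return Integer cell count `nx * ny`.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  grid$nx * grid$ny
}

#' Cell-centre coordinates
#'
#' @param grid A `grid_geometry`.
#' @param cells Optional integer cell indices (default all cells, in storage
#'   order).
#' @return A two-column matrix of (x, y) cell-centre coordinates.
#' @export
cell_centers <- function(grid, cells = NULL) {
  stopifnot(inherits(grid, "grid_geometry"))
  if (is.null(cells)) cells <- seq_len(n_cells(grid))
  cells <- as.integer(cells)
  if (any(is.na(cells)) || any(cells < 1L) || any(cells > n_cells(grid)))
    stop("cell index out of range")
  i <- ((cells - 1L) %% grid$nx) + 1L
  j <- ((cells - 1L) %/% grid$nx) + 1L
  cbind(x = grid$origin[1] + (i - 0.5) * grid$cell_size,
        y = grid$origin[2] + (j - 0.5) * grid$cell_size)
}

#' Map coordinates to cell indices
#'
#' Real-valued coordinates are assigned to cells by floor division on the
#' cell size; points must fall inside the grid extent.
#'
#' @param grid A `grid_geometry`.
#' @param x,y Coordinate vectors of equal length.
#' @return Integer vector of 1-based cell indices.
#' @export
cell_index <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_geometry"), length(x) == length(y))
  i <- floor((x - grid$origin[1]) / grid$cell_size)
  j <- floor((y - grid$origin[2]) / grid$cell_size)
  # points exactly on the top/right boundary belong to the last cell
  i[x == grid$origin[1] + grid$nx * grid$cell_size & i == grid$nx] <- grid$nx - 1
  j[y == grid$origin[2] + grid$ny * grid$cell_size & j == grid$ny] <- grid$ny - 1
  bad <- !is.finite(i) | !is.finite(j) | i < 0 | i >= grid$nx | j < 0 | j >= grid$ny
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the grid extent", sum(bad)))
  as.integer(j * grid$nx + i + 1)
}

#' Extend a grid symmetrically
#'
#' Adds `extension` cells of padding on every side; used to push lattice
#' boundary effects away from the study window.
#'
#' @param grid A `grid_geometry`.
#' @param extension Non-negative integer number of padding cells per side.
#' @return List with the extended `grid` and `window`, the indices of the
#'   original cells inside the extended grid (in the original storage order).
#' @export
extend_grid <- function(grid, extension) {
  stopifnot(inherits(grid, "grid_geometry"))
  extension <- as.integer(extension)
  if (is.na(extension) || extension < 0L) stop("extension must be >= 0")
  if (extension == 0L)
    return(list(grid = grid, window = seq_len(n_cells(grid))))
  gx <- grid_geometry(grid$nx + 2L * extension, grid$ny + 2L * extension,
                      grid$cell_size,
                      grid$origin - extension * grid$cell_size)
  i <- rep(seq_len(grid$nx), grid$ny) + extension
  j <- rep(seq_len(grid$ny), each = grid$nx) + extension
  window <- as.integer((j - 1L) * gx$nx + i)
  list(grid = gx, window = window)
}

#' Latent field on a grid
#'
#' A real-valued surface stored as one value per grid cell (row-major,
#' x fastest).
#'
#' @param grid A `grid_geometry`.
#' @param values Numeric vector of length `n_cells(grid)`, all finite.
#' @return An object of class `latent_field`.
#' @export
latent_field <- function(grid, values) {
  stopifnot(inherits(grid, "grid_geometry"))
  values <- as.numeric(values)
  if (length(values) != n_cells(grid))
    stop("values must have one entry per grid cell")
  if (any(!is.finite(values)))
    stop("field values must all be finite")
  structure(list(grid = grid, values = values), class = "latent_field")
}

#' @export
print.latent_field <- function(x, ...) {
  cat(sprintf("<latent_field> on %d x %d grid; range [%.3g, %.3g]\n",
              x$grid$nx, x$grid$ny, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.latent_field <- function(x, ...) {
  matrix(x$values, nrow = x$grid$ny, ncol = x$grid$nx, byrow = TRUE)
}
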