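#' Regular analysis grid
#'
#' A regular grid of square cells in projected planar km. Cells are
#' identified by integer ids `0 .. n_rows * n_cols - 1` in row-major
#' order with row 0 the northernmost row. Each cell covers the half-open
#' square `[x0, x0 + s) x [y0, y0 + s)` so every boundary point belongs
#' to exactly one cell.
#'
#' @param n_rows,n_cols Positive integers.
#' @param cell_size_km Cell edge length (km, > 0).
#' @param origin Numeric `(x, y)`: south-west corner of the grid in km.
#' @return Object of class `div_grid`.
#' @examples
#' g <- make_grid(4, 5, cell_size_km = 5)
#' head(cell_centroids(g))
#' @export
make_grid <- function(n_rows, n_cols, cell_size_km, origin = c(0, 0)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_km > 0,
            length(origin) == 2)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_km = cell_size_km, origin = as.numeric(origin),
                 n_cells = as.integer(n_rows) * as.integer(n_cols)),
            class = "div_grid")
}

#' @export
print.div_grid <- function(x, ...) {
  cat(sprintf("Grid: %d x %d cells of %g km (%d cells), origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size_km, x$n_cells,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell id to (row, col) and back
#'
#' Row-major bijection between 0-based cell ids and 0-based `(row, col)`
#' pairs, with row 0 northernmost.
#'
#' @param grid A `div_grid`.
#' @param cell_id Integer vector of cell ids.
#' @return `cell_rowcol`: data.frame with columns `cell_id`, `row`, `col`.
#' @export
cell_rowcol <- function(grid, cell_id = seq_len(grid$n_cells) - 1L) {
  cell_id <- as.integer(cell_id)
  if (any(cell_id < 0 | cell_id >= grid$n_cells))
    stop("cell_id out of range")
  data.frame(cell_id = cell_id,
             row = cell_id %/% grid$n_cols,
             col = cell_id %% grid$n_cols)
}

#' @rdname cell_rowcol
#' @param row,col 0-based row (from north) and column (from west) indices.
#' @export
cell_id_at <- function(grid, row, col) {
  stopifnot(all(row >= 0 & row < grid$n_rows),
            all(col >= 0 & col < grid$n_cols))
  as.integer(row) * grid$n_cols + as.integer(col)
}

#' Cell centroids in projected km
#'
#' @param grid A `div_grid`.
#' @return data.frame with columns `cell_id`, `x`, `y` (km); `y` grows
#'   northward.
#' @export
cell_centroids <- function(grid) {
  rc <- cell_rowcol(grid)
  s <- grid$cell_size_km
  data.frame(cell_id = rc$cell_id,
             x = grid$origin[1] + (rc$col + 0.5) * s,
             y = grid$origin[2] + (grid$n_rows - rc$row - 0.5) * s)
}

# lower-left corners; cells are half-open [x0, x0+s) x [y0, y0+s)
cell_corners <- function(grid, cell_id = seq_len(grid$n_cells) - 1L) {
  rc <- cell_rowcol(grid, cell_id)
  s <- grid$cell_size_km
  data.frame(cell_id = rc$cell_id,
             x0 = grid$origin[1] + rc$col * s,
             y0 = grid$origin[2] + (grid$n_rows - rc$row - 1) * s)
}

# full extent of the grid as (xmin, xmax, ymin, ymax)
grid_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + grid$n_cols * grid$cell_size_km,
    ymin = grid$origin[2],
    ymax = grid$origin[2] + grid$n_rows * grid$cell_size_km)
}

# reshape a per-cell vector (row-major, row 0 north) into a matrix
cell_vector_to_matrix <- function(grid, values) {
  stopifnot(length(values) == grid$n_cells)
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

matrix_to_cell_vector <- function(m) as.vector(t(m))
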