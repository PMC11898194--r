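# Smoothed-noise environmental surfaces. A surface is seeded white noise
# on the grid, convolved with a separable Gaussian kernel of scale
# `autocorr_length_cells` (reflection padding), then linearly rescaled to
# a range appropriate for the named variable. This produces the spatial
# autocorrelation the downstream statistics must cope with without
# committing to a particular covariance family.

.SURFACE_RANGES <- list(
  elevation = c(500, 4500),    # m
  MAT       = c(-2, 18),       # degrees C
  AP        = c(400, 1600),    # mm
  elev_sd   = c(20, 400),      # m, within-cell elevation SD
  MAT_lgm1  = c(-8, -2), MAT_lgm2 = c(-8, -2), MAT_lgm3 = c(-8, -2),
  AP_lgm1   = c(-400, -50), AP_lgm2 = c(-400, -50), AP_lgm3 = c(-400, -50),
  lu_cropland = c(0, 1), lu_forest = c(0, 1), lu_ugs = c(0, 1),
  lu_other  = c(0, 1),
  unit      = c(0, 1)
)

gaussian_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-hw:hw) / sigma)^2)
  k <- k / sum(k)
  pad_reflect <- function(x, hw) {
    n <- length(x)
    i <- c(pmin(hw:1, n), 1:n, pmax(n - (1:hw) + 1, 1))
    x[i]
  }
  conv1 <- function(x) {
    xp <- pad_reflect(x, hw)
    as.numeric(stats::filter(xp, k, sides = 2))[(hw + 1):(hw + length(x))]
  }
  m <- apply(m, 2, conv1)
  m <- t(apply(m, 1, conv1))
  m
}

rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) return(rep((lo + hi) / 2, length(x)))
  (x - rng[1]) / diff(rng) * (hi - lo) + lo
}

#' Generate a spatially autocorrelated environmental surface
#'
#' Draws seeded white noise on the grid of `config`, smooths it with an
#' isotropic Gaussian kernel of scale `config$autocorr_length_cells`
#' (in cells) and rescales it linearly to the named variable's range
#' (e.g. elevation in 500-4500 m, MAT in -2-18 degrees C). Deterministic:
#' the same config (including seed) always yields the same surface, and
#' each surface name draws from its own seed stream.
#'
#' @param config A [landscape_config()].
#' @param which Surface name: `elevation`, `MAT`, `AP`, `elev_sd`,
#'   `MAT_lgm1..3`, `AP_lgm1..3`, `lu_cropland`, `lu_forest`, `lu_ugs`,
#'   `lu_other` or `unit`.
#' @return Numeric vector with one value per grid cell (row-major,
#'   row 0 = northernmost).
#' @examples
#' cfg <- landscape_config(n_rows = 8, n_cols = 8, n_species = 5, seed = 7)
#' elev <- generate_surface(cfg, "elevation")
#' @export
generate_surface <- function(config, which) {
  config <- validate_landscape_config(config)
  if (!which %in% names(.SURFACE_RANGES))
    stop("unknown surface '", which, "'; valid surfaces: ",
         paste(names(.SURFACE_RANGES), collapse = ", "))
  rng <- .SURFACE_RANGES[[which]]
  seed <- .child_seed(config$seed, .SEED_OFFSETS[[which]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- matrix(rnorm(config$n_rows * config$n_cols),
              nrow = config$n_rows, ncol = config$n_cols)
  m <- gaussian_smooth_matrix(m, config$autocorr_length_cells)
  rescale_range(matrix_to_cell_vector(m), rng[1], rng[2])
}

# save/restore the global RNG state so seeded component draws do not
# disturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a habitat raster by banding elevation
#'
#' Classifies per-cell elevation into three bands at its terciles,
#' mimicking the elevation-habitat confounding of montane systems.
#'
#' @param elevation Per-cell elevation (m).
#' @return Character vector of habitat codes
#'   (`"lowland"`, `"montane"`, `"alpine"`).
#' @export
habitat_from_elevation <- function(elevation) {
  q <- quantile(elevation, c(1 / 3, 2 / 3), names = FALSE)
  codes <- c("lowland", "montane", "alpine")
  codes[1L + (elevation > q[1]) + (elevation > q[2])]
}

#' Moran's I at a given lag on the analysis grid
#'
#' Brute-force Moran's I from its definition, with binary weights linking
#' cell pairs at the given rook-neighbourhood lag. Used to verify the
#' autocorrelation of generated surfaces.
#'
#' @param grid A `div_grid`.
#' @param values Per-cell numeric vector.
#' @param lag Integer lag in cells (1 = immediate rook neighbours).
#' @return Moran's I (numeric scalar).
#' @export
morans_i <- function(grid, values, lag = 1L) {
  stopifnot(length(values) == grid$n_cells)
  rc <- cell_rowcol(grid)
  z <- values - mean(values)
  num <- 0; s0 <- 0
  # neighbours at exactly `lag` steps along rows or columns
  for (shift in list(c(lag, 0L), c(0L, lag))) {
    r2 <- rc$row + shift[1]; c2 <- rc$col + shift[2]
    ok <- r2 < grid$n_rows & c2 < grid$n_cols
    i <- which(ok)
    j <- cell_id_at(grid, r2[ok], c2[ok]) + 1L
    num <- num + 2 * sum(z[i] * z[j])  # symmetric pairs counted both ways
    s0 <- s0 + 2 * length(i)
  }
  (grid$n_cells / s0) * num / sum(z^2)
}
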