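#' Configuration for the synthetic landscape generator
#'
#' Collects every knob of the synthetic study system in one validated
#' object. The defaults define a scaled-down montane study region: a
#' 20 x 20 grid of 5 x 5 km cells (400 cells) with 40 species, smoothed
#' environmental surfaces, an east-to-west richness gradient, correlated
#' size traits, and land-use fields that shape where species ranges sit.
#'
#' @param n_rows,n_cols Grid dimensions; `n_rows * n_cols` must be >= 4.
#' @param cell_size_km Cell edge length in projected km (> 0).
#' @param n_species Number of species to simulate (>= 3).
#' @param autocorr_length_cells Gaussian smoothing scale (in cells, >= 0)
#'   applied to the white-noise environmental surfaces; 0 gives
#'   spatially uncorrelated surfaces.
#' @param richness_gradient_strength East-west trend coefficient for
#'   range placement; 0 removes the gradient, larger values concentrate
#'   range centres eastward so assembled richness declines westward.
#' @param trait_corr Log-scale correlation injected between the designated
#'   trait pairs (hindfoot/tail length and body length/body mass); must
#'   lie strictly inside (-1, 1).
#' @param yule_birth_rate Speciation rate of the Yule tree (> 0).
#' @param missing_trait_frac Expected fraction of species given one
#'   missing trait value, exercising the completeness filter (in [0, 1)).
#' @param range_width_frac Two-vector: min and max species range extent
#'   as a fraction of the landscape extent per axis.
#' @param landuse_effects Named numeric vector (`forest`, `cropland`):
#'   log-density coefficients with which the standardized land-use fields
#'   weight range-centre placement. Positive `forest` concentrates
#'   species (hence richness) in forested cells.
#' @param climate_effect Log-density coefficient of standardized MAT on
#'   range-centre placement; a positive value makes warm cells richer,
#'   the dominant smooth driver of richness in montane systems.
#' @param seed Integer root seed; every downstream draw derives a
#'   component-specific child seed from it.
#'
#' @return An object of class `landscape_config` (a validated list).
#' @examples
#' cfg <- landscape_config(n_rows = 8, n_cols = 8, n_species = 10, seed = 1)
#' @export
landscape_config <- function(n_rows = 20L, n_cols = 20L, cell_size_km = 5,
                             n_species = 600L, autocorr_length_cells = 3,
                             richness_gradient_strength = 0.5,
                             trait_corr = 0.5, yule_birth_rate = 1,
                             missing_trait_frac = 0.2,
                             range_width_frac = c(0.05, 0.18),
                             landuse_effects = c(forest = 1.5,
                                                 cropland = -1.75),
                             climate_effect = 0.3,
                             seed = 1L) {
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_km = cell_size_km, n_species = as.integer(n_species),
    autocorr_length_cells = autocorr_length_cells,
    richness_gradient_strength = richness_gradient_strength,
    trait_corr = trait_corr, yule_birth_rate = yule_birth_rate,
    missing_trait_frac = missing_trait_frac,
    range_width_frac = range_width_frac,
    landuse_effects = landuse_effects,
    climate_effect = climate_effect,
    seed = as.integer(seed)
  )
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
}

validate_landscape_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_rows * cfg$n_cols < 4)
    stop("grid must have at least 4 cells (n_rows * n_cols >= 4)")
  if (cfg$n_species < 3)
    stop("n_species must be >= 3")
  if (!is.numeric(cfg$cell_size_km) || cfg$cell_size_km <= 0)
    stop("cell_size_km must be a positive real")
  if (!is.numeric(cfg$autocorr_length_cells) || cfg$autocorr_length_cells < 0)
    stop("autocorr_length_cells must be >= 0")
  if (abs(cfg$trait_corr) >= 1)
    stop("trait_corr must lie strictly inside (-1, 1)")
  if (cfg$yule_birth_rate <= 0)
    stop("yule_birth_rate must be positive")
  if (cfg$missing_trait_frac < 0 || cfg$missing_trait_frac >= 1)
    stop("missing_trait_frac must be in [0, 1)")
  if (length(cfg$range_width_frac) != 2 ||
      any(cfg$range_width_frac <= 0) ||
      cfg$range_width_frac[1] > cfg$range_width_frac[2])
    stop("range_width_frac must be an increasing pair of positive fractions")
  if (!all(c("forest", "cropland") %in% names(cfg$landuse_effects)))
    stop("landuse_effects must name 'forest' and 'cropland'")
  if (!is.numeric(cfg$climate_effect) || length(cfg$climate_effect) != 1)
    stop("climate_effect must be a single number")
  if (is.na(cfg$seed))
    stop("seed must be an integer")
  cfg
}

#' @export
print.landscape_config <- function(x, ...) {
  cat("Synthetic landscape configuration\n")
  cat(sprintf("  grid: %d x %d cells of %g km\n", x$n_rows, x$n_cols,
              x$cell_size_km))
  cat(sprintf("  species: %d  (missing-trait fraction %.2f)\n",
              x$n_species, x$missing_trait_frac))
  cat(sprintf("  surface autocorrelation: %g cells\n",
              x$autocorr_length_cells))
  cat(sprintf("  richness gradient: %g; land-use effects: forest %+g, cropland %+g\n",
              x$richness_gradient_strength, x$landuse_effects[["forest"]],
              x$landuse_effects[["cropland"]]))
  cat(sprintf("  trait correlation %g, Yule rate %g, seed %d\n",
              x$trait_corr, x$yule_birth_rate, x$seed))
  invisible(x)
}
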