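.TRAIT_NAMES <- c("hindfoot_length", "tail_length", "body_length",
                  "body_mass", "litters_per_year", "litter_size",
                  "maturity", "generation_length", "gestation_length")

# size traits treated as log-normal throughout (transformed before
# standardization in the trait space, and generated on the log scale)
.SIZE_TRAITS <- c("hindfoot_length", "tail_length", "body_length",
                  "body_mass")

# log-scale location and spread per trait (mammal-like orders of magnitude)
.TRAIT_MEANLOG <- c(3.4, 5.0, 5.7, 6.9, 0.2, 1.1, 6.0, 6.8, 4.2)
.TRAIT_SDLOG   <- c(0.6, 0.6, 0.6, 0.9, 0.3, 0.3, 0.4, 0.4, 0.4)

#' Generate a Yule phylogeny for the synthetic species pool
#'
#' Simulates a rooted, bifurcating pure-birth (Yule) tree with
#' `config$n_species` tips labelled `sp0001`, `sp0002`, ... and strictly
#' positive branch lengths, via [ape::rphylo()] conditioned on the tip
#' count. Deterministic for a fixed config seed.
#'
#' @param config A [landscape_config()].
#' @return An [ape::phylo] object.
#' @export
generate_phylogeny <- function(config) {
  if (config$n_species < 2) stop("need at least 2 species for a phylogeny")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.child_seed(config$seed, .SEED_OFFSETS[["phylogeny"]]))
  tree <- ape::rphylo(config$n_species, birth = config$yule_birth_rate,
                      death = 0)
  tree$tip.label <- species_ids(config$n_species)
  tree
}

species_ids <- function(n) sprintf("sp%04d", seq_len(n))

#' Generate a correlated species trait table
#'
#' Draws the nine mammal traits (hindfoot length mm, tail length mm,
#' body length mm, body mass g, litters per year, litter size, maturity,
#' generation length, gestation length) from a multivariate log-normal.
#' The designated pairs hindfoot/tail length and body length/body mass
#' get log-scale correlation `config$trait_corr`; all other pairs are
#' uncorrelated. A fraction `config$missing_trait_frac` of species
#' receives one missing value to exercise the completeness filter.
#'
#' @param config A [landscape_config()].
#' @return data.frame with column `species_id`, the nine trait columns,
#'   and logical `complete`.
#' @export
generate_traits <- function(config) {
  if (config$n_species < 2) stop("need at least 2 species")
  if (abs(config$trait_corr) >= 1)
    stop("trait_corr must lie strictly inside (-1, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.child_seed(config$seed, .SEED_OFFSETS[["traits"]]))

  k <- length(.TRAIT_NAMES)
  R <- diag(k)
  pair_idx <- list(c(1L, 2L), c(3L, 4L)) # hindfoot~tail, body length~mass
  for (p in pair_idx) {
    R[p[1], p[2]] <- config$trait_corr
    R[p[2], p[1]] <- config$trait_corr
  }
  z <- matrix(rnorm(config$n_species * k), config$n_species, k) %*% chol(R)
  logx <- sweep(sweep(z, 2, .TRAIT_SDLOG, `*`), 2, .TRAIT_MEANLOG, `+`)
  x <- exp(logx)
  colnames(x) <- .TRAIT_NAMES
  traits <- data.frame(species_id = species_ids(config$n_species), x,
                       stringsAsFactors = FALSE)

  incomplete <- runif(config$n_species) < config$missing_trait_frac
  for (i in which(incomplete))
    traits[i, .TRAIT_NAMES[sample.int(k, 1)]] <- NA_real_
  traits$complete <- stats::complete.cases(traits[, .TRAIT_NAMES])
  traits
}

#' Generate species range rectangles with elevation and habitat limits
#'
#' Each species receives an axis-aligned rectangular extent-of-occurrence
#' polygon, an elevation interval and a non-empty set of tolerated
#' habitat codes. Range centres are sampled over cells with density
#' proportional to `exp(g * east + b_f * forest_z + b_c * cropland_z)`,
#' where `g` is `richness_gradient_strength` and the `b` are the
#' configured `landuse_effects`; assembled richness therefore declines
#' westward and tracks the land-use fields with known signs. Elevation
#' limits are the 5th-95th percentile of elevation over the cells the
#' rectangle covers; habitat codes are those covering at least 15% of
#' those cells (always including the modal code).
#'
#' @param config A [landscape_config()].
#' @param elevation Per-cell elevation (m).
#' @param habitat Per-cell habitat code; defaults to elevation terciles.
#' @param landuse Optional data.frame with per-cell `forest` and
#'   `cropland` fields used for the placement weights; when absent the
#'   land-use effects are not injected.
#' @param climate Optional per-cell MAT values; when present, placement
#'   density includes `climate_effect * z(MAT)`.
#' @return List of species ranges; each element is a list with
#'   `species_id`, `polygon` (closed-ring matrix of x/y vertices, km),
#'   `elev_lo`, `elev_hi` and `habitat_codes`.
#' @export
generate_ranges <- function(config, elevation,
                            habitat = habitat_from_elevation(elevation),
                            landuse = NULL, climate = NULL) {
  grid <- make_grid(config$n_rows, config$n_cols, config$cell_size_km)
  stopifnot(length(elevation) == grid$n_cells,
            length(habitat) == grid$n_cells)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.child_seed(config$seed, .SEED_OFFSETS[["ranges"]]))

  rc <- cell_rowcol(grid)
  east <- rc$col / max(1L, grid$n_cols - 1L)
  logw <- 0
  if (!is.null(landuse)) {
    zf <- as.numeric(scale(landuse$forest))
    zc <- as.numeric(scale(landuse$cropland))
    logw <- logw + config$landuse_effects[["forest"]] * zf +
      config$landuse_effects[["cropland"]] * zc
  }
  if (!is.null(climate))
    logw <- logw + config$climate_effect * as.numeric(scale(climate))
  # suitability effects pass through a bounded monotone link (no single
  # best cell can absorb most range centres); the directional east-west
  # gradient multiplies in as a smooth exponential trend
  w <- exp(config$richness_gradient_strength * east) *
    stats::plogis(logw / 1.5)
  cen <- cell_centroids(grid)
  ext <- unname(grid_extent(grid))
  span <- c(ext[2] - ext[1], ext[4] - ext[3])

  lapply(seq_len(config$n_species), function(s) {
    cell <- sample.int(grid$n_cells, 1L, prob = w)
    cx <- cen$x[cell] + runif(1, -0.5, 0.5) * grid$cell_size_km
    cy <- cen$y[cell] + runif(1, -0.5, 0.5) * grid$cell_size_km
    wx <- runif(1, config$range_width_frac[1], config$range_width_frac[2]) *
      span[1]
    wy <- runif(1, config$range_width_frac[1], config$range_width_frac[2]) *
      span[2]
    poly <- cbind(x = c(cx - wx / 2, cx + wx / 2, cx + wx / 2, cx - wx / 2),
                  y = c(cy - wy / 2, cy - wy / 2, cy + wy / 2, cy + wy / 2))
    rng <- list(species_id = species_ids(config$n_species)[s],
                polygon = poly, elev_lo = 0, elev_hi = 1,
                habitat_codes = character(0))
    cells <- rasterize_range(rng, grid)
    ev <- elevation[cells + 1L]
    lo <- quantile(ev, 0.05, names = FALSE)
    hi <- quantile(ev, 0.95, names = FALSE)
    if (hi - lo < 1) { lo <- lo - 25; hi <- hi + 25 }
    hv <- habitat[cells + 1L]
    tab <- table(hv) / length(hv)
    codes <- union(names(tab)[which.max(tab)], names(tab)[tab >= 0.15])
    rng$elev_lo <- lo
    rng$elev_hi <- hi
    rng$habitat_codes <- codes
    rng
  })
}
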