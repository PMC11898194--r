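#' Synthesize a complete study system
#'
#' Generates every input of the diversity analysis from one seed: the
#' analysis grid; smoothed elevation, climate and land-use surfaces;
#' a habitat raster banded from elevation (three elevation belts, which
#' confounds habitat with elevation as in real mountain systems); LGM
#' climate layers for three synthetic GCMs (current surface plus a
#' smoothed model-specific perturbation); rectangular species ranges
#' with elevation limits and habitat codes; a correlated trait table; a
#' Yule phylogeny; a per-cell predictor table (including a deliberately
#' collinear `elev_range` column so the collinearity screen has work to
#' do); and six rectangular "mountain region" labels for group
#' comparisons.
#'
#' @param config A [landscape_config()].
#' @return Object of class `synthetic_study`: list with `config`,
#'   `grid`, `elevation`, `habitat`, `ranges`, `traits`, `tree`,
#'   `predictors`, `region` and `centroids`.
#' @export
synthesize_study <- function(config) {
  config <- validate_landscape_config(config)
  grid <- make_grid(config$n_rows, config$n_cols, config$cell_size_km)

  elevation <- generate_surface(config, "elevation")
  habitat <- habitat_from_elevation(elevation)

  # montane temperature is dominated by the elevational lapse rate, with
  # a smoothed mesoclimatic residual on top
  mat_meso <- generate_surface(config, "MAT")
  mat_z <- 0.75 * as.numeric(scale(-elevation)) +
    0.25 * as.numeric(scale(mat_meso))
  mat <- rescale_range(mat_z, .SURFACE_RANGES$MAT[1], .SURFACE_RANGES$MAT[2])
  ap <- generate_surface(config, "AP")
  mat_lgm <- sapply(1:3, function(g)
    mat + generate_surface(config, paste0("MAT_lgm", g)))
  ap_lgm <- sapply(1:3, function(g)
    ap + generate_surface(config, paste0("AP_lgm", g)))

  # land-use proportions: softmax over four smoothed fields, the fourth
  # ("other") absorbing the remainder so reported proportions sum to < 1
  # land use varies at a finer spatial scale than climate: half the
  # climate correlation length (at least one cell). Each class's
  # proportion is a capped logistic transform of its own latent field,
  # so the three reported proportions are mutually independent and sum
  # to < 1 (the remainder is other cover).
  lu_config <- config
  lu_config$autocorr_length_cells <- max(1, config$autocorr_length_cells / 2)
  lu_fields <- sapply(c("lu_cropland", "lu_forest", "lu_ugs"),
                      function(s) generate_surface(lu_config, s))
  lu_z <- scale(lu_fields)
  lu_prop <- cbind(cropland = 0.35 * stats::plogis(lu_z[, 1]),
                   forest = 0.55 * stats::plogis(lu_z[, 2]),
                   ugs = 0.10 * stats::plogis(lu_z[, 3]))

  elev_sd <- generate_surface(config, "elev_sd")

  # placement effects act on the latent (Gaussian) land-use fields; each
  # reported proportion is a monotone transform of its own field
  landuse <- data.frame(forest = lu_fields[, "lu_forest"],
                        cropland = lu_fields[, "lu_cropland"])
  ranges <- generate_ranges(config, elevation, habitat, landuse,
                            climate = mat)
  traits <- generate_traits(config)
  tree <- generate_phylogeny(config)

  predictors <- data.frame(
    cell_id = seq_len(grid$n_cells) - 1L,
    MAT = mat, AP = ap,
    lgm_mat_anomaly = lgm_anomaly(mat, mat_lgm),
    lgm_ap_anomaly = lgm_anomaly(ap, ap_lgm),
    prop_cropland = lu_prop[, "cropland"],
    prop_forest = lu_prop[, "forest"],
    prop_ugs = lu_prop[, "ugs"],
    elev_sd = elev_sd,
    # near-duplicate of elev_sd: exercises the pairwise screen stage
    elev_range = 2.2 * elev_sd + generate_surface(config, "unit") * 40
  )

  rc <- cell_rowcol(grid)
  region <- paste0(ifelse(rc$row < grid$n_rows / 2, "N", "S"),
                   c("W", "C", "E")[pmin(3, 1 + (rc$col * 3) %/%
                                           grid$n_cols)])

  structure(list(config = config, grid = grid, elevation = elevation,
                 habitat = habitat, ranges = ranges, traits = traits,
                 tree = tree, predictors = predictors, region = region,
                 centroids = cell_centroids(grid)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study system\n")
  print(x$grid)
  cat(sprintf("  %d species ranges, %d trait-complete species, tree with %d tips\n",
              length(x$ranges), sum(x$traits$complete),
              length(x$tree$tip.label)))
  cat(sprintf("  predictors: %s\n",
              paste(setdiff(names(x$predictors), "cell_id"),
                    collapse = ", ")))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes ranges as a GeoJSON FeatureCollection, traits and predictors
#' as CSV, the tree as Newick, elevation/habitat/region as CSV matrices
#' (first row = northernmost) and the config as YAML.
#'
#' @param study A [synthesize_study()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  feats <- lapply(study$ranges, function(r) {
    ring <- rbind(r$polygon, r$polygon[1, , drop = FALSE]) # close ring
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))),
         properties = list(species_id = r$species_id,
                           elev_lo = r$elev_lo, elev_hi = r$elev_hi,
                           habitat_codes = as.list(r$habitat_codes)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       p("ranges.geojson"), auto_unbox = TRUE, digits = NA)

  write.csv(study$traits, p("traits.csv"), row.names = FALSE)
  write.csv(study$predictors, p("predictors.csv"), row.names = FALSE)
  ape::write.tree(study$tree, p("tree.nwk"))
  g <- study$grid
  utils::write.table(cell_vector_to_matrix(g, study$elevation),
                     p("elevation.csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cell_vector_to_matrix(g, study$habitat),
                     p("habitat.csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cell_vector_to_matrix(g, study$region),
                     p("region.csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  cfg <- study$config
  cfg$landuse_effects <- as.list(cfg$landuse_effects)
  cfg$range_width_frac <- as.numeric(cfg$range_width_frac)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a synthetic study back from [write_study()] output
#'
#' @param dir Directory written by [write_study()].
#' @return A `synthetic_study` object (regions/centroids reconstructed
#'   from the config grid).
#' @export
read_study <- function(dir) {
  p <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing study file: ", path)
    path
  }
  cfg_raw <- yaml::read_yaml(p("config.yaml"))
  cfg_raw$landuse_effects <- unlist(cfg_raw$landuse_effects)
  config <- do.call(landscape_config, cfg_raw)
  grid <- make_grid(config$n_rows, config$n_cols, config$cell_size_km)

  gj <- jsonlite::fromJSON(p("ranges.geojson"), simplifyVector = FALSE)
  ranges <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    colnames(ring) <- c("x", "y")
    list(species_id = f$properties$species_id,
         polygon = ring[-nrow(ring), , drop = FALSE],
         elev_lo = f$properties$elev_lo, elev_hi = f$properties$elev_hi,
         habitat_codes = unlist(f$properties$habitat_codes))
  })

  traits <- read.csv(p("traits.csv"), stringsAsFactors = FALSE)
  predictors <- read.csv(p("predictors.csv"))
  tree <- ape::read.tree(p("tree.nwk"))
  elevation <- matrix_to_cell_vector(as.matrix(
    read.csv(p("elevation.csv"), header = FALSE)))
  habitat <- matrix_to_cell_vector(as.matrix(
    read.csv(p("habitat.csv"), header = FALSE, stringsAsFactors = FALSE)))
  region <- matrix_to_cell_vector(as.matrix(
    read.csv(p("region.csv"), header = FALSE, stringsAsFactors = FALSE)))

  structure(list(config = config, grid = grid, elevation = elevation,
                 habitat = habitat, ranges = ranges, traits = traits,
                 tree = tree, predictors = predictors, region = region,
                 centroids = cell_centroids(grid)),
            class = "synthetic_study")
}
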