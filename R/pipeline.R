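# Pipeline orchestration: synth -> assemble -> metrics -> nulls -> stats,
# with one seed and one output layout, producing deterministic CSVs plus
# a JSON manifest of per-stage accounting.

#' Pipeline run configuration
#'
#' Collects the analysis constants: 999 null replicates, +/-1.96 SES
#' dispersion thresholds, the |r| < 0.7 and VIF < 5 collinearity screen,
#' and REML spatial GLS are the defaults.
#'
#' @param synth A [landscape_config()] describing the synthetic study,
#'   or `NULL` when `study_dir` is given.
#' @param study_dir Optional directory of a written study to analyse
#'   instead of synthesizing one.
#' @param n_reps Null-model replicates (default 999).
#' @param trades_per_rep Curveball trades per replicate (`NULL` =
#'   `max(5 * n_species, 1000)`).
#' @param null_metrics Metrics to standardize: subset of `c("fd", "pd")`.
#' @param ses_threshold Dispersion threshold (default 1.96).
#' @param r_max,vif_max Collinearity screen thresholds (0.7, 5).
#' @param gls_method `"REML"` or `"ML"`.
#' @param seed Root seed for the run (synth seed and null seeds derive
#'   from it).
#' @return Object of class `run_config`.
#' @export
run_config <- function(synth = landscape_config(), study_dir = NULL,
                       n_reps = 999, trades_per_rep = NULL,
                       null_metrics = c("fd", "pd"),
                       ses_threshold = 1.96, r_max = 0.7, vif_max = 5,
                       gls_method = "REML", seed = 1L) {
  if (is.null(study_dir)) {
    synth$seed <- as.integer(seed)
    synth <- validate_landscape_config(synth)
  }
  stopifnot(n_reps >= 1, ses_threshold > 0, r_max > 0, vif_max > 1)
  null_metrics <- match.arg(null_metrics, c("fd", "pd"), several.ok = TRUE)
  structure(list(synth = synth, study_dir = study_dir,
                 n_reps = as.integer(n_reps),
                 trades_per_rep = trades_per_rep,
                 null_metrics = null_metrics,
                 ses_threshold = ses_threshold, r_max = r_max,
                 vif_max = vif_max, gls_method = gls_method,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline config from YAML (strict schema)
#'
#' Unknown keys are errors; `synth:` holds [landscape_config()] fields.
#'
#' @param path YAML file path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "synth")
  unknown <- setdiff(names(raw), c(known, "synth"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$synth)) {
    s_unknown <- setdiff(names(raw$synth), names(formals(landscape_config)))
    if (length(s_unknown))
      stop("unknown synth key(s): ", paste(s_unknown, collapse = ", "))
    if (!is.null(raw$synth$landuse_effects))
      raw$synth$landuse_effects <- unlist(raw$synth$landuse_effects)
    args$synth <- do.call(landscape_config, raw$synth)
  }
  do.call(run_config, args)
}

#' Run the full diversity-facet pipeline
#'
#' Executes synth (or study loading), community assembly (rasterize,
#' elevation/habitat refinement, trait-completeness filter), diversity
#' metrics, Curveball null models with SES, and the statistical stage
#' (collinearity screen, standardization, spatial GLS per facet,
#' modified t-test correlations, Kruskal-Wallis/Dunn region
#' comparisons). All numeric outputs are pure functions of the config,
#' so rerunning with the same config reproduces them byte-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for stage CSVs and the manifest.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"),
                              3)
    res
  }

  # --- synth -------------------------------------------------------------
  study <- stage("synth", {
    if (!is.null(config$study_dir)) read_study(config$study_dir)
    else synthesize_study(config$synth)
  })
  write_study(study, p("study"))

  # --- assemble ----------------------------------------------------------
  asm <- stage("assemble", {
    raw <- build_presence(study$ranges, study$grid)
    ref <- refine_occurrences(raw, study$ranges, study$elevation,
                              study$habitat)
    flt <- filter_trait_complete(ref$presence, study$traits)
    list(raw = raw, refined = ref, filtered = flt)
  })
  presence <- asm$filtered$presence
  write.csv(data.frame(species_id = rownames(presence), presence,
                       check.names = FALSE),
            p("presence.csv"), row.names = FALSE)

  # --- metrics -----------------------------------------------------------
  space <- build_trait_space(study$traits)
  tree <- ape::keep.tip(study$tree, rownames(presence))
  profile <- stage("metrics",
    diversity_profile(presence, study$traits, tree, space = space,
                      group = study$region))
  write.csv(as.data.frame(profile), p("diversity.csv"), row.names = FALSE)

  # --- nulls -------------------------------------------------------------
  ens <- stage("nulls",
    generate_nulls(presence, n_reps = config$n_reps,
                   trades_per_rep = config$trades_per_rep,
                   seed = .child_seed(config$seed,
                                      .SEED_OFFSETS[["nulls"]]),
                   metrics = config$null_metrics, space = space,
                   tree = tree))
  ses <- list()
  for (met in config$null_metrics) {
    obs <- profile[[met]]
    names(obs) <- profile$cell_id
    ses[[met]] <- compute_ses(obs, ens, metric = met,
                              threshold = config$ses_threshold)
    write.csv(as.data.frame(ses[[met]]), p(sprintf("ses_%s.csv", met)),
              row.names = FALSE)
  }

  # --- stats -------------------------------------------------------------
  stats_out <- stage("stats", {
    screen <- collinearity_screen(study$predictors, config$r_max,
                                  config$vif_max)
    Xz <- standardize_predictors(
      study$predictors[, screen$retained, drop = FALSE])
    coords <- study$centroids[, c("x", "y")]
    responses <- c(list(richness = as.numeric(profile$richness)),
                   lapply(ses, function(s) s$ses))
    fits <- list()
    for (nm in names(responses)) {
      y <- responses[[nm]]
      ok <- !is.na(y)
      if (sum(ok) <= ncol(Xz) + 3) { # facet undefined in most cells
        fits[[nm]] <- structure(
          list(coefficients = NULL, range = NA_real_, n = sum(ok),
               k = ncol(Xz) + 1L, method = config$gls_method,
               converged = FALSE,
               diagnostics = "too few defined cells for the model"),
          class = "gls_fit")
        next
      }
      fits[[nm]] <- gls_exponential(y[ok], Xz[ok, , drop = FALSE],
                                    coords[ok, ], method = config$gls_method)
      if (fits[[nm]]$converged)
        write.csv(fits[[nm]]$coefficients, p(sprintf("gls_%s.csv", nm)),
                  row.names = FALSE)
    }
    cors <- lapply(c(fd = "fd", pd = "pd"), function(met) {
      ok <- !is.na(profile[[met]])
      if (sum(ok) < 10) return(NULL)
      modified_ttest(profile$richness[ok], profile[[met]][ok], coords[ok, ])
    })
    cor_df <- do.call(rbind, lapply(names(cors), function(met) {
      ct <- cors[[met]]
      if (is.null(ct)) return(NULL)
      data.frame(pair = paste0("richness_", met), r = ct$r, ess = ct$ess,
                 t = ct$t, p = ct$p)
    }))
    if (!is.null(cor_df))
      write.csv(cor_df, p("correlations.csv"), row.names = FALSE)
    groups <- lapply(c(richness = "richness", fd = "fd", pd = "pd"),
                     function(v) {
      ok <- !is.na(profile[[v]])
      tab <- table(study$region[ok])
      use <- ok & study$region %in% names(tab)[tab >= 2]
      if (length(unique(study$region[use])) < 2) return(NULL)
      group_compare(profile[[v]][use], study$region[use])
    })
    gc_df <- do.call(rbind, lapply(names(groups), function(v) {
      g <- groups[[v]]
      if (is.null(g)) return(NULL)
      data.frame(facet = v, H = g$kw$statistic, df = g$kw$df,
                 p = g$kw$p,
                 letters = paste(names(g$letters), g$letters, sep = ":",
                                 collapse = ";"))
    }))
    if (!is.null(gc_df))
      write.csv(gc_df, p("group_comparisons.csv"), row.names = FALSE)
    list(screen = screen, fits = fits, correlations = cors,
         groups = groups)
  })

  manifest <- list(
    seed = config$seed,
    n_reps = config$n_reps,
    trades_per_rep = ens$trades_per_rep,
    ses_threshold = config$ses_threshold,
    counts = list(
      n_cells = study$grid$n_cells,
      species_total = length(study$ranges),
      species_retained = nrow(presence),
      species_excluded_traits = length(asm$filtered$excluded),
      occurrences_removed_refinement =
        sum(asm$refined$removed),
      cells_fd_defined = sum(!is.na(profile$fd)),
      cells_pd_defined = sum(!is.na(profile$pd))
    ),
    predictors_retained = stats_out$screen$retained,
    files = setdiff(list.files(out_dir), "manifest.json"),
    timings_s = timings,
    total_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 3)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Summaries of a completed pipeline run
#'
#' Recomputes the headline summary shapes from the per-cell result
#' files: mean +/- SD of each facet over defined cells (overall and per
#' region) and the counts and fractions of over-/under-dispersed cells
#' for the standardized facets.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return List with `facets` (data.frame of per-facet mean/SD/n),
#'   `by_region` (the same per region) and `dispersion` (per-metric
#'   class counts and fractions).
#' @export
summarize_run <- function(out_dir) {
  div_path <- file.path(out_dir, "diversity.csv")
  if (!file.exists(div_path)) stop("missing results file: ", div_path)
  div <- read.csv(div_path)
  facet_stats <- function(df) do.call(rbind, lapply(
    c("richness", "fd", "pd"), function(v)
      data.frame(facet = v, mean = mean(df[[v]], na.rm = TRUE),
                 sd = sd(df[[v]], na.rm = TRUE),
                 n_defined = sum(!is.na(df[[v]])))))
  out <- list(facets = facet_stats(div))
  if (!is.null(div$group))
    out$by_region <- do.call(rbind, lapply(split(div, div$group),
      function(d) cbind(region = d$group[1], facet_stats(d))))
  disp <- list()
  for (met in c("fd", "pd")) {
    f <- file.path(out_dir, sprintf("ses_%s.csv", met))
    if (!file.exists(f)) next
    s <- read.csv(f)
    tab <- table(factor(s$class, levels = c("overdispersed",
                                            "underdispersed", "neither",
                                            "undefined")))
    disp[[met]] <- data.frame(metric = met, class = names(tab),
                              n_cells = as.integer(tab),
                              fraction = as.integer(tab) / nrow(s))
  }
  out$dispersion <- do.call(rbind, disp)
  rownames(out$dispersion) <- NULL
  out
}
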