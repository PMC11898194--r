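# The synthetic-landscape generator: determinism, injected spatial
# autocorrelation, Yule tree properties, trait correlation structure and
# range construction.

test_that("surfaces are deterministic and validated", {
  cfg <- landscape_config(n_rows = 10, n_cols = 10, n_species = 5, seed = 4)
  expect_identical(generate_surface(cfg, "elevation"),
                   generate_surface(cfg, "elevation"))
  expect_false(identical(generate_surface(cfg, "elevation"),
                         generate_surface(cfg, "AP")))
  expect_error(generate_surface(cfg, "bogus"), "valid surfaces")
  expect_length(generate_surface(cfg, "MAT"), 100)
})

test_that("unsmoothed surfaces are spatially white", {
  # zero smoothing scale: lag-1 autocorrelation ~ 0 across seeds
  g <- make_grid(12, 12, 1)
  acs <- sapply(1:20, function(s) {
    cfg <- landscape_config(n_rows = 12, n_cols = 12, n_species = 5,
                            autocorr_length_cells = 0, seed = s)
    morans_i(g, generate_surface(cfg, "elevation"), lag = 1)
  })
  expect_lt(abs(mean(acs)), 3 / sqrt(144))
})

test_that("smoothing at scale 5 on a 40x40 grid yields strong Moran's I", {
  cfg <- landscape_config(n_rows = 40, n_cols = 40, n_species = 5,
                          autocorr_length_cells = 5, seed = 9)
  x <- generate_surface(cfg, "elevation")
  g <- make_grid(40, 40, 1)
  obs <- morans_i(g, x, lag = 1)
  expect_gt(obs, 0.5)
  # oracle straight from the definition: I = (n/S0) sum_ij w_ij z_i z_j / sum z^2
  rc <- cell_rowcol(g)
  W <- (abs(outer(rc$row, rc$row, "-")) +
          abs(outer(rc$col, rc$col, "-"))) == 1
  z <- x - mean(x)
  oracle <- (length(x) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
  expect_equal(obs, oracle, tolerance = 1e-10)
  # and ape's implementation with row-normalized weights agrees closely
  expect_equal(obs, ape::Moran.I(x, W / rowSums(W))$observed,
               tolerance = 0.05)
})

test_that("Yule phylogenies are valid, labelled and Newick-stable", {
  cfg <- landscape_config(n_rows = 4, n_cols = 4, n_species = 12, seed = 2)
  tr <- generate_phylogeny(cfg)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), sprintf("sp%04d", 1:12))
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.binary(tr) && ape::is.rooted(tr))

  cfg2 <- landscape_config(n_rows = 4, n_cols = 4, n_species = 3, seed = 2)
  cfg2$n_species <- 2L # below the config floor, allowed by the op itself
  tr2 <- generate_phylogeny(cfg2)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)

  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_true(ape::all.equal.phylo(tr, back, tolerance = 1e-9))
})

test_that("tree heights are consistent with the Yule expectation", {
  # oracle: direct simulation of exponential inter-speciation waits,
  # conditioned on the tip count
  yule_height_oracle <- function(n, lambda) {
    sum(stats::rexp(n - 1, rate = lambda * (2:n))) # wait while k lineages
  }
  lambda <- 1
  set.seed(42)
  oracle <- replicate(400, yule_height_oracle(16, lambda))
  heights <- sapply(1:200, function(s) {
    cfg <- landscape_config(n_rows = 4, n_cols = 4, n_species = 16,
                            yule_birth_rate = lambda, seed = s)
    max(ape::node.depth.edgelength(generate_phylogeny(cfg)))
  })
  # means agree within 3 combined standard errors
  se <- sqrt(var(heights) / 200 + var(oracle) / 400)
  expect_lt(abs(mean(heights) - mean(oracle)), 3 * se)
})

test_that("trait tables carry the configured correlation and missingness", {
  cfg <- landscape_config(n_rows = 4, n_cols = 4, n_species = 500,
                          trait_corr = 0, missing_trait_frac = 0, seed = 5)
  tr <- generate_traits(cfg)
  expect_true(all(tr$complete))
  expect_true(all(tr[divfacets:::.TRAIT_NAMES] > 0))
  r <- cor(log(tr$hindfoot_length), log(tr$tail_length))
  expect_lt(abs(r), 0.15) # designated pair uncorrelated at trait_corr = 0

  cfg2 <- landscape_config(n_rows = 4, n_cols = 4, n_species = 500,
                           trait_corr = 0.7, missing_trait_frac = 0,
                           seed = 6)
  tr2 <- generate_traits(cfg2)
  expect_gt(cor(log(tr2$hindfoot_length), log(tr2$tail_length)), 0.55)
  expect_gt(cor(log(tr2$body_length), log(tr2$body_mass)), 0.55)

  cfg3 <- landscape_config(n_rows = 4, n_cols = 4, n_species = 100,
                           missing_trait_frac = 0.2, seed = 7)
  n_inc <- sum(!generate_traits(cfg3)$complete)
  expect_gte(n_inc, qbinom(0.025, 100, 0.2)) # binomial 95% band around 20
  expect_lte(n_inc, qbinom(0.975, 100, 0.2))

  expect_error(landscape_config(trait_corr = 1), "strictly inside")
})

test_that("every generated range intersects the grid", {
  cfg <- landscape_config(n_rows = 8, n_cols = 8, n_species = 40, seed = 3)
  elev <- generate_surface(cfg, "elevation")
  rngs <- generate_ranges(cfg, elev)
  g <- make_grid(8, 8, cfg$cell_size_km)
  hits <- vapply(rngs, function(r) length(rasterize_range(r, g)),
                 integer(1))
  expect_true(all(hits >= 1))
  expect_true(all(vapply(rngs, function(r) r$elev_lo < r$elev_hi,
                         logical(1))))
  expect_true(all(vapply(rngs, function(r) length(r$habitat_codes) > 0,
                         logical(1))))
})

test_that("the east-west richness gradient scales with its coefficient", {
  assemble_richness <- function(g_strength, seed) {
    cfg <- landscape_config(n_rows = 10, n_cols = 10, n_species = 150,
                            range_width_frac = c(0.2, 0.4),
                            richness_gradient_strength = g_strength,
                            seed = seed)
    elev <- generate_surface(cfg, "elevation")
    rngs <- generate_ranges(cfg, elev) # no land-use/climate injection
    g <- make_grid(10, 10, cfg$cell_size_km)
    list(rich = species_richness(build_presence(rngs, g)),
         col = cell_rowcol(g)$col)
  }
  # no injected gradient: per-seed column slopes are centred on zero
  slopes <- sapply(1:20, function(s) {
    a <- assemble_richness(0, s)
    unname(coef(lm(a$rich ~ a$col))[2])
  })
  expect_gt(t.test(slopes)$p.value, 0.05)
  # strong gradient: richness ranks track the column index
  rhos <- sapply(1:5, function(s) {
    a <- assemble_richness(2, s + 100)
    cor(a$col, a$rich, method = "spearman")
  })
  expect_gt(mean(rhos), 0.5)
})

test_that("full study generation is reproducible and cross-referenced", {
  cfg <- landscape_config(n_rows = 6, n_cols = 6, n_species = 12, seed = 8)
  s1 <- synthesize_study(cfg)
  s2 <- synthesize_study(cfg)
  expect_identical(s1$elevation, s2$elevation)
  expect_identical(s1$traits, s2$traits)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$predictors, s2$predictors)

  ids <- vapply(s1$ranges, `[[`, character(1), "species_id")
  expect_setequal(ids, s1$tree$tip.label)
  expect_setequal(ids, s1$traits$species_id)
  lu <- s1$predictors[c("prop_cropland", "prop_forest", "prop_ugs")]
  expect_true(all(lu >= 0 & lu <= 1))
  expect_true(all(rowSums(lu) <= 1))
})

test_that("studies round-trip through their plain-text file formats", {
  s1 <- small_study(seed = 10, n_species = 8, n_rows = 5, n_cols = 5)
  dir <- tempfile("study")
  write_study(s1, dir)
  s2 <- read_study(dir)
  expect_equal(s1$elevation, s2$elevation, tolerance = 1e-12)
  expect_identical(s1$habitat, s2$habitat)
  expect_equal(s1$predictors, s2$predictors, tolerance = 1e-12)
  expect_equal(s1$ranges, s2$ranges, tolerance = 1e-12)
  expect_equal(sum(s1$tree$edge.length), sum(s2$tree$edge.length),
               tolerance = 1e-6)
  expect_error(read_study(tempfile()), "missing study file")
})
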