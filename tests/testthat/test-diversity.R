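# Species richness, Faith's PD and convex-hull functional richness.

test_that("species richness is the column sums of the binary matrix", {
  m <- random_presence(20, 30, seed = 3)
  oracle <- colSums(m)
  storage.mode(oracle) <- "integer"
  expect_identical(species_richness(m), oracle)
  m2 <- m; m2[, 1] <- 0L
  expect_equal(unname(species_richness(m2)[1]), 0L)
  m3 <- m; m3[, 2] <- 1L
  expect_equal(unname(species_richness(m3)[2]), 20L)
  expect_error(species_richness(m * 2L), "binary")
})

test_that("faith_pd matches hand sums on the three-tip tree", {
  tr <- ape::read.tree(text = "((A:1.0,B:1.0):1.0,C:2.0);")
  expect_equal(faith_pd(tr, c("A", "B")), 3.0)   # tip edges + their stem
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5.0) # total tree length
  expect_equal(faith_pd(tr, c("A", "C")), 4.0)
  expect_true(is.na(faith_pd(tr, "A")))
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
})

test_that("faith_pd agrees with the path-marking oracle and picante", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    tr <- ape::rphylo(n, 1, 0)
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    sub <- sample(tr$tip.label, sample(2:n, 1))
    expect_equal(faith_pd(tr, sub), pd_path_oracle(tr, sub),
                 tolerance = 1e-9)
  }
  tr <- ape::rphylo(12, 1, 0)
  comm <- matrix(rbinom(3 * 12, 1, 0.6), nrow = 3,
                 dimnames = list(NULL, tr$tip.label))
  comm <- comm[rowSums(comm) >= 2, , drop = FALSE]
  mine <- apply(comm, 1, function(r)
    faith_pd(tr, colnames(comm)[r == 1]))
  ref <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(unname(mine), ref, tolerance = 1e-9)
})

test_that("faith_pd is monotone and batch/cell-wise consistent", {
  set.seed(12)
  tr <- ape::rphylo(15, 1, 0)
  tr$tip.label <- sprintf("t%02d", 1:15)
  sub <- sample(tr$tip.label, 5)
  for (extra in setdiff(tr$tip.label, sub))
    expect_gte(faith_pd(tr, c(sub, extra)), faith_pd(tr, sub))
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))
  expect_equal(faith_pd(tr, sub), faith_pd(tr, rev(sub)))

  pres <- random_presence(15, 12, seed = 4)
  rownames(pres) <- tr$tip.label
  batch <- divfacets:::faith_pd_cells(pres, tr)
  for (j in seq_len(ncol(pres))) {
    sp <- rownames(pres)[pres[, j] == 1]
    expected <- if (length(sp) >= 2) faith_pd(tr, sp) else NA_real_
    expect_equal(unname(batch[j]), expected)
  }
})

test_that("hull volumes are exact on known shapes and degenerate sets", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(as.numeric(hull_volume(sq)), 1.0)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(as.numeric(hull_volume(tri)), 0.5)
  seg <- cbind(c(0, 2, 5))
  expect_equal(as.numeric(hull_volume(seg)), 5) # 1-D: range length
  flat <- cbind(rnorm(8), rnorm(8), 0)
  v <- hull_volume(flat)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))
  # unit cube with interior points
  cube <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                matrix(runif(9, 0.2, 0.8), 3))
  expect_equal(as.numeric(hull_volume(cube)), 1.0)
})

test_that("hull volumes match the scipy qhull oracle", {
  set.seed(13)
  sets <- lapply(1:12, function(i) {
    d <- sample(2:5, 1)
    matrix(rnorm((d + sample(2:8, 1)) * d), ncol = d)
  })
  expect_equal(sapply(sets, function(x) as.numeric(hull_volume(x))),
               scipy_hull_volumes(sets), tolerance = 1e-8)
})

test_that("trait space is pool-standardized with orthonormal axes", {
  cfg <- landscape_config(n_rows = 4, n_cols = 4, n_species = 40,
                          missing_trait_frac = 0.1, seed = 14)
  traits <- generate_traits(cfg)
  space <- build_trait_space(traits)
  expect_equal(nrow(space$scores), sum(traits$complete))
  # standardized traits: mean 0, sd 1 across the pool
  z <- scale(space$scores %*% t(space$rotation), center = FALSE,
             scale = FALSE) # scores back-rotated = standardized traits
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # rotation is orthonormal, so hull volumes are basis-independent
  expect_equal(crossprod(space$rotation), diag(9), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("functional richness follows the dimensionality policy", {
  cfg <- landscape_config(n_rows = 4, n_cols = 4, n_species = 30,
                          missing_trait_frac = 0, seed = 15)
  space <- build_trait_space(generate_traits(cfg))
  pool <- rownames(space$scores)
  expect_true(is.na(functional_richness(space, pool[1:2])))
  expect_error(functional_richness(space, c(pool[1:3], "nope")), "nope")
  # n <= 9 species: d = n - 1 principal axes
  v5 <- functional_richness(space, pool[1:5])
  expect_equal(as.numeric(v5),
               as.numeric(hull_volume(space$scores[pool[1:5], 1:4])))
  # n > 9 species: full 9-axis space, equal to raw standardized volume
  v12 <- functional_richness(space, pool[1:12])
  expect_equal(as.numeric(v12),
               as.numeric(hull_volume(space$scores[pool[1:12], ])))
  # permutation invariance and monotonicity at fixed dimensionality
  expect_equal(as.numeric(functional_richness(space, rev(pool[1:12]))),
               as.numeric(v12))
  expect_gte(as.numeric(functional_richness(space, pool[1:13])),
             as.numeric(v12))
})

test_that("diversity profiles equal metric-by-metric recomputation", {
  study <- small_study(seed = 16, n_species = 20, n_rows = 5, n_cols = 5)
  pres <- build_presence(study$ranges, study$grid)
  flt <- suppressMessages(filter_trait_complete(pres, study$traits))
  tree <- ape::keep.tip(study$tree, rownames(flt$presence))
  space <- build_trait_space(study$traits)
  prof <- diversity_profile(flt$presence, study$traits, tree,
                            space = space, group = study$region)
  expect_equal(nrow(prof), 25)
  for (j in seq_len(ncol(flt$presence))) {
    sp <- rownames(flt$presence)[flt$presence[, j] == 1]
    expect_equal(prof$richness[j], length(sp))
    expect_equal(prof$pd[j],
                 if (length(sp) >= 2) faith_pd(tree, sp) else NA_real_)
    expect_equal(prof$fd[j],
                 if (length(sp) >= 3)
                   as.numeric(functional_richness(space, sp))
                 else NA_real_)
  }
  expect_true(all(is.na(prof$fd[prof$richness < 3])))
  expect_true(all(is.na(prof$pd[prof$richness < 2])))
  s <- summary(prof)
  expect_equal(s$overall["mean", "richness"], mean(prof$richness))
  expect_equal(s$overall["sd", "pd"], sd(prof$pd, na.rm = TRUE))
})
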