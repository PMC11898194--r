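# Curveball trades, null ensembles and standardized effect sizes.

test_that("trades preserve margins and fix saturated matrices", {
  m <- matrix(1L, 2, 2)
  set.seed(1)
  expect_identical(curveball_trade(m), m) # no unique columns to trade

  m <- random_presence(10, 15, seed = 5)
  set.seed(2)
  out <- curveball_randomize(m, 1000)
  expect_identical(rowSums(out), rowSums(m))
  expect_identical(colSums(out), colSums(m))
  expect_true(all(out %in% c(0L, 1L)))
  expect_error(curveball_trade(m * 3L), "binary")
})

test_that("single trades on the 2x2 checkerboard are uniform over states", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  admissible <- enumerate_fixed_margin(rowSums(m), colSums(m))
  expect_length(admissible, 2) # the checkerboard and its flip
  set.seed(3)
  keys <- replicate(10000, matrix_key(curveball_trade(m, rows = c(1, 2))))
  expect_setequal(unique(keys), sapply(admissible, matrix_key))
  freq <- mean(keys == matrix_key(m))
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("the chain reaches every fixed-margin matrix of a 6x4 system", {
  set.seed(4)
  m <- matrix(rbinom(24, 1, 0.45), 6, 4)
  m[rowSums(m) == 0, 1] <- 1L
  admissible <- sapply(enumerate_fixed_margin(rowSums(m), colSums(m)),
                       matrix_key)
  expect_gt(length(admissible), 1)
  seen <- character(0)
  set.seed(5)
  for (i in 1:5000) {
    m <- curveball_trade(m)
    seen <- union(seen, matrix_key(m))
  }
  expect_setequal(seen, admissible)
})

test_that("compiled chains sample fixed-margin states near-uniformly", {
  # curveball's stationary distribution is uniform over the admissible
  # matrices; check the compiled chain's visit frequencies on a small
  # enumerable system
  set.seed(6)
  m <- matrix(c(1L, 1L, 0L, 0L,
                0L, 1L, 1L, 0L,
                0L, 0L, 1L, 1L,
                1L, 0L, 0L, 1L), 4, 4, byrow = TRUE)
  states <- sapply(enumerate_fixed_margin(rowSums(m), colSums(m)),
                   matrix_key)
  k <- length(states)
  expect_gt(k, 5)
  set.seed(7)
  cur <- m
  keys <- character(3000)
  for (i in seq_along(keys)) {
    cur <- curveball_randomize(cur, 25)
    keys[i] <- matrix_key(cur)
  }
  freq <- table(factor(keys, levels = states)) / length(keys)
  expect_true(all(freq > 0))
  expect_true(all(freq > 0.4 / k & freq < 2.5 / k))
})

test_that("null ensembles conserve margins and honour trades_per_rep = 0", {
  study <- small_study(seed = 17, n_species = 20, n_rows = 5, n_cols = 5)
  pres <- build_presence(study$ranges, study$grid)
  flt <- suppressMessages(filter_trait_complete(pres, study$traits))
  tree <- ape::keep.tip(study$tree, rownames(flt$presence))
  space <- build_trait_space(study$traits)

  ens0 <- generate_nulls(flt$presence, n_reps = 1, trades_per_rep = 0,
                         seed = 1, metrics = "pd", tree = tree)
  prof <- diversity_profile(flt$presence, study$traits, tree, space = space)
  expect_equal(unname(ens0$metrics$pd[1, ]), prof$pd)

  expect_error(generate_nulls(flt$presence, n_reps = 0), "n_reps")
  expect_error(generate_nulls(flt$presence, n_reps = 1,
                              trades_per_rep = -1, seed = 1,
                              metrics = "pd", tree = tree),
               "trades_per_rep")

  # richness inside every null equals observed richness (margins fixed)
  ens <- generate_nulls(flt$presence, n_reps = 20, seed = 2,
                        metrics = "richness")
  expect_true(all(t(ens$metrics$richness) ==
                    as.numeric(species_richness(flt$presence))))
})

test_that("SES follows its formula and the +/-1.96 classification", {
  fake_ens <- structure(list(
    n_reps = 3, trades_per_rep = 0, seed = 1,
    metrics = list(fd = matrix(c(2, 3, 4,   1, 1, 1,  5, 5, 5),
                               nrow = 3,
                               dimnames = list(NULL, c("0", "1", "2"))))),
    class = "null_ensemble")
  obs <- c(`0` = 3, `1` = 3, `2` = NA)
  ses <- compute_ses(obs, fake_ens, "fd")
  expect_equal(ses$mean_null, c(3, 1, 5))
  expect_equal(ses$sd_null, c(1, 0, 0))
  expect_equal(ses$ses, c(0, NA, NA)) # sd 0 and NA obs are undefined
  expect_equal(as.character(ses$class),
               c("neither", "undefined", "undefined"))

  # obs = 5, null mean 3, null sd 1 -> SES 2 > 1.96: overdispersed
  e2 <- fake_ens
  e2$metrics$fd <- matrix(c(2, 3, 4), 3, 1,
                          dimnames = list(NULL, "0"))
  s2 <- compute_ses(c(`0` = 5), e2, "fd")
  expect_equal(s2$ses, 2.0)
  expect_equal(as.character(s2$class), "overdispersed")
  s3 <- compute_ses(c(`0` = 1), e2, "fd")
  expect_equal(as.character(s3$class), "underdispersed")
  # sd uses the n-1 denominator over replicates
  expect_equal(s2$sd_null, sd(c(2, 3, 4)))
})

test_that("richness SES is everywhere undefined under the null", {
  pres <- random_presence(12, 20, seed = 9)
  ens <- generate_nulls(pres, n_reps = 30, seed = 3, metrics = "richness")
  ses <- compute_ses(species_richness(pres), ens, "richness")
  expect_true(all(ses$sd_null == 0))
  expect_true(all(as.character(ses$class) == "undefined"))
})

test_that("SES stabilizes once chains pass the default length", {
  # doubling the trade count changes SES by little (chain mixing)
  study <- small_study(seed = 18, n_species = 30, n_rows = 6, n_cols = 6)
  pres <- build_presence(study$ranges, study$grid)
  flt <- suppressMessages(filter_trait_complete(pres, study$traits))
  tree <- ape::keep.tip(study$tree, rownames(flt$presence))
  prof <- divfacets:::faith_pd_cells(flt$presence, tree)
  T0 <- max(5 * nrow(flt$presence), 1000)
  ses_T <- compute_ses(prof, generate_nulls(flt$presence, 400,
                                            trades_per_rep = T0, seed = 4,
                                            metrics = "pd", tree = tree))
  ses_2T <- compute_ses(prof, generate_nulls(flt$presence, 400,
                                             trades_per_rep = 2 * T0,
                                             seed = 5, metrics = "pd",
                                             tree = tree))
  d <- abs(ses_T$ses - ses_2T$ses)
  expect_lt(mean(d, na.rm = TRUE), 0.1)
})

test_that("margin preservation matches vegan's curveball null model", {
  m <- random_presence(10, 12, seed = 10)
  mine <- curveball_randomize(m, 2000)
  nm <- vegan::nullmodel(m, "curveball")
  ref <- simulate(nm, nsim = 1, seed = 1)[, , 1]
  expect_identical(unname(rowSums(mine)), unname(rowSums(ref)))
  expect_identical(unname(colSums(mine)), unname(colSums(ref)))
})
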