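# Richness- and occupancy-preserving null communities via the Curveball
# algorithm, and standardized effect sizes with dispersion classes.

check_binary <- function(m) {
  if (!is.matrix(m) || !all(m %in% c(0L, 1L)))
    stop("matrix must be binary (0/1)")
}

#' One Curveball trade
#'
#' Picks two distinct rows uniformly at random, pools the columns held
#' by exactly one of them, and reallocates that pool uniformly among the
#' two rows while preserving both row sums. Column sums are trivially
#' preserved, so the full margins of the matrix are invariant.
#'
#' @param m Binary presence matrix with at least 2 rows.
#' @param rows Optional pair of distinct 1-based row indices; sampled
#'   uniformly when missing.
#' @return The (possibly unchanged) matrix after one trade.
#' @export
curveball_trade <- function(m, rows = NULL) {
  check_binary(m)
  if (nrow(m) < 2) stop("need at least two rows")
  if (is.null(rows)) rows <- sample.int(nrow(m), 2L)
  stopifnot(length(rows) == 2, rows[1] != rows[2])
  a <- m[rows[1], ]
  b <- m[rows[2], ]
  ua <- which(a == 1L & b == 0L) # columns unique to the first row
  ub <- which(a == 0L & b == 1L)
  na <- length(ua)
  if (na == 0L || length(ub) == 0L) return(m)
  pool <- c(ua, ub)
  keep <- sample(pool, na) # which pooled columns the first row keeps
  a[pool] <- 0L; b[pool] <- 1L
  a[keep] <- 1L; b[keep] <- 0L
  m[rows[1], ] <- a
  m[rows[2], ] <- b
  m
}

#' Run a Curveball trade chain
#'
#' Applies `n_trades` Curveball trades to a copy of the matrix (compiled
#' inner loop; uses R's RNG so results are seed-reproducible).
#'
#' @param m Binary presence matrix.
#' @param n_trades Number of trades (>= 0; 0 returns the input).
#' @return Randomized matrix with identical row and column sums.
#' @export
curveball_randomize <- function(m, n_trades) {
  check_binary(m)
  if (n_trades < 0) stop("n_trades must be >= 0")
  if (n_trades == 0) return(m)
  out <- .curveball_chain_cpp(m, as.integer(n_trades))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(m)
  out
}

#' Generate a null ensemble of randomized communities
#'
#' Builds `n_reps` independent null matrices, each obtained by applying
#' `trades_per_rep` Curveball trades to a fresh copy of the observed
#' matrix under a replicate-specific child seed, and evaluates the
#' requested per-cell metrics on every null matrix. Functional richness
#' inside nulls reuses the pooled trait-space basis of the observed
#' data: the null varies composition, not the trait space.
#'
#' @param presence Observed binary species x cell matrix.
#' @param n_reps Number of null replicates (default 999).
#' @param trades_per_rep Trades per replicate; default
#'   `max(5 * nrow(presence), 1000)`, a mixing margin over the
#'   O(rows) guidance for fixed-margin chains. 0 reproduces the
#'   observed matrix.
#' @param seed Integer seed for the ensemble.
#' @param metrics Character subset of `c("fd", "pd", "richness")`.
#' @param space [build_trait_space()] object (required for `"fd"`).
#' @param tree Rooted phylogeny (required for `"pd"`).
#' @return Object of class `null_ensemble`: list with `n_reps`,
#'   `trades_per_rep`, `seed` and `metrics`, a named list of
#'   `n_reps x n_cells` matrices of null metric values.
#' @export
generate_nulls <- function(presence, n_reps = 999, trades_per_rep = NULL,
                           seed = 1L, metrics = c("fd", "pd"),
                           space = NULL, tree = NULL) {
  check_binary(presence)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(trades_per_rep))
    trades_per_rep <- max(5L * nrow(presence), 1000L)
  if (trades_per_rep < 0) stop("trades_per_rep must be >= 0")
  metrics <- match.arg(metrics, c("fd", "pd", "richness"),
                       several.ok = TRUE)
  if ("fd" %in% metrics && is.null(space))
    stop("metric 'fd' needs a trait space")
  if ("pd" %in% metrics && is.null(tree))
    stop("metric 'pd' needs a phylogeny")
  pe <- if ("pd" %in% metrics) pd_edge_incidence(tree)
  n_cells <- ncol(presence)
  vals <- lapply(metrics, function(m)
    matrix(NA_real_, nrow = n_reps, ncol = n_cells,
           dimnames = list(NULL, colnames(presence))))
  names(vals) <- metrics

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (r in seq_len(n_reps)) {
    set.seed(.child_seed(seed, 7919 * r))
    nm <- curveball_randomize(presence, trades_per_rep)
    for (met in metrics) {
      vals[[met]][r, ] <- switch(met,
        richness = as.numeric(species_richness(nm)),
        pd = faith_pd_cells(nm, tree, pe),
        fd = {
          fd <- rep(NA_real_, n_cells)
          for (j in seq_len(n_cells)) {
            sp <- rownames(nm)[nm[, j] == 1L]
            if (length(sp) >= 3)
              fd[j] <- as.numeric(functional_richness(space, sp))
          }
          fd
        })
    }
  }
  structure(list(n_reps = n_reps, trades_per_rep = trades_per_rep,
                 seed = seed, metrics = vals),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Curveball null ensemble: %d replicates, %d trades each, seed %d\n",
              x$n_reps, x$trades_per_rep, x$seed))
  cat("  metrics:", paste(names(x$metrics), collapse = ", "), "\n")
  invisible(x)
}

#' Standardized effect sizes against a null ensemble
#'
#' For each cell, `SES = (obs - mean_null) / sd_null` with the sample
#' (n-1) standard deviation over replicates. Cells are classified as
#' overdispersed when `SES > threshold`, underdispersed when
#' `SES < -threshold` (default 1.96), `neither` in between, and
#' `undefined` when the observed metric is undefined or the null SD is
#' zero — notably, any metric that is a function of column sums alone
#' (such as richness) has zero null SD everywhere, since the null
#' preserves the margins by construction.
#'
#' @param obs Named per-cell observed metric values.
#' @param ensemble A [generate_nulls()] ensemble.
#' @param metric Which ensemble metric to use (defaults to the first).
#' @param threshold Two-sided dispersion threshold (default 1.96).
#' @return data.frame of class `ses_result` with columns `cell_id`,
#'   `obs`, `mean_null`, `sd_null`, `ses`, `class`; the per-class counts
#'   and fractions are in `attr(, "summary")`.
#' @export
compute_ses <- function(obs, ensemble, metric = names(ensemble$metrics)[1],
                        threshold = 1.96) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  nulls <- ensemble$metrics[[metric]]
  if (is.null(nulls)) stop("ensemble has no metric '", metric, "'")
  if (length(obs) != ncol(nulls))
    stop("obs length does not match the ensemble's cells")
  mean_null <- colMeans(nulls)
  sd_null <- apply(nulls, 2, sd) # sample (n-1) estimator
  ses <- ifelse(is.na(obs) | is.na(sd_null) | sd_null == 0,
                NA_real_, (obs - mean_null) / sd_null)
  cls <- ifelse(is.na(ses), "undefined",
                ifelse(ses > threshold, "overdispersed",
                       ifelse(ses < -threshold, "underdispersed",
                              "neither")))
  out <- data.frame(
    cell_id = if (!is.null(colnames(nulls))) as.integer(colnames(nulls))
              else seq_along(obs) - 1L,
    obs = as.numeric(obs), mean_null = mean_null, sd_null = sd_null,
    ses = ses,
    class = factor(cls, levels = c("overdispersed", "underdispersed",
                                   "neither", "undefined")),
    row.names = NULL)
  counts <- table(out$class)
  attr(out, "summary") <- data.frame(
    class = names(counts), n_cells = as.integer(counts),
    fraction = as.numeric(counts) / nrow(out))
  attr(out, "threshold") <- threshold
  class(out) <- c("ses_result", "data.frame")
  out
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("SES over %d cells (threshold +/-%.2f):\n", nrow(x),
              attr(x, "threshold")))
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}
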