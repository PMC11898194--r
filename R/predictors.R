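# Predictor preparation: LGM climate anomalies averaged over GCMs,
# collinearity screening (pairwise |r| then VIF) and standardization.

#' Last Glacial Maximum climate anomaly averaged over GCMs
#'
#' Per cell, the mean over general circulation models of the absolute
#' difference between the current and LGM value of a climate variable —
#' a proxy for long-term climate (in)stability whose model uncertainty
#' is reduced by averaging.
#'
#' @param current Per-cell current climate values.
#' @param lgm_by_gcm Matrix with one column per GCM (same cells as
#'   `current`), or a list of per-cell vectors.
#' @return Per-cell mean absolute anomaly (>= 0).
#' @examples
#' lgm_anomaly(10, cbind(8, 7, 6)) # mean(|2|,|3|,|4|) = 3
#' @export
lgm_anomaly <- function(current, lgm_by_gcm) {
  if (is.list(lgm_by_gcm) && !is.data.frame(lgm_by_gcm))
    lgm_by_gcm <- do.call(cbind, lgm_by_gcm)
  lgm_by_gcm <- as.matrix(lgm_by_gcm)
  if (nrow(lgm_by_gcm) != length(current))
    stop("GCM layers must match the number of cells")
  if (anyNA(current) || anyNA(lgm_by_gcm))
    stop("missing values in a model layer")
  rowMeans(abs(current - lgm_by_gcm))
}

vif_values <- function(x) {
  # VIF_j = 1 / (1 - R^2_j) of predictor j on the others; equivalently
  # the diagonal of the inverse correlation matrix
  R <- cor(x)
  diag(solve(R))
}

#' Collinearity screen by pairwise correlation and VIF
#'
#' Two-stage iterative screen mirroring the usual macroecological
#' workflow: while any predictor pair has `|r| >= r_max`, the member of
#' the worst pair with the larger mean absolute correlation to all
#' remaining predictors is dropped; then, while any variance inflation
#' factor is `>= vif_max`, the largest-VIF predictor is dropped. Ties
#' break deterministically toward the later column.
#'
#' @param table data.frame of numeric predictor columns (a `cell_id`
#'   column, if present, is ignored).
#' @param r_max Pairwise absolute-correlation threshold (default 0.7:
#'   retain `|r| < 0.7`).
#' @param vif_max VIF threshold (default 5: retain VIF < 5).
#' @return List with `retained` (character vector of kept names) and
#'   `removed` (data.frame logging each drop with its stage and
#'   triggering statistic).
#' @export
collinearity_screen <- function(table, r_max = 0.7, vif_max = 5) {
  x <- as.data.frame(table)
  x$cell_id <- NULL
  x <- x[vapply(x, is.numeric, logical(1))]
  if (ncol(x) < 2) stop("need at least 2 predictors")
  if (nrow(x) < 3) stop("need at least 3 cells")
  const <- names(x)[vapply(x, function(v) sd(v) == 0, logical(1))]
  if (length(const))
    stop("constant predictor(s): ", paste(const, collapse = ", "))

  log <- data.frame(variable = character(0), stage = character(0),
                    statistic = numeric(0))
  repeat {
    R <- abs(cor(x)); diag(R) <- 0
    if (max(R) < r_max || ncol(x) <= 1) break
    worst <- which(R == max(R), arr.ind = TRUE)[1, ]
    cand <- sort(unname(worst))
    mean_abs <- colMeans(abs(cor(x)))[cand] # includes the 1 on the
    drop <- cand[which.max(mean_abs)]       # diagonal, same for both
    if (mean_abs[1] == mean_abs[2]) drop <- max(cand)
    log <- rbind(log, data.frame(variable = names(x)[drop],
                                 stage = "pairwise",
                                 statistic = max(R)))
    x[[drop]] <- NULL
  }
  while (ncol(x) >= 2) {
    v <- vif_values(x)
    if (max(v) < vif_max) break
    drop <- which(v == max(v))
    drop <- max(drop) # tie toward later column
    log <- rbind(log, data.frame(variable = names(x)[drop],
                                 stage = "vif", statistic = max(v)))
    x[[drop]] <- NULL
  }
  list(retained = names(x), removed = log)
}

#' Standardize predictor columns
#'
#' Centers every numeric predictor to mean 0 and scales to SD 1 (n-1
#' denominator) so regression estimates are comparable across
#' predictors; the transform parameters are kept as attributes.
#'
#' @param table data.frame of numeric predictors (`cell_id` passed
#'   through untouched).
#' @return data.frame of the same shape with attributes `center` and
#'   `scale`.
#' @export
standardize_predictors <- function(table) {
  x <- as.data.frame(table)
  keep_id <- x$cell_id
  x$cell_id <- NULL
  const <- names(x)[vapply(x, function(v) sd(v) == 0, logical(1))]
  if (length(const))
    stop("constant column(s): ", paste(const, collapse = ", "))
  ctr <- vapply(x, mean, numeric(1))
  scl <- vapply(x, sd, numeric(1))
  out <- as.data.frame(mapply(function(v, m, s) (v - m) / s, x, ctr, scl,
                              SIMPLIFY = FALSE))
  if (!is.null(keep_id)) out <- cbind(cell_id = keep_id, out)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
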