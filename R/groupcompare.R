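#' Compare a diversity facet among groups (Kruskal-Wallis + Dunn)
#'
#' Rank-based comparison of per-cell values among regions: the global
#' Kruskal-Wallis H test (with tie correction) followed by pairwise
#' Dunn z tests with multiplicity adjustment, and a compact-letter
#' display in which groups sharing no letter differ significantly.
#'
#' @param values Per-cell numeric values.
#' @param groups Per-cell group labels (>= 2 groups of >= 2 members).
#' @param adjust p-value adjustment for the Dunn tests: `"holm"`
#'   (default), `"bonferroni"` or `"none"`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `group_compare`: list with `kw` (statistic,
#'   df, p), `dunn` (data.frame of pairwise z and p), `letters` (named
#'   character vector, groups ordered by decreasing mean rank) and
#'   `adjust`.
#' @export
group_compare <- function(values, groups, adjust = c("holm", "bonferroni",
                                                     "none"),
                          alpha = 0.05) {
  adjust <- match.arg(adjust)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  kw <- kruskal.test(values, groups)

  # Dunn's test from pooled mean ranks with tie correction
  N <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z[i] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    p_raw[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  p_adj <- p.adjust(p_raw, method = adjust)
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                     p = p_raw, p_adj = p_adj)

  letters <- cld_letters(lv[order(-mean_rank)], dunn, alpha)

  structure(list(kw = list(statistic = unname(kw$statistic),
                           df = unname(kw$parameter),
                           p = unname(kw$p.value)),
                 dunn = dunn, letters = letters, adjust = adjust,
                 mean_rank = mean_rank),
            class = "group_compare")
}

# insert-and-absorb compact letter display: groups ordered by rank; any
# pair with adjusted p < alpha must share no letter
cld_letters <- function(ordered_groups, dunn, alpha) {
  sets <- list(ordered_groups) # letter groups of mutually similar groups
  for (i in seq_len(nrow(dunn))) {
    if (dunn$p_adj[i] >= alpha) next
    g1 <- dunn$group1[i]; g2 <- dunn$group2[i]
    for (s in seq_along(sets)) {
      if (g1 %in% sets[[s]] && g2 %in% sets[[s]]) {
        sets[[length(sets) + 1L]] <- setdiff(sets[[s]], g1)
        sets[[s]] <- setdiff(sets[[s]], g2)
      }
    }
    # absorb sets contained in another (empty sets vanish too)
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets))
      for (t in seq_along(sets))
        if (s != t && keep[t] && keep[s] &&
            all(sets[[s]] %in% sets[[t]]) &&
            (length(sets[[s]]) < length(sets[[t]]) || s > t))
          keep[s] <- FALSE
    sets <- sets[keep]
  }
  # order letters by the first (highest-ranked) member they contain
  first_pos <- vapply(sets, function(s)
    min(match(s, ordered_groups)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- vapply(ordered_groups, function(g)
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = ""),
    character(1))
  names(out) <- ordered_groups
  out
}

#' @export
print.group_compare <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
              x$kw$statistic, x$kw$df, x$kw$p))
  cat("Compact letters (groups by decreasing mean rank):\n")
  print(x$letters)
  cat(sprintf("Pairwise Dunn tests (%s-adjusted):\n", x$adjust))
  print(x$dunn, row.names = FALSE, digits = 4)
  invisible(x)
}
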