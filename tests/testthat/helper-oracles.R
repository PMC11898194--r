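# Independent oracles used across the test suite. Each deliberately
# re-derives its quantity by a different route than the package code.

# Faith's PD by per-tip root-path marking on the raw edge table
pd_path_oracle <- function(tree, species) {
  marked <- rep(FALSE, nrow(tree$edge))
  root <- length(tree$tip.label) + 1L
  for (sp in species) {
    node <- match(sp, tree$tip.label)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      marked[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[marked])
}

# Convex-hull volumes via scipy's qhull binding, batched in one process
scipy_hull_volumes <- function(point_sets) {
  dir <- tempfile("hulls")
  dir.create(dir)
  for (i in seq_along(point_sets))
    write.table(point_sets[[i]], file.path(dir, sprintf("p%04d.txt", i)),
                row.names = FALSE, col.names = FALSE)
  out <- file.path(dir, "volumes.txt")
  script <- file.path(dir, "hulls.py")
  writeLines(c(
    "import sys, glob, numpy as np",
    "from scipy.spatial import ConvexHull",
    sprintf("files = sorted(glob.glob('%s/p*.txt'))", dir),
    "vols = [ConvexHull(np.loadtxt(f, ndmin=2)).volume for f in files]",
    sprintf("open('%s', 'w').write('\\n'.join(repr(v) for v in vols) + '\\n')",
            out)
  ), script)
  res <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out))
    stop("scipy oracle failed: ", paste(res, collapse = "\n"))
  as.numeric(readLines(out))
}

# exhaustive enumeration of binary matrices with given margins
enumerate_fixed_margin <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  out <- list()
  rec <- function(rows_done, col_left) {
    if (rows_done == nr) {
      if (all(col_left == 0)) out[[length(out) + 1L]] <<- mat
      return(invisible(NULL))
    }
    r <- row_sums[rows_done + 1L]
    cols <- which(col_left > 0)
    if (length(cols) < r) return(invisible(NULL))
    for (pick in utils::combn(cols, r, simplify = FALSE)) {
      mat[rows_done + 1L, ] <<- 0L
      mat[rows_done + 1L, pick] <<- 1L
      cl <- col_left
      cl[pick] <- cl[pick] - 1L
      rec(rows_done + 1L, cl)
    }
  }
  mat <- matrix(0L, nr, nc)
  rec(0L, col_sums)
  out
}

matrix_key <- function(m) paste(as.integer(m), collapse = "")

# small random study for integration-style tests
small_study <- function(seed = 1, n_species = 25, n_rows = 8, n_cols = 8) {
  cfg <- landscape_config(n_rows = n_rows, n_cols = n_cols,
                          n_species = n_species, seed = seed)
  synthesize_study(cfg)
}

# random binary matrix with no empty rows/columns
random_presence <- function(n_sp, n_cells, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_sp * n_cells, 1, p), n_sp, n_cells,
                dimnames = list(sprintf("sp%04d", seq_len(n_sp)),
                                as.character(seq_len(n_cells) - 1L)))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
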