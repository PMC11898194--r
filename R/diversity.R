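# Per-cell diversity facets: species richness (column sums), Faith's
# phylogenetic diversity (root-inclusive minimal spanning subtree) and
# functional richness (convex-hull volume in standardized trait space).

#' Per-cell species richness
#'
#' Column sums of the (trait-filtered) presence/absence matrix.
#'
#' @param presence Binary species x cell matrix.
#' @return Named integer vector, one entry per cell.
#' @export
species_richness <- function(presence) {
  if (!all(presence %in% c(0L, 1L))) stop("presence matrix must be binary")
  out <- colSums(presence)
  storage.mode(out) <- "integer"
  out
}

# edge x tip incidence of a rooted tree: entry 1 when the tip descends
# from the edge. Summing branch lengths over rows with any selected tip
# gives root-inclusive Faith's PD, vectorizable across many cells.
pd_edge_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(post$edge)
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  ei <- vector("list", ne)
  for (e in seq_len(ne)) {
    child <- post$edge[e, 2]
    parent <- post$edge[e, 1]
    ei[[e]] <- below[[child]]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  # tip paths are O(log n) of the edges, so the incidence is sparse
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(ne), lengths(ei)), j = unlist(ei), x = 1,
    dims = c(ne, nt), dimnames = list(NULL, tree$tip.label))
  list(incidence = inc, lengths = post$edge.length)
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of the branch lengths of the minimal subtree connecting the
#' selected tips and the root (root-inclusive convention, matching the
#' classic index as implemented by picante's default).
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param species Character vector of tip labels (>= 2 distinct tips for
#'   a defined value).
#' @return PD in branch-length units, or `NA` when fewer than two
#'   distinct tips are supplied (the metric is undefined there).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B")) # 3: both tip edges plus their stem
#' @export
faith_pd <- function(tree, species) {
  species <- unique(species)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(species) < 2) return(NA_real_)
  pe <- pd_edge_incidence(tree)
  on_path <- as.matrix(pe$incidence[, species, drop = FALSE])
  sum(pe$lengths[rowSums(on_path) > 0])
}

# PD for every column of a presence matrix at once (used by the null
# ensembles: one matrix product per null replicate)
faith_pd_cells <- function(presence, tree, pe = pd_edge_incidence(tree)) {
  sp <- rownames(presence)
  unknown <- setdiff(sp, colnames(pe$incidence))
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  hits <- as(pe$incidence[, sp, drop = FALSE] %*% presence, "matrix") > 0
  pd <- as.numeric(pe$lengths %*% hits)
  pd[colSums(presence) < 2] <- NA_real_
  names(pd) <- colnames(presence)
  pd
}

#' Convex hull volume of a point cloud
#'
#' Exact hull volume in `d` dimensions (area for `d = 2`, length for
#' `d = 1`) via an incremental convex-hull construction. Degenerate
#' point sets (affine rank below `d`) return volume 0 with a flag
#' rather than an error, since reduced trait spaces can be degenerate.
#'
#' @param points Numeric matrix, one point per row.
#' @return Hull volume (numeric scalar) with attribute `degenerate`.
#' @examples
#' hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1))) # 0.5
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  res <- .convhull_volume_cpp(points)
  structure(res$volume, degenerate = res$degenerate)
}

#' Build the standardized trait space of the species pool
#'
#' Log10-transforms the size traits (hindfoot, tail and body length,
#' body mass), z-scores every trait across the full retained species
#' pool (so cell values are comparable across cells), and rotates onto
#' the pool's principal components. Hull volumes are invariant under the
#' orthogonal rotation, so using the leading axes for small assemblages
#' is consistent with using the full space for large ones.
#'
#' @param traits Trait table (`species_id` plus numeric trait columns);
#'   incomplete species are dropped.
#' @param log_size Log10-transform the size traits first (default TRUE).
#' @return Object of class `trait_space`: list with `scores` (species x
#'   axes matrix), `center`, `scale`, `rotation` and `trait_names`.
#' @export
build_trait_space <- function(traits, log_size = TRUE) {
  tn <- intersect(.TRAIT_NAMES, names(traits))
  if (!length(tn)) # arbitrary numeric trait tables are allowed
    tn <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                  "species_id")
  x <- as.matrix(traits[, tn, drop = FALSE])
  rownames(x) <- traits$species_id
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 trait-complete species")
  if (log_size) {
    lg <- intersect(.SIZE_TRAITS, tn)
    if (any(x[, lg] <= 0)) stop("size traits must be positive for log10")
    x[, lg] <- log10(x[, lg])
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) stop("constant trait column: ",
                          paste(tn[scl == 0], collapse = ", "))
  z <- scale(x, center = ctr, scale = scl)
  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  structure(list(scores = pca$x, center = ctr, scale = scl,
                 rotation = pca$rotation, trait_names = tn,
                 log_size = log_size),
            class = "trait_space")
}

#' Functional richness of a species set
#'
#' Convex-hull volume of the species' points in the pool-standardized
#' trait space, reduced to `d = min(n - 1, n_traits)` pool principal
#' axes so the hull is full-dimensional whenever the points are in
#' general position.
#'
#' @param space A [build_trait_space()] object.
#' @param species Character vector of species ids (>= 3 for a defined
#'   value).
#' @return Hull volume (>= 0) with attribute `degenerate`, or `NA` when
#'   fewer than 3 species are supplied.
#' @export
functional_richness <- function(space, species) {
  species <- unique(species)
  unknown <- setdiff(species, rownames(space$scores))
  if (length(unknown))
    stop("species not in trait space: ", paste(unknown, collapse = ", "))
  n <- length(species)
  if (n < 3) return(NA_real_)
  d <- min(n - 1L, ncol(space$scores))
  hull_volume(space$scores[species, seq_len(d), drop = FALSE])
}

#' Per-cell diversity profile
#'
#' Computes species richness, functional richness and Faith's PD for
#' every grid cell of a (trait-filtered) presence matrix. FD and PD are
#' undefined (NA) below their minimum assemblage sizes (3 and 2 species
#' respectively).
#'
#' @param presence Binary species x cell matrix (trait-complete species).
#' @param traits Trait table covering the species (used to build the
#'   trait space unless `space` is given).
#' @param tree Rooted phylogeny containing all species as tips.
#' @param space Optional pre-built [build_trait_space()] object.
#' @param group Optional per-cell labels (e.g. mountain regions) for
#'   grouped summaries via [summary()].
#' @return A data.frame of class `diversity_profile` with columns
#'   `cell_id`, `richness`, `fd`, `pd`, `fd_degenerate` and optionally
#'   `group`.
#' @export
diversity_profile <- function(presence, traits, tree, space = NULL,
                              group = NULL) {
  if (is.null(space)) space <- build_trait_space(traits)
  rich <- species_richness(presence)
  pd <- faith_pd_cells(presence, tree)
  n_cells <- ncol(presence)
  fd <- rep(NA_real_, n_cells)
  deg <- rep(NA, n_cells)
  for (j in seq_len(n_cells)) {
    sp <- rownames(presence)[presence[, j] == 1L]
    if (length(sp) >= 3) {
      v <- functional_richness(space, sp)
      fd[j] <- as.numeric(v)
      deg[j] <- attr(v, "degenerate")
    }
  }
  out <- data.frame(cell_id = as.integer(colnames(presence)),
                    richness = as.integer(rich), fd = fd, pd = pd,
                    fd_degenerate = deg)
  if (!is.null(group)) out$group <- group
  class(out) <- c("diversity_profile", "data.frame")
  out
}

#' @export
summary.diversity_profile <- function(object, ...) {
  facet_stats <- function(df) {
    vapply(c(richness = "richness", fd = "fd", pd = "pd"), function(v) {
      x <- df[[v]]
      c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
        n_defined = sum(!is.na(x)))
    }, numeric(3))
  }
  out <- list(overall = facet_stats(object))
  if (!is.null(object$group))
    out$by_group <- lapply(split(as.data.frame(object), object$group),
                           facet_stats)
  out
}
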