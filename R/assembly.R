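# Community assembly: range polygon -> grid-cell presences, refined by
# per-species elevation limits and habitat types, then filtered to
# trait-complete species. The presence/absence matrix produced here is
# the single source of truth for per-cell richness downstream.

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) { # drop explicit closure
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# TRUE when the closed ring is an axis-aligned rectangle (fast path)
is_axis_rect <- function(poly) {
  p <- poly
  n <- nrow(p)
  if (n == 5 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) != 4 || nrow(unique(p)) != 4) return(FALSE)
  length(unique(p[, 1])) == 2 && length(unique(p[, 2])) == 2
}

#' Rasterize a species range polygon onto the grid
#'
#' Returns the ids of grid cells whose square has a positive-area
#' intersection with the range polygon. A polygon that merely touches a
#' cell boundary (zero-area intersection) does not confer presence, so
#' presence is insensitive to floating-point grazing contacts.
#' Axis-aligned rectangles take an exact interval-overlap fast path;
#' general polygons are clipped to each candidate cell with
#' [polyclip::polyclip()].
#'
#' @param range A species range: list with at least `polygon`, a matrix
#'   of x/y vertices (projected km, ring closed implicitly or
#'   explicitly, at least 3 distinct vertices).
#' @param grid A `div_grid`.
#' @return Sorted integer vector of 0-based cell ids.
#' @export
rasterize_range <- function(range, grid) {
  poly <- range$polygon
  if (is.null(dim(poly)) || nrow(poly) < 3)
    stop("polygon must have at least 3 vertices")
  if (polygon_area(poly) <= 0)
    stop("degenerate polygon: zero area")
  s <- grid$cell_size_km
  ext <- unname(grid_extent(grid)) # xmin, xmax, ymin, ymax
  names(ext) <- c("xmin", "xmax", "ymin", "ymax")
  bb <- unname(c(range(poly[, 1]), range(poly[, 2])))
  # candidate columns/rows overlapping the bounding box (positive overlap)
  col0 <- max(0L, floor((bb[1] - ext["xmin"]) / s))
  col1 <- min(grid$n_cols - 1L, ceiling((bb[2] - ext["xmin"]) / s) - 1L)
  # y grows northward while rows count from the north
  row0 <- max(0L, floor((ext["ymax"] - bb[4]) / s))
  row1 <- min(grid$n_rows - 1L, ceiling((ext["ymax"] - bb[3]) / s) - 1L)
  if (col1 < col0 || row1 < row0) return(integer(0))

  if (is_axis_rect(poly)) {
    cols <- col0:col1
    rows <- row0:row1
    cx0 <- ext["xmin"] + cols * s
    ry1 <- ext["ymax"] - rows * s
    keep_c <- pmin(bb[2], cx0 + s) - pmax(bb[1], cx0) > 0
    keep_r <- pmin(bb[4], ry1) - pmax(bb[3], ry1 - s) > 0
    ids <- as.vector(outer(rows[keep_r] * grid$n_cols, cols[keep_c], `+`))
    return(sort(as.integer(ids)))
  }

  ring <- list(x = poly[, 1], y = poly[, 2])
  tol <- 1e-9 * s * s
  hits <- integer(0)
  for (r in row0:row1) {
    y1 <- ext["ymax"] - r * s
    for (cc in col0:col1) {
      x0 <- ext["xmin"] + cc * s
      cellring <- list(x = c(x0, x0 + s, x0 + s, x0),
                       y = c(y1 - s, y1 - s, y1, y1))
      inter <- polyclip::polyclip(ring, cellring, op = "intersection")
      a <- sum(vapply(inter, function(p) polygon_area(cbind(p$x, p$y)),
                      numeric(1)))
      if (a > tol) hits <- c(hits, r * grid$n_cols + cc)
    }
  }
  sort(hits)
}

#' Assemble the presence/absence matrix from range polygons
#'
#' @param ranges List of species ranges (see [generate_ranges()]).
#' @param grid A `div_grid`.
#' @return Binary integer matrix, species (rows, named by `species_id`)
#'   by cells (columns, named by 0-based cell id).
#' @export
build_presence <- function(ranges, grid) {
  ids <- vapply(ranges, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) stop("duplicated species ids in ranges")
  m <- matrix(0L, nrow = length(ranges), ncol = grid$n_cells,
              dimnames = list(ids, as.character(seq_len(grid$n_cells) - 1L)))
  for (i in seq_along(ranges))
    m[i, rasterize_range(ranges[[i]], grid) + 1L] <- 1L
  m
}

#' Refine occurrences by elevation limits and habitat types
#'
#' Sets a presence to absence wherever the cell's elevation lies outside
#' the species' elevation interval (inclusive on both ends) or the
#' cell's habitat code is not among the species' tolerated codes. Never
#' converts an absence to a presence; idempotent.
#'
#' @param presence Binary species x cell matrix (rows named by species).
#' @param ranges List of species ranges carrying `elev_lo`, `elev_hi`
#'   and `habitat_codes` for every species in `presence`.
#' @param elevation,habitat Per-cell elevation (m) and habitat code on
#'   the same grid as `presence`.
#' @return List with `presence` (refined matrix) and `removed` (named
#'   per-species count of cells set to absence).
#' @export
refine_occurrences <- function(presence, ranges, elevation, habitat) {
  stopifnot(ncol(presence) == length(elevation),
            ncol(presence) == length(habitat))
  ids <- vapply(ranges, `[[`, character(1), "species_id")
  missing <- setdiff(rownames(presence), ids)
  if (length(missing))
    stop("no constraints for species: ", paste(missing, collapse = ", "))
  out <- presence
  removed <- integer(nrow(presence))
  names(removed) <- rownames(presence)
  for (sp in rownames(presence)) {
    rng <- ranges[[match(sp, ids)]]
    ok <- elevation >= rng$elev_lo & elevation <= rng$elev_hi &
      habitat %in% rng$habitat_codes
    before <- out[sp, ]
    out[sp, ] <- before * as.integer(ok)
    removed[sp] <- sum(before) - sum(out[sp, ])
  }
  list(presence = out, removed = removed)
}

#' Drop species with incomplete trait data
#'
#' Removes rows of species missing any of the nine traits, so that the
#' same retained species pool underlies richness, functional and
#' phylogenetic diversity alike.
#'
#' @param presence Binary species x cell matrix.
#' @param traits Trait table with `species_id` and a logical `complete`
#'   column (or the nine trait columns, from which completeness is
#'   derived).
#' @return List with `presence` (filtered matrix) and `excluded`
#'   (character vector of dropped species ids).
#' @export
filter_trait_complete <- function(presence, traits) {
  missing <- setdiff(rownames(presence), traits$species_id)
  if (length(missing))
    stop("trait table lacks species: ", paste(missing, collapse = ", "))
  if (is.null(traits$complete)) {
    tc <- intersect(.TRAIT_NAMES, names(traits))
    traits$complete <- stats::complete.cases(traits[, tc])
  }
  complete_ids <- traits$species_id[traits$complete]
  keep <- rownames(presence) %in% complete_ids
  if (!any(keep)) stop("no species remain after the trait-completeness filter")
  excluded <- rownames(presence)[!keep]
  if (length(excluded))
    message(length(excluded), " trait-incomplete species excluded")
  list(presence = presence[keep, , drop = FALSE], excluded = excluded)
}
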