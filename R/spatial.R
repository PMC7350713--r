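# Gridded richness summaries and centroid distances ----------------------

#' Per-cell species richness split by threat class
#'
#' Threatened means VU/EN/CR (codes 3-5); non-threatened means LC/NT (codes
#' 1-2). Extinct (EX) species are excluded from both maps. Every species in
#' the grid must have a final status.
#'
#' @param grid a `range_grid` (see [simulate_ranges()]).
#' @param statuses named vector of final status codes (1-6) or category
#'   labels, covering all species in the grid.
#' @param which `"threatened"`, `"nonthreatened"`, or `"all"`.
#' @return matrix of per-cell counts with the grid's dimensions.
#' @export
richness_map <- function(grid, statuses,
                         which = c("threatened", "nonthreatened", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(grid, "range_grid"))
  sp <- rownames(grid$occupancy)
  st <- statuses[sp]
  if (anyNA(st))
    stop("species in grid without a final status: ",
         paste(head(sp[is.na(st)], 5), collapse = ", "), call. = FALSE)
  code <- if (is.numeric(st)) st else .iucn_codes[as.character(st)]
  sel <- switch(which,
                threatened = code %in% 3:5,
                nonthreatened = code %in% 1:2,
                all = code %in% 1:5)
  counts <- colSums(grid$occupancy[sel, , drop = FALSE])
  matrix(counts, grid$dims[1], grid$dims[2])
}

#' EDGE-weighted richness map
#'
#' Cell value is the sum of EDGE scores over occupying species. Species
#' without an EDGE score (e.g., extinct ones) are skipped; the skipped count
#' is attached as an attribute.
#'
#' @param grid a `range_grid`.
#' @param edge_table data.frame with `species` and `edge` columns.
#' @return matrix of per-cell EDGE sums; attribute `n_skipped`.
#' @export
edge_weighted_richness <- function(grid, edge_table) {
  stopifnot(inherits(grid, "range_grid"))
  sp <- rownames(grid$occupancy)
  w <- setNames(edge_table$edge, edge_table$species)[sp]
  skipped <- sum(is.na(w))
  w[is.na(w)] <- 0
  vals <- colSums(grid$occupancy * w)
  out <- matrix(vals, grid$dims[1], grid$dims[2])
  attr(out, "n_skipped") <- skipped
  out
}

#' Pairwise Euclidean distances between range centroids
#'
#' Distances on the grid's planar equal-area coordinates; symmetric with a
#' zero diagonal.
#'
#' @param centroids n x 2 matrix (rows named by species).
#' @return n x n distance matrix.
#' @export
centroid_distance_matrix <- function(centroids) {
  if (anyNA(centroids)) stop("missing centroid coordinates", call. = FALSE)
  D <- as.matrix(dist(centroids))
  dimnames(D) <- list(rownames(centroids), rownames(centroids))
  D
}
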