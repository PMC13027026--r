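# Background filtering: cells partially hidden behind a neighbor have an
# artificially small visible footprint. Adjacency is defined by the minimum
# perimeter-to-perimeter distance between fitted ellipses (< 5 px = 0.068 um),
# computed from 100 sampled perimeter points per cell; adjacent cells smaller
# than 0.7x the mean area of their neighbors are removed.

#' Neighbor-filter constants
#'
#' @param distance_threshold_px Adjacency threshold: two cells are neighbors
#'   iff their minimum perimeter distance is strictly below this (default 5 px
#'   = 0.068 um at the default calibration).
#' @param perimeter_samples Number of points sampled along each ellipse
#'   perimeter (default 100).
#' @param size_factor A cell is removed iff its area is strictly below
#'   `size_factor` x the arithmetic mean of its neighbors' areas (default 0.7).
#' @return Object of class `"neighbor_rule"`.
#' @export
neighbor_rule <- function(distance_threshold_px = 5, perimeter_samples = 100L,
                          size_factor = 0.7) {
  stopifnot(distance_threshold_px > 0, perimeter_samples >= 3,
            size_factor > 0)
  structure(list(distance_threshold_px = distance_threshold_px,
                 perimeter_samples = as.integer(perimeter_samples),
                 size_factor = size_factor),
            class = "neighbor_rule")
}

#' Sample equally spaced points along an ellipse perimeter
#'
#' Points are taken at equal parameter steps t = 2*pi*k/n (k = 0..n-1) in the
#' ellipse's own frame, then rotated and translated to image coordinates.
#' Equal parameter spacing, not equal arc length: for the moderate
#' eccentricities of ovoid cocci the largest gap between consecutive points
#' stays below twice the mean arc step.
#'
#' @param fit An `"ellipse_fit"` with `fit_ok = TRUE`.
#' @param n Number of points (>= 3).
#' @return An n x 2 matrix of (x, y) image coordinates.
#' @export
sample_perimeter <- function(fit, n = 100L) {
  stopifnot(inherits(fit, "ellipse_fit"), n >= 3)
  if (!isTRUE(fit$fit_ok)) {
    stop("cannot sample the perimeter of a failed ellipse fit; exclude the cell")
  }
  t <- 2 * pi * (seq_len(n) - 1L) / n
  a <- fit$major_axis_px / 2
  b <- fit$minor_axis_px / 2
  th <- fit$orientation_deg * pi / 180
  u <- a * cos(t); v <- b * sin(t)
  cbind(x = fit$center[["x"]] + u * cos(th) - v * sin(th),
        y = fit$center[["y"]] + u * sin(th) + v * cos(th))
}

#' Minimum perimeter-to-perimeter distance between two ellipses
#'
#' Minimum Euclidean distance over all n x n pairs of sampled perimeter
#' points; symmetric in its arguments. Overlapping or touching ellipses give
#' values near zero (sampled, so not exactly zero in general).
#'
#' @param a,b `"ellipse_fit"` objects.
#' @param n Perimeter samples per ellipse.
#' @return Distance in pixels.
#' @export
min_perimeter_distance <- function(a, b, n = 100L) {
  pa <- sample_perimeter(a, n)
  pb <- sample_perimeter(b, n)
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  sqrt(min(dx * dx + dy * dy))
}

# uniform-grid spatial index on centroids: returns candidate pairs (i < j)
# whose centroid distance is at most r_i + r_j + extra. The grid bucket edge
# is the largest possible search radius, so scanning the 3x3 bucket
# neighborhood yields a guaranteed superset of qualifying pairs.
grid_candidate_pairs <- function(cx, cy, radius, extra) {
  n <- length(cx)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  cell <- max(2 * max(radius) + extra, 1e-9)
  gx <- floor(cx / cell); gy <- floor(cy / cell)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  coords <- unique(data.frame(gx = gx, gy = gy, key = key))
  out <- vector("list", nrow(coords))
  for (i in seq_len(nrow(coords))) {
    here <- buckets[[coords$key[i]]]
    neigh_keys <- paste(rep(coords$gx[i] + (-1:1), each = 3),
                        rep(coords$gy[i] + (-1:1), times = 3))
    there <- unlist(buckets[intersect(neigh_keys, names(buckets))],
                    use.names = FALSE)
    pr <- expand.grid(a = here, b = there)
    pr <- pr[pr$a < pr$b, , drop = FALSE]
    out[[i]] <- as.matrix(pr)
  }
  pairs <- unique(do.call(rbind, out))
  if (!nrow(pairs)) return(pairs)
  d2 <- (cx[pairs[, 1]] - cx[pairs[, 2]])^2 + (cy[pairs[, 1]] - cy[pairs[, 2]])^2
  lim <- (radius[pairs[, 1]] + radius[pairs[, 2]] + extra)^2
  pairs[d2 <= lim, , drop = FALSE]
}

#' Build the adjacency graph of segmented cells
#'
#' Candidate pairs are pre-screened with a uniform-grid spatial index on
#' centroids (search radius = sum of semi-major axes + threshold, a guaranteed
#' superset of true adjacencies), then tested exactly by sampled minimum
#' perimeter distance. An edge connects two cells iff that distance is
#' strictly below the threshold.
#'
#' @param fits List of `"ellipse_fit"` objects (all `fit_ok`).
#' @param rule A [neighbor_rule()].
#' @return Object of class `"adjacency_graph"`: list with `n`, `edges` (data
#'   frame i, j, distance_px with i < j) and `neighbors` (list of integer
#'   vectors, per cell).
#' @export
build_adjacency <- function(fits, rule = neighbor_rule()) {
  stopifnot(inherits(rule, "neighbor_rule"))
  n <- length(fits)
  edges <- data.frame(i = integer(0), j = integer(0), distance_px = numeric(0))
  if (n >= 2L) {
    stopifnot(all(vapply(fits, function(f) isTRUE(f$fit_ok), TRUE)))
    cx <- vapply(fits, function(f) f$center[["x"]], 0)
    cy <- vapply(fits, function(f) f$center[["y"]], 0)
    rad <- vapply(fits, function(f) f$major_axis_px / 2, 0)
    cand <- grid_candidate_pairs(cx, cy, rad, rule$distance_threshold_px)
    if (nrow(cand)) {
      d <- vapply(seq_len(nrow(cand)), function(k) {
        min_perimeter_distance(fits[[cand[k, 1]]], fits[[cand[k, 2]]],
                               rule$perimeter_samples)
      }, 0)
      keep <- d < rule$distance_threshold_px
      edges <- data.frame(i = cand[keep, 1], j = cand[keep, 2],
                          distance_px = d[keep])
    }
  }
  neighbors <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(edges))) {
    neighbors[[edges$i[k]]] <- c(neighbors[[edges$i[k]]], edges$j[k])
    neighbors[[edges$j[k]]] <- c(neighbors[[edges$j[k]]], edges$i[k])
  }
  structure(list(n = n, edges = edges, neighbors = neighbors),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency graph: %d cells, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Remove locally small (occluded/background) cells
#'
#' Single, non-iterative pass over the original graph: a cell is removed iff
#' it has at least one neighbor and its area is strictly below
#' `size_factor` x the arithmetic mean of its neighbors' areas. Isolated
#' cells are always kept (the rule targets cells obscured by other bacteria,
#' and "mean neighbor area" is undefined without neighbors). Decisions use
#' the original areas and graph, so the kept set is independent of cell order
#' and of other removals.
#'
#' @param areas_px2 Numeric vector of cell areas (mask pixel counts), aligned
#'   with the graph's nodes.
#' @param graph An `"adjacency_graph"` from [build_adjacency()].
#' @param rule A [neighbor_rule()].
#' @return Data frame with one row per cell: `neighbor_count`,
#'   `mean_neighbor_area_px2` (NA when isolated), and `removed` (logical).
#' @export
local_size_filter <- function(areas_px2, graph, rule = neighbor_rule()) {
  stopifnot(inherits(graph, "adjacency_graph"),
            length(areas_px2) == graph$n)
  nn <- vapply(graph$neighbors, length, 0L)
  mean_area <- vapply(graph$neighbors, function(ix) {
    if (length(ix)) mean(areas_px2[ix]) else NA_real_
  }, 0)
  removed <- nn > 0L & areas_px2 < rule$size_factor * mean_area
  data.frame(neighbor_count = nn,
             mean_neighbor_area_px2 = mean_area,
             removed = removed)
}
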