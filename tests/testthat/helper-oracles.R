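# Independent oracles and fixture builders, kept deliberately naive.

# O(n^2) pairwise definition of Cliff's delta
brute_cliffs <- function(x, y) {
  s <- outer(x, y, function(a, b) sign(a - b))
  sum(s) / length(s)
}

# ellipse_fit object with exact geometry (bypasses fitting)
make_fit <- function(cx, cy, a, b, theta_deg = 0) {
  structure(list(center = c(x = cx, y = cy),
                 major_axis_px = 2 * max(a, b), minor_axis_px = 2 * min(a, b),
                 orientation_deg = theta_deg %% 180, fit_ok = TRUE),
            class = "ellipse_fit")
}

# all-pairs adjacency, no spatial index
brute_adjacency <- function(fits, rule = neighbor_rule()) {
  n <- length(fits)
  edges <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- min_perimeter_distance(fits[[i]], fits[[j]], rule$perimeter_samples)
      if (d < rule$distance_threshold_px) {
        edges[[length(edges) + 1]] <- data.frame(i = i, j = j, distance_px = d)
      }
    }
  }
  if (length(edges)) do.call(rbind, edges)
  else data.frame(i = integer(0), j = integer(0), distance_px = numeric(0))
}

# minimum perimeter distance from dense sampling (chunked to bound memory)
dense_min_distance <- function(a, b, n = 5000L) {
  pa <- sample_perimeter(a, n)
  pb <- sample_perimeter(b, n)
  best <- Inf
  for (k in split(seq_len(n), ceiling(seq_len(n) / 500))) {
    dx <- outer(pa[k, 1], pb[, 1], "-")
    dy <- outer(pa[k, 2], pb[, 2], "-")
    best <- min(best, min(dx * dx + dy * dy))
  }
  sqrt(best)
}

# paint one or more ellipses into a label matrix (1-based pixel centers)
ellipse_label_mask <- function(geoms, H, W) {
  m <- matrix(0L, H, W)
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    px <- coccimorph:::ellipse_pixels(g$cx, g$cy, g$a, g$b,
                                      g$theta %||% 0, H, W)
    m[px$idx] <- i
  }
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# single-region helper: region list for a filled ellipse
ellipse_region <- function(cx, cy, a, b, theta = 0, H = 200, W = 200) {
  labels_to_regions(ellipse_label_mask(list(list(cx = cx, cy = cy, a = a,
                                                 b = b, theta = theta)),
                                       H, W))[[1]]
}
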