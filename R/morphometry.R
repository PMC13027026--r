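# Ellipse morphometry: direct least-squares conic fit (Halir & Flusser's
# numerically stable variant of Fitzgibbon's method), constrained so the
# solution is always an ellipse, plus the artifact-size exclusion rule.

#' Fit an ellipse to a contour by direct least squares
#'
#' Solves the ellipse-specific constrained least-squares conic problem
#' (4ac - b^2 = 1) on the contour points, then converts the conic to center,
#' axis lengths and orientation. Points are centered and scaled before
#' solving for conditioning; the reported geometry is in image coordinates.
#'
#' @param x A region from [labels_to_regions()] (its `$contour` is used) or a
#'   two-column matrix of (x, y) points.
#' @param pixel_correction Add 0.5 px to each semi-axis to undo quantization
#'   bias: contour points are centers of boundary pixels, which lie about half
#'   a pixel inside the true object boundary. Defaults to `TRUE` when `x` is a
#'   region (pixel-quantized contour) and `FALSE` for a raw point matrix.
#' @return Object of class `"ellipse_fit"`: list with `center` (x, y),
#'   `major_axis_px`, `minor_axis_px` (full axis lengths, major >= minor),
#'   `orientation_deg` (major axis vs image x-axis, in \[0, 180)), and
#'   `fit_ok`. Degenerate inputs (collinear points, non-elliptical solutions)
#'   return `fit_ok = FALSE`.
#' @references Halir, R. and Flusser, J. (1998) Numerically stable direct
#'   least squares fitting of ellipses.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 50)
#' fit_ellipse(cbind(10 + 30 * cos(t), 20 + 15 * sin(t)))
#' @export
fit_ellipse <- function(x, pixel_correction = NULL) {
  from_region <- is.list(x) && !is.null(x$contour)
  if (is.null(pixel_correction)) pixel_correction <- from_region
  pts <- if (from_region) x$contour else x
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stop("contour must be a two-column (x, y) matrix")
  if (nrow(pts) < 5L) {
    stop("ellipse fitting requires at least 5 contour points; ",
         "run size_filter() first")
  }
  bad <- structure(list(center = c(x = NA_real_, y = NA_real_),
                        major_axis_px = NA_real_, minor_axis_px = NA_real_,
                        orientation_deg = NA_real_, fit_ok = FALSE),
                   class = "ellipse_fit")

  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  s <- max(stats::sd(pts[, 1]), stats::sd(pts[, 2]))
  if (!is.finite(s) || s == 0) return(bad)
  X <- (pts[, 1] - mx) / s
  Y <- (pts[, 2] - my) / s

  D1 <- cbind(X^2, X * Y, Y^2)
  D2 <- cbind(X, Y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(bad)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(bad)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(bad)
  a1 <- V[, ok[1]]
  coef <- c(a1, T1 %*% a1)  # (A, B, C, D, E, F) in scaled frame

  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; FF <- coef[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0) return(bad)
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + FF
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Mq, symmetric = TRUE)
  semis2 <- -fc / eq$values
  if (any(!is.finite(semis2)) || any(semis2 <= 0)) return(bad)
  semis <- sqrt(semis2)
  i_major <- which.max(semis)
  vmaj <- eq$vectors[, i_major]
  ang <- (atan2(vmaj[2], vmaj[1]) * 180 / pi) %% 180

  corr <- if (pixel_correction) 0.5 else 0
  structure(list(
    center = c(x = x0 * s + mx, y = y0 * s + my),
    major_axis_px = 2 * (semis[i_major] * s + corr),
    minor_axis_px = 2 * (min(semis) * s + corr),
    orientation_deg = ang,
    fit_ok = TRUE
  ), class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  if (x$fit_ok) {
    cat(sprintf(
      "ellipse: center (%.1f, %.1f), axes %.1f x %.1f px, orientation %.1f deg\n",
      x$center[1], x$center[2], x$major_axis_px, x$minor_axis_px,
      x$orientation_deg))
  } else {
    cat("ellipse fit failed (degenerate input)\n")
  }
  invisible(x)
}

#' Artifact-size exclusion rule
#'
#' Regions with fewer than `min_contour_points` contour points or an area
#' strictly below `min_area_px2` are segmentation artifacts and are excluded
#' before any measurement. Defaults are the standard constants (5 points,
#' 1000 px^2 = 0.183 um^2 at the area-implied calibration); both inequalities
#' are strict.
#'
#' @param min_contour_points Minimum contour points to keep a region.
#' @param min_area_px2 Minimum area in px^2 to keep a region.
#' @return Object of class `"size_filter_rule"`.
#' @export
size_filter_rule <- function(min_contour_points = 5L, min_area_px2 = 1000) {
  stopifnot(min_contour_points > 0, min_area_px2 > 0)
  structure(list(min_contour_points = as.integer(min_contour_points),
                 min_area_px2 = min_area_px2),
            class = "size_filter_rule")
}

#' Exclude artifact-sized regions
#'
#' @param regions A `"sem_regions"` list.
#' @param rule A [size_filter_rule()].
#' @return List with `kept` (a `"sem_regions"` list) and `excluded` (a data
#'   frame of label, area_px2, n_contour_points, reason).
#' @examples
#' # a region of 999 px^2 is excluded, 1000 px^2 is kept
#' @export
size_filter <- function(regions, rule = size_filter_rule()) {
  stopifnot(inherits(rule, "size_filter_rule"))
  if (!length(regions)) {
    return(list(kept = structure(list(), class = "sem_regions"),
                excluded = data.frame(label = integer(0), area_px2 = numeric(0),
                                      n_contour_points = integer(0),
                                      reason = character(0))))
  }
  npts <- vapply(regions, function(r) nrow(r$contour), 0L)
  areas <- vapply(regions, `[[`, 0, "area_px2")
  small_contour <- npts < rule$min_contour_points
  small_area <- areas < rule$min_area_px2
  drop <- small_contour | small_area
  reason <- ifelse(small_contour & small_area, "contour+area",
                   ifelse(small_contour, "contour", "area"))
  list(
    kept = structure(regions[!drop], class = "sem_regions"),
    excluded = data.frame(
      label = vapply(regions, `[[`, 0L, "label")[drop],
      area_px2 = areas[drop],
      n_contour_points = npts[drop],
      reason = reason[drop]
    )
  )
}
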