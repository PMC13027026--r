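# Surface-texture metric: erode each cell mask to drop edge artifacts, detrend
# the [0,1]-normalized intensities with a full second-order polynomial surface
# z = a0 + a1 x + a2 y + a3 x^2 + a4 y^2 + a5 xy, and report the residual rms.
# The polynomial absorbs global illumination gradients (specimen tilt) and the
# gentle dome of an intact cell, so the residual isolates high-frequency
# roughness attributable to surface damage.

#' Erode a binary mask
#'
#' Morphological erosion with a square all-ones structuring element, applied
#' repeatedly. The mask is zero-padded before eroding, so pixels at the mask's
#' bounding box behave as if surrounded by background.
#'
#' @param mask Logical or 0/1 matrix.
#' @param kernel_size Side of the square structuring element (default 7).
#' @param iterations Number of erosion passes (default 2).
#' @return Logical matrix of the same dimensions; possibly all `FALSE`.
#' @examples
#' sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE   # 20x20 square
#' sum(erode_mask(sq))                                   # 64 = 8x8
#' @export
erode_mask <- function(mask, kernel_size = 7L, iterations = 2L) {
  stopifnot(kernel_size >= 1, iterations >= 0)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (iterations == 0L) return(m > 0)
  pad <- (kernel_size %/% 2L) * iterations
  big <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  kern <- EBImage::makeBrush(kernel_size, shape = "box")
  for (i in seq_len(iterations)) big <- EBImage::erode(big, kern)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] > 0
}

#' Fit a second-order polynomial surface to intensities
#'
#' Ordinary least squares on the design columns (1, x, y, x^2, y^2, xy).
#' Coordinates are centered on their mean and scaled to unit half-width before
#' solving (conditioning); coefficients are reported in that frame, residuals
#' are frame-independent.
#'
#' @param coords Two-column matrix of (x, y) pixel coordinates.
#' @param z Intensities on the \[0, 1\] scale, one per coordinate row.
#' @return Object of class `"poly_surface_fit"`: coefficients `a0`..`a5`,
#'   `n_pixels`, `rms`, `mean_abs`, `max_abs` residual summaries, `residuals`,
#'   `fitted`, and `valid` (FALSE for rank-deficient designs, e.g. collinear
#'   pixels, or fewer than 6 pixels).
#' @examples
#' xy <- expand.grid(x = 1:20, y = 1:20)
#' f <- fit_poly_surface(as.matrix(xy), 0.2 + 0.01 * xy$x - 0.002 * xy$x^2)
#' f$rms   # 0: the field is in the model span
#' @export
fit_poly_surface <- function(coords, z) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, length(z) == nrow(coords))
  invalid <- structure(list(coefficients = rep(NA_real_, 6), n_pixels = nrow(coords),
                            rms = NA_real_, mean_abs = NA_real_, max_abs = NA_real_,
                            residuals = NULL, fitted = NULL, valid = FALSE),
                       class = "poly_surface_fit")
  if (nrow(coords) < 6L) return(invalid)
  x <- coords[, 1] - mean(coords[, 1])
  y <- coords[, 2] - mean(coords[, 2])
  hw <- max(abs(c(x, y)), 1e-12)
  x <- x / hw; y <- y / hw
  X <- cbind(1, x, y, x^2, y^2, x * y)
  fit <- stats::lm.fit(X, z)
  if (fit$rank < 6L) return(invalid)
  res <- fit$residuals
  structure(list(
    coefficients = stats::setNames(fit$coefficients,
                            c("a0", "a1", "a2", "a3", "a4", "a5")),
    n_pixels = nrow(coords),
    rms = sqrt(mean(res^2)),
    mean_abs = mean(abs(res)),
    max_abs = max(abs(res)),
    residuals = res,
    fitted = fit$fitted.values,
    valid = TRUE
  ), class = "poly_surface_fit")
}

#' @export
print.poly_surface_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("second-order surface fit on %d px: rms residual %.5f\n",
                x$n_pixels, x$rms))
  } else {
    cat("surface fit invalid (rank-deficient or too few pixels)\n")
  }
  invisible(x)
}

#' Per-cell surface-texture value
#'
#' Erodes the region mask (square kernel, default 7x7, 2 iterations) to
#' exclude edge artifacts, normalizes raw \[0, 255\] intensities by 255
#' (globally, preserving cross-cell comparability), fits the second-order
#' polynomial surface over the eroded pixels, and returns the rms residual as
#' the texture value. Higher values indicate rougher, damaged surfaces. Cells
#' whose eroded mask falls below `min_pixels` are flagged invalid: a
#' six-parameter fit on fewer pixels is noise-dominated.
#'
#' @param region A region from [labels_to_regions()].
#' @param image Numeric image matrix on the \[0, 255\] scale (full image; the
#'   region's bounding box addresses into it).
#' @param kernel_size,iterations Erosion parameters.
#' @param min_pixels Minimum eroded pixel count for a valid value (default 50).
#' @return Object of class `"texture_result"`: `texture_value` (rms),
#'   `texture_mean_abs`, `eroded_pixels`, `valid`, and the underlying
#'   `"poly_surface_fit"`.
#' @export
texture_value <- function(region, image, kernel_size = 7L, iterations = 2L,
                          min_pixels = 50L) {
  er <- erode_mask(region$mask, kernel_size, iterations)
  n_er <- sum(er)
  out <- list(texture_value = NA_real_, texture_mean_abs = NA_real_,
              eroded_pixels = n_er, valid = FALSE, fit = NULL)
  if (n_er < min_pixels) return(structure(out, class = "texture_result"))
  px <- which(er, arr.ind = TRUE)
  rows <- px[, 1] + region$bbox[1] - 1L
  cols <- px[, 2] + region$bbox[3] - 1L
  z <- image[cbind(rows, cols)] / 255
  fit <- fit_poly_surface(cbind(x = cols, y = rows), z)
  if (!fit$valid) return(structure(out, class = "texture_result"))
  out$texture_value <- fit$rms
  out$texture_mean_abs <- fit$mean_abs
  out$valid <- TRUE
  out$fit <- fit
  structure(out, class = "texture_result")
}

#' @export
print.texture_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("texture value %.5f over %d eroded px\n",
                x$texture_value, x$eroded_pixels))
  } else {
    cat(sprintf("texture invalid (eroded mask %d px)\n", x$eroded_pixels))
  }
  invisible(x)
}
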