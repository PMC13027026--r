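#' Read a grayscale micrograph
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF and returns a numeric matrix on
#' the scale encoded in the file (0..255 for 8-bit, 0..65535 for 16-bit).
#' Multi-channel images are reduced to grayscale by averaging channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix, rows = image rows (y), columns = image columns (x).
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    depth <- attr(arr, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(arr, "bits.per.sample")
  } else {
    stop("unsupported image format: .", ext)
  }
  if (is.null(depth)) depth <- 8L
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1L, 2L), mean)
  arr * (2^depth - 1)
}

#' Read an instance label mask
#'
#' Reads a label mask stored as a grayscale PNG/TIFF in which the pixel value
#' is the integer cell label (0 = background). Values are rescaled back from
#' the file encoding and rounded; a value further than 1e-3 from an integer is
#' an error, since label identity must be exact.
#'
#' @inheritParams read_gray
#' @return Integer matrix of labels, 0 = background.
#' @export
read_label_mask <- function(path) {
  m <- read_gray(path)
  if (max(abs(m - round(m))) > 1e-3) {
    stop("mask is not integer-valued: ", path)
  }
  mode(m) <- "integer"
  m
}

#' Write an image or label mask
#'
#' Images are written as 8-bit grayscale (values clipped to \[0, 255\] and
#' rounded by the encoder); label masks as 16-bit TIFF so up to 65535 labels
#' survive a round trip, or as 8-bit PNG when all labels fit in 8 bits.
#'
#' @param x Numeric matrix (image, 0..255) or integer matrix (mask).
#' @param path Output path; `.png`, `.tif`/`.tiff` by extension.
#' @param what `"image"` or `"mask"`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(x, path, what = c("image", "mask")) {
  what <- match.arg(what)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff")) stop("unsupported image format: .", ext)
  if (what == "image") {
    v <- pmin(pmax(x, 0), 255) / 255
    bits <- 8L
  } else {
    if (max(x) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
    bits <- if (max(x) > 255L) 16L else 8L
    if (bits == 16L && ext == "png") {
      stop("label masks with >255 labels must be written as TIFF")
    }
    v <- x / (2^bits - 1)
  }
  if (ext == "png") {
    png::writePNG(v, path)
  } else {
    tiff::writeTIFF(v, path, bits.per.sample = bits)
  }
  invisible(path)
}

#' Linearly rescale intensities to \[0, 255\]
#'
#' Per-image min-max rescale: the minimum maps to 0 and the maximum to 255.
#' A constant image maps to all zeros (with a warning), since it carries no
#' contrast to preserve.
#'
#' @param image Numeric matrix.
#' @return Numeric matrix with values in \[0, 255\].
#' @export
rescale_to_255 <- function(image) {
  rng <- range(image, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant image: rescaled to all zeros")
    return(array(0, dim = dim(image)))
  }
  (image - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Crop an image or mask
#'
#' Crop boxes are 1-based and inclusive, `c(row_min, row_max, col_min,
#' col_max)`, the package-wide convention. `NULL` means no crop.
#'
#' @param x Matrix.
#' @param crop_box Integer vector of length 4, or `NULL`.
#' @return The cropped matrix.
#' @export
crop_image <- function(x, crop_box = NULL) {
  if (is.null(crop_box)) return(x)
  stopifnot(length(crop_box) == 4L)
  cb <- as.integer(crop_box)
  if (cb[1] < 1L || cb[3] < 1L || cb[2] > nrow(x) || cb[4] > ncol(x) ||
      cb[1] > cb[2] || cb[3] > cb[4]) {
    stop(sprintf("crop box [%d,%d]x[%d,%d] outside image %dx%d",
                 cb[1], cb[2], cb[3], cb[4], nrow(x), ncol(x)))
  }
  x[cb[1]:cb[2], cb[3]:cb[4], drop = FALSE]
}

#' Load and preprocess a micrograph / label-mask pair
#'
#' Applies the standard preprocessing: both arrays are cropped identically
#' (e.g. to remove a scale bar banner), the image is linearly min-max rescaled
#' to \[0, 255\], and mask labels are preserved unchanged.
#'
#' @param image Path to the micrograph, or a numeric matrix.
#' @param mask Path to the label mask, or an integer matrix.
#' @param crop_box 1-based inclusive crop `c(row_min, row_max, col_min,
#'   col_max)`, or `NULL` for none.
#' @param cal A [calibration()].
#' @return An object of class `"micrograph_pair"`: list with `image` (numeric,
#'   \[0,255\]), `label_mask` (integer), `calibration`, `crop_box` and source
#'   paths (if loaded from files).
#' @export
load_pair <- function(image, mask, crop_box = NULL, cal = calibration()) {
  image_path <- if (is.character(image)) image else NA_character_
  mask_path <- if (is.character(mask)) mask else NA_character_
  if (is.character(image)) image <- read_gray(image)
  if (is.character(mask)) mask <- read_label_mask(mask)
  if (!is.numeric(mask) || max(abs(mask - round(mask))) > 0) {
    stop("label mask must be integer-valued")
  }
  mode(mask) <- "integer"
  if (any(mask < 0L)) stop("label mask must be non-negative (0 = background)")
  if (!identical(dim(image), dim(mask))) {
    stop(sprintf("image (%dx%d) and mask (%dx%d) shapes differ",
                 nrow(image), ncol(image), nrow(mask), ncol(mask)))
  }
  image <- crop_image(image, crop_box)
  mask <- crop_image(mask, crop_box)
  structure(
    list(image = rescale_to_255(image), label_mask = mask,
         calibration = cal, crop_box = crop_box,
         image_path = image_path, mask_path = mask_path),
    class = "micrograph_pair"
  )
}

#' @export
print.micrograph_pair <- function(x, ...) {
  cat(sprintf("micrograph pair: %dx%d px, %d cells, %.4g um/px\n",
              nrow(x$image), ncol(x$image),
              length(setdiff(unique(as.vector(x$label_mask)), 0L)),
              x$calibration$pixel_size_um))
  invisible(x)
}
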