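# Label-mask post-processing: one Region per instance label, with the outer
# contour of its largest connected component. External instance segmenters
# (e.g. a pretrained deep-learning model) plug in upstream via the adapter
# contract: any tool producing an integer label mask of the image's shape,
# 0 = background, can feed this module through load_pair().

#' Convert an instance label mask into per-cell regions
#'
#' For every distinct nonzero label, extracts the region's pixels, keeps the
#' largest connected component if the label splits into several (with a
#' warning), computes its area (pixel count), centroid and ordered outer
#' contour, and flags regions touching the image border.
#'
#' @param x A `"micrograph_pair"` from [load_pair()], a `"sem_scene"`, or a
#'   bare integer label matrix.
#' @return List of regions (class `"sem_regions"`); each region is a list with
#'   `label`, `area_px2`, `centroid` (x, y), `contour` (matrix with columns
#'   x, y; 1-based pixel centers, ordered along the boundary), `bbox`
#'   (row_min, row_max, col_min, col_max), `mask` (logical matrix local to
#'   `bbox`), `edge` (touches border), and `n_components`.
#' @examples
#' sc <- generate_scene(scene_params(n_cells = 3, image_width_px = 256,
#'                                   image_height_px = 256, seed = 2))
#' regs <- labels_to_regions(sc)
#' length(regs)
#' @export
labels_to_regions <- function(x) {
  mask <- if (inherits(x, "micrograph_pair")) x$label_mask
          else if (inherits(x, "sem_scene")) x$label_mask
          else x
  if (!is.matrix(mask)) stop("'x' must carry a label-mask matrix")
  if (any(mask != round(mask))) stop("label mask must be integer-valued")
  mode(mask) <- "integer"
  H <- nrow(mask); W <- ncol(mask)
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (!length(labs)) return(structure(list(), class = "sem_regions"))

  # bounding boxes in one pass
  nz <- which(mask != 0L)
  lab_of <- mask[nz]
  rows <- (nz - 1L) %% H + 1L
  cols <- (nz - 1L) %/% H + 1L
  rmin <- tapply(rows, lab_of, min); rmax <- tapply(rows, lab_of, max)
  cmin <- tapply(cols, lab_of, min); cmax <- tapply(cols, lab_of, max)

  regions <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    lab <- labs[i]
    key <- as.character(lab)
    bb <- c(rmin[[key]], rmax[[key]], cmin[[key]], cmax[[key]])
    local <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE] == lab
    cc <- EBImage::bwlabel(local)
    ncomp <- max(cc)
    if (ncomp > 1L) {
      warning(sprintf("label %d has %d connected components; keeping largest",
                      lab, ncomp))
      sizes <- tabulate(cc[cc > 0], nbins = ncomp)
      local <- cc == which.max(sizes)
      # tighten the bbox to the kept component
      keep <- which(local, arr.ind = TRUE)
      bb <- c(bb[1] + min(keep[, 1]) - 1L, bb[1] + max(keep[, 1]) - 1L,
              bb[3] + min(keep[, 2]) - 1L, bb[3] + max(keep[, 2]) - 1L)
      local <- local[(min(keep[, 1]):max(keep[, 1])),
                     (min(keep[, 2]):max(keep[, 2])), drop = FALSE]
    }
    px <- which(local, arr.ind = TRUE)
    oc <- EBImage::ocontour(matrix(as.integer(local), nrow(local)))[[1]]
    # ocontour returns 0-based (dim1, dim2) = (row-1, col-1) local coordinates
    contour <- cbind(x = oc[, 2] + bb[3], y = oc[, 1] + bb[1])
    regions[[i]] <- list(
      label = lab,
      area_px2 = nrow(px),
      centroid = c(x = mean(px[, 2]) + bb[3] - 1, y = mean(px[, 1]) + bb[1] - 1),
      contour = contour,
      bbox = bb,
      mask = local,
      edge = bb[1] == 1L || bb[2] == H || bb[3] == 1L || bb[4] == W,
      n_components = ncomp
    )
  }
  structure(regions, class = "sem_regions")
}

#' Reassemble regions into a label image
#'
#' Inverse of [labels_to_regions()] for well-formed (single-component) masks:
#' paints each region's mask at its bounding box under its label.
#'
#' @param regions A `"sem_regions"` list.
#' @param dim Image dimensions `c(rows, cols)`.
#' @return Integer label matrix.
#' @export
regions_to_labels <- function(regions, dim) {
  out <- matrix(0L, dim[1], dim[2])
  for (r in regions) {
    sub <- out[r$bbox[1]:r$bbox[2], r$bbox[3]:r$bbox[4], drop = FALSE]
    sub[r$mask] <- r$label
    out[r$bbox[1]:r$bbox[2], r$bbox[3]:r$bbox[4]] <- sub
  }
  out
}

#' @export
print.sem_regions <- function(x, ...) {
  cat(sprintf("%d segmented regions; areas %s px^2\n", length(x),
              if (length(x)) paste(range(vapply(x, `[[`, 0, "area_px2")),
                                   collapse = "-") else "-"))
  invisible(x)
}
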