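# Synthetic SEM scene generator: ovoid cocci rendered as shaded ellipses with
# known ground truth, so every downstream stage can be validated without real
# micrographs.

#' Parameters of a synthetic SEM scene
#'
#' Defaults emulate an untreated *S. sanguinis* field at x20,000
#' magnification: mean projected cell area 0.37 um^2 with CV 0.29, ovoid
#' aspect ratios, chains of near-equal-sized cells, and surface roughness
#' that lands the texture metric near 0.02.
#'
#' @param image_width_px,image_height_px Image size in pixels.
#' @param n_cells Number of cells to place (placement failures may yield
#'   fewer; see the `placement_failures` field of the scene).
#' @param mean_area_um2 Target mean projected (full-ellipse) cell area, um^2.
#' @param area_cv Coefficient of variation of cell area (lognormal sampling).
#' @param aspect_ratio_range Bounds (each >= 1) for uniform sampling of the
#'   major:minor axis ratio.
#' @param roughness_amplitude Standard deviation of the zero-mean
#'   high-frequency intensity noise added inside each cell, on the \[0,1\]
#'   intensity scale. This is the quantity the texture metric estimates.
#' @param gradient_slope Length-2 numeric: planar illumination gradient per
#'   pixel in (x, y), \[0,1\] intensity scale. Applied globally.
#' @param background_noise_sd SD of global additive Gaussian noise, \[0,1\]
#'   scale.
#' @param occluded_fraction Fraction of cells rendered partially behind a
#'   dedicated neighbor (paint-over z-ordering), so that their visible area is
#'   below 0.7x the occluder's area and the neighbor filter removes them.
#' @param chain_probability Probability that a cell continues the current
#'   chain rather than starting a new chain/single.
#' @param pixel_size_um Micrometers per pixel edge.
#' @param seed Integer seed; scenes are bit-reproducible given identical
#'   parameters and seed.
#'
#' @return Object of class `"scene_params"`.
#' @export
scene_params <- function(image_width_px = 1024L, image_height_px = 1024L,
                         n_cells = 60L,
                         mean_area_um2 = 0.37, area_cv = 0.29,
                         aspect_ratio_range = c(1.1, 1.7),
                         roughness_amplitude = 0.02,
                         gradient_slope = c(2e-4, 1e-4),
                         background_noise_sd = 0.01,
                         occluded_fraction = 0,
                         chain_probability = 0.5,
                         pixel_size_um = 0.0136,
                         seed = 1L) {
  p <- list(image_width_px = as.integer(image_width_px),
            image_height_px = as.integer(image_height_px),
            n_cells = as.integer(n_cells),
            mean_area_um2 = mean_area_um2, area_cv = area_cv,
            aspect_ratio_range = as.numeric(aspect_ratio_range),
            roughness_amplitude = roughness_amplitude,
            gradient_slope = as.numeric(gradient_slope),
            background_noise_sd = background_noise_sd,
            occluded_fraction = occluded_fraction,
            chain_probability = chain_probability,
            pixel_size_um = pixel_size_um,
            seed = as.integer(seed))
  stopifnot(p$image_width_px > 0L, p$image_height_px > 0L, p$n_cells >= 0L,
            p$mean_area_um2 > 0, p$area_cv >= 0,
            length(p$aspect_ratio_range) == 2L, all(p$aspect_ratio_range >= 1),
            p$aspect_ratio_range[1] <= p$aspect_ratio_range[2],
            p$roughness_amplitude >= 0, p$roughness_amplitude <= 1,
            length(p$gradient_slope) == 2L,
            p$background_noise_sd >= 0, p$background_noise_sd <= 1,
            p$occluded_fraction >= 0, p$occluded_fraction <= 1,
            p$chain_probability >= 0, p$chain_probability <= 1,
            p$pixel_size_um > 0)
  # image must accommodate at least one mean-sized cell
  mean_r <- sqrt(p$mean_area_um2 / p$pixel_size_um^2 / pi)
  if (p$n_cells > 0L && min(p$image_width_px, p$image_height_px) <
      2 * mean_r * sqrt(p$aspect_ratio_range[2])) {
    stop("image dimensions cannot accommodate a mean-sized cell")
  }
  structure(p, class = "scene_params")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pixels whose centers fall inside the ellipse; x = column, y = row, 1-based.
# Returns linear indices into an H x W matrix plus the normalized squared
# elliptical radius r2 in [0, 1] at each pixel.
ellipse_pixels <- function(cx, cy, a, b, theta_deg, H, W) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ex <- sqrt((a * ct)^2 + (b * st)^2)  # bbox half-extents
  ey <- sqrt((a * st)^2 + (b * ct)^2)
  cols <- max(1L, floor(cx - ex)):min(W, ceiling(cx + ex))
  rows <- max(1L, floor(cy - ey)):min(H, ceiling(cy + ey))
  if (!length(cols) || !length(rows)) {
    return(list(idx = integer(0), r2 = numeric(0)))
  }
  dx <- rep(cols, each = length(rows)) - cx
  dy <- rep(rows, times = length(cols)) - cy
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  r2 <- u * u + v * v
  keep <- r2 <= 1
  idx <- rep(rows, times = length(cols)) +
    (rep(cols, each = length(rows)) - 1L) * H
  list(idx = idx[keep], r2 = r2[keep])
}

# TRUE if the pixel set forms one 4/8-connected component
single_component <- function(idx, H) {
  if (!length(idx)) return(FALSE)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  rr <- range(rows); cc <- range(cols)
  sub <- matrix(0L, rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L)
  sub[cbind(rows - rr[1] + 1L, cols - cc[1] + 1L)] <- 1L
  max(EBImage::bwlabel(sub)) == 1L
}

# geometry spec for one cell: center, semi-axes, orientation
cell_geom <- function(cx, cy, area_px2, aspect, theta_deg) {
  b <- sqrt(area_px2 / (pi * aspect))
  list(cx = cx, cy = cy, a = b * aspect, b = b, theta = theta_deg %% 180)
}

# TRUE if the geometry, grown by `margin`, fits inside the image and touches
# no label other than those in `allowed`
placement_ok <- function(g, margin, L, allowed = integer(0)) {
  H <- nrow(L); W <- ncol(L)
  ext <- margin + max(g$a, g$b)
  if (g$cx - ext < 1 || g$cx + ext > W || g$cy - ext < 1 || g$cy + ext > H) {
    return(FALSE)
  }
  own <- ellipse_pixels(g$cx, g$cy, g$a, g$b, g$theta, H, W)
  if (any(L[own$idx] != 0L)) return(FALSE)
  grown <- ellipse_pixels(g$cx, g$cy, g$a + margin, g$b + margin, g$theta, H, W)
  hits <- L[grown$idx]
  all(hits == 0L | hits %in% allowed)
}

#' Generate a synthetic SEM scene with ground truth
#'
#' Cells are filled ellipses with quadratic dome shading (bright center,
#' darker rim) plus per-cell high-frequency Gaussian roughness; a planar
#' illumination gradient and global background noise are added, and the image
#' is clipped to \[0, 255\]. Chains of adjacent near-equal-sized cells mimic
#' streptococcal growth; optional occluded cells are painted first and partly
#' overwritten by a dedicated neighbor so their visible footprint is locally
#' small. Because the dome, the gradient and any rotated quadratic all lie in
#' the span of a second-order polynomial in image coordinates, a scene with
#' zero roughness yields texture values at the quantization floor.
#'
#' Placement guarantees (relied on by validation):
#' * non-occluded cells never overlap and keep a >= 6 px mask gap (7 px
#'   placement margin) to cells outside their own chain, so no spurious
#'   adjacency arises;
#' * consecutive chain members sit ~2 px apart (adjacent) and share a common
#'   sampled area up to +/-5% jitter, so none is locally small;
#' * each occluded cell's visible area is driven into
#'   \[1000 px^2, 0.6 x occluder area\] by a binary search on the occluder
#'   offset, so it survives the artifact-size filter and is removed by the
#'   0.7x mean-neighbor-area rule; geometries where that window is empty have
#'   the occluded flag unset;
#' * all cells are placed fully inside the image (no edge truncation).
#'
#' @param params A [scene_params()] object.
#' @return Object of class `"sem_scene"`: list with `image` (numeric matrix,
#'   values in \[0, 255\], not quantized), `label_mask` (integer matrix, 0 =
#'   background), `truth` (data frame, one row per placed cell), `params`,
#'   and `placement_failures` (count of cells that could not be placed).
#' @seealso [truth_table()], [write_scene()]
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  H <- p$image_height_px; W <- p$image_width_px
  L <- matrix(0L, H, W)
  px_area_mean <- p$mean_area_um2 / p$pixel_size_um^2
  sig2 <- log(1 + p$area_cv^2)
  mu <- log(px_area_mean) - sig2 / 2
  draw_area <- function(n) {
    if (p$area_cv == 0) rep(px_area_mean, n) else rlnorm(n, mu, sqrt(sig2))
  }
  draw_aspect <- function(n) runif(n, p$aspect_ratio_range[1], p$aspect_ratio_range[2])

  cells <- list()   # committed geometries + metadata
  next_label <- 1L
  failures <- 0L

  commit <- function(g, area_intended, occluded, occluder, chain_id) {
    px <- ellipse_pixels(g$cx, g$cy, g$a, g$b, g$theta, H, W)
    lab <- next_label
    L[px$idx] <<- lab
    next_label <<- next_label + 1L
    cells[[lab]] <<- list(label = lab, geom = g, idx = px$idx,
                          area_intended = area_intended,
                          occluded = occluded, occluder = occluder,
                          chain_id = chain_id)
    lab
  }

  n_occ <- min(round(p$occluded_fraction * p$n_cells), p$n_cells %/% 2L)
  n_free <- p$n_cells - 2L * n_occ
  chain_id <- 0L

  # -- occlusion pairs (isolated from everything else) --
  for (k in seq_len(n_occ)) {
    placed <- FALSE
    for (attempt in 1:40) {
      A_o <- max(draw_area(1), 2400)
      A_h <- max(draw_area(1), 1400, 0.45 * A_o)  # keeps the visible-area window non-empty
      g_h <- cell_geom(runif(1, 1, W), runif(1, 1, H), A_h, draw_aspect(1),
                       runif(1, 0, 180))
      if (!placement_ok(g_h, 7, L)) next
      th_o <- runif(1, 0, 180); psi <- runif(1, 0, 2 * pi)
      asp_o <- draw_aspect(1)
      v_lo <- max(1050, 0.35 * A_o); v_hi <- min(0.6 * A_o, 0.9 * A_h)
      if (v_lo >= v_hi) next  # cannot happen given the area floors; safety
      v_target <- (v_lo + v_hi) / 2
      b_o <- sqrt(A_o / (pi * asp_o)); a_o <- b_o * asp_o
      own <- ellipse_pixels(g_h$cx, g_h$cy, g_h$a, g_h$b, g_h$theta, H, W)
      lo <- 0; hi <- g_h$a + a_o; d <- hi / 2; g_o <- NULL; vis <- NA
      for (it in 1:30) {
        d <- (lo + hi) / 2
        g_try <- cell_geom(g_h$cx + d * cos(psi), g_h$cy + d * sin(psi),
                           A_o, asp_o, th_o)
        occ <- ellipse_pixels(g_try$cx, g_try$cy, g_try$a, g_try$b,
                              g_try$theta, H, W)
        vis <- length(setdiff(own$idx, occ$idx))
        if (vis >= v_lo && vis <= v_hi) { g_o <- g_try; break }
        if (vis < v_target) lo <- d else hi <- d
      }
      if (is.null(g_o)) next
      # the visible crescent must stay in one piece, or the region extractor
      # would keep only its largest fragment and the size guarantee breaks
      if (!single_component(setdiff(own$idx,
                                    ellipse_pixels(g_o$cx, g_o$cy, g_o$a,
                                                   g_o$b, g_o$theta,
                                                   H, W)$idx), H)) next
      if (!placement_ok(g_o, 7, L)) next
      chain_id <- chain_id + 1L
      lab_h <- commit(g_h, A_h, TRUE, NA_integer_, chain_id)
      lab_o <- commit(g_o, A_o, FALSE, NA_integer_, chain_id)  # paints over h
      cells[[lab_h]]$occluder <- lab_o
      placed <- TRUE
      break
    }
    if (!placed) failures <- failures + 2L
  }

  # -- chains and singles --
  remaining <- n_free
  while (remaining > 0L) {
    len <- 1L
    while (len < remaining && len < 6L && runif(1) < p$chain_probability) {
      len <- len + 1L
    }
    base_area <- draw_area(1)
    areas <- base_area * runif(len, 0.95, 1.05)
    aspects <- draw_aspect(len)
    placed <- FALSE
    for (attempt in 1:40) {
      phi <- runif(1, 0, 180)
      jit <- runif(len, -4, 4)
      gs <- vector("list", len)
      cx <- runif(1, 1, W); cy <- runif(1, 1, H)
      ok <- TRUE
      for (i in seq_len(len)) {
        gs[[i]] <- cell_geom(cx, cy, areas[i], aspects[i], phi + jit[i])
        # earlier members of this chain are not yet painted, so this checks
        # the margin (7 px) against all other chains/pairs only; intra-chain spacing
        # (2 px gaps, no overlap) holds by construction of the step below
        if (!placement_ok(gs[[i]], 7, L)) { ok <- FALSE; break }
        if (i < len) {
          b_next <- sqrt(areas[i + 1] / (pi * aspects[i + 1]))
          step <- gs[[i]]$a + b_next * aspects[i + 1] + 2  # 2 px perimeter gap
          cx <- cx + step * cos(phi * pi / 180)
          cy <- cy + step * sin(phi * pi / 180)
        }
      }
      if (!ok) next
      chain_id <- chain_id + 1L
      labs <- integer(len)
      for (i in seq_len(len)) {
        labs[i] <- commit(gs[[i]], areas[i], FALSE, NA_integer_, chain_id)
      }
      placed <- TRUE
      break
    }
    if (!placed) failures <- failures + len
    remaining <- remaining - len
  }

  # -- render --
  img <- matrix(0.18, H, W)
  n_cells_placed <- length(cells)
  vis_counts <- integer(n_cells_placed)
  for (k in seq_len(n_cells_placed)) {
    ck <- cells[[k]]
    visible <- ck$idx[L[ck$idx] == ck$label]
    vis_counts[k] <- length(visible)
    g <- ck$geom
    th <- g$theta * pi / 180
    col <- (visible - 1L) %/% H + 1L
    row <- (visible - 1L) %% H + 1L
    dx <- col - g$cx; dy <- row - g$cy
    u <- (dx * cos(th) + dy * sin(th)) / g$a
    v <- (-dx * sin(th) + dy * cos(th)) / g$b
    r2 <- u * u + v * v
    val <- 0.78 - 0.38 * r2
    if (p$roughness_amplitude > 0) {
      val <- val + rnorm(length(visible), 0, p$roughness_amplitude)
    }
    img[visible] <- val
  }
  xg <- matrix(rep(seq_len(W) - 1L, each = H), H, W)
  yg <- matrix(rep(seq_len(H) - 1L, times = W), H, W)
  img <- img + p$gradient_slope[1] * xg + p$gradient_slope[2] * yg
  if (p$background_noise_sd > 0) {
    img <- img + rnorm(H * W, 0, p$background_noise_sd)
  }
  img <- pmin(pmax(img * 255, 0), 255)

  truth <- if (n_cells_placed == 0L) {
    data.frame(cell = integer(0), center_x = numeric(0), center_y = numeric(0),
               major_axis_px = numeric(0), minor_axis_px = numeric(0),
               orientation_deg = numeric(0), area_px2 = numeric(0),
               visible_area_px2 = integer(0), area_um2 = numeric(0),
               visible_area_um2 = numeric(0), occluded = logical(0),
               occluder = integer(0), chain_id = integer(0),
               roughness_amplitude = numeric(0))
  } else {
    geoms <- lapply(cells, `[[`, "geom")
    area_full <- vapply(geoms, function(g) pi * g$a * g$b, 0)
    data.frame(
      cell = vapply(cells, `[[`, 0L, "label"),
      center_x = vapply(geoms, `[[`, 0, "cx"),
      center_y = vapply(geoms, `[[`, 0, "cy"),
      major_axis_px = 2 * vapply(geoms, `[[`, 0, "a"),
      minor_axis_px = 2 * vapply(geoms, `[[`, 0, "b"),
      orientation_deg = vapply(geoms, `[[`, 0, "theta"),
      area_px2 = area_full,
      visible_area_px2 = vis_counts,
      area_um2 = area_full * p$pixel_size_um^2,
      visible_area_um2 = vis_counts * p$pixel_size_um^2,
      occluded = vapply(cells, `[[`, TRUE, "occluded"),
      occluder = vapply(cells, `[[`, 0L, "occluder"),
      chain_id = vapply(cells, `[[`, 0L, "chain_id"),
      roughness_amplitude = p$roughness_amplitude
    )
  }

  structure(list(image = img, label_mask = L, truth = truth, params = p,
                 placement_failures = failures),
            class = "sem_scene")
}

#' Ground-truth table of a synthetic scene
#'
#' @param scene A `"sem_scene"` from [generate_scene()].
#' @return Data frame, one row per nonzero label: center, full axis lengths
#'   (px), orientation (degrees), intended full-ellipse area and visible mask
#'   area in both px^2 and um^2, occlusion flags, chain id, and the roughness
#'   amplitude used.
#' @export
truth_table <- function(scene) {
  stopifnot(inherits(scene, "sem_scene"))
  scene$truth
}

#' @export
print.sem_scene <- function(x, ...) {
  cat(sprintf("synthetic SEM scene: %dx%d px, %d cells (%d occluded), seed %d\n",
              nrow(x$image), ncol(x$image), nrow(x$truth),
              sum(x$truth$occluded), x$params$seed))
  if (x$placement_failures > 0L) {
    cat(sprintf("  note: %d cells could not be placed\n", x$placement_failures))
  }
  invisible(x)
}

#' Write a scene to disk
#'
#' Writes the micrograph as 8-bit grayscale, the label mask as 16-bit TIFF
#' (8-bit PNG when labels fit), the truth table as CSV, and a manifest JSON
#' recording parameters and seed.
#'
#' @param scene A `"sem_scene"`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the four files.
#' @param format `"png"` or `"tiff"` for the image.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene", format = c("png", "tiff")) {
  stopifnot(inherits(scene, "sem_scene"))
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tif"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(name, "_image.", ext)),
    mask = file.path(dir, paste0(name, "_mask.",
                                 if (max(scene$label_mask) > 255L) "tif" else ext)),
    truth = file.path(dir, paste0(name, "_truth.csv")),
    manifest = file.path(dir, paste0(name, "_manifest.json"))
  )
  write_gray(scene$image, paths["image"], "image")
  write_gray(scene$label_mask, paths["mask"], "mask")
  utils::write.csv(scene$truth, paths["truth"], row.names = FALSE)
  jsonlite::write_json(
    list(params = unclass(scene$params),
         placement_failures = scene$placement_failures,
         n_cells_placed = nrow(scene$truth)),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
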