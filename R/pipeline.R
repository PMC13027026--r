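# End-to-end orchestration: scene generation or file loading -> regions ->
# artifact-size filter -> ellipse fits -> adjacency -> local size filter ->
# texture -> group statistics, with per-stage bookkeeping in a manifest.

#' Process one micrograph/mask pair into a per-cell table
#'
#' Runs the full single-image chain: regions from the label mask, artifact
#' size filter, ellipse fits, perimeter-distance adjacency, local size
#' (background) filter, and per-cell texture. Every segmented label keeps a
#' row; filter columns record why a cell dropped out.
#'
#' @param pair A `"micrograph_pair"` or `"sem_scene"`.
#' @param image_id Identifier recorded in the table.
#' @param group Group label recorded in the table.
#' @param cal A [calibration()]; defaults to the pair's own (or the scene's
#'   pixel size).
#' @param size_rule A [size_filter_rule()].
#' @param nb_rule A [neighbor_rule()].
#' @param kernel_size,iterations,min_texture_pixels Texture-stage settings.
#' @return List with `cells` (data frame) and `counts` (named integer vector:
#'   segmented, size_excluded, fit_failed, background_removed,
#'   texture_invalid, kept).
#' @export
process_image <- function(pair, image_id = "img1", group = "control",
                          cal = NULL,
                          size_rule = size_filter_rule(),
                          nb_rule = neighbor_rule(),
                          kernel_size = 7L, iterations = 2L,
                          min_texture_pixels = 50L) {
  if (is.null(cal)) {
    cal <- if (inherits(pair, "micrograph_pair")) pair$calibration
           else calibration(pair$params$pixel_size_um)
  }
  image <- pair$image
  regions <- labels_to_regions(pair)
  n_seg <- length(regions)
  if (n_seg == 0L) {
    return(list(cells = empty_cell_table(),
                counts = c(segmented = 0L, size_excluded = 0L, fit_failed = 0L,
                           background_removed = 0L, texture_invalid = 0L,
                           kept = 0L)))
  }

  sf <- size_filter(regions, size_rule)
  kept <- sf$kept
  fits <- lapply(kept, fit_ellipse)
  fit_ok <- vapply(fits, function(f) isTRUE(f$fit_ok), TRUE)

  live <- kept[fit_ok]
  live_fits <- fits[fit_ok]
  areas <- vapply(live, `[[`, 0, "area_px2")
  graph <- build_adjacency(live_fits, nb_rule)
  lf <- local_size_filter(areas, graph, nb_rule)

  tex <- lapply(seq_along(live), function(i) {
    if (lf$removed[i]) NULL
    else texture_value(live[[i]], image, kernel_size, iterations,
                       min_texture_pixels)
  })

  row_for <- function(r, fit = NULL, size_reason = NA_character_,
                      nb = NULL, tx = NULL) {
    data.frame(
      image_id = image_id, group = group, label = r$label,
      edge = r$edge,
      n_contour_points = nrow(r$contour),
      area_px2 = r$area_px2,
      area_um2 = px_area_to_um2(r$area_px2, cal),
      centroid_x = r$centroid[["x"]], centroid_y = r$centroid[["y"]],
      fit_ok = if (is.null(fit)) NA else fit$fit_ok,
      ellipse_major_px = if (is.null(fit)) NA_real_ else fit$major_axis_px,
      ellipse_minor_px = if (is.null(fit)) NA_real_ else fit$minor_axis_px,
      orientation_deg = if (is.null(fit)) NA_real_ else fit$orientation_deg,
      size_excluded = !is.na(size_reason), size_reason = size_reason,
      neighbor_count = if (is.null(nb)) NA_integer_ else nb$neighbor_count,
      mean_neighbor_area_px2 = if (is.null(nb)) NA_real_
                               else nb$mean_neighbor_area_px2,
      removed_by_background_filter = if (is.null(nb)) NA else nb$removed,
      texture_value = if (is.null(tx)) NA_real_ else tx$texture_value,
      texture_mean_abs = if (is.null(tx)) NA_real_ else tx$texture_mean_abs,
      eroded_pixels = if (is.null(tx)) NA_integer_ else tx$eroded_pixels,
      texture_valid = if (is.null(tx)) FALSE else tx$valid,
      stringsAsFactors = FALSE
    )
  }

  rows <- list()
  for (k in seq_len(nrow(sf$excluded))) {
    r <- regions[[match(sf$excluded$label[k],
                        vapply(regions, `[[`, 0L, "label"))]]
    rows[[length(rows) + 1L]] <- row_for(r, size_reason = sf$excluded$reason[k])
  }
  bad_fit <- which(!fit_ok)
  for (k in bad_fit) {
    rows[[length(rows) + 1L]] <- row_for(kept[[k]], fits[[k]])
  }
  for (i in seq_along(live)) {
    rows[[length(rows) + 1L]] <-
      row_for(live[[i]], live_fits[[i]], nb = lf[i, ], tx = tex[[i]])
  }
  cells <- do.call(rbind, rows)
  cells <- cells[order(cells$label), , drop = FALSE]
  rownames(cells) <- NULL
  cells$kept <- !cells$size_excluded & !is.na(cells$fit_ok) & cells$fit_ok &
    !is.na(cells$removed_by_background_filter) &
    !cells$removed_by_background_filter

  counts <- c(segmented = n_seg,
              size_excluded = nrow(sf$excluded),
              fit_failed = sum(!fit_ok),
              background_removed = sum(lf$removed),
              texture_invalid = sum(cells$kept & !cells$texture_valid),
              kept = sum(cells$kept))
  list(cells = cells, counts = counts)
}

empty_cell_table <- function() {
  data.frame(image_id = character(0), group = character(0), label = integer(0),
             edge = logical(0), n_contour_points = integer(0),
             area_px2 = numeric(0), area_um2 = numeric(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             fit_ok = logical(0), ellipse_major_px = numeric(0),
             ellipse_minor_px = numeric(0), orientation_deg = numeric(0),
             size_excluded = logical(0), size_reason = character(0),
             neighbor_count = integer(0), mean_neighbor_area_px2 = numeric(0),
             removed_by_background_filter = logical(0),
             texture_value = numeric(0), texture_mean_abs = numeric(0),
             eroded_pixels = integer(0), texture_valid = logical(0),
             kept = logical(0))
}

#' Build a run configuration
#'
#' In synthetic mode each group lists a number of images and the scene
#' parameters they share; in files mode each group lists image/mask path
#' pairs. Exactly one group is the control. All filter constants default to
#' the standard values (1000 px^2 / 5 contour points; 5 px / 100 samples /
#' 0.7x; 7x7 kernel x 2 iterations; effect thresholds 0.474/0.33/0.147).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param groups List of group specs. Synthetic: `list(label =, n_images =,
#'   params = scene_params(...))`. Files: `list(label =, images = c(...),
#'   masks = c(...), crop_box = NULL)`.
#' @param control Label of the control group.
#' @param cal A [calibration()] (files mode; synthetic scenes carry their own
#'   pixel size).
#' @param size_rule,nb_rule Filter rules.
#' @param kernel_size,iterations,min_texture_pixels Texture settings.
#' @param include_edge_cells Include border-touching cells in statistics?
#' @param seed Top-level seed; per-image seeds are derived from it.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "files"), groups, control,
                       cal = calibration(),
                       size_rule = size_filter_rule(),
                       nb_rule = neighbor_rule(),
                       kernel_size = 7L, iterations = 2L,
                       min_texture_pixels = 50L,
                       include_edge_cells = FALSE,
                       seed = 1L) {
  mode <- match.arg(mode)
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("group labels must be unique")
  if (sum(labels == control) != 1L) {
    stop("exactly one group must be the control ('", control, "' not found)")
  }
  structure(list(mode = mode, groups = groups, control = control,
                 cal = cal, size_rule = size_rule, nb_rule = nb_rule,
                 kernel_size = as.integer(kernel_size),
                 iterations = as.integer(iterations),
                 min_texture_pixels = as.integer(min_texture_pixels),
                 include_edge_cells = include_edge_cells,
                 seed = as.integer(seed)),
            class = "run_config")
}

# deterministic per-image seed stream below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 100003 + as.double(k) * 7919) %% 2147483647)
}

#' Run the full morphometric pipeline
#'
#' Executes generate/load -> regions -> size filter -> ellipse fit ->
#' adjacency -> background filter -> texture -> group statistics for every
#' image of every group, deterministically for a fixed config and seed.
#'
#' @param config A [run_config()].
#' @return Object of class `"cocci_run"`: list with `cells` (per-cell table
#'   across all images), `comparison` (a `"group_comparison"`), `manifest`
#'   (per-image stage counts, parameters, seed) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  all_cells <- list()
  per_image <- list()
  img_k <- 0L
  for (g in config$groups) {
    n_img <- if (config$mode == "synthetic") g$n_images else length(g$images)
    for (i in seq_len(n_img)) {
      img_k <- img_k + 1L
      image_id <- sprintf("%s_%02d", g$label, i)
      if (config$mode == "synthetic") {
        p <- unclass(g$params)
        p$seed <- derive_seed(config$seed, img_k)
        pair <- generate_scene(do.call(scene_params, p))
        cal <- calibration(p$pixel_size_um)
      } else {
        pair <- tryCatch(
          load_pair(g$images[i], g$masks[i], g$crop_box, config$cal),
          error = function(e) stop("stage load_pair, image '", image_id,
                                   "': ", conditionMessage(e), call. = FALSE))
        cal <- config$cal
      }
      res <- process_image(pair, image_id = image_id, group = g$label,
                           cal = cal, size_rule = config$size_rule,
                           nb_rule = config$nb_rule,
                           kernel_size = config$kernel_size,
                           iterations = config$iterations,
                           min_texture_pixels = config$min_texture_pixels)
      all_cells[[img_k]] <- res$cells
      per_image[[img_k]] <- c(list(image_id = image_id, group = g$label),
                              as.list(res$counts),
                              list(background_removed_fraction =
                                     unname(res$counts["background_removed"] /
                                            max(1L, res$counts["segmented"]))))
    }
  }
  cells <- do.call(rbind, all_cells)
  kept <- cells[cells$kept, , drop = FALSE]
  comparison <- summarize_groups(kept, config$control,
                                 config$include_edge_cells)
  manifest <- list(
    package_version = as.character(utils::packageVersion("coccimorph")),
    seed = config$seed,
    mode = config$mode,
    control = config$control,
    parameters = list(
      pixel_size_um = config$cal$pixel_size_um,
      min_area_px2 = config$size_rule$min_area_px2,
      min_contour_points = config$size_rule$min_contour_points,
      distance_threshold_px = config$nb_rule$distance_threshold_px,
      perimeter_samples = config$nb_rule$perimeter_samples,
      size_factor = config$nb_rule$size_factor,
      erosion_kernel = config$kernel_size,
      erosion_iterations = config$iterations,
      min_texture_pixels = config$min_texture_pixels),
    images = per_image
  )
  structure(list(cells = cells, comparison = comparison, manifest = manifest,
                 config = config),
            class = "cocci_run")
}

#' @export
print.cocci_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("morphometry run: %d images, %d segmented cells, %d kept\n",
              length(m$images), nrow(x$cells), sum(x$cells$kept)))
  print(x$comparison)
  invisible(x)
}

#' @export
summary.cocci_run <- function(object, ...) {
  img <- do.call(rbind, lapply(object$manifest$images, function(i)
    data.frame(image_id = i$image_id, group = i$group, segmented = i$segmented,
               size_excluded = i$size_excluded,
               background_removed = i$background_removed,
               removed_fraction = round(i$background_removed_fraction, 3),
               kept = i$kept)))
  cat("per-image stage counts:\n")
  print(img, row.names = FALSE)
  invisible(img)
}

#' @export
plot.cocci_run <- function(x, metric = c("area_um2", "texture_value"), ...) {
  plot(x$comparison, metric = match.arg(metric), ...)
}

#' Write run artifacts to a directory
#'
#' Writes `cells.csv` (one row per segmented cell with all stage columns),
#' `groups.csv`, `comparisons.csv`, `manifest.json`, and violin figures for
#' both metrics.
#'
#' @param run A `"cocci_run"`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "cocci_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             groups = file.path(dir, "groups.csv"),
             comparisons = file.path(dir, "comparisons.csv"),
             manifest = file.path(dir, "manifest.json"),
             violin_area = file.path(dir, "violin_area.png"),
             violin_texture = file.path(dir, "violin_texture.png"))
  utils::write.csv(run$cells, paths["cells"], row.names = FALSE)
  utils::write.csv(run$comparison$groups, paths["groups"], row.names = FALSE)
  utils::write.csv(run$comparison$comparisons, paths["comparisons"],
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  grDevices::png(paths["violin_area"], 900, 600)
  plot(run$comparison, "area_um2", main = "projected cell area")
  grDevices::dev.off()
  grDevices::png(paths["violin_texture"], 900, 600)
  plot(run$comparison, "texture_value", main = "surface texture")
  grDevices::dev.off()
  invisible(paths)
}

#' Read a run configuration from YAML
#'
#' Schema: `mode`, `control`, `seed`, optional `pixel_size_um`, optional
#' filter overrides (`min_area_px2`, `min_contour_points`,
#' `distance_threshold_px`, `perimeter_samples`, `size_factor`,
#' `kernel_size`, `iterations`), and `groups`: a list of
#' `{label, n_images, params: {...scene_params fields...}}` (synthetic) or
#' `{label, images: [...], masks: [...], crop_box: [r1, r2, c1, c2]}` (files).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cal <- calibration(y$pixel_size_um %||% 0.0136)
  groups <- lapply(y$groups, function(g) {
    if ((y$mode %||% "synthetic") == "synthetic") {
      pars <- g$params %||% list()
      pars$pixel_size_um <- pars$pixel_size_um %||% cal$pixel_size_um
      list(label = g$label, n_images = g$n_images %||% 1L,
           params = do.call(scene_params, pars))
    } else {
      list(label = g$label, images = unlist(g$images),
           masks = unlist(g$masks),
           crop_box = if (is.null(g$crop_box)) NULL else unlist(g$crop_box))
    }
  })
  run_config(
    mode = y$mode %||% "synthetic", groups = groups, control = y$control,
    cal = cal,
    size_rule = size_filter_rule(y$min_contour_points %||% 5L,
                                 y$min_area_px2 %||% 1000),
    nb_rule = neighbor_rule(y$distance_threshold_px %||% 5,
                            y$perimeter_samples %||% 100L,
                            y$size_factor %||% 0.7),
    kernel_size = y$kernel_size %||% 7L,
    iterations = y$iterations %||% 2L,
    include_edge_cells = isTRUE(y$include_edge_cells),
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
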