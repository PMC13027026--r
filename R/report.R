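# Group-level reporting: per-condition summaries of projected cell area and
# surface texture, percent changes versus the control group, and Cliff's delta
# effect sizes with categorical annotation.

summary_row <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  c(n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
    sd = stats::sd(v, na.rm = TRUE), q1 = q[1], median = q[2], q3 = q[3])
}

#' Summarize and compare treatment groups
#'
#' Computes per-group n, mean, sd and quartiles for projected cell area and
#' texture value, and compares every treatment group to the designated
#' control with percent change of the mean and Cliff's delta (with category).
#' Cells flagged as touching the image border are excluded by default (their
#' areas are truncated); texture summaries use only texture-valid cells.
#'
#' @param cells Data frame with one row per kept cell; must contain `group`,
#'   `area_um2`, `texture_value`, `texture_valid`, and (optionally) `edge`.
#' @param control Label of the control group (must be present).
#' @param include_edge_cells Keep border-touching cells in statistics?
#' @return Object of class `"group_comparison"`: list with `groups` (summary
#'   data frame), `comparisons` (per treatment x metric: percent change,
#'   delta, category, stars), `control`, and the cell table used.
#' @export
summarize_groups <- function(cells, control, include_edge_cells = FALSE) {
  stopifnot(is.data.frame(cells),
            all(c("group", "area_um2", "texture_value", "texture_valid")
                %in% names(cells)))
  if (!include_edge_cells && "edge" %in% names(cells)) {
    cells <- cells[!cells$edge, , drop = FALSE]
  }
  if (!control %in% cells$group) {
    stop("control group '", control, "' not present in the cell table")
  }
  groups <- unique(cells$group)
  groups <- c(control, setdiff(groups, control))

  gs <- do.call(rbind, lapply(groups, function(g) {
    sub <- cells[cells$group == g, , drop = FALSE]
    a <- summary_row(sub$area_um2)
    t <- summary_row(sub$texture_value[sub$texture_valid])
    data.frame(group = g, n_cells = nrow(sub),
               area_mean = a["mean"], area_sd = a["sd"],
               area_q1 = a["q1"], area_median = a["median"], area_q3 = a["q3"],
               n_texture = t["n"],
               texture_mean = t["mean"], texture_sd = t["sd"],
               texture_q1 = t["q1"], texture_median = t["median"],
               texture_q3 = t["q3"],
               row.names = NULL)
  }))

  ctrl <- cells[cells$group == control, , drop = FALSE]
  cmp <- do.call(rbind, lapply(setdiff(groups, control), function(g) {
    sub <- cells[cells$group == g, , drop = FALSE]
    d_area <- cliffs_delta(sub$area_um2, ctrl$area_um2)
    d_tex <- cliffs_delta(sub$texture_value[sub$texture_valid],
                          ctrl$texture_value[ctrl$texture_valid])
    data.frame(
      group = g,
      metric = c("area_um2", "texture_value"),
      percent_change = c(
        percent_change(mean(sub$area_um2), mean(ctrl$area_um2)),
        percent_change(mean(sub$texture_value[sub$texture_valid]),
                       mean(ctrl$texture_value[ctrl$texture_valid]))),
      delta = c(d_area$delta, d_tex$delta),
      category = c(d_area$category, d_tex$category),
      stars = category_stars(c(d_area$category, d_tex$category)),
      row.names = NULL
    )
  }))
  if (is.null(cmp)) {
    cmp <- data.frame(group = character(0), metric = character(0),
                      percent_change = numeric(0), delta = numeric(0),
                      category = character(0), stars = character(0))
  }

  structure(list(groups = gs, comparisons = cmp, control = control,
                 cells = cells),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison vs control '%s'\n\n", x$control))
  g <- x$groups
  cat("per-group summaries:\n")
  print(data.frame(group = g$group, n = g$n_cells,
                   area_um2 = sprintf("%.4f +/- %.4f", g$area_mean, g$area_sd),
                   texture = sprintf("%.4f +/- %.4f", g$texture_mean,
                                     g$texture_sd)),
        row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\ncomparisons vs control:\n")
    c2 <- x$comparisons
    print(data.frame(group = c2$group, metric = c2$metric,
                     change = sprintf("%+.1f%%", c2$percent_change),
                     delta = sprintf("%.3f", c2$delta), effect = c2$stars),
          row.names = FALSE)
  }
  invisible(x)
}

#' Violin plot of a per-cell metric by group
#'
#' Kernel-density violins with horizontal quartile lines, one violin per
#' group, control first.
#'
#' @param x A `"group_comparison"`.
#' @param metric `"area_um2"` or `"texture_value"`.
#' @param ... Passed to [graphics::plot()] (e.g. `main`).
#' @return Invisibly, the list of group values plotted.
#' @export
plot.group_comparison <- function(x, metric = c("area_um2", "texture_value"),
                                  ...) {
  metric <- match.arg(metric)
  cells <- x$cells
  if (metric == "texture_value") cells <- cells[cells$texture_valid, ]
  groups <- x$groups$group
  vals <- lapply(groups, function(g) cells[[metric]][cells$group == g])
  names(vals) <- groups
  ylim <- range(unlist(vals))
  graphics::plot(NA, xlim = c(0.5, length(vals) + 0.5), ylim = ylim,
                 xaxt = "n", xlab = "", ylab = metric, ...)
  graphics::axis(1, at = seq_along(vals), labels = groups, las = 2)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (length(v) < 2) next
    d <- stats::density(v)
    keep <- d$x >= min(v) & d$x <= max(v)
    w <- 0.4 * d$y[keep] / max(d$y[keep])
    graphics::polygon(c(i - w, rev(i + w)), c(d$x[keep], rev(d$x[keep])),
                      col = "grey85", border = "grey40")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    for (qq in q) {
      at <- which.min(abs(d$x[keep] - qq))
      graphics::segments(i - w[at], qq, i + w[at], qq,
                         lwd = c(1, 2, 1)[match(qq, q)])
    }
  }
  invisible(vals)
}
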