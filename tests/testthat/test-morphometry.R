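test_that("a filled circle fits as a circle of the right diameter", {
  r <- ellipse_region(50, 50, 30, 30, 0, 110, 110)
  f <- fit_ellipse(r)
  expect_true(f$fit_ok)
  expect_equal(f$major_axis_px, 60, tolerance = 0.02)
  expect_equal(f$minor_axis_px, 60, tolerance = 0.02)
})

test_that("a rendered noise-free ellipse is recovered within 2% and 2 deg", {
  r <- ellipse_region(60, 60, 30, 15, 30, 130, 130)
  f <- fit_ellipse(r)
  expect_equal(f$major_axis_px, 60, tolerance = 0.02)
  expect_equal(f$minor_axis_px, 30, tolerance = 0.02)
  expect_lt(abs(f$orientation_deg - 30), 2)
  expect_equal(unname(f$center), c(60, 60), tolerance = 0.02)
})

test_that("exact perimeter points fit back to the generating ellipse", {
  t <- seq(0, 2 * pi, length.out = 61)[-61]
  th <- 70 * pi / 180
  x <- 25 + 40 * cos(t) * cos(th) - 18 * sin(t) * sin(th)
  y <- 80 + 40 * cos(t) * sin(th) + 18 * sin(t) * cos(th)
  f <- fit_ellipse(cbind(x, y))
  expect_equal(f$major_axis_px, 80, tolerance = 1e-6)
  expect_equal(f$minor_axis_px, 36, tolerance = 1e-6)
  expect_equal(f$orientation_deg, 70, tolerance = 1e-4)
})

test_that("degenerate collinear contours fail cleanly", {
  f <- fit_ellipse(cbind(1:20, 3 * (1:20) + 2))
  expect_false(f$fit_ok)
  expect_error(fit_ellipse(cbind(1:3, 1:3)), "at least 5")
})

test_that("orientation is rotation-equivariant", {
  for (phi in c(0, 25, 60, 115)) {
    r <- ellipse_region(70, 70, 32, 16, phi, 150, 150)
    f <- fit_ellipse(r)
    d <- abs(((f$orientation_deg - phi) + 90) %% 180 - 90)
    expect_lt(d, 2)
  }
})

test_that("size filter applies both strict inequalities", {
  mk <- function(area, npts) {
    list(label = 1L, area_px2 = area,
         contour = cbind(seq_len(npts), seq_len(npts)))
  }
  rule <- size_filter_rule()
  sf <- size_filter(structure(list(mk(999, 60)), class = "sem_regions"), rule)
  expect_equal(nrow(sf$excluded), 1)
  expect_equal(sf$excluded$reason, "area")
  sf <- size_filter(structure(list(mk(1000, 60)), class = "sem_regions"), rule)
  expect_length(sf$kept, 1)
  sf <- size_filter(structure(list(mk(5000, 4)), class = "sem_regions"), rule)
  expect_equal(sf$excluded$reason, "contour")
  sf <- size_filter(structure(list(mk(5000, 5)), class = "sem_regions"), rule)
  expect_length(sf$kept, 1)
})

test_that("size filter keeps every cell of an artifact-free scene", {
  sc <- generate_scene(scene_params(n_cells = 40, occluded_fraction = 0,
                                    seed = 12))
  sf <- size_filter(labels_to_regions(sc))
  expect_length(sf$kept, nrow(truth_table(sc)))
  expect_equal(nrow(sf$excluded), 0)
})

test_that("measured mean area recovers the generator mean within 5%", {
  scenes <- lapply(1:4, function(s) generate_scene(
    scene_params(n_cells = 55, occluded_fraction = 0, seed = 100 + s)))
  measured <- unlist(lapply(scenes, function(sc)
    vapply(labels_to_regions(sc), `[[`, 0, "area_px2")))
  truth <- unlist(lapply(scenes, function(sc) truth_table(sc)$area_px2))
  expect_gt(length(measured), 200)
  expect_lt(abs(mean(measured) / mean(truth) - 1), 0.05)
})

test_that("fitted ellipse area stays within 25% of mask area", {
  sc <- generate_scene(scene_params(n_cells = 30, seed = 44))
  regs <- labels_to_regions(sc)
  for (r in regs) {
    f <- fit_ellipse(r)
    expect_lt(abs(pi * f$major_axis_px * f$minor_axis_px / 4 / r$area_px2 - 1),
              0.25)
  }
})
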