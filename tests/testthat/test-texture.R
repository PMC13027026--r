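test_that("square erosion arithmetic is exact", {
  sq <- matrix(FALSE, 40, 40); sq[11:30, 11:30] <- TRUE
  e <- erode_mask(sq)
  expect_equal(sum(e), 64)                      # 20 - 2*6 = 8 per side
  px <- which(e, arr.ind = TRUE)
  expect_equal(range(px[, 1]), c(17, 24))
  small <- matrix(FALSE, 20, 20); small[5:16, 5:16] <- TRUE   # 12 x 12
  expect_equal(sum(erode_mask(small)), 0)
})

test_that("erosion matches the brute-force structuring-element definition", {
  # two passes of a 7x7 kernel equal one erosion by a 13x13 square:
  # p survives iff every offset within the 13x13 window is inside the mask
  m <- matrix(FALSE, 70, 70)
  px <- coccimorph:::ellipse_pixels(35, 35, 30, 30, 0, 70, 70)
  m[px$idx] <- TRUE
  got <- erode_mask(m, 7, 2)
  ref <- matrix(FALSE, 70, 70)
  off <- expand.grid(dr = -6:6, dc = -6:6)
  for (r in 7:64) for (c in 7:64) {
    ref[r, c] <- all(m[cbind(r + off$dr, c + off$dc)])
  }
  expect_identical(got, ref)
})

test_that("fields in the model span leave zero residual", {
  xy <- as.matrix(expand.grid(x = 1:40, y = 1:30))
  f <- fit_poly_surface(xy, rep(0.37, nrow(xy)))
  expect_equal(f$rms, 0, tolerance = 1e-12)
  expect_equal(unname(f$coefficients["a0"]), 0.37, tolerance = 1e-12)
  expect_true(all(abs(f$coefficients[-1]) < 1e-10))
  z <- 0.2 + 0.01 * xy[, 1] - 0.02 * xy[, 2] + 0.003 * xy[, 1] * xy[, 2]
  expect_equal(fit_poly_surface(xy, z)$rms, 0, tolerance = 1e-10)
})

test_that("residuals are orthogonal to the design columns", {
  set.seed(2)
  xy <- as.matrix(expand.grid(x = 1:25, y = 1:25))
  z <- runif(nrow(xy))
  f <- fit_poly_surface(xy, z)
  x <- (xy[, 1] - mean(xy[, 1])); y <- (xy[, 2] - mean(xy[, 2]))
  hw <- max(abs(c(x, y))); x <- x / hw; y <- y / hw
  X <- cbind(1, x, y, x^2, y^2, x * y)
  expect_lt(max(abs(crossprod(X, f$residuals))), 1e-8 * nrow(xy))
})

test_that("rank-deficient designs are flagged invalid", {
  xy <- cbind(1:20, rep(3, 20))  # collinear pixels
  expect_false(fit_poly_surface(xy, runif(20))$valid)
  expect_false(fit_poly_surface(cbind(1:5, 1:5), runif(5))$valid)
})

test_that("uniform noise on a dome leaves rms near eps/sqrt(3)", {
  set.seed(9)
  xy <- as.matrix(expand.grid(x = 1:100, y = 1:100))
  dome <- 0.7 - 1e-4 * (xy[, 1] - 50)^2 - 2e-4 * (xy[, 2] - 50)^2
  eps <- 0.05
  z <- dome + runif(nrow(xy), -eps, eps)
  f <- fit_poly_surface(xy, z)
  expect_equal(f$rms, eps / sqrt(3), tolerance = 0.05)
})

test_that("texture is invariant to planar gradients and model-span offsets", {
  sc <- generate_scene(scene_params(n_cells = 6, roughness_amplitude = 0,
                                    background_noise_sd = 0, seed = 19))
  regs <- labels_to_regions(sc)
  tv <- texture_value(regs[[1]], sc$image)
  expect_true(tv$valid)
  expect_lt(tv$texture_value, 0.002)   # dome + gradient are in the span
  # doubling the global planar gradient must not change the value
  H <- nrow(sc$image); W <- ncol(sc$image)
  xg <- matrix(rep(seq_len(W) - 1L, each = H), H, W)
  yg <- matrix(rep(seq_len(H) - 1L, times = W), H, W)
  img2 <- sc$image + 255 * (2e-4 * xg + 1e-4 * yg)
  tv2 <- texture_value(regs[[1]], img2)
  expect_equal(tv2$texture_value, tv$texture_value, tolerance = 1e-6)
  # adding any quadratic in the span leaves the value unchanged
  img3 <- sc$image + 255 * (0.05 + 1e-7 * xg^2 + 2e-7 * xg * yg)
  tv3 <- texture_value(regs[[1]], img3)
  expect_equal(tv3$texture_value, tv$texture_value, tolerance = 1e-6)
})

test_that("texture scales linearly with intensity contrast", {
  sc <- generate_scene(scene_params(n_cells = 5, roughness_amplitude = 0.02,
                                    background_noise_sd = 0,
                                    gradient_slope = c(0, 0), seed = 23))
  regs <- labels_to_regions(sc)
  t1 <- texture_value(regs[[1]], sc$image)$texture_value
  t2 <- texture_value(regs[[1]], 0.5 * sc$image)$texture_value
  expect_equal(t2, 0.5 * t1, tolerance = 1e-9)
})

test_that("texture estimates the planted roughness amplitude", {
  vals <- unlist(lapply(1:3, function(s) {
    sc <- generate_scene(scene_params(n_cells = 40, roughness_amplitude = 0.02,
                                      background_noise_sd = 0, seed = 400 + s))
    res <- process_image(sc, "i", "g")
    k <- res$cells[res$cells$kept & res$cells$texture_valid, ]
    k$texture_value
  }))
  expect_gt(length(vals), 100)
  expect_equal(mean(vals), 0.02, tolerance = 0.15)
})

test_that("the quadratic fit never beats a planar fit in residual rms", {
  set.seed(31)
  for (k in 1:5) {
    xy <- as.matrix(expand.grid(x = 1:30, y = 1:30))
    z <- runif(nrow(xy))
    quad <- fit_poly_surface(xy, z)$rms
    planar <- sqrt(mean(stats::lm.fit(cbind(1, xy), z)$residuals^2))
    expect_lte(quad, planar + 1e-12)
  }
})

test_that("small eroded masks are flagged texture-invalid", {
  r <- ellipse_region(30, 30, 9, 9, 0, 60, 60)  # eroded to < 50 px
  tv <- texture_value(r, matrix(128, 60, 60))
  expect_false(tv$valid)
})
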