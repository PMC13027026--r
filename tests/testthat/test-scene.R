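test_that("empty scene is gradient and noise only", {
  sc <- generate_scene(scene_params(n_cells = 0, image_width_px = 128,
                                    image_height_px = 96, seed = 3))
  expect_equal(dim(sc$image), c(96, 128))
  expect_true(all(sc$label_mask == 0L))
  expect_equal(nrow(truth_table(sc)), 0L)
})

test_that("identical params and seed reproduce bit-identical scenes", {
  p <- scene_params(n_cells = 20, occluded_fraction = 0.2, seed = 42)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$label_mask, b$label_mask)
  expect_identical(a$truth, b$truth)
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  generate_scene(scene_params(n_cells = 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("truth labels exactly match nonzero mask labels", {
  sc <- generate_scene(scene_params(n_cells = 30, occluded_fraction = 0.2,
                                    seed = 5))
  expect_setequal(truth_table(sc)$cell,
                  setdiff(unique(as.vector(sc$label_mask)), 0L))
})

test_that("non-occluded mask areas match intended ellipse areas within 2%", {
  sc <- generate_scene(scene_params(n_cells = 50, occluded_fraction = 0.15,
                                    seed = 8))
  tt <- truth_table(sc)
  non <- tt[!tt$occluded, ]
  expect_gt(nrow(non), 30)
  expect_lt(max(abs(non$visible_area_px2 / non$area_px2 - 1)), 0.02)
})

test_that("truth areas convert to um^2 with the squared pixel size", {
  sc <- generate_scene(scene_params(n_cells = 10, seed = 13,
                                    pixel_size_um = 0.0136))
  tt <- truth_table(sc)
  expect_equal(tt$area_um2, px_area_to_um2(tt$area_px2, calibration(0.0136)))
  # intended full area follows the ellipse formula: axes 40 x 20 px -> 628.3
  g <- coccimorph:::cell_geom(50, 50, pi * 20 * 10, 2, 0)
  expect_equal(pi * g$a * g$b, pi * 20 * 10, tolerance = 1e-12)
  expect_equal(px_area_to_um2(628.3, calibration(0.0136)), 628.3 * 0.0136^2)
})

test_that("occluded cells are visibly smaller than 0.7x their occluder", {
  sc <- generate_scene(scene_params(n_cells = 60, occluded_fraction = 0.25,
                                    seed = 21))
  tt <- truth_table(sc)
  occ <- tt[tt$occluded, ]
  expect_gt(nrow(occ), 5)
  occluder_vis <- tt$visible_area_px2[match(occ$occluder, tt$cell)]
  expect_true(all(occ$visible_area_px2 < 0.7 * occluder_vis))
  # and they stay above the artifact-size cutoff so only the neighbor
  # filter can remove them
  expect_true(all(occ$visible_area_px2 >= 1000))
})

test_that("scene files round-trip through disk", {
  sc <- generate_scene(scene_params(n_cells = 8, image_width_px = 512,
                                    image_height_px = 512, seed = 17))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, "sc")
  expect_true(all(file.exists(paths)))
  mask <- read_label_mask(paths[["mask"]])
  expect_identical(mask, sc$label_mask)
  img <- read_gray(paths[["image"]])
  expect_lt(max(abs(img - sc$image)), 0.5 + 1e-9)  # 8-bit quantization
})
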