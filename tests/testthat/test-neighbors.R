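test_that("perimeter sampling follows the parametric definition", {
  f <- make_fit(0, 0, 30, 30)
  p <- sample_perimeter(f, 4)
  expect_equal(sqrt(rowSums(p^2)), rep(30, 4))
  expect_equal(p[1, ], c(x = 30, y = 0))
  g <- make_fit(12, -5, 31, 14, 25)
  q <- sample_perimeter(g, 100)
  # all points satisfy the implicit ellipse equation
  th <- 25 * pi / 180
  u <- ((q[, 1] - 12) * cos(th) + (q[, 2] + 5) * sin(th)) / 31
  v <- (-(q[, 1] - 12) * sin(th) + (q[, 2] + 5) * cos(th)) / 14
  expect_lt(max(abs(u^2 + v^2 - 1)), 1e-6)
})

test_that("equal-parameter spacing bounds the perimeter gap", {
  f <- make_fit(0, 0, 30, 15)
  p <- sample_perimeter(f, 100)
  dense <- sample_perimeter(f, 1e5)
  per <- sum(sqrt(rowSums((dense - dense[c(2:1e5, 1), ])^2)))
  gaps <- sqrt(rowSums((p - p[c(2:100, 1), ])^2))
  expect_lt(max(gaps), 2 * per / 100)
})

test_that("failed fits cannot be sampled", {
  bad <- structure(list(fit_ok = FALSE), class = "ellipse_fit")
  expect_error(sample_perimeter(bad), "exclude")
})

test_that("collinear circles give the analytic perimeter distance", {
  a <- make_fit(0, 0, 30, 30)
  b <- make_fit(100, 0, 30, 30)
  expect_equal(min_perimeter_distance(a, b, 100), 40, tolerance = 0.05 / 40)
  expect_equal(min_perimeter_distance(a, b, 100),
               min_perimeter_distance(b, a, 100))
  expect_equal(min_perimeter_distance(a, a, 100), 0)
})

test_that("100-point distances agree with dense sampling within 1%", {
  set.seed(5)
  for (k in 1:5) {
    a <- make_fit(runif(1, 0, 50), runif(1, 0, 50), 30, 15, runif(1, 0, 180))
    b <- make_fit(runif(1, 70, 120), runif(1, 70, 120), 30, 15,
                  runif(1, 0, 180))
    d100 <- min_perimeter_distance(a, b, 100)
    dd <- dense_min_distance(a, b)
    expect_lt(abs(d100 - dd) / dd, 0.01)
  }
})

test_that("adjacency threshold is strict at 5 px", {
  rule <- neighbor_rule()
  near <- list(make_fit(0, 0, 30, 30), make_fit(64.9, 0, 30, 30))
  g <- build_adjacency(near, rule)
  expect_equal(nrow(g$edges), 1)
  at <- list(make_fit(0, 0, 30, 30), make_fit(65, 0, 30, 30))
  g2 <- build_adjacency(at, rule)
  expect_equal(nrow(g2$edges), 0)
})

test_that("indexed adjacency equals brute force on random scenes", {
  set.seed(11)
  for (rep in 1:3) {
    fits <- lapply(1:50, function(i)
      make_fit(runif(1, 0, 600), runif(1, 0, 600),
               runif(1, 10, 30), runif(1, 8, 15), runif(1, 0, 180)))
    g <- build_adjacency(fits)
    b <- brute_adjacency(fits)
    expect_equal(g$edges[order(g$edges$i, g$edges$j), c("i", "j")],
                 b[order(b$i, b$j), c("i", "j")], ignore_attr = TRUE)
  }
})

test_that("local size filter uses a strict 0.7x mean-neighbor threshold", {
  two <- list(make_fit(0, 0, 20, 20), make_fit(42, 0, 20, 20))  # 2 px apart
  g <- build_adjacency(two)
  expect_equal(nrow(g$edges), 1)
  expect_equal(local_size_filter(c(50, 100), g)$removed, c(TRUE, FALSE))
  expect_equal(local_size_filter(c(69.9, 100), g)$removed, c(TRUE, FALSE))
  expect_equal(local_size_filter(c(70, 100), g)$removed, c(FALSE, FALSE))
})

test_that("isolated cells are never removed", {
  lone <- list(make_fit(0, 0, 20, 20), make_fit(500, 500, 20, 20))
  g <- build_adjacency(lone)
  expect_equal(nrow(g$edges), 0)
  expect_equal(local_size_filter(c(1, 1e6), g)$removed, c(FALSE, FALSE))
})

test_that("removal decisions are order-independent", {
  set.seed(3)
  fits <- lapply(1:12, function(i) make_fit(40 * i, 0, 21, 20))  # a chain
  areas <- runif(12, 50, 200)
  g <- build_adjacency(fits)
  removed <- local_size_filter(areas, g)$removed
  perm <- sample(12)
  g2 <- build_adjacency(fits[perm])
  removed2 <- local_size_filter(areas[perm], g2)$removed
  expect_equal(removed2, removed[perm])
})

test_that("planted occlusions are removed and nothing else is", {
  sc <- generate_scene(scene_params(n_cells = 60, occluded_fraction = 0.25,
                                    chain_probability = 0.6, seed = 77))
  tt <- truth_table(sc)
  res <- process_image(sc, "img", "g")
  removed <- res$cells$label[!is.na(res$cells$removed_by_background_filter) &
                               res$cells$removed_by_background_filter]
  expect_setequal(removed, tt$cell[tt$occluded])
})
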