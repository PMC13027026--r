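fake_cells <- function(groups, n, area_means, texture_means, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(group = groups[i],
               area_um2 = rlnorm(n, log(area_means[i]) - 0.3^2 / 2, 0.3),
               texture_value = rlnorm(n, log(texture_means[i]) - 0.2^2 / 2, 0.2),
               texture_valid = TRUE, edge = FALSE)
  }))
}

test_that("identical distributions compare as null", {
  # n chosen so |delta| < 0.05 sits ~2.7 sigma from the null sampling sd
  cells <- fake_cells(c("control", "treated"), 2000, c(0.37, 0.37),
                      c(0.02, 0.02), seed = 4)
  gc <- summarize_groups(cells, "control")
  cmp <- gc$comparisons
  expect_true(all(abs(cmp$delta) < 0.05))
  expect_true(all(abs(cmp$percent_change) < 5))
})

test_that("an imposed 25% area shift is recovered", {
  cells <- fake_cells(c("control", "treated"), 1000, c(0.37, 0.37 * 1.25),
                      c(0.02, 0.02), seed = 6)
  gc <- summarize_groups(cells, "control")
  pc <- gc$comparisons$percent_change[gc$comparisons$metric == "area_um2"]
  expect_equal(pc, 25, tolerance = 0.2)
  expect_lt(abs(pc - 25), 5)
})

test_that("group ns equal kept row counts and control comes first", {
  cells <- fake_cells(c("a", "control", "b"), 40, c(0.3, 0.3, 0.3),
                      c(0.02, 0.02, 0.02))
  gc <- summarize_groups(cells, "control")
  expect_equal(gc$groups$group[1], "control")
  expect_equal(gc$groups$n_cells, c(40, 40, 40))
  expect_true(all(gc$groups$area_q1 <= gc$groups$area_median &
                    gc$groups$area_median <= gc$groups$area_q3))
})

test_that("edge cells are excluded by default but can be kept", {
  cells <- fake_cells(c("control", "t"), 30, c(0.3, 0.3), c(0.02, 0.02))
  cells$edge[1:10] <- TRUE
  gc <- summarize_groups(cells, "control")
  expect_equal(sum(gc$groups$n_cells), 50)
  gc2 <- summarize_groups(cells, "control", include_edge_cells = TRUE)
  expect_equal(sum(gc2$groups$n_cells), 60)
})

test_that("a missing control group is a hard error", {
  cells <- fake_cells("treated", 10, 0.3, 0.02)
  expect_error(summarize_groups(cells, "control"), "control")
})

test_that("category strings always match the stored delta", {
  cells <- fake_cells(c("control", "t1", "t2"), 200, c(0.3, 0.34, 0.45),
                      c(0.02, 0.021, 0.03), seed = 11)
  gc <- summarize_groups(cells, "control")
  expect_equal(gc$comparisons$category,
               categorize_effect(gc$comparisons$delta))
  expect_equal(gc$comparisons$stars,
               category_stars(gc$comparisons$category))
})

test_that("violin plots render without error", {
  cells <- fake_cells(c("control", "t"), 60, c(0.3, 0.4), c(0.02, 0.025))
  gc <- summarize_groups(cells, "control")
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(gc, "area_um2"))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})
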