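test_that("segmentation recovers generator ground truth across coverages", {
  # battery over seeded scenes spanning sparse attachment to near-confluent
  targets <- seq(0.05, 0.6, length.out = 8)
  for (i in seq_along(targets)) {
    s <- sample_scene(300 + i, target_area_fraction = targets[i],
                      shape = c(256, 256), n_colonies = 8, mean_radius_px = 16)
    img <- render_phase(s$scene, render_spec(noise_sigma = 0.03))
    measured <- cell_area(segment_phase(img))
    expect_lt(abs(measured - s$truth$area_fraction) / s$truth$area_fraction, 0.15)
  }
})

test_that("segmentation handles degenerate and hollow inputs", {
  flat <- matrix(0.5, 128, 128)
  expect_warning(m <- segment_phase(flat), "degenerate")
  expect_equal(cell_area(m), 0)
  # a bright ring with dark interior becomes a filled disc after fill-holes
  img <- matrix(0.4, 128, 128)
  yy <- matrix(1:128, 128, 128); xx <- t(yy)
  d <- sqrt((yy - 64)^2 + (xx - 64)^2)
  img[d <= 30 & d > 26] <- 0.9
  mask <- segment_phase(img, segmentation_params(tophat_radius = 8))
  expect_true(all(mask[d <= 28]))
})

test_that("area and fold arithmetic", {
  expect_equal(cell_area(matrix(FALSE, 4, 4)), 0)
  expect_equal(cell_area(matrix(TRUE, 4, 4)), 1)
  checker <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(cell_area(checker), 0.5)
  expect_error(cell_area(matrix(1, 2, 2)), "logical")
  expect_equal(fold_increase(0.3, 0.1), 3)
  expect_equal(fold_increase(0.1, 0.1), 1)
  expect_equal(fold_increase(0, 0.1), 0)
  expect_error(fold_increase(0.3, 0), "zero")
})

test_that("a 6x-grown scene is recovered within 15% through the full pipeline", {
  s <- sample_scene(31, target_area_fraction = 0.075)
  a0 <- cell_area(segment_phase(render_phase(s$scene)))
  g <- grow_scene(s$scene, 6)
  a1 <- cell_area(segment_phase(render_phase(g)))
  expect_equal(fold_increase(a1, a0), 6, tolerance = 0.15)
})

test_that("measured area is monotone for nested scenes", {
  s <- sample_scene(37, target_area_fraction = 0.1)
  folds <- c(1, 2, 4)
  areas <- vapply(folds, function(f) {
    sc <- grow_scene(s$scene, f)
    cell_area(segment_phase(render_phase(sc)))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("reporter fraction is recovered and edge cases flagged", {
  s <- sample_scene(41, target_area_fraction = 0.2, reporter_fraction = 0.5)
  mask <- segment_phase(render_phase(s$scene))
  fl <- render_fluorescence(s$scene, s$truth)
  expect_equal(sox1_fraction(mask, fl)$fraction, 0.5, tolerance = 0.05)
  # no fluorescence above background
  s0 <- sample_scene(41, target_area_fraction = 0.2, reporter_fraction = 0)
  fl0 <- render_fluorescence(s0$scene, s0$truth)
  expect_lt(sox1_fraction(mask, fl0)$fraction, 0.02)
  # fluorescence mask equal to the phase mask gives 1: render a fully
  # reporter-positive scene
  s1 <- sample_scene(41, target_area_fraction = 0.2, reporter_fraction = 1)
  fl1 <- render_fluorescence(s1$scene, s1$truth, render_spec(noise_sigma = 0))
  expect_equal(sox1_fraction(s1$truth$cell_mask, fl1)$fraction, 1, tolerance = 0.02)
  empty <- matrix(FALSE, 8, 8)
  expect_warning(res <- sox1_fraction(empty, matrix(0.5, 8, 8)), "undefined")
  expect_true(res$undefined)
  expect_error(sox1_fraction(empty, matrix(0.5, 4, 4)), "differ")
})

test_that("condition aggregation follows image -> chamber -> experiment -> mean/sd", {
  one <- data.frame(experiment = 1, chamber = 1, value = 0.3)
  s1 <- aggregate_condition(one)
  expect_equal(s1$mean, 0.3)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 1)
  # hand-computed toy: experiment 1 chambers (0.1,0.2),(0.4) -> exp mean 0.275
  #                    experiment 2 chambers (0.2,0.2),(0.6) -> exp mean 0.40
  #                    experiment 3 chambers (0.3),(0.5)     -> exp mean 0.40
  toy <- data.frame(
    experiment = c(1, 1, 1, 2, 2, 2, 3, 3),
    chamber = c(1, 1, 2, 1, 1, 2, 1, 2),
    value = c(0.1, 0.2, 0.4, 0.2, 0.2, 0.6, 0.3, 0.5)
  )
  s <- aggregate_condition(toy)
  expect_equal(s$per_experiment$value, c(0.275, 0.40, 0.40))
  expect_equal(s$mean, mean(c(0.275, 0.4, 0.4)))
  expect_equal(s$sd, sd(c(0.275, 0.4, 0.4)))
  expect_equal(s$n, 3)
  same <- toy; same$value <- 0.25
  expect_equal(aggregate_condition(same)$sd, 0)
  expect_error(aggregate_condition(data.frame(x = 1)), "columns")
})

test_that("pooled-variance t-test matches the hand formula and the reference", {
  res <- ttest_unpaired_equal_var(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  expect_equal(res$df, 4)
  swap <- ttest_unpaired_equal_var(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)
  same <- ttest_unpaired_equal_var(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  expect_warning(sep <- ttest_unpaired_equal_var(c(2, 2), c(3, 3)), "zero pooled")
  expect_equal(sep$p, 0)
  expect_error(ttest_unpaired_equal_var(1, c(1, 2)), "n >= 2")
  # random battery against the installed reference implementation
  set.seed(123)
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    mine <- ttest_unpaired_equal_var(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})
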