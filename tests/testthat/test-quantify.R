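test_that("stained area counts mask-positive pixels", {
  expect_equal(as.numeric(measure_stained_area(matrix(0, 20, 20))), 0)
  blk <- matrix(0, 30, 30)
  blk[11:20, 11:20] <- 200
  expect_equal(
    as.numeric(measure_stained_area(blk, "fixed", fixed_value = 100)),
    100
  )
})

test_that("stained area recovers planted puncta area within 10% at SNR 5", {
  sc <- generate_scene(scene_params(
    height = 256, width = 256, n_cells = 20,
    condition = "ABI", noise_sd = 8, seed = 71
  ))
  planted <- sum(sc$truth$rendered_green_area)
  measured <- as.numeric(measure_stained_area(sc$channels$green))
  expect_lt(abs(measured - planted) / planted, 0.10)
})

test_that("nucleus counting recovers planted non-touching nuclei", {
  expect_equal(as.integer(count_cells_from_nuclei(matrix(0, 50, 50))), 0)
  sc <- generate_scene(scene_params(
    height = 384, width = 384, n_cells = 30,
    noise_sd = 8, seed = 72
  ))
  expect_equal(as.integer(count_cells_from_nuclei(sc$channels$blue)), 30)
})

test_that("watershed separates two overlapping nuclei blobs", {
  blue <- matrix(0, 48, 48)
  for (cc in list(c(24, 20), c(24, 31))) {
    for (i in 1:48) {
      for (j in 1:48) {
        d2 <- (i - cc[1])^2 + (j - cc[2])^2
        blue[i, j] <- blue[i, j] + 180 * exp(-d2 / (2 * 4^2))
      }
    }
  }
  blue <- pmin(blue, 255)
  expect_equal(as.integer(count_cells_from_nuclei(blue, watershed = TRUE)), 2)
  expect_equal(as.integer(count_cells_from_nuclei(blue, watershed = FALSE)), 1)
})

test_that("area per cell is stained area over cell count, undefined at zero cells", {
  g <- matrix(0, 40, 40)
  g[1:10, 1:10] <- 200 # 100 px^2
  b <- matrix(0, 40, 40)
  for (i in 1:40) {
    for (j in 1:40) {
      for (cc in list(c(10, 30), c(30, 10))) {
        if ((i - cc[1])^2 + (j - cc[2])^2 <= 16) b[i, j] <- 250
      }
    }
  }
  f <- quantify_field(g, b, field_id = 3, condition = "x", threshold_method = "fixed", fixed_value = 100)
  expect_equal(f$stained_area, 100)
  expect_equal(f$cell_count, 2L)
  expect_equal(f$area_per_cell, 50)
  expect_warning(
    f0 <- quantify_field(g, matrix(0, 40, 40), threshold_method = "fixed", fixed_value = 100),
    "zero cells"
  )
  expect_true(is.na(f0$area_per_cell))
  expect_error(quantify_field(g, matrix(0, 2, 2)), "shape")
})

test_that("identical groups give fold 1, t = 0, p = 1", {
  x <- c(3, 5, 8, 2)
  cc <- compare_conditions(x, x)
  expect_equal(cc$fold_change, 1)
  expect_equal(cc$t_statistic, 0)
  expect_equal(cc$p_value, 1)
  # zero variance in both groups with equal means
  cc0 <- compare_conditions(c(4, 4), c(4, 4))
  expect_equal(cc0$t_statistic, 0)
  expect_equal(cc0$p_value, 1)
})

test_that("pooled t and p match the closed form on the worked example", {
  cc <- compare_conditions(c(1, 2, 3), c(2, 4, 6))
  expect_equal(cc$fold_change, 2)
  # hand-evaluated pooled form: sp2 = (1 + 4) / 2, se = sqrt(sp2 * 2/3)
  se <- sqrt((5 / 2) * (2 / 3))
  expect_equal(cc$t_statistic, 2 / se, tolerance = 1e-12)
  expect_equal(cc$p_value, 2 * pt(-2 / se, 4), tolerance = 1e-12)
})

test_that("t and p agree with the reference implementation to 1e-9", {
  withr::with_seed(73, {
    for (i in 1:1000) {
      a <- rnorm(sample(2:8, 1), 10, 3)
      b <- rnorm(sample(2:8, 1), runif(1, 5, 20), 3)
      cc <- compare_conditions(a, b)
      ref <- t.test(b, a, var.equal = TRUE)
      expect_equal(cc$t_statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(cc$p_value, ref$p.value, tolerance = 1e-9)
    }
    # Welch variant against its reference
    for (i in 1:50) {
      a <- rnorm(5, 10, 1)
      b <- rnorm(7, 14, 6)
      cc <- compare_conditions(a, b, var_equal = FALSE)
      ref <- t.test(b, a, var.equal = FALSE)
      expect_equal(cc$t_statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(cc$p_value, ref$p.value, tolerance = 1e-9)
      expect_equal(cc$df, unname(ref$parameter), tolerance = 1e-9)
    }
  })
})

test_that("swapping groups inverts the fold change and negates t", {
  withr::with_seed(74, {
    for (i in 1:20) {
      a <- rnorm(5, 10, 2)
      b <- rnorm(5, 30, 5)
      ab <- compare_conditions(a, b)
      ba <- compare_conditions(b, a)
      expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
      expect_equal(ab$t_statistic, -ba$t_statistic, tolerance = 1e-12)
      expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    }
  })
})

test_that("comparison tidiers and plot work", {
  cc <- compare_conditions(c(1, 2, 3), c(2, 4, 6), labels = c("AB", "ABI"))
  td <- tidy(cc)
  expect_equal(td$condition_b, "ABI")
  expect_equal(glance(cc)$fold_change, 2)
  expect_s3_class(autoplot(cc), "ggplot")
  expect_error(compare_conditions(1, c(2, 3)), ">= 2")
})
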