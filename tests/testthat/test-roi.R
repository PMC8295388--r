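test_that("ROI means are per-label arithmetic means of each channel", {
  labs <- label_components(matrix(c(rep(1L, 4), rep(0L, 4), rep(1L, 4)), 3, 4))
  uniform <- matrix(7, 3, 4)
  out <- extract_roi_means(labs, list(green = uniform))
  expect_true(all(out$mfi_green == 7))
  # one 2x2 ROI with green {0, 0, 10, 10} -> MFI 5
  m <- matrix(0L, 4, 4)
  m[2:3, 2:3] <- 1L
  g <- matrix(0, 4, 4)
  g[2:3, 3] <- 10
  one <- extract_roi_means(label_components(m), list(green = g))
  expect_equal(one$mfi_green, 5)
  expect_equal(one$area, 4)
  expect_equal(one$centroid_row, 1.5) # 0-based centroid of rows 1..2
  expect_equal(one$centroid_col, 1.5)
  expect_error(extract_roi_means(labs, list(green = matrix(0, 2, 2))), "shape")
})

test_that("ROI means match the scalar accumulation oracle on random fields", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      mask <- rand_mask(12, 12, 0.5)
      labs <- label_components(mask)
      ch <- rand_img(12, 12)
      out <- extract_roi_means(labs, list(x = ch))
      for (lab in seq_len(n_components(labs))) {
        px <- which(unclass(labs) == lab)
        tot <- 0
        for (p in px) tot <- tot + ch[p]
        expect_equal(out$mfi_x[out$roi_id == lab], tot / length(px))
      }
    }
  })
  empty <- extract_roi_means(label_components(matrix(0L, 3, 3)), list(g = matrix(0, 3, 3)))
  expect_equal(nrow(empty), 0)
})

test_that("gate thresholds follow their stated definitions", {
  expect_equal(derive_gate_threshold(c(5, 9), "fixed", 100), 100)
  expect_equal(derive_gate_threshold(c(0, 0, 0, 0), "mean_plus_k_sd", 2), 0)
  expect_equal(
    derive_gate_threshold(c(1, 2, 3, 4), "mean_plus_k_sd", 3),
    mean(c(1, 2, 3, 4)) + 3 * sd(c(1, 2, 3, 4))
  )
  # nearest-rank percentile vs sort-and-index oracle
  expect_equal(derive_gate_threshold(1:100, "percentile", 95), 95)
  withr::with_seed(62, {
    for (i in 1:10) {
      v <- runif(sample(5:50, 1), 0, 100)
      p <- runif(1, 1, 99)
      s <- sort(v)
      expect_equal(
        derive_gate_threshold(v, "percentile", p),
        s[ceiling(p / 100 * length(v))]
      )
    }
  })
  expect_error(derive_gate_threshold(numeric(0), "mean_plus_k_sd"), ">= 2")
  expect_error(derive_gate_threshold(1:10, "percentile", 150), "\\[0, 100\\]")
})

test_that("quadrant gating counts strictly-positive cells per channel", {
  rois <- tibble::tibble(mfi_green = c(1, 2, 3), mfi_red = c(1, 1, 2))
  low <- gate_quadrants(rois, 10, 10)
  expect_equal(low$summary$fraction, c(1, 0, 0, 0))
  expect_equal(sum(low$summary$count), low$n_cells)
  # planted disjoint populations: no double positives
  disj <- tibble::tibble(
    mfi_green = c(rep(50, 40), rep(1, 20)),
    mfi_red = c(rep(0, 40), rep(80, 20))
  )
  g <- gate_quadrants(disj, 10, 10)
  expect_equal(g$summary$count[g$summary$quadrant == "G+R+"], 0L)
  expect_equal(g$summary$fraction[g$summary$quadrant == "G+R-"], 40 / 60)
  # boundary values are negative (strict inequality)
  edge <- gate_quadrants(tibble::tibble(mfi_green = 10, mfi_red = 10), 10, 10)
  expect_equal(edge$summary$count[1], 1L)
})

test_that("quadrant fractions match the exhaustive counting oracle and are order-invariant", {
  withr::with_seed(63, {
    rois <- tibble::tibble(
      mfi_green = rexp(1000, 1 / 20),
      mfi_red = rexp(1000, 1 / 15)
    )
    gt <- 25
    rt <- 18
    g <- gate_quadrants(rois, gt, rt)
    counts <- c(0L, 0L, 0L, 0L)
    for (i in seq_len(1000)) {
      gp <- rois$mfi_green[i] > gt
      rp <- rois$mfi_red[i] > rt
      k <- 1L + gp + 2L * rp
      counts[k] <- counts[k] + 1L
    }
    expect_equal(g$summary$count, counts)
    expect_equal(sum(g$summary$fraction), 1, tolerance = 1e-9)
    shuffled <- gate_quadrants(rois[sample(1000), ], gt, rt)
    expect_equal(shuffled$summary$count, g$summary$count)
  })
})

test_that("gating tidiers expose per-quadrant and one-row summaries", {
  rois <- tibble::tibble(mfi_green = c(1, 50), mfi_red = c(0, 0))
  g <- gate_quadrants(rois, 10, 10)
  td <- tidy(g)
  expect_equal(nrow(td), 4)
  gl <- glance(g)
  expect_equal(gl$n_cells, 2L)
  expect_equal(gl$fraction_Gpos_Rneg, 0.5)
  expect_s3_class(autoplot(g), "ggplot")
})
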