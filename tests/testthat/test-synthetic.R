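test_that("scenes are bit-identical when regenerated from the same seed", {
  p <- scene_params(
    height = 160, width = 160, n_cells = 8, noise_sd = 5,
    red_positive_fraction = 0.25, seed = 81
  )
  a <- generate_scene(p)
  b <- generate_scene(p)
  for (ch in names(a$channels)) {
    expect_identical(
      as_pixel_matrix(a$channels[[ch]]),
      as_pixel_matrix(b$channels[[ch]])
    )
  }
  expect_identical(a$truth, b$truth)
})

test_that("an empty scene is background only with an empty truth table", {
  sc <- generate_scene(scene_params(
    height = 64, width = 64, n_cells = 0,
    seed = 82
  ))
  expect_equal(nrow(sc$truth), 0)
  expect_true(all(as_pixel_matrix(sc$channels$green) == 8))
  expect_true(all(as_pixel_matrix(sc$channels$DIC) == 120))
})

test_that("planted green-area totals scale exactly with the condition multiplier", {
  pa <- scene_params(height = 256, width = 256, n_cells = 15, condition = "AB", seed = 83)
  pb <- scene_params(height = 256, width = 256, n_cells = 15, condition = "ABI", seed = 83)
  a <- generate_scene(pa)
  b <- generate_scene(pb)
  expect_equal(
    sum(b$truth$true_green_area) / sum(a$truth$true_green_area),
    20,
    tolerance = 1e-12
  )
  # and cell geometry is unchanged between the two conditions
  expect_equal(a$truth$row, b$truth$row)
  expect_equal(a$truth$radius, b$truth$radius)
})

test_that("rendered puncta area lands within a couple of pixels of the planted target", {
  sc <- generate_scene(scene_params(
    height = 320, width = 320, n_cells = 20,
    condition = "ABI", seed = 84
  ))
  expect_true(all(abs(sc$truth$rendered_green_area - sc$truth$true_green_area) <= 2.5))
})

test_that("cells lie fully inside the frame and respect the distance constraint", {
  p <- scene_params(height = 300, width = 300, n_cells = 12, seed = 85)
  sc <- generate_scene(p)
  tr <- sc$truth
  expect_true(all(tr$row - tr$radius >= 0 & tr$row + tr$radius <= p$height - 1))
  expect_true(all(tr$col - tr$radius >= 0 & tr$col + tr$radius <= p$width - 1))
  d <- as.matrix(dist(cbind(tr$row, tr$col)))
  diag(d) <- Inf
  expect_true(all(d >= p$min_distance - 1e-9))
})

test_that("infeasible packings error after bounded attempts", {
  expect_error(
    generate_scene(scene_params(height = 96, width = 96, n_cells = 40, seed = 86)),
    "infeasible packing"
  )
})

test_that("mutual exclusivity is a hard constraint in the truth table", {
  sc <- generate_scene(scene_params(
    height = 384, width = 384, n_cells = 25,
    condition = "ABI", red_positive_fraction = 0.3,
    mutual_exclusive = TRUE, seed = 87
  ))
  tr <- sc$truth
  expect_true(all(tr$green_class[tr$red_status == "pos"] == "basal"))
  expect_true(all(tr$red_status[tr$green_class == "high"] == "neg"))
  expect_gt(sum(tr$red_status == "pos"), 0)
})

test_that("basal green-area fractions follow the truncated normal law", {
  withr::with_seed(88, {
    mu <- 0.005
    sig <- 0.002
    lo <- 1e-4
    hi <- 0.02
    ptrunc <- function(q) {
      (pnorm((q - mu) / sig) - pnorm((lo - mu) / sig)) /
        (pnorm((hi - mu) / sig) - pnorm((lo - mu) / sig))
    }
    draws <- autophagr:::rtrunc_norm(1e4, mu, sig, lo, hi)
    ks <- suppressWarnings(ks.test(draws, ptrunc))
    expect_gt(ks$p.value, 0.01)
    expect_true(all(draws >= lo & draws <= hi))
  })
  # the law reaches the truth table: pooled cells from several scenes
  fracs <- unlist(lapply(1:6, function(s) {
    sc <- generate_scene(scene_params(
      height = 256, width = 256,
      n_cells = 15, condition = "AB", seed = 880 + s
    ))
    sc$truth$true_green_area / (pi * sc$truth$radius^2)
  }))
  mu <- 0.005
  sig <- 0.002
  lo <- 1e-4
  hi <- 0.02
  ptrunc <- function(q) {
    (pnorm((q - mu) / sig) - pnorm((lo - mu) / sig)) /
      (pnorm((hi - mu) / sig) - pnorm((lo - mu) / sig))
  }
  ks2 <- suppressWarnings(ks.test(fracs, ptrunc))
  expect_gt(ks2$p.value, 0.01)
})

test_that("detection matching is exact on identity and empty cases", {
  tr <- tibble::tibble(row = c(10, 40, 70), col = c(10, 40, 70))
  det <- tibble::tibble(centroid_row = tr$row, centroid_col = tr$col)
  m <- match_detections_to_truth(det, tr, 5)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  none <- match_detections_to_truth(det[0, ], tr, 5)
  expect_equal(none$recall, 0)
  expect_equal(none$f1, 0)
  expect_error(match_detections_to_truth(det, tr, 0), "> 0")
})

test_that("greedy matching is order-invariant and optimal on separated points", {
  withr::with_seed(89, {
    for (rep in 1:10) {
      # truth points pairwise separated by > 2 * match radius
      radius <- 6
      tru <- matrix(numeric(0), 0, 2)
      while (nrow(tru) < 6) {
        cand <- runif(2, 0, 100)
        if (!nrow(tru) || min(sqrt(rowSums(sweep(tru, 2, cand)^2))) > 2 * radius + 1) {
          tru <- rbind(tru, cand)
        }
      }
      keep <- runif(6) < 0.8
      det <- tru[keep, , drop = FALSE] + matrix(runif(2 * sum(keep), -3, 3), ncol = 2)
      spurious <- matrix(runif(4, 0, 100), 2, 2)
      det <- rbind(det, spurious)
      det_tbl <- tibble::tibble(centroid_row = det[, 1], centroid_col = det[, 2])
      tru_tbl <- tibble::tibble(row = tru[, 1], col = tru[, 2])
      m1 <- match_detections_to_truth(det_tbl, tru_tbl, radius)
      m2 <- match_detections_to_truth(det_tbl[sample(nrow(det_tbl)), ], tru_tbl, radius)
      expect_equal(m1$n_matched, m2$n_matched)
      expect_equal(m1$f1, m2$f1)
      expect_equal(m1$n_matched, oracle_match_count(det, tru, radius))
    }
  })
})
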