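test_that("sobel magnitude matches the explicit kernel convolution", {
  expect_equal(as.vector(sobel_edges(matrix(9, 4, 4))), rep(0, 16))
  # vertical step: maximal response on the two columns adjoining the step
  step <- cbind(matrix(0, 6, 3), matrix(255, 6, 3))
  s <- as_pixel_matrix(sobel_edges(step))
  expect_true(all(s[, 3:4] == 4 * 255))
  expect_true(all(s[, c(1, 2, 5, 6)] == 0))
  withr::with_seed(5, {
    for (i in 1:25) {
      m <- rand_img(5, 7)
      expect_identical(as_pixel_matrix(sobel_edges(m)), oracle_sobel(m))
    }
  })
  expect_error(sobel_edges(matrix(0, 2, 5)), "3x3")
})

test_that("smooth_mean3 is the edge-replicated 3x3 mean", {
  expect_equal(as_pixel_matrix(smooth_mean3(matrix(4, 3, 3))), matrix(4, 3, 3))
  spot <- matrix(0, 5, 5)
  spot[3, 3] <- 9
  sm <- as_pixel_matrix(smooth_mean3(spot))
  expect_equal(sm[2:4, 2:4], matrix(1, 3, 3))
  expect_equal(sm[1, 1], 0)
  withr::with_seed(6, {
    for (i in 1:25) {
      m <- rand_img(6, 6)
      expect_identical(as_pixel_matrix(smooth_mean3(m)), oracle_smooth(m))
    }
  })
})

test_that("rank filter with radius 0 is the identity for both modes", {
  withr::with_seed(8, {
    for (i in 1:10) {
      m <- rand_img(7, 9)
      expect_identical(as_pixel_matrix(rank_filter(m, se_disk(0), "min")), m + 0)
      expect_identical(as_pixel_matrix(rank_filter(m, se_disk(0), "max")), m + 0)
    }
  })
})

test_that("max filter with a radius-1 disk spreads a point into the 5-pixel cross", {
  m <- matrix(0, 7, 7)
  m[4, 4] <- 10
  out <- as_pixel_matrix(rank_filter(m, se_disk(1), "max"))
  expect_equal(sum(out > 0), 5)
  expect_equal(out[4, 3:5], c(10, 10, 10))
  expect_equal(out[3, 4], 10)
  expect_equal(out[5, 4], 10)
  expect_equal(out[3, 3], 0) # diagonals excluded at radius 1
})

test_that("rank filters match the exhaustive neighborhood scan", {
  withr::with_seed(9, {
    for (i in 1:20) {
      m <- rand_img(8, 8)
      for (se in list(se_disk(2), se_disk(5), se_square(1))) {
        expect_identical(
          as_pixel_matrix(rank_filter(m, se, "min")),
          oracle_rank(m, se$offsets, min)
        )
        expect_identical(
          as_pixel_matrix(rank_filter(m, se, "max")),
          oracle_rank(m, se$offsets, max)
        )
      }
    }
  })
})

test_that("fast disk path equals the offset loop at large radii", {
  withr::with_seed(10, {
    for (i in 1:5) {
      m <- rand_img(20, 31)
      for (r in c(8, 10.5)) {
        offs <- se_disk(r)$offsets
        expect_identical(rank_disk_fast(m + 0, r, pmin), oracle_rank(m, offs, min))
        expect_identical(rank_disk_fast(m + 0, r, pmax), oracle_rank(m, offs, max))
      }
    }
  })
})

test_that("min/max duality holds: min(x) == M - max(M - x)", {
  withr::with_seed(12, {
    for (i in 1:10) {
      m <- rand_img(9, 9)
      for (se in list(se_disk(2), se_square(2))) {
        lhs <- as_pixel_matrix(rank_filter(m, se, "min"))
        rhs <- 255 - as_pixel_matrix(rank_filter(255 - m, se, "max"))
        expect_identical(lhs, rhs)
      }
    }
  })
})

test_that("filters are translation-equivariant away from borders", {
  withr::with_seed(13, {
    m <- rand_img(12, 12)
    shifted <- matrix(0L, 13, 13)
    shifted[2:13, 2:13] <- m
    ops <- list(
      function(x) as_pixel_matrix(sobel_edges(x)),
      function(x) as_pixel_matrix(smooth_mean3(x)),
      function(x) as_pixel_matrix(rank_filter(x, se_disk(2), "max")),
      function(x) as_pixel_matrix(rank_filter(x, se_disk(2), "min"))
    )
    for (op in ops) {
      a <- op(m)
      b <- op(shifted)
      # compare interiors (3 px margin clears every kernel involved)
      expect_identical(a[4:9, 4:9], b[5:10, 5:10])
    }
  })
})

test_that("rolling-ball subtraction flattens background and keeps small peaks", {
  flat <- matrix(37, 10, 10)
  expect_equal(as.vector(subtract_background(flat, 3)), rep(0, 100))
  # small bright spot on flat background survives at its original height
  spot <- matrix(20, 15, 15)
  spot[8, 8] <- 120
  out <- as_pixel_matrix(subtract_background(spot, 4))
  expect_equal(out[8, 8], 100)
  expect_equal(sum(out != 0), 1)
  # ramp + spot: matches the explicit opening oracle, ramp suppressed
  withr::with_seed(14, {
    ramp <- matrix(rep(seq(0, 50, length.out = 12), each = 12), 12, 12)
    ramp[6, 6] <- ramp[6, 6] + 80
    offs <- se_disk(3)$offsets
    bg <- oracle_rank(oracle_rank(ramp, offs, min), offs, max)
    expect_identical(
      as_pixel_matrix(subtract_background(ramp, 3)),
      pmax(ramp - bg, 0)
    )
    out2 <- as_pixel_matrix(subtract_background(ramp, 3))
    expect_gt(out2[6, 6], 75)
  })
  # fixed-offset variant
  expect_equal(
    as.vector(subtract_background(matrix(c(10, 60), 2, 2), method = "fixed", offset = 50)),
    c(0, 10, 0, 10)
  )
})
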