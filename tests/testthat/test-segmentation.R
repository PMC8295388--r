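test_that("a blank field segments to zero ROIs with a warning", {
  expect_warning(
    labs <- segment_dic(matrix(100, 64, 64)),
    "zero ROIs"
  )
  expect_equal(n_components(labs), 0)
})

test_that("well-separated cells are recovered with centroids near planted centers", {
  sc <- generate_scene(scene_params(n_cells = 20, seed = 111))
  labs <- segment_dic(sc$channels$DIC, segmentation_params(min_area = 200))
  rois <- extract_roi_means(labs)
  expect_true(abs(nrow(rois) - 20) <= 1)
  m <- match_detections_to_truth(rois, sc$truth, match_radius = 5)
  expect_equal(m$recall, 1)
})

test_that("segmentation accepts an RGB triple for the DIC channel", {
  sc <- generate_scene(scene_params(
    height = 192, width = 192, n_cells = 5,
    seed = 112
  ))
  dic <- as_pixel_matrix(sc$channels$DIC)
  rgb <- list(dic, dic, dic)
  a <- segment_dic(rgb, segmentation_params(min_area = 200))
  b <- segment_dic(dic, segmentation_params(min_area = 200))
  expect_equal(n_components(a), n_components(b))
  expect_true(any(grepl("rgb_to_gray", attr(a, "log"))))
})

test_that("watershed splitting never lowers the ROI count on touching pairs", {
  sc <- generate_scene(scene_params(
    n_cells = 20, seed = 113,
    touching_fraction = 0.3
  ))
  with_ws <- segment_dic(
    sc$channels$DIC,
    segmentation_params(min_area = 200, watershed = TRUE)
  )
  without_ws <- segment_dic(
    sc$channels$DIC,
    segmentation_params(min_area = 200, watershed = FALSE)
  )
  expect_gte(n_components(with_ws), n_components(without_ws))
  expect_gt(n_components(with_ws), 0)
})

test_that("raising min_area never increases the ROI count", {
  sc <- generate_scene(scene_params(
    height = 256, width = 256, n_cells = 10,
    noise_sd = 8, seed = 114
  ))
  counts <- vapply(c(0, 50, 200, 500, 1200), function(a) {
    labs <- suppressWarnings(
      segment_dic(sc$channels$DIC, segmentation_params(min_area = a))
    )
    n_components(labs)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the segmentation log records every stage and the radius-0 no-op", {
  sc <- generate_scene(scene_params(
    height = 160, width = 160, n_cells = 4,
    seed = 115
  ))
  labs <- segment_dic(sc$channels$DIC, segmentation_params(min_area = 200))
  log <- attr(labs, "log")
  for (stage in c(
    "equalize_histogram", "sobel_edges", "rank_filter",
    "smooth_mean3", "to_8bit", "subtract_background",
    "auto_threshold", "gray_morphology", "binary_watershed",
    "label_components"
  )) {
    expect_true(any(grepl(stage, log)))
  }
  expect_true(any(grepl("no-op", log)))
})
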