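#' Parameters of the synthetic macrophage-field generator
#'
#' Describes one simulated field of adherent macrophages at x10
#' magnification: cell number and size, the condition preset governing the
#' planted per-cell autophagosome (green) area, the red-reporter-positive
#' subpopulation, background and noise. Condition presets scale a basal
#' per-cell green-area fraction: `"AB"` (basal, x1), `"ABI"` (strong
#' induction, x20), `"AB+CQ"` (lysosomal block on basal flux, x10) and
#' `"ABI+CQ"` (block on induced flux, x3 over `"ABI"`, i.e. x60 basal);
#' `"custom"` uses `green_multiplier` directly. These presets mirror the
#' fold enrichments the analysis is designed to detect; they are emulation
#' targets, not measured truths. Per-cell green-area fractions follow a
#' truncated normal law scaled by the condition multiplier, so two scenes
#' generated from the same seed under different conditions have planted
#' total green areas in exactly the ratio of their multipliers.
#'
#' @param height,width Field size in px.
#' @param n_cells Number of cells (>= 0).
#' @param cell_radius_mean,cell_radius_sd Cell radius law (px), truncated
#'   to `[cell_radius_mean/2, 1.5 * cell_radius_mean]`.
#' @param condition `"AB"`, `"ABI"`, `"AB+CQ"`, `"ABI+CQ"` or `"custom"`.
#' @param green_multiplier Multiplier applied to the basal green-area
#'   fraction when `condition = "custom"`.
#' @param basal_green_fraction_mean,basal_green_fraction_sd Basal per-cell
#'   green-area fraction law (fraction of the cell footprint), truncated
#'   to `[1e-4, 0.02]` before scaling.
#' @param red_positive_fraction Fraction of cells carrying the red
#'   reporter, in `[0, 1]`.
#' @param mutual_exclusive Force red-positive cells to basal green and
#'   green-high cells to zero red (the structure observed in infected
#'   fields)?
#' @param dic_background,fluor_background Background levels (a.u.).
#' @param background_gradient Amplitude of a linear left-to-right
#'   illumination ramp added to every channel (a.u.).
#' @param relief_amplitude Amplitude of the DIC relief shading (a.u.);
#'   the reference signal for signal-to-noise ratios.
#' @param texture_sd Intracellular DIC texture (a.u.), part of the cell
#'   rendering (present even in noise-free scenes).
#' @param green_amplitude,blue_amplitude,red_amplitude Fluorophore
#'   intensities above background (a.u.).
#' @param nucleus_radius_frac Nucleus radius as a fraction of the cell
#'   radius.
#' @param min_distance Minimum center-to-center distance between cells
#'   (px). The default, `2 * cell_radius_mean + 20`, keeps typical cells
#'   at least 20 px apart edge to edge.
#' @param touching_fraction Fraction of cells placed as touching pairs
#'   (partner centers at 0.95 of the sum of radii), overriding the
#'   minimum-distance constraint within each pair.
#' @param noise_sd Gaussian noise added to every channel last (a.u.).
#' @param poisson Apply Poisson resampling (shot noise) to each channel?
#' @param seed Integer seed; the whole scene is reproducible from it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(height = 384, width = 384, n_cells = 25,
                         cell_radius_mean = 12, cell_radius_sd = 2,
                         condition = c("AB", "ABI", "AB+CQ", "ABI+CQ", "custom"),
                         green_multiplier = 1,
                         basal_green_fraction_mean = 0.005,
                         basal_green_fraction_sd = 0.002,
                         red_positive_fraction = 0,
                         mutual_exclusive = TRUE,
                         dic_background = 120, fluor_background = 8,
                         background_gradient = 0,
                         relief_amplitude = 40, texture_sd = 25,
                         green_amplitude = 150, blue_amplitude = 180,
                         red_amplitude = 120,
                         nucleus_radius_frac = 0.35,
                         min_distance = NULL, touching_fraction = 0,
                         noise_sd = 0, poisson = FALSE, seed = NULL) {
  condition <- match.arg(condition)
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  if (cell_radius_mean <= 0) stop("cell radius must be > 0", call. = FALSE)
  if (red_positive_fraction < 0 || red_positive_fraction > 1) {
    stop("`red_positive_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (touching_fraction < 0 || touching_fraction > 1) {
    stop("`touching_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (is.null(min_distance)) min_distance <- 2 * cell_radius_mean + 20
  structure(
    list(
      height = height, width = width, n_cells = n_cells,
      cell_radius_mean = cell_radius_mean, cell_radius_sd = cell_radius_sd,
      condition = condition, green_multiplier = green_multiplier,
      basal_green_fraction_mean = basal_green_fraction_mean,
      basal_green_fraction_sd = basal_green_fraction_sd,
      red_positive_fraction = red_positive_fraction,
      mutual_exclusive = mutual_exclusive,
      dic_background = dic_background, fluor_background = fluor_background,
      background_gradient = background_gradient,
      relief_amplitude = relief_amplitude, texture_sd = texture_sd,
      green_amplitude = green_amplitude, blue_amplitude = blue_amplitude,
      red_amplitude = red_amplitude,
      nucleus_radius_frac = nucleus_radius_frac,
      min_distance = min_distance, touching_fraction = touching_fraction,
      noise_sd = noise_sd, poisson = poisson, seed = seed
    ),
    class = "scene_params"
  )
}

#' Green-area multiplier of a condition preset
#'
#' @param condition Condition label (see [scene_params()]).
#' @param green_multiplier Multiplier used for `"custom"`.
#' @return A single number.
#' @export
condition_green_multiplier <- function(condition, green_multiplier = 1) {
  switch(condition,
    "AB" = 1, "ABI" = 20, "AB+CQ" = 10, "ABI+CQ" = 60,
    "custom" = green_multiplier,
    stop("unknown condition `", condition, "`", call. = FALSE)
  )
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# Rejection-sample cell centers (1-based, fractional) honoring the margin
# and minimum-distance constraints; touching pairs override the distance
# rule within the pair.
place_cells <- function(p, radii) {
  n <- p$n_cells
  rows <- numeric(n)
  cols <- numeric(n)
  partner_of <- rep(NA_integer_, n)
  n_pairs <- floor(p$touching_fraction * n / 2)
  pair_second <- if (n_pairs > 0) seq_len(n_pairs) * 2L else integer(0)
  max_tries <- 2000L * max(n, 1L)
  tries <- 0L
  for (i in seq_len(n)) {
    margin <- radii[i] + 1
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("infeasible packing: could not place ", n, " cells after ",
          max_tries, " attempts",
          call. = FALSE
        )
      }
      if (i %in% pair_second) {
        j <- i - 1L
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- 0.95 * (radii[i] + radii[j])
        ri <- rows[j] + dist * sin(ang)
        ci <- cols[j] + dist * cos(ang)
        if (ri < margin + 1 || ri > p$height - margin ||
          ci < margin + 1 || ci > p$width - margin) {
          next
        }
        others <- setdiff(seq_len(i - 1L), j)
      } else {
        ri <- stats::runif(1, margin + 1, p$height - margin)
        ci <- stats::runif(1, margin + 1, p$width - margin)
        others <- seq_len(i - 1L)
      }
      if (length(others)) {
        d2 <- (rows[others] - ri)^2 + (cols[others] - ci)^2
        if (min(d2) < p$min_distance^2) next
      }
      rows[i] <- ri
      cols[i] <- ci
      if (i %in% pair_second) partner_of[i] <- i - 1L
      break
    }
  }
  list(rows = rows, cols = cols, partner_of = partner_of)
}

# Rasterize puncta for one cell until the union of punctum pixels reaches
# the target area; returns linear indices into the field.
render_puncta <- function(target, c_row, c_col, radius, height, width) {
  taken <- integer(0)
  if (target < 0.5) {
    return(taken)
  }
  punct_radii <- c(1.5, 2)
  punct_areas <- c(9, 13)
  guard <- 0L
  while (length(taken) + 6.5 < target && guard < 400L) {
    guard <- guard + 1L
    ok_sizes <- which(punct_areas <= target - length(taken) + 2)
    k <- if (length(ok_sizes)) sample(length(ok_sizes), 1L) else 1L
    pr <- punct_radii[k]
    d <- stats::runif(1, 0.25, 0.72) * radius
    ang <- stats::runif(1, 0, 2 * pi)
    pr_row <- c_row + d * sin(ang)
    pr_col <- c_col + d * cos(ang)
    ir <- seq.int(max(1, floor(pr_row - pr)), min(height, ceiling(pr_row + pr)))
    ic <- seq.int(max(1, floor(pr_col - pr)), min(width, ceiling(pr_col + pr)))
    grid <- expand.grid(i = ir, j = ic)
    inside <- (grid$i - pr_row)^2 + (grid$j - pr_col)^2 <= pr^2
    idx <- (grid$j[inside] - 1L) * height + grid$i[inside]
    taken <- union(taken, idx)
  }
  # top up pixel by pixel, accreting onto existing puncta so every planted
  # pixel belongs to a resolvable blob, until within a pixel of the target
  guard <- 0L
  while (length(taken) + 0.5 < target && guard < 400L) {
    guard <- guard + 1L
    if (!length(taken)) {
      d <- stats::runif(1, 0.25, 0.72) * radius
      ang <- stats::runif(1, 0, 2 * pi)
      i <- round(c_row + d * sin(ang))
      j <- round(c_col + d * cos(ang))
      if (i < 1 || i > height || j < 1 || j > width) next
      taken <- (j - 1L) * height + i
      next
    }
    p <- taken[sample.int(length(taken), 1L)]
    i <- (p - 1L) %% height + 1L
    j <- (p - 1L) %/% height + 1L
    step <- sample(4L, 1L)
    i <- i + c(-1L, 1L, 0L, 0L)[step]
    j <- j + c(0L, 0L, -1L, 1L)[step]
    if (i < 1 || i > height || j < 1 || j > width) next
    cand <- (j - 1L) * height + i
    if (!cand %in% taken) taken <- c(taken, cand)
  }
  taken
}

#' Generate a synthetic multi-channel macrophage field
#'
#' Renders one field with planted ground truth. Cells are placed by
#' rejection sampling under a minimum-distance constraint (optionally with
#' touching pairs). The DIC channel renders each cell as a relief-shaded
#' disk (a directional intensity ramp plus intracellular texture) so that
#' Sobel edge detection produces closed outlines; the blue channel holds
#' Gaussian nucleus blobs; the green channel holds perinuclear puncta
#' whose union area per cell meets the planted green-area target to within
#' a couple of pixels; the red channel is a whole-cell fill for
#' reporter-positive cells. With `mutual_exclusive` on, red-positive cells
#' are forced to basal green and green-high cells carry no red. Background,
#' gradient and noise are applied last; every stochastic choice is drawn
#' from one seeded stream in a fixed order, so scenes are reproducible
#' from the seed.
#'
#' @param params A [scene_params()] object.
#' @return A list of class `synthetic_scene` with elements `channels`
#'   (named list of `image_plane`s: `DIC`, `blue`, `green`, `red`),
#'   `truth` (tibble: `cell_id`, 0-based `row`/`col` center, `radius`,
#'   nucleus center and radius, planted `true_green_area` px^2, rendered
#'   `rendered_green_area` px^2, `green_class`, `red_status`,
#'   `touching_partner`) and `params`.
#' @export
#'
#' @examples
#' sc <- generate_scene(scene_params(
#'   height = 128, width = 128,
#'   n_cells = 3, seed = 7
#' ))
#' sc$truth
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  run <- function() {
    h <- p$height
    w <- p$width
    n <- p$n_cells
    dic <- matrix(0, h, w)
    blue <- matrix(0, h, w)
    green <- matrix(0, h, w)
    red <- matrix(0, h, w)
    mult <- condition_green_multiplier(p$condition, p$green_multiplier)
    if (n > 0) {
      radii <- rtrunc_norm(
        n, p$cell_radius_mean, p$cell_radius_sd,
        p$cell_radius_mean / 2, 1.5 * p$cell_radius_mean
      )
      pos <- place_cells(p, radii)
      n_red <- round(p$red_positive_fraction * n)
      red_pos <- rep(FALSE, n)
      if (n_red > 0) red_pos[sample.int(n, n_red)] <- TRUE
      base_frac <- rtrunc_norm(
        n, p$basal_green_fraction_mean,
        p$basal_green_fraction_sd, 1e-4, 0.02
      )
      cell_mult <- rep(mult, n)
      if (isTRUE(p$mutual_exclusive)) cell_mult[red_pos] <- 1
      target_area <- cell_mult * base_frac * pi * radii^2
      rendered <- numeric(n)
      rows_idx <- matrix(seq_len(h), h, w)
      cols_idx <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (i in seq_len(n)) {
        cr <- pos$rows[i]
        cc <- pos$cols[i]
        r <- radii[i]
        ir <- seq.int(max(1, floor(cr - r - 1)), min(h, ceiling(cr + r + 1)))
        ic <- seq.int(max(1, floor(cc - r - 1)), min(w, ceiling(cc + r + 1)))
        sub_r <- rows_idx[ir, ic]
        sub_c <- cols_idx[ir, ic]
        d2 <- (sub_r - cr)^2 + (sub_c - cc)^2
        inside <- d2 <= r^2
        lin <- (as.vector(sub_c[inside]) - 1L) * h + as.vector(sub_r[inside])
        # DIC relief: directional ramp across the cell plus texture
        u <- ((sub_r - cr) + (sub_c - cc))[inside] / (sqrt(2) * r)
        dic[lin] <- dic[lin] + p$relief_amplitude * u +
          stats::rnorm(length(lin), 0, p$texture_sd)
        # nucleus blob
        nr <- max(3.5, p$nucleus_radius_frac * r)
        sigma <- nr / 1.2
        blue[lin] <- blue[lin] +
          p$blue_amplitude * exp(-d2[inside] / (2 * sigma^2))
        # red reporter fill
        if (red_pos[i]) red[lin] <- red[lin] + p$red_amplitude
        # green puncta
        punct <- render_puncta(target_area[i], cr, cc, r, h, w)
        green[punct] <- p$green_amplitude
        rendered[i] <- length(punct)
      }
      truth <- tibble::tibble(
        cell_id = seq_len(n),
        row = pos$rows - 1, col = pos$cols - 1, # 0-based centers
        radius = radii,
        nucleus_row = pos$rows - 1, nucleus_col = pos$cols - 1,
        nucleus_radius = pmax(3.5, p$nucleus_radius_frac * radii),
        true_green_area = target_area,
        rendered_green_area = rendered,
        green_class = ifelse(cell_mult > 1, "high", "basal"),
        red_status = ifelse(red_pos, "pos", "neg"),
        touching_partner = pos$partner_of
      )
    } else {
      truth <- tibble::tibble(
        cell_id = integer(0), row = numeric(0), col = numeric(0),
        radius = numeric(0), nucleus_row = numeric(0),
        nucleus_col = numeric(0), nucleus_radius = numeric(0),
        true_green_area = numeric(0), rendered_green_area = numeric(0),
        green_class = character(0), red_status = character(0),
        touching_partner = integer(0)
      )
    }
    grad <- if (p$background_gradient != 0) {
      matrix(
        rep(seq(0, p$background_gradient, length.out = w), each = h), h, w
      )
    } else {
      0
    }
    finish <- function(m, bg, channel) {
      m <- m + bg + grad
      if (p$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, p$noise_sd)
      if (isTRUE(p$poisson)) {
        m <- matrix(stats::rpois(length(m), pmax(m, 0)), nrow(m), ncol(m))
      }
      image_plane(pmin(pmax(m, 0), 255), bit_depth = 8, channel = channel)
    }
    channels <- list(
      DIC = finish(dic, p$dic_background, "DIC"),
      blue = finish(blue, p$fluor_background, "blue"),
      green = finish(green, p$fluor_background, "green"),
      red = finish(red, p$fluor_background, "red")
    )
    structure(list(channels = channels, truth = truth, params = p),
      class = "synthetic_scene"
    )
  }
  if (!is.null(p$seed)) {
    withr::with_seed(p$seed, run())
  } else {
    run()
  }
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px, %d cell(s), condition %s\n",
    x$params$height, x$params$width, nrow(x$truth), x$params$condition
  ))
  invisible(x)
}

#' Score detections against planted ground truth
#'
#' One-to-one matching of detected centroids to planted cell centers:
#' candidate pairs within `match_radius` are accepted greedily in order of
#' increasing distance, each detection and each truth center matching at
#' most once (globally greedy, hence invariant to the order of the
#' detections). Precision, recall and F1 follow the standard definitions.
#'
#' @param detections Data frame with `centroid_row` / `centroid_col`
#'   columns (as from [extract_roi_means()]), 0-based px.
#' @param truth Ground-truth table with `row` / `col` columns (as from
#'   [generate_scene()]).
#' @param match_radius Maximum center distance for a match (px), > 0.
#' @return A one-row tibble: `n_truth`, `n_detected`, `n_matched`,
#'   `precision`, `recall`, `f1`.
#' @export
match_detections_to_truth <- function(detections, truth, match_radius) {
  if (match_radius <= 0) stop("`match_radius` must be > 0", call. = FALSE)
  nd <- nrow(detections)
  nt <- nrow(truth)
  n_matched <- 0L
  if (nd > 0 && nt > 0) {
    dmat <- sqrt(
      outer(detections$centroid_row, truth$row, "-")^2 +
        outer(detections$centroid_col, truth$col, "-")^2
    )
    cand <- which(dmat <= match_radius, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]
        j <- cand[k, 2L]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE
          used_t[j] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  precision <- if (nd > 0) n_matched / nd else NA_real_
  recall <- if (nt > 0) n_matched / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble::tibble(
    n_truth = nt, n_detected = nd, n_matched = n_matched,
    precision = precision, recall = recall, f1 = f1
  )
}
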