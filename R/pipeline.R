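#' Run an end-to-end analysis
#'
#' Ties the stages into the two field analyses, optionally preceded by
#' simulation:
#'
#' * `"single_cell"` — single-cell infection analysis: segment each composite
#'   tile from the DIC channel, extract per-ROI mean green/red
#'   fluorescence (ROI coordinates mapped back to the composite frame via
#'   tile offsets), derive gates and quadrant-gate the pooled cells.
#'   Writes `rois.csv` and `quadrants.csv`.
#' * `"field_quant"` — per-field autophagy quantification: total green stained
#'   area, nucleus count and area per cell for every field of each of two
#'   conditions, followed by the between-condition fold change and
#'   two-tailed unpaired t-test. Writes `fields.csv` and
#'   `comparison.csv`.
#' * `"simulate+single_cell"` / `"simulate+field_quant"` — generate the input scenes
#'   from `config$scene` (deterministically from `config$seed`) before
#'   running the analysis.
#'
#' Every parameter actually used is echoed to `run_log.yaml` in the output
#' directory, and identical config + seed give byte-identical CSV outputs.
#'
#' @param config A [run_config()].
#' @param mode One of `"single_cell"`, `"field_quant"`, `"simulate+single_cell"`,
#'   `"simulate+field_quant"`.
#' @param input_dir Directory of channel TIFFs (non-simulated modes; see
#'   [read_scene_channels()]). For `"field_quant"`, a directory with
#'   subdirectories `a/` and `b/`, one scene directory per replicate
#'   field.
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config, mode = c(
                           "single_cell", "field_quant",
                           "simulate+single_cell", "simulate+field_quant"
                         ),
                         input_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  simulate <- startsWith(mode, "simulate")
  analysis <- sub("^simulate\\+", "", mode)
  if (!simulate) {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("`input_dir` must point to an existing directory for mode ",
        mode,
        call. = FALSE
      )
    }
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seg_params <- do.call(
    segmentation_params,
    utils::modifyList(list(min_area = 200), config$segmentation)
  )
  log <- list(
    mode = mode, seed = config$seed,
    segmentation = unclass(seg_params), quant = config$quant,
    gate = config$gate, layout = config$layout
  )
  result <- list()

  if (analysis == "single_cell") {
    channels <- if (simulate) {
      sp <- do.call(
        scene_params,
        utils::modifyList(config$scene, list(seed = config$seed))
      )
      scene <- generate_scene(sp)
      write_scene(scene, file.path(out_dir, "scene"))
      log$scene <- unclass(sp)
      result$scene <- scene
      scene$channels
    } else {
      read_scene_channels(input_dir)
    }
    if (is.null(channels$DIC) || is.null(channels$green) ||
      is.null(channels$red)) {
      stop("single_cell needs DIC, green and red channels", call. = FALSE)
    }
    layout <- composite_layout(config$layout[1], config$layout[2])
    dic_tiles <- split_composite(channels$DIC, layout)
    green_tiles <- split_composite(channels$green, layout)
    red_tiles <- split_composite(channels$red, layout)
    rois <- purrr::map_dfr(seq_len(nrow(dic_tiles)), function(k) {
      labs <- segment_dic(dic_tiles$tile[[k]], seg_params)
      r <- extract_roi_means(labs, list(
        green = green_tiles$tile[[k]],
        red = red_tiles$tile[[k]]
      ))
      r$tile_id <- dic_tiles$tile_id[k]
      r$centroid_row <- r$centroid_row + dic_tiles$row_offset[k]
      r$centroid_col <- r$centroid_col + dic_tiles$col_offset[k]
      r
    })
    rois$roi_id <- seq_len(nrow(rois))
    gate_cfg <- config$gate
    g_thr <- gate_cfg$green_threshold
    r_thr <- gate_cfg$red_threshold
    method <- gate_cfg$method %||% "mean_plus_k_sd"
    k_or_p <- gate_cfg$k_or_p %||% 3
    if (is.null(g_thr)) {
      g_thr <- derive_gate_threshold(rois$mfi_green, method, k_or_p)
    }
    if (is.null(r_thr)) {
      r_thr <- derive_gate_threshold(rois$mfi_red, method, k_or_p)
    }
    gating <- gate_quadrants(rois, g_thr, r_thr)
    log$gate_used <- list(green_threshold = g_thr, red_threshold = r_thr)
    readr::write_csv(rois, file.path(out_dir, "rois.csv"))
    readr::write_csv(tidy(gating), file.path(out_dir, "quadrants.csv"))
    result$rois <- rois
    result$gating <- gating
    result$files <- file.path(out_dir, c("rois.csv", "quadrants.csv"))
  } else { # field_quant
    quant_args <- config$quant
    quantify_dir <- function(dir, condition, field_id) {
      ch <- read_scene_channels(dir)
      if (is.null(ch$green) || is.null(ch$blue)) {
        stop("field_quant needs green and blue channels in ", dir, call. = FALSE)
      }
      do.call(quantify_field, c(
        list(ch$green, ch$blue, field_id = field_id, condition = condition),
        quant_args
      ))
    }
    if (simulate) {
      cmp <- config$compare
      cond_a <- cmp$condition_a %||% "AB"
      cond_b <- cmp$condition_b %||% "ABI"
      n_rep <- cmp$n_replicates %||% 5L
      log$compare <- list(
        condition_a = cond_a, condition_b = cond_b,
        n_replicates = n_rep
      )
      one <- function(cond, mult, rep_i, offset) {
        ov <- list(condition = cond, seed = config$seed + offset + rep_i)
        if (!is.null(mult)) {
          ov$condition <- "custom"
          ov$green_multiplier <- mult
        }
        sp <- do.call(scene_params, utils::modifyList(config$scene, ov))
        sc <- generate_scene(sp)
        do.call(quantify_field, c(
          list(sc$channels$green, sc$channels$blue,
            field_id = rep_i, condition = cond
          ),
          quant_args
        ))
      }
      fields <- dplyr::bind_rows(
        purrr::map_dfr(seq_len(n_rep), function(i) {
          one(cond_a, cmp$green_multiplier_a, i, 0L)
        }),
        purrr::map_dfr(seq_len(n_rep), function(i) {
          one(cond_b, cmp$green_multiplier_b, i, 1000L)
        })
      )
      cond_levels <- c(cond_a, cond_b)
    } else {
      dirs_a <- list.dirs(file.path(input_dir, "a"), recursive = FALSE)
      dirs_b <- list.dirs(file.path(input_dir, "b"), recursive = FALSE)
      if (!length(dirs_a) || !length(dirs_b)) {
        stop("field_quant needs replicate scene directories under a/ and b/",
          call. = FALSE
        )
      }
      fields <- dplyr::bind_rows(
        purrr::imap_dfr(dirs_a, function(d, i) quantify_dir(d, "a", i)),
        purrr::imap_dfr(dirs_b, function(d, i) quantify_dir(d, "b", i))
      )
      cond_levels <- c("a", "b")
    }
    comparison <- compare_conditions(
      fields$area_per_cell[fields$condition == cond_levels[1]],
      fields$area_per_cell[fields$condition == cond_levels[2]],
      labels = cond_levels
    )
    readr::write_csv(fields, file.path(out_dir, "fields.csv"))
    readr::write_csv(tidy(comparison), file.path(out_dir, "comparison.csv"))
    result$fields <- fields
    result$comparison <- comparison
    result$files <- file.path(out_dir, c("fields.csv", "comparison.csv"))
  }
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  result$log <- log
  result$log_file <- file.path(out_dir, "run_log.yaml")
  invisible(result)
}
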