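#' Run configuration
#'
#' A plain-text-serializable bundle of every parameter a pipeline run uses:
#' the segmentation parameters, scene-generator parameters (for simulated
#' runs), quantification and gating settings, the composite tile layout,
#' the seed and the output directory. Unknown keys in any section are
#' rejected by name, and a config round-trips losslessly through its
#' on-disk YAML representation.
#'
#' @param seed Integer seed used for every stochastic step of a run.
#' @param out_dir Output directory for run artifacts.
#' @param segmentation Named list of [segmentation_params()] overrides.
#'   The packaged field analyses default to `min_area = 200` px^2, the
#'   particle window suited to macrophages at x10.
#' @param scene Named list of [scene_params()] overrides (simulated runs).
#' @param gate Named list: `method`, `k_or_p` (see
#'   [derive_gate_threshold()]), or fixed `green_threshold` /
#'   `red_threshold`.
#' @param quant Named list: `threshold_method`, `fixed_value`,
#'   `min_area`, `max_area` for [quantify_field()].
#' @param layout `c(rows, cols)` tile grid of composite inputs.
#' @param compare Named list for two-condition runs: `condition_a`,
#'   `condition_b`, `n_replicates`, optional `green_multiplier_a` /
#'   `green_multiplier_b`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("autophagr_run_"),
                       segmentation = list(), scene = list(),
                       gate = list(), quant = list(),
                       layout = c(1L, 1L),
                       compare = list()) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown ", section, " config key(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    x
  }
  segmentation <- check_keys(
    segmentation, names(formals(segmentation_params)), "segmentation"
  )
  scene <- check_keys(scene, names(formals(scene_params)), "scene")
  gate <- check_keys(
    gate, c("method", "k_or_p", "green_threshold", "red_threshold"), "gate"
  )
  quant <- check_keys(
    quant, c("threshold_method", "fixed_value", "min_area", "max_area"),
    "quant"
  )
  compare <- check_keys(
    compare,
    c(
      "condition_a", "condition_b", "n_replicates",
      "green_multiplier_a", "green_multiplier_b"
    ),
    "compare"
  )
  structure(
    list(
      seed = as.integer(seed), out_dir = out_dir,
      segmentation = segmentation, scene = scene, gate = gate,
      quant = quant, layout = as.integer(layout), compare = compare
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path of the YAML representation.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(run_config, raw)
}
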