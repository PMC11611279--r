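#' Run configuration for the correction pipeline
#'
#' Bundles and validates everything one correction run needs: the model
#' file, the per-material coefficients, the reflection table, the back-end,
#' the sampling strategy and the output path. A config can come from a
#' YAML/JSON file ([load_run_config()]) with individual fields overridden.
#'
#' @param model_path Path to the segmented volume (NPY or TIFF stack).
#' @param voxel_size_um Voxel size in micrometres.
#' @param coefficients Named list/vector of per-material coefficients in
#'   um^-1, or a preset name (see [material_coefficients()]).
#' @param reflections_path CSV/JSON reflection table.
#' @param output_path Where the factors JSON is written.
#' @param format Volume format, see [load_volume()].
#' @param label_map Material code map.
#' @param method Back-end: `standard`, `bisection` or `gridding`.
#' @param sampling List with `method`, `ratio`, `seed` (defaults:
#'   systematic at 0.5%).
#' @param workers Parallel workers.
#' @param precision `"double"` or `"single"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(model_path, voxel_size_um, coefficients,
                       reflections_path, output_path,
                       format = "auto", label_map = default_label_map(),
                       method = c("standard", "bisection", "gridding"),
                       sampling = list(method = "systematic", ratio = 0.005,
                                       seed = 1L),
                       workers = 1L,
                       precision = c("double", "single")) {
  method <- match.arg(method)
  precision <- match.arg(precision)
  coeffs <- if (is.character(coefficients) && length(coefficients) == 1L) {
    material_coefficients(preset = coefficients)
  } else {
    do.call(material_coefficients, as.list(coefficients))
  }
  sampling$method <- match.arg(sampling$method,
                               c("systematic", "randomized_systematic",
                                 "random", "stratified", "none"))
  if (sampling$method != "none") check_ratio(sampling$ratio)
  structure(
    list(model_path = model_path, format = format,
         voxel_size_um = voxel_size_um,
         label_map = validate_label_map(label_map), coefficients = coeffs,
         reflections_path = reflections_path, method = method,
         sampling = sampling, workers = as.integer(workers),
         precision = precision, output_path = output_path),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML or JSON config file.
#' @param ... Field overrides, as in `run_config()`.
#' @export
load_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$label_map)) raw$label_map <- unlist(raw$label_map)
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  do.call(run_config, raw)
}

#' Execute a full correction run
#'
#' Loads the model and reflections, builds the sampling plan, dispatches the
#' configured back-end, writes the ordered factors JSON with its metadata
#' block, and logs per-stage wall times.
#'
#' @param config A [run_config()].
#' @param quiet Suppress log messages.
#' @return The `absorption_result`, invisibly.
#' @export
run_correction <- function(config, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(what, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    say("[%s] %.2f s", what, proc.time()[["elapsed"]] - t0)
    val
  }
  volume <- stage("load model", load_volume(config$model_path, config$format,
                                            voxel_size_um = config$voxel_size_um,
                                            label_map = config$label_map))
  reflections <- stage("load reflections", load_reflections(config$reflections_path))
  say("%d reflections, %s back-end", nrow(reflections), config$method)
  plan <- if (config$sampling$method == "none") NULL else {
    stage("sampling plan",
          sampling_plan(volume, config$sampling$method,
                        ratio = config$sampling$ratio,
                        seed = config$sampling$seed %||% 1L))
  }
  result <- stage("absorption factors",
                  absorb(reflections, volume, config$coefficients,
                         method = config$method, plan = plan,
                         workers = config$workers,
                         precision = config$precision))
  write_factors(result, config$output_path)
  say("wrote %d factors to %s", nrow(result), config$output_path)
  invisible(result)
}
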