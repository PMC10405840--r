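#' Two-group Student t comparison
#'
#' Classical Student t test (pooled variance for the unpaired case, as in
#' standard two-group comparisons of imaging readouts), plus the percent
#' decrease of group A relative to group B.
#'
#' @param values_a,values_b numeric vectors.
#' @param paired logical; paired test requires equal lengths.
#' @return list of class `group_comparison`: `mean_a`, `mean_b`,
#'   `percent_decrease` (= 100 (1 - mean_a / mean_b)), `t_statistic`,
#'   `degrees_of_freedom`, `p_value`.
#' @export
two_group_t <- function(values_a, values_b, paired = FALSE) {
  if (paired && length(values_a) != length(values_b)) {
    stop("paired comparison requires equal group sizes")
  }
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  tt <- stats::t.test(values_a, values_b, paired = paired, var.equal = TRUE)
  ma <- mean(values_a); mb <- mean(values_b)
  structure(list(mean_a = ma, mean_b = mb,
                 percent_decrease = if (mb != 0) 100 * (1 - ma / mb) else NA_real_,
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "group_comparison")
}

#' Ordinary least-squares regression between a dose-like and an outcome
#' variable
#'
#' Simple linear regression (e.g. cumulative opening volume against time in
#' the target quadrant), returning slope, intercept, r-squared and the F test
#' for a non-zero slope.
#'
#' @param x,y paired numeric vectors (>= 3 points).
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `F_statistic`, `p_value`, `n`.
#' @export
regress <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("regression needs at least 3 paired points")
  }
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 F_statistic = unname(fs[1]),
                 p_value = unname(stats::pf(fs[1], fs[2], fs[3],
                                            lower.tail = FALSE)),
                 n = length(x)),
            class = "regression_result")
}

#' Read a run configuration
#'
#' YAML configuration for a full run: stage parameters (thresholds, k, radii,
#' slab, `n_mc`), channel map, pixel/voxel sizes and a root seed.  Missing
#' fields are filled with the package defaults so every report carries a
#' complete parameter record.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged over the file values.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    mr = list(init_threshold = 1.3, max_iter = 40L, slab = NULL),
    tau = list(k = 3L, radius_range = c(5, 12), closing_radius = 2,
               neighborhood_radius = NULL, n_mc = 1e5,
               statistic = "top5_mean"),
    plaques = list(fixed_threshold = 2, min_size = 20,
                   volume_model = "sphere"),
    channels = list(nuclei = 1L, tau = 2L, amyloid = 3L),
    pixel_size = 1, voxel_size = c(1, 1, 1)
  )
  cfg <- defaults
  merge_into <- function(base, extra) {
    for (nm in names(extra)) {
      base[[nm]] <- if (is.list(extra[[nm]]) && is.list(base[[nm]])) {
        merge_into(base[[nm]], extra[[nm]])
      } else extra[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path))
  cfg <- merge_into(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Assemble a deterministic quantification report
#'
#' Collects the outputs of any subset of stages into one JSON-serializable
#' report carrying the exact configuration, the root seed and the package
#' version.  Reports contain no timestamps, so a rerun from the same config
#' and seeds is byte-identical.
#'
#' @param stages named list of stage outputs (any of `mr_volumetry`,
#'   `tau_morphometry`, `plaque_quant`, `pet_suvr`, `statistics`, ...).
#' @param config a [read_run_config()] object.
#' @param path optional path; when given the JSON is written there.
#' @return The report list (class `quant_report`), invisibly when written.
#' @export
assemble_report <- function(stages, config, path = NULL) {
  if (!length(stages) || is.null(names(stages)) || any(names(stages) == "")) {
    stop("at least one named stage output is required")
  }
  if (!inherits(config, "run_config")) stop("a run_config is required")
  version <- as.character(utils::packageVersion("sonoquant"))
  strip <- function(x) {
    if (inherits(x, "raster_volume") || inherits(x, "skeleton_graph")) {
      return(NULL)
    }
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  report <- list(software = list(package = "sonoquant", version = version),
                 config = strip(unclass(config)),
                 stages = strip(stages))
  class(report) <- "quant_report"
  if (!is.null(path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}
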