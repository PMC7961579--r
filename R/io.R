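#' Read and write synthetic-cohort configurations as JSON
#'
#' @param config A [synth_config()].
#' @param file Path to a JSON file.
#' @return `write_synth_config` returns `file` invisibly;
#'   `read_synth_config` returns a [synth_config()].
#' @export
write_synth_config <- function(config, file) {
  stopifnot(inherits(config, "synth_config"))
  obj <- list(
    n_per_class = config$n_per_class,
    axis_noise_sd = config$axis_noise_sd,
    classes = lapply(config$classes, function(p) unclass(p)),
    protocols = lapply(config$protocols, function(p) unclass(p))
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  classes <- lapply(obj$classes, function(p) do.call(class_params, p))
  protocols <- lapply(obj$protocols, function(p) {
    stretch_protocol(
      laser_power_mW = p$laser_power,
      stretch_s = p$stretch_duration,
      relax_s = p$relax_duration,
      pre_stretch_s = p$pre_stretch_duration,
      frame_rate_hz = p$frame_rate,
      step_stress_Pa = p$step_stress,
      peak_force_pN = p$peak_force
    )
  })
  synth_config(classes,
    protocols = protocols,
    n_per_class = obj$n_per_class, axis_noise_sd = obj$axis_noise_sd
  )
}

#' Write cohort ground truth as CSV
#'
#' @param truth The ground-truth data.frame of [generate_cohort()].
#' @param file Path to a CSV file.
#' @return `file`, invisibly.
#' @export
write_ground_truth <- function(truth, file) {
  utils::write.csv(truth, file, row.names = FALSE)
  invisible(file)
}
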