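#' Step-stress protocol for an optical-stretcher measurement
#'
#' Describes one step-stress creep experiment: a pre-stretch (trap-only)
#' baseline, a stretch phase during which a constant optical surface stress is
#' applied, and a relaxation phase at trapping power. The applied stress and
#' peak stretching force scale linearly with laser power (see
#' [stress_from_power()]).
#'
#' @param laser_power_mW Laser power during the stretch phase, in milliwatts.
#' @param stretch_s Duration of the step stress, in seconds.
#' @param relax_s Duration of the observed relaxation phase, in seconds.
#' @param pre_stretch_s Duration of the trap-only baseline recorded before the
#'   step, in seconds. Used downstream to normalise deformation curves.
#' @param frame_rate_hz Imaging frame rate, in Hz.
#' @param step_stress_Pa Applied step stress in pascals; derived from
#'   `laser_power_mW` via [stress_from_power()] when `NULL`.
#' @param peak_force_pN Peak stretching force in piconewtons; derived from
#'   `laser_power_mW` via [force_from_power()] when `NULL`.
#' @param stress_coef,force_coef Linear calibration coefficients passed to
#'   [stress_from_power()] / [force_from_power()].
#'
#' @return An object of class `stretch_protocol`: a list with elements
#'   `laser_power`, `step_stress`, `peak_force`, `pre_stretch_duration`,
#'   `stretch_duration`, `relax_duration`, `frame_rate`.
#' @seealso [clinical_protocols()], [cell_line_protocol()]
#' @export
stretch_protocol <- function(laser_power_mW,
                             stretch_s,
                             relax_s = 2,
                             pre_stretch_s = 1,
                             frame_rate_hz = 30,
                             step_stress_Pa = NULL,
                             peak_force_pN = NULL,
                             stress_coef = 0.38 / 400,
                             force_coef = 80 / 400) {
  stopifnot(is.numeric(laser_power_mW), length(laser_power_mW) == 1L)
  if (laser_power_mW < 0) stop("laser power must be >= 0")
  if (stretch_s <= 0) stop("stretch duration must be > 0")
  if (relax_s < 0) stop("relaxation duration must be >= 0")
  if (pre_stretch_s < 0) stop("pre-stretch duration must be >= 0")
  if (frame_rate_hz <= 0) stop("frame rate must be > 0")
  if (is.null(step_stress_Pa)) {
    step_stress_Pa <- stress_from_power(laser_power_mW, stress_coef)
  }
  if (is.null(peak_force_pN)) {
    peak_force_pN <- force_from_power(laser_power_mW, force_coef)
  }
  if (step_stress_Pa < 0) stop("step stress must be >= 0")
  structure(
    list(
      laser_power = laser_power_mW,
      step_stress = step_stress_Pa,
      peak_force = peak_force_pN,
      pre_stretch_duration = pre_stretch_s,
      stretch_duration = stretch_s,
      relax_duration = relax_s,
      frame_rate = frame_rate_hz
    ),
    class = "stretch_protocol"
  )
}

#' @export
print.stretch_protocol <- function(x, ...) {
  cat(sprintf(
    "<stretch_protocol> %g mW (sigma = %.3g Pa, F = %.3g pN), %gs pre + %gs stretch + %gs relax @ %g Hz\n",
    x$laser_power, x$step_stress, x$peak_force,
    x$pre_stretch_duration, x$stretch_duration, x$relax_duration, x$frame_rate
  ))
  invisible(x)
}

#' Standard measurement protocols
#'
#' `clinical_protocols()` returns the three-power protocol set used for
#' patient-derived samples: 400, 800 and 1200 mW, each with a 10 s step stress
#' and 2 s relaxation. `cell_line_protocol()` returns the single-power
#' cell-line protocol: 875 mW, 5 s step stress, 2 s relaxation.
#'
#' @param frame_rate_hz Imaging frame rate in Hz.
#' @param pre_stretch_s Trap-only baseline duration in seconds.
#' @return A list of [stretch_protocol()] objects (`clinical_protocols`) or a
#'   single one (`cell_line_protocol`).
#' @export
clinical_protocols <- function(frame_rate_hz = 30, pre_stretch_s = 1) {
  lapply(c(400, 800, 1200), stretch_protocol,
    stretch_s = 10, relax_s = 2,
    pre_stretch_s = pre_stretch_s, frame_rate_hz = frame_rate_hz
  )
}

#' @rdname clinical_protocols
#' @export
cell_line_protocol <- function(frame_rate_hz = 30, pre_stretch_s = 1) {
  stretch_protocol(875,
    stretch_s = 5, relax_s = 2,
    pre_stretch_s = pre_stretch_s, frame_rate_hz = frame_rate_hz
  )
}

#' Linear power-to-stress and power-to-force calibration
#'
#' The optical surface stress and the peak stretching force scale linearly
#' with laser power. Default coefficients are anchored at 400 mW producing a
#' 0.38 Pa step stress and an 80 pN peak force, so 800 mW maps to 0.76 Pa /
#' 160 pN and 1200 mW to 1.14 Pa / 240 pN.
#'
#' @param P Laser power in milliwatts (vectorised).
#' @param coef Calibration coefficient: Pa/mW for `stress_from_power`,
#'   pN/mW for `force_from_power`.
#' @return Stress in pascals, or force in piconewtons.
#' @export
stress_from_power <- function(P, coef = 0.38 / 400) {
  if (any(P < 0)) stop("laser power must be >= 0")
  coef * P
}

#' @rdname stress_from_power
#' @export
force_from_power <- function(P, coef = 80 / 400) {
  if (any(P < 0)) stop("laser power must be >= 0")
  coef * P
}

#' Frame times of a protocol
#'
#' @param protocol A [stretch_protocol()].
#' @return Numeric vector of frame times in seconds, `floor(total * rate) + 1`
#'   frames starting at 0.
#' @export
protocol_times <- function(protocol) {
  total <- protocol$pre_stretch_duration + protocol$stretch_duration +
    protocol$relax_duration
  n <- floor(total * protocol$frame_rate) + 1L
  (seq_len(n) - 1L) / protocol$frame_rate
}
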