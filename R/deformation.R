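#' Deformation curves of a traced cell
#'
#' `relative_deformation` is the fractional elongation of the long axis,
#' \eqn{d(t) = (L(t) - L_0)/L_0}, with \eqn{L_0} the mean long axis over the
#' pre-stretch window. `elliptic_deformation` is the change of the
#' long-to-short axis ratio relative to the resting shape,
#' \eqn{\varepsilon(t) = [L(t)/S(t)]/e_0 - 1}, with \eqn{e_0} the mean
#' resting ratio; it captures the Poisson effect (thinning of the short axis
#' under elongation) that pure elongation misses. Both curves average to
#' approximately zero over the baseline by construction.
#'
#' @param trace A valid [axis_trace()] with at least one pre-stretch frame.
#' @return An object of class `deformation_curve`: a list with `time`,
#'   `value`, `signal` (`"relative"` or `"elliptic"`), phase marks
#'   `stretch_start` / `stretch_end`, `protocol` and `cell_id`.
#' @export
relative_deformation <- function(trace) {
  baseline <- pre_stretch_window(trace)
  L0 <- mean(trace$long_um[baseline])
  if (!is.finite(L0) || L0 <= 0) stop("non-positive baseline long axis")
  new_deformation_curve(trace, (trace$long_um - L0) / L0, "relative")
}

#' @rdname relative_deformation
#' @export
elliptic_deformation <- function(trace) {
  baseline <- pre_stretch_window(trace)
  if (any(trace$short_um <= 0)) stop("non-positive short axis")
  ratio <- trace$long_um / trace$short_um
  e0 <- mean(ratio[baseline])
  new_deformation_curve(trace, ratio / e0 - 1, "elliptic")
}

pre_stretch_window <- function(trace) {
  if (!isTRUE(trace$valid)) stop("trace is invalid")
  npre <- n_pre_stretch(trace)
  if (npre < 1) stop("no pre-stretch frames for the baseline")
  seq_len(npre)
}

new_deformation_curve <- function(trace, value, signal) {
  stopifnot(all(is.finite(value)))
  structure(
    list(
      time = trace$time, value = value, signal = signal,
      stretch_start = trace$stretch_start, stretch_end = trace$stretch_end,
      protocol = trace$protocol, cell_id = trace$cell_id
    ),
    class = "deformation_curve"
  )
}

#' @export
print.deformation_curve <- function(x, ...) {
  cat(sprintf(
    "<deformation_curve> %s, cell %s: %d frames, end-of-stretch value %.4g\n",
    x$signal, x$cell_id, length(x$time), x$value[x$stretch_end]
  ))
  invisible(x)
}

#' Shape restoration after the step stress
#'
#' How much of the stretch-induced elongation the cell recovers early in the
#' relaxation phase: the elongation at the end of the step stress minus the
#' elongation 1.5 s after it, each sampled at the nearest frame. Positive
#' values indicate elastic (recoverable) behaviour, values near zero a
#' viscous, dissipative response.
#'
#' @param curve A [relative_deformation()] (or elliptic) curve whose
#'   relaxation phase covers at least 1.5 s.
#' @return A list of class `restoration_result` with
#'   `elongation_end_stretch`, `elongation_1p5s_after` and
#'   `shape_restoration` (their difference, exactly).
#' @export
shape_restoration <- function(curve) {
  t_end <- curve$time[curve$stretch_end]
  t_target <- t_end + 1.5
  if (max(curve$time) < t_target - 1e-9) {
    stop("relaxation phase shorter than 1.5 s")
  }
  i2 <- which.min(abs(curve$time - t_target))
  d_end <- curve$value[curve$stretch_end]
  d_after <- curve$value[i2]
  structure(
    list(
      elongation_end_stretch = d_end,
      elongation_1p5s_after = d_after,
      shape_restoration = d_end - d_after
    ),
    class = "restoration_result"
  )
}

#' Active / non-active cell label from a fitted activity
#'
#' A cell is considered active when the activity parameter of the active
#' Kelvin-Voigt fit strictly exceeds `threshold` (default 0.001 Pa/s; smaller
#' fitted activities vanish in the fit noise). Non-converged fits give an
#' undetermined label.
#'
#' @param fit A [fit_kv()] result from the active model.
#' @param threshold Activity threshold, Pa/s.
#' @return `"active"`, `"non_active"` or `"undetermined"`.
#' @export
classify_activity <- function(fit, threshold = 0.001) {
  if (!isTRUE(fit$converged)) {
    return("undetermined")
  }
  if (is.na(fit$a)) stop("fit has no activity parameter; use the active model")
  if (fit$a > threshold) "active" else "non_active"
}
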