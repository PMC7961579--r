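#' Fit a Kelvin-Voigt model to a deformation curve
#'
#' Nonlinear least squares (trust-region Levenberg-Marquardt with box
#' bounds, via \pkg{minpack.lm}) of the passive or active Kelvin-Voigt creep
#' model to the stretch-phase samples of a deformation curve, either over the
#' entire step-stress duration (`window = "full"`) or over its first 2 s
#' (`window = "first2s"`).
#'
#' Initialisation: `E0 = sigma0 / gamma_end` (with `gamma_end` the mean
#' strain near the end of the window), `tau0 = 0.3 * T_window`, `a0 = 0`.
#' Bounds: `E` in (0, 1e6] Pa, `tau` in (1e-3, 1e3] s, `a` in [0, 10] Pa/s;
#' at most 200 iterations, cost tolerance 1e-10. Degenerate inputs (flat or
#' non-positive end-of-window strain) and fits that run into the upper `E`
#' bound are flagged as non-converged and carry `NA` parameters rather than
#' silent defaults.
#'
#' @param curve A [relative_deformation()] / [elliptic_deformation()] curve.
#' @param window `"full"` or `"first2s"`.
#' @param model `"passive"` (E, tau) or `"active"` (E, tau, a).
#' @param sigma0 Step stress in Pa; taken from the curve's protocol when
#'   `NULL`.
#' @return A list of class `kv_fit`: `E` (Pa), `eta` (Pa s), `tau` (s), `a`
#'   (Pa/s; `NA` for the passive model), `fit_error` (RMS residual,
#'   dimensionless), `window`, `signal`, `model`, `converged`, `n` (samples
#'   used), `sigma0`.
#' @export
fit_kv <- function(curve, window = c("full", "first2s"),
                   model = c("passive", "active"), sigma0 = NULL) {
  window <- match.arg(window)
  model <- match.arg(model)
  if (is.null(sigma0)) {
    if (is.null(curve$protocol)) stop("sigma0 or a protocol is required")
    sigma0 <- curve$protocol$step_stress
  }
  idx <- curve$stretch_start:curve$stretch_end
  t <- curve$time[idx] - curve$time[curve$stretch_start]
  y <- curve$value[idx]
  if (window == "first2s") {
    keep <- t <= 2 + 1e-9
    t <- t[keep]
    y <- y[keep]
  }
  if (length(t) < 10) stop("fit window contains fewer than 10 samples")
  Twin <- max(t)
  tail_idx <- t >= 0.9 * Twin
  gamma_end <- mean(y[tail_idx])
  lower_E <- 1e-6
  upper_E <- 1e6
  if (!is.finite(gamma_end) || gamma_end <= 1e-6) {
    return(kv_fit_sentinel(curve, window, model, sigma0, length(t), y))
  }
  E0 <- min(max(sigma0 / gamma_end, lower_E * 10), upper_E / 10)
  # two tau starts: the prescribed fraction of the window, and the time at
  # which the curve first reaches 63% of its end level (the KV time constant
  # read off the data); LM keeps whichever converges to the lower cost
  i63 <- which(y >= (1 - exp(-1)) * gamma_end)[1]
  tau_data <- if (is.na(i63)) 0.3 * Twin else max(t[i63], 1e-2)
  tau_starts <- unique(c(min(max(tau_data, 0.01 * Twin), 0.8 * Twin), 0.3 * Twin))
  lower <- c(lower_E, 1e-3)
  upper <- c(upper_E, 1e3)
  if (model == "active") {
    lower <- c(lower, 0)
    upper <- c(upper, 10)
  }
  resid_fn <- function(p) {
    g <- if (model == "passive") {
      kv_creep(t, p[1], p[1] * p[2], sigma0)
    } else {
      active_kv_creep(t, p[1], p[1] * p[2], sigma0, p[3])
    }
    g - y
  }
  fit <- NULL
  for (tau0 in tau_starts) {
    par0 <- c(E = E0, tau = tau0)
    if (model == "active") par0 <- c(par0, a = 0)
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
  }
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(kv_fit_sentinel(curve, window, model, sigma0, length(t), y))
  }
  p <- fit$par
  if (p[1] >= 0.5 * upper_E) {
    return(kv_fit_sentinel(curve, window, model, sigma0, length(t), y))
  }
  res <- resid_fn(p)
  structure(
    list(
      E = unname(p[1]), eta = unname(p[1] * p[2]), tau = unname(p[2]),
      a = if (model == "active") unname(p[3]) else NA_real_,
      fit_error = sqrt(mean(res^2)),
      window = window, signal = curve$signal, model = model,
      converged = TRUE, n = length(t), sigma0 = sigma0,
      cell_id = curve$cell_id
    ),
    class = "kv_fit"
  )
}

kv_fit_sentinel <- function(curve, window, model, sigma0, n, y) {
  structure(
    list(
      E = NA_real_, eta = NA_real_, tau = NA_real_, a = NA_real_,
      fit_error = stats::sd(y),
      window = window, signal = curve$signal, model = model,
      converged = FALSE, n = n, sigma0 = sigma0, cell_id = curve$cell_id
    ),
    class = "kv_fit"
  )
}

#' @export
print.kv_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<kv_fit> %s/%s/%s: E = %.3g Pa, tau = %.3g s%s, rms = %.2g\n",
      x$signal, x$window, x$model, x$E, x$tau,
      if (!is.na(x$a)) sprintf(", a = %.3g Pa/s", x$a) else "",
      x$fit_error
    ))
  } else {
    cat(sprintf(
      "<kv_fit> %s/%s/%s: NOT CONVERGED\n", x$signal, x$window, x$model
    ))
  }
  invisible(x)
}

#' All eight Kelvin-Voigt fits of one cell
#'
#' Fits both models (passive, active) to both deformation signals (relative,
#' elliptic) over both windows (full, first 2 s): eight fits per cell, all
#' exported as features downstream. The activity used for the active /
#' non-active label is by convention the one from the active fit to the
#' relative deformation over the full window.
#'
#' @param trace A valid [axis_trace()].
#' @return A named list of eight `kv_fit` objects, names
#'   `<signal>_<window>_<model>`.
#' @export
fit_cell <- function(trace) {
  curves <- list(
    relative = relative_deformation(trace),
    elliptic = elliptic_deformation(trace)
  )
  out <- list()
  for (sig in names(curves)) {
    for (win in c("full", "first2s")) {
      for (mod in c("passive", "active")) {
        out[[paste(sig, win, mod, sep = "_")]] <-
          fit_kv(curves[[sig]], window = win, model = mod)
      }
    }
  }
  out
}

#' Tabulate fits as a data.frame
#'
#' @param fits A list of `kv_fit` objects (possibly nested per cell).
#' @return A data.frame with one row per fit.
#' @export
fits_to_df <- function(fits) {
  if (length(fits) && inherits(fits[[1]], "kv_fit")) fits <- list(fits)
  rows <- lapply(fits, function(cell_fits) {
    do.call(rbind, lapply(cell_fits, function(f) {
      data.frame(
        cell_id = f$cell_id, signal = f$signal, window = f$window,
        model = f$model, E_Pa = f$E, eta_Pas = f$eta, tau_s = f$tau,
        activity_Pas = f$a, fit_error = f$fit_error, converged = f$converged,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
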