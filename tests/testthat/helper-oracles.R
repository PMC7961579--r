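# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: the creep oracle integrates the governing ODE
# numerically, the KS oracle enumerates ECDF gaps.

# numerical initial-value solution of eta*g' + E*g = max(sigma0 - a*t, 0)
ode_creep <- function(t, E, eta, sigma0, a = 0) {
  rhs <- function(tt, y, parms) {
    list((max(sigma0 - a * tt, 0) - E * y[1]) / eta)
  }
  tt <- sort(unique(c(0, t)))
  sol <- deSolve::lsoda(
    y = c(g = 0), times = tt, func = rhs, parms = NULL,
    rtol = 1e-12, atol = 1e-14
  )
  stats::approx(sol[, "time"], sol[, "g"], xout = t)$y
}

# brute-force two-sample KS statistic: ECDF gap at every jump point
ecdf_gap_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)
  Fy <- stats::ecdf(y)
  max(abs(Fx(pts) - Fy(pts)))
}

# ray-casting point-in-polygon (polygon given as x/y vectors, open ring)
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimal hand-built trace: constant pre-stretch baseline then given values
manual_trace <- function(long_um, short_um = NULL, protocol = NULL,
                         orient_deg = NULL, time = NULL) {
  n <- length(long_um)
  if (is.null(short_um)) short_um <- long_um
  if (is.null(orient_deg)) orient_deg <- rep(0, n)
  if (is.null(time)) time <- seq(0, by = 1 / 30, length.out = n)
  if (is.null(protocol)) {
    protocol <- osmech::stretch_protocol(400,
      stretch_s = max(time[n] - 1, 1),
      relax_s = 0, pre_stretch_s = 1, frame_rate_hz = 30
    )
  }
  osmech::axis_trace(time, long_um, short_um, orient_deg,
    rep(1, n),
    protocol = protocol
  )
}

# ground-truth list for simulate_trace
make_truth <- function(E = 100, eta = 100, a = 0, radius = 5, e0 = 1,
                       brightness = 1.3, rot = 0, nu = 0.45,
                       id = "cell_test") {
  list(
    cell_id = id, E_Pa = E, eta_Pas = eta, activity_Pas = a,
    radius_um = radius, init_ellipticity = e0, brightness = brightness,
    rotation_dps = rot, poisson_ratio = nu
  )
}
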