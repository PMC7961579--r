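# Kelvin-Voigt forward models, deformation metrics and model fitting.

test_that("passive creep matches its worked values and limits", {
  expect_equal(kv_creep(0, 100, 100, 1), 0)
  expect_equal(kv_creep(1, 100, 100, 1), 0.0063212, tolerance = 1e-5)
  # equilibrium of the spring at t >> tau
  expect_equal(kv_creep(50, 100, 100, 1), 1 / 100, tolerance = 1e-9)
  expect_error(kv_creep(1, -5, 100, 1), "E")
  expect_error(kv_creep(1, 100, 0, 1), "eta")
})

test_that("active creep reduces to passive at a = 0 and matches the ODE", {
  t <- seq(0, 10, 0.25)
  expect_equal(active_kv_creep(t, 80, 120, 0.76, 0), kv_creep(t, 80, 120, 0.76))
  expect_equal(active_kv_creep(1, 100, 100, 1, 0.1), 0.0059533,
    tolerance = 1e-5
  )
  expect_error(active_kv_creep(1, 100, 100, 1, -0.1), "a")
})

test_that("closed forms agree with a numerical IVP solver on a parameter grid", {
  t <- seq(0, 10, 0.05)
  worst <- 0
  for (E in c(10, 100, 1000)) {
    for (tau in c(0.1, 1, 10)) {
      for (a in c(0, 0.1, 0.5)) {
        closed <- active_kv_creep(t, E, E * tau, 1, a)
        num <- ode_creep(t, E, E * tau, 1, a)
        worst <- max(worst, max(abs(closed - num)))
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("creep is monotone in time and stress-like in parameters", {
  t <- seq(0.01, 10, 0.1)
  g <- kv_creep(t, 50, 100, 0.76)
  expect_true(all(diff(g) > 0))
  # stiffer cell deforms strictly less at any fixed time
  expect_true(all(kv_creep(t, 200, 400, 0.76) < g))
  # activity only ever lowers the strain
  expect_true(all(active_kv_creep(t, 50, 100, 0.76, 0.05) <= g))
})

test_that("strain decays after the contraction clamps the stress to zero", {
  # sigma0/a = 2 s < T: beyond the clamp the strain must not increase
  t <- seq(2, 10, 0.1)
  g <- active_kv_creep(t, 100, 100, 0.2, 0.1)
  expect_true(all(diff(g) < 0))
})

test_that("relaxation is exponential with full recovery", {
  expect_equal(kv_relax(0, 0.006, 1), 0.006)
  expect_equal(kv_relax(1.5, 0.006, 1), 0.0013388, tolerance = 1e-4)
  expect_lt(kv_relax(100, 0.006, 1), 1e-40)
})

test_that("relative deformation is the normalised long-axis change", {
  p <- stretch_protocol(400, stretch_s = 2, relax_s = 0, pre_stretch_s = 1)
  # 31 baseline frames at 10 um, then a jump to 10.3 um
  L <- c(rep(10, 31), rep(10.3, 60))
  tr <- manual_trace(L[1:91], protocol = p)
  d <- relative_deformation(tr)
  expect_equal(d$value[1], 0)
  expect_equal(d$value[91], 0.03)
  # constant trace -> identically zero
  d0 <- relative_deformation(manual_trace(rep(10, 91), protocol = p))
  expect_true(all(d0$value == 0))
})

test_that("elliptic deformation normalises the axis ratio by the resting shape", {
  p <- stretch_protocol(400, stretch_s = 2, relax_s = 0, pre_stretch_s = 1)
  L <- c(rep(10, 31), rep(10.5, 60))
  S <- c(rep(10, 31), rep(9.5, 60))
  e <- elliptic_deformation(manual_trace(L, S, protocol = p))
  expect_equal(e$value[1], 0)
  expect_equal(e$value[91], 10.5 / 9.5 - 1, tolerance = 1e-12)
})

test_that("with zero Poisson coupling elliptic equals relative deformation", {
  p <- stretch_protocol(800, stretch_s = 10)
  tr <- simulate_trace(make_truth(E = 50, eta = 100, nu = 0, e0 = 1),
    p,
    axis_noise_sd = 0, seed = 1
  )
  d <- relative_deformation(tr)
  e <- elliptic_deformation(tr)
  expect_equal(e$value, d$value, tolerance = 1e-12)
})

test_that("noise-free deformation follows the closed-form creep", {
  p <- stretch_protocol(1200, stretch_s = 10)
  tr <- simulate_trace(make_truth(E = 60, eta = 90), p,
    axis_noise_sd = 0, seed = 1
  )
  d <- relative_deformation(tr)
  expected <- kv_strain_profile(d$time, 60, 90, p$step_stress, 0, p)
  expect_lt(max(abs(d$value - expected)), 1e-9)
})

test_that("kv fits recover parameters from clean curves", {
  p <- stretch_protocol(400, stretch_s = 10)
  tr <- simulate_trace(make_truth(E = 100, eta = 100), p,
    axis_noise_sd = 0, seed = 1
  )
  d <- relative_deformation(tr)
  for (win in c("full", "first2s")) {
    f <- fit_kv(d, win, "passive")
    expect_true(f$converged)
    expect_equal(f$E, 100, tolerance = 1e-3)
    expect_equal(f$tau, 1, tolerance = 1e-3)
    expect_equal(f$eta, f$E * f$tau, tolerance = 1e-9)
    expect_lt(f$fit_error, 1e-9)
  }
  tra <- simulate_trace(make_truth(E = 100, eta = 100, a = 0.1), p,
    axis_noise_sd = 0, seed = 1
  )
  fa <- fit_kv(relative_deformation(tra), "full", "active")
  expect_true(fa$converged)
  expect_equal(fa$a, 0.1, tolerance = 1e-2)
  expect_equal(fa$E, 100, tolerance = 1e-2)
})

test_that("degenerate flat curves are flagged, not silently fitted", {
  p <- stretch_protocol(400, stretch_s = 10)
  tr <- manual_trace(rep(10, 391),
    protocol = p,
    time = seq(0, 13, length.out = 391)
  )
  f <- fit_kv(relative_deformation(tr), "full", "passive")
  expect_false(f$converged)
  expect_true(is.na(f$E))
  expect_error(
    fit_kv(relative_deformation(tr), window = "nope"),
    "arg"
  )
})

test_that("shape restoration is the elongation drop 1.5 s into relaxation", {
  p <- stretch_protocol(400, stretch_s = 2, relax_s = 2, frame_rate_hz = 10)
  # values chosen by hand: d(T) = 0.03, d(T + 1.5) = 0.01
  n <- length(protocol_times(p))
  tt <- protocol_times(p)
  L <- rep(10, n)
  L[tt >= 1 & tt <= 3] <- 10.3
  L[tt > 3] <- 10.1
  r <- shape_restoration(
    relative_deformation(manual_trace(L, protocol = p, time = tt))
  )
  expect_equal(r$shape_restoration, 0.02, tolerance = 1e-12)
  expect_equal(
    r$shape_restoration,
    r$elongation_end_stretch - r$elongation_1p5s_after
  )
  # plateau (no recovery) -> zero restoration
  L2 <- rep(10, n)
  L2[tt >= 1] <- 10.3
  r2 <- shape_restoration(
    relative_deformation(manual_trace(L2, protocol = p, time = tt))
  )
  expect_equal(r2$shape_restoration, 0)
})

test_that("passive KV restoration follows the relaxation closed form", {
  p <- stretch_protocol(800, stretch_s = 10, relax_s = 2)
  tr <- simulate_trace(make_truth(E = 50, eta = 50), p, # tau = 1 s
    axis_noise_sd = 0, seed = 1
  )
  d <- relative_deformation(tr)
  r <- shape_restoration(d)
  gT <- d$value[d$stretch_end]
  expect_equal(r$shape_restoration, gT * (1 - exp(-1.5)), tolerance = 1e-3)
})

test_that("restoration requires 1.5 s of relaxation", {
  p <- stretch_protocol(400, stretch_s = 2, relax_s = 1)
  n <- length(protocol_times(p))
  tr <- manual_trace(rep(10, n), protocol = p, time = protocol_times(p))
  expect_error(shape_restoration(relative_deformation(tr)), "1.5")
})

test_that("activity labels use a strict 0.001 Pa/s threshold", {
  fit <- function(a, conv = TRUE) {
    structure(list(a = a, converged = conv), class = "kv_fit")
  }
  expect_identical(classify_activity(fit(0.079)), "active")
  expect_identical(classify_activity(fit(0.0005)), "non_active")
  expect_identical(classify_activity(fit(0.001)), "non_active")
  expect_identical(classify_activity(fit(0.5, conv = FALSE)), "undetermined")
})

test_that("power maps linearly to stress and force", {
  expect_equal(stress_from_power(400), 0.38)
  expect_equal(force_from_power(400), 80)
  expect_equal(stress_from_power(800), 0.76)
  expect_equal(force_from_power(800), 160)
  expect_equal(stress_from_power(1200), 1.14)
  expect_equal(force_from_power(1200), 240)
  expect_equal(stress_from_power(0), 0)
  expect_error(stress_from_power(-1), ">= 0")
})
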