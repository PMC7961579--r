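# Contour detection, ellipse fitting, axis tracking and morphology.

single_frame_trace <- function(L, S, theta = 0, brightness = 1.3) {
  structure(
    list(
      time = 0, long_um = L, short_um = S, orient_deg = theta,
      brightness = brightness, protocol = NULL, cell_id = "fx",
      stretch_start = 1L, stretch_end = 1L, valid = TRUE
    ),
    class = "axis_trace"
  )
}

render_one <- function(L, S, theta = 0, noise = 0, seed = 1, size = 96,
                       scale = 0.25) {
  render_frames(single_frame_trace(L, S, theta),
    image_size = size,
    pixel_scale = scale, background_noise_sd = noise, seed = seed
  )[, , 1]
}

test_that("the detected contour encloses the rendered cell", {
  fr <- render_one(12, 8, 30)
  cc <- detect_contour(fr)
  expect_false(is.null(cc))
  # true mask pixel centers (in the contour's x = col, y = row convention)
  cx <- (96 + 1) / 2
  xs <- (col(fr) - cx) * 0.25
  ys <- (row(fr) - cx) * 0.25
  th <- 30 * pi / 180
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  inside <- (u / 6)^2 + (v / 4)^2 < 1
  px <- col(fr)[inside]
  py <- row(fr)[inside]
  frac <- mean(points_in_polygon(px, py, cc$x, cc$y))
  expect_gte(frac, 0.98)
})

test_that("blank frames fail detection and the larger of two objects wins", {
  withr::with_seed(1, {
    blank <- matrix(rnorm(96 * 96, 0.5, 0.01), 96, 96)
  })
  expect_null(detect_contour(blank))
  # two objects: shift a small and a large ellipse into opposite corners
  big <- render_one(10, 10)
  small <- render_one(4, 4, size = 96)
  two <- pmax(
    big[c(25:96, 1:24), ], # translate by 24 px
    small[, c(70:96, 1:69)]
  )
  cc <- detect_contour(two)
  expect_gt(attr(cc, "area_px"), pi * (5 / 0.25)^2 * 0.9)
})

test_that("ellipse fitting recovers axes, orientation and degeneracies", {
  fr <- render_one(12, 8, 30)
  fe <- fit_ellipse(detect_contour(fr), pixel_scale = 0.25)
  expect_lt(abs(fe$L_um - 12) / 12, 0.02)
  expect_lt(abs(fe$S_um - 8) / 8, 0.02)
  expect_lt(abs(fe$orientation_deg - 30), 2)
  # perfect circle: equal axes, finite orientation
  fc <- fit_ellipse(detect_contour(render_one(10, 10)), pixel_scale = 0.25)
  expect_equal(fc$L_um, fc$S_um, tolerance = 1e-2)
  expect_true(is.finite(fc$orientation_deg))
  # too few / collinear points
  expect_error(fit_ellipse(list(x = 1:4, y = 1:4)), "5")
  expect_error(fit_ellipse(list(x = 1:10, y = 2 * (1:10))), "collinear|ellipse")
})

test_that("axis tracking round-trips a rendered synthetic stack", {
  p <- stretch_protocol(875, stretch_s = 5, relax_s = 2, frame_rate_hz = 10)
  tr <- simulate_trace(make_truth(E = 40, eta = 60, radius = 5.5, e0 = 1.08,
    rot = 2, nu = 0.4
  ), p, axis_noise_sd = 0, seed = 2)
  stk <- render_frames(tr,
    image_size = 96, pixel_scale = 0.25,
    background_noise_sd = 0.01, seed = 3
  )
  tr2 <- trace_axes(stk, p, cell_id = "rt")
  expect_true(tr2$valid)
  expect_length(tr2$time, dim(stk)[3])
  expect_lt(max(abs(tr2$long_um - tr$long_um) / tr$long_um), 0.02)
  expect_lt(max(abs(tr2$short_um - tr$short_um) / tr$short_um), 0.02)
  expect_equal(tr2$stretch_start, tr$stretch_start)
})

test_that("an untrackable stack is flagged invalid", {
  p <- stretch_protocol(875, stretch_s = 1, relax_s = 0, frame_rate_hz = 5,
    pre_stretch_s = 1)
  withr::with_seed(4, {
    blank <- array(rnorm(48 * 48 * 11, 0.5, 0.01), dim = c(48, 48, 11))
  })
  attr(blank, "pixel_scale") <- 0.25
  tr <- trace_axes(blank, p)
  expect_false(tr$valid)
})

test_that("morphology identities hold on a constant circular cell", {
  p <- stretch_protocol(400, stretch_s = 2, relax_s = 0, pre_stretch_s = 1)
  tr <- manual_trace(rep(10, 91), rep(10, 91), protocol = p)
  m <- compute_morphology(tr)
  expect_equal(m$area_um2, 25 * pi)
  expect_equal(m$effective_radius_um, 5)
  expect_equal(m$effective_radius_um, sqrt(m$area_um2 / pi), tolerance = 1e-9)
  expect_equal(m$initial_ellipticity, 1)
  expect_equal(m$rotation_degree, 0)
})

test_that("rotation degree sums absolute unwrapped steps and ignores offsets", {
  p <- stretch_protocol(400,
    stretch_s = 2, relax_s = 0, pre_stretch_s = 1,
    frame_rate_hz = 1
  )
  # orientation 0, 10, 5 over the stretch phase
  tr <- manual_trace(rep(10, 4), rep(9, 4),
    protocol = p,
    orient_deg = c(0, 0, 10, 5), time = 0:3
  )
  expect_equal(compute_morphology(tr)$rotation_degree, 15)
  tr_off <- manual_trace(rep(10, 4), rep(9, 4),
    protocol = p,
    orient_deg = c(0, 0, 10, 5) + 90, time = 0:3
  )
  expect_equal(compute_morphology(tr_off)$rotation_degree, 15)
  # wrap-around at the 180 degree seam: 178 -> 2 is a 4 degree step
  tr_wrap <- manual_trace(rep(10, 4), rep(9, 4),
    protocol = p,
    orient_deg = c(170, 178, 2, 6), time = 0:3
  )
  expect_equal(compute_morphology(tr_wrap)$rotation_degree, 8)
})
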