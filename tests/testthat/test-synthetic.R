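# Synthetic cohort generator: populations, traces, cohorts, rendering.

test_that("population sampling is seeded, sized and distributionally faithful", {
  cfg <- synth_preset("clinical_like", n_per_class = 5)
  expect_identical(
    sample_population(cfg, seed = 7),
    sample_population(cfg, seed = 7)
  )
  expect_false(identical(
    sample_population(cfg, seed = 7),
    sample_population(cfg, seed = 8)
  ))
  pop <- sample_population(cfg, seed = 7)
  expect_equal(unname(table(pop$class_label)["PBMC"]), 5, ignore_attr = TRUE)
  # empty case
  cfg0 <- synth_preset("clinical_like", n_per_class = 0)
  expect_equal(nrow(sample_population(cfg0, seed = 1)), 0)
})

test_that("sampled medians converge to the configured medians", {
  cfg <- synth_config(
    classes = list(X = class_params(
      E_median_Pa = 100, eta_median_Pas = 100, radius_median_um = 5
    )),
    protocols = clinical_protocols(), n_per_class = 5000
  )
  pop <- sample_population(cfg, seed = 11)
  expect_lt(abs(median(pop$E_Pa) - 100) / 100, 0.05)
  expect_lt(abs(median(pop$eta_Pas) - 100) / 100, 0.05)
  expect_lt(abs(median(pop$radius_um) - 5) / 5, 0.05)
})

test_that("invalid distribution parameters are rejected at configuration", {
  expect_error(
    class_params(E_median_Pa = -1, eta_median_Pas = 1, radius_median_um = 5),
    "must be > 0"
  )
  expect_error(
    class_params(
      E_median_Pa = 1, eta_median_Pas = 1, radius_median_um = 5,
      active_fraction = 1.2
    ),
    "active_fraction"
  )
  expect_error(synth_config(list()), "named list")
})

test_that("trace simulation has the exact frame count and initial condition", {
  p <- stretch_protocol(400, stretch_s = 10, relax_s = 2, pre_stretch_s = 1)
  tr <- simulate_trace(make_truth(), p, axis_noise_sd = 0, seed = 1)
  expect_length(tr$time, floor(13 * 30) + 1) # 391
  d <- relative_deformation(tr)
  expect_equal(d$value[d$stretch_start], 0, tolerance = 1e-12)
  expect_error(
    simulate_trace(make_truth(), p, axis_noise_sd = -1, seed = 1),
    ">= 0"
  )
})

test_that("noise-free passive traces match the closed form to 1e-9", {
  p <- stretch_protocol(800, stretch_s = 10)
  tr <- simulate_trace(make_truth(E = 35, eta = 70, e0 = 1.05), p,
    axis_noise_sd = 0, seed = 2
  )
  g <- kv_strain_profile(tr$time, 35, 70, p$step_stress, 0, p)
  L0 <- 2 * 5 * sqrt(1.05)
  expect_lt(max(abs(tr$long_um / (L0 * (1 + g)) - 1)), 1e-9)
})

test_that("noisy traces keep the axis ordering invariant", {
  p <- stretch_protocol(400, stretch_s = 10)
  tr <- simulate_trace(make_truth(e0 = 1.0), p, axis_noise_sd = 0.3, seed = 5)
  expect_true(all(tr$long_um >= tr$short_um))
  expect_true(all(tr$short_um > 0))
})

test_that("cohorts assign protocols uniformly and are fully reproducible", {
  cfg <- synth_preset("clinical_like", n_per_class = 1500, axis_noise_sd = 0)
  co <- generate_cohort(cfg, seed = 3)
  frac <- as.numeric(table(co$truth$protocol_index)) / nrow(co$truth)
  expect_true(all(abs(frac - 1 / 3) < 0.03))
  # single protocol: degenerate assignment
  cfg1 <- synth_preset("clinical_like",
    n_per_class = 10,
    protocols = list(cell_line_protocol())
  )
  co1 <- generate_cohort(cfg1, seed = 3)
  expect_true(all(co1$truth$laser_power_mW == 875))
  # determinism end to end
  co2 <- generate_cohort(cfg1, seed = 3)
  expect_identical(co1$traces, co2$traces)
  expect_identical(co1$truth, co2$truth)
})

test_that("rendered frames are seeded, sized and area-faithful", {
  trc <- manual_trace(rep(10, 2), rep(10, 2),
    protocol = stretch_protocol(400, stretch_s = 1, pre_stretch_s = 0, relax_s = 0),
    time = c(0, 0.5)
  )
  trc$brightness <- rep(1.3, 2) # contrast against the 0.5 background
  st <- render_frames(trc,
    image_size = 96, pixel_scale = 0.25,
    background_noise_sd = 0, seed = 1
  )
  expect_equal(dim(st), c(96, 96, 2))
  # mask area of a 10 um circle within 2% of pi * 25 um^2
  cover <- (st[, , 1] - 0.5) / (0.5 * 0.3)
  expect_lt(abs(sum(cover) * 0.25^2 - pi * 25) / (pi * 25), 0.02)
  # identical seeds give bit-identical stacks
  stn <- render_frames(trc, 96, 0.25, background_noise_sd = 0.02, seed = 9)
  stn2 <- render_frames(trc, 96, 0.25, background_noise_sd = 0.02, seed = 9)
  expect_identical(stn, stn2)
  # zero-length trace -> zero frames
  tr0 <- structure(
    list(
      time = numeric(0), long_um = numeric(0), short_um = numeric(0),
      orient_deg = numeric(0), brightness = numeric(0), protocol = NULL,
      cell_id = "x", stretch_start = 1L, stretch_end = 2L, valid = TRUE
    ),
    class = "axis_trace"
  )
  expect_equal(dim(render_frames(tr0, 32, 0.25, 0, seed = 1))[3], 0)
})

test_that("ellipses that do not fit in the frame are rejected", {
  trc <- structure(
    list(
      time = 0, long_um = 30, short_um = 20, orient_deg = 0, brightness = 1.3,
      protocol = NULL, cell_id = "big", stretch_start = 1L, stretch_end = 1L,
      valid = TRUE
    ),
    class = "axis_trace"
  )
  expect_error(render_frames(trc, image_size = 64, pixel_scale = 0.25),
    "bounds")
})

test_that("trace CSV round-trips through the shared schema", {
  p <- stretch_protocol(400, stretch_s = 10)
  trs <- list(
    simulate_trace(make_truth(id = "a"), p, 0.05, seed = 1),
    simulate_trace(make_truth(id = "b"), p, 0.05, seed = 2)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_axis_traces(trs, f)
  back <- read_axis_traces(f, p)
  expect_length(back, 2)
  expect_equal(back[["a"]]$long_um, trs[[1]]$long_um)
  expect_equal(back[["b"]]$stretch_start, trs[[2]]$stretch_start)
})

test_that("synthetic configs survive a JSON round trip", {
  cfg <- synth_preset("clinical_like", n_per_class = 12, axis_noise_sd = 0.02)
  f <- withr::local_tempfile(fileext = ".json")
  write_synth_config(cfg, f)
  cfg2 <- read_synth_config(f)
  expect_equal(cfg2$n_per_class, 12)
  expect_equal(cfg2$axis_noise_sd, 0.02)
  expect_equal(cfg2$classes$PBMC$E_median_Pa, cfg$classes$PBMC$E_median_Pa)
  expect_equal(cfg2$protocols[[2]]$step_stress, cfg$protocols[[2]]$step_stress)
  # identical cohorts from the round-tripped config
  expect_identical(
    generate_cohort(cfg, seed = 4)$truth,
    generate_cohort(cfg2, seed = 4)$truth
  )
})
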