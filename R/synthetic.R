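#' Per-class parameter distributions for the synthetic generator
#'
#' Strictly positive mechanical parameters (elastic modulus, viscosity,
#' radius, brightness, rotation rate) are drawn from log-normal distributions
#' parameterised by their median and log-scale sd; the resting ellipticity is
#' normal truncated at 1; the activity is zero-inflated log-normal (a cell is
#' active with probability `active_fraction`, in which case its activity is
#' log-normal).
#'
#' @param E_median_Pa,E_sdlog Median (Pa) and log-sd of the elastic modulus.
#' @param eta_median_Pas,eta_sdlog Median (Pa s) and log-sd of the viscosity.
#' @param radius_median_um,radius_sdlog Median (um) and log-sd of the cell
#'   radius.
#' @param poisson_ratio Effective in-plane Poisson ratio coupling the
#'   short-axis strain to the long-axis strain (`S` strain = -nu * `L`
#'   strain), in `[0, 0.5]`.
#' @param ellipticity_mean,ellipticity_sd Mean and sd of the resting
#'   long/short axis ratio (truncated at 1).
#' @param brightness_median,brightness_sdlog Median and log-sd of the relative
#'   cell brightness.
#' @param active_fraction Probability that a cell is active, in `[0, 1]`.
#' @param activity_median_Pas,activity_sdlog Median (Pa/s) and log-sd of the
#'   activity of active cells.
#' @param rotation_median_dps,rotation_sdlog Median (deg/s) and log-sd of the
#'   in-plane rotation rate.
#' @return A list of class `class_params`.
#' @export
class_params <- function(E_median_Pa, E_sdlog = 0.25,
                         eta_median_Pas, eta_sdlog = 0.25,
                         radius_median_um, radius_sdlog = 0.12,
                         poisson_ratio = 0.3,
                         ellipticity_mean = 1.05, ellipticity_sd = 0.02,
                         brightness_median = 1.3, brightness_sdlog = 0.1,
                         active_fraction = 0.375,
                         activity_median_Pas = 0.08, activity_sdlog = 0.5,
                         rotation_median_dps = 1, rotation_sdlog = 0.7) {
  p <- as.list(environment())
  for (nm in c(
    "E_median_Pa", "E_sdlog", "eta_median_Pas", "eta_sdlog",
    "radius_median_um", "radius_sdlog", "ellipticity_sd",
    "brightness_median", "brightness_sdlog", "activity_median_Pas",
    "activity_sdlog", "rotation_median_dps", "rotation_sdlog"
  )) {
    if (p[[nm]] <= 0) stop("distribution parameter '", nm, "' must be > 0")
  }
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must be in [0, 1]")
  }
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop("poisson_ratio must be in [0, 0.5]")
  }
  if (ellipticity_mean < 1) stop("ellipticity_mean must be >= 1")
  structure(p, class = "class_params")
}

#' Synthetic-cohort configuration
#'
#' Bundles the per-class parameter distributions, the measurement protocols
#' and the axis measurement noise into a single configuration consumed by
#' [sample_population()] and [generate_cohort()].
#'
#' @param classes Named list of [class_params()]; names are the class labels.
#' @param protocols List of [stretch_protocol()]; each simulated cell is
#'   assigned one protocol uniformly at random.
#' @param n_per_class Number of cells per class (`>= 0`).
#' @param axis_noise_sd Gaussian measurement noise added to each per-frame
#'   axis length, micrometers (`>= 0`).
#' @return A list of class `synth_config`.
#' @seealso [synth_preset()] for ready-made configurations.
#' @export
synth_config <- function(classes, protocols = clinical_protocols(),
                         n_per_class = 100, axis_noise_sd = 0.05) {
  if (length(classes) == 0 || is.null(names(classes)) ||
    any(!nzchar(names(classes)))) {
    stop("'classes' must be a named list of class_params")
  }
  if (!all(vapply(classes, inherits, logical(1), "class_params"))) {
    stop("all elements of 'classes' must be class_params objects")
  }
  if (length(protocols) == 0) stop("at least one protocol is required")
  if (inherits(protocols, "stretch_protocol")) protocols <- list(protocols)
  if (!all(vapply(protocols, inherits, logical(1), "stretch_protocol"))) {
    stop("'protocols' must be stretch_protocol objects")
  }
  if (n_per_class < 0) stop("n_per_class must be >= 0")
  if (axis_noise_sd < 0) stop("axis_noise_sd must be >= 0")
  structure(
    list(
      classes = classes, protocols = protocols,
      n_per_class = as.integer(n_per_class), axis_noise_sd = axis_noise_sd
    ),
    class = "synth_config"
  )
}

#' Ready-made synthetic cohort presets
#'
#' * `"clinical_like"` — two classes, PBMC-like and CTC-candidate-like, under the
#'   clinical three-power protocol. The PBMC-like class is softer (E median
#'   30 Pa vs 50 Pa), smaller (radius median 4.7 um vs 7.5 um), more
#'   dissipative (tau = 3 s vs 0.8 s, hence lower shape restoration) and has a
#'   stronger Poisson coupling (0.45 vs 0.2), so its end-of-stretch elliptic
#'   deformation is about twice that of the CTC-like class. Both classes share
#'   the activity distribution: active fraction 0.375 (active:non-active ratio
#'   0.6), active-cell activity median 0.08 Pa/s.
#' * `"identical"` — both class labels drawn from the same (PBMC-like)
#'   distributions; a null cohort for calibration checks.
#' * `"separated"` — the clinical_like contrasts widened (about fourfold on the
#'   log scale for radius and stiffness) to give an easily separable cohort.
#'
#' @param name Preset name.
#' @param n_per_class,axis_noise_sd,protocols Overrides passed to
#'   [synth_config()].
#' @return A [synth_config()].
#' @export
synth_preset <- function(name = c("clinical_like", "identical", "separated"),
                         n_per_class = 100, axis_noise_sd = 0.05,
                         protocols = clinical_protocols()) {
  name <- match.arg(name)
  pbmc <- class_params(
    E_median_Pa = 30, E_sdlog = 0.45, eta_median_Pas = 90, eta_sdlog = 0.45,
    radius_median_um = 4.7, radius_sdlog = 0.18,
    poisson_ratio = 0.45, brightness_median = 1.2, brightness_sdlog = 0.15
  )
  ctc <- class_params(
    E_median_Pa = 50, E_sdlog = 0.45, eta_median_Pas = 40, eta_sdlog = 0.45,
    radius_median_um = 7.5, radius_sdlog = 0.18,
    poisson_ratio = 0.2, brightness_median = 1.2, brightness_sdlog = 0.15
  )
  classes <- switch(name,
    clinical_like = list(PBMC = pbmc, CTC_candidate = ctc),
    identical = list(PBMC = pbmc, CTC_candidate = pbmc),
    separated = list(
      PBMC = class_params(
        E_median_Pa = 15, eta_median_Pas = 90, radius_median_um = 4,
        E_sdlog = 0.15, radius_sdlog = 0.08,
        poisson_ratio = 0.45, brightness_median = 1.3
      ),
      CTC_candidate = class_params(
        E_median_Pa = 120, eta_median_Pas = 60, radius_median_um = 11,
        E_sdlog = 0.15, radius_sdlog = 0.08,
        poisson_ratio = 0.1, brightness_median = 1.15
      )
    )
  )
  synth_config(classes,
    protocols = protocols, n_per_class = n_per_class,
    axis_noise_sd = axis_noise_sd
  )
}

#' Sample a population of cells with known ground truth
#'
#' Draws `n_per_class` cells per configured class from the per-class
#' parameter distributions. The result is deterministic given `(config,
#' seed)`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A data.frame with one row per cell: `cell_id`, `class_label`,
#'   `E_Pa`, `eta_Pas`, `tau_s`, `activity_Pas`, `radius_um`,
#'   `init_ellipticity`, `brightness`, `rotation_dps`, `poisson_ratio`.
#' @export
sample_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_per_class
  if (n == 0L) {
    return(empty_population())
  }
  withr::with_seed(seed, {
    rows <- lapply(names(config$classes), function(lbl) {
      p <- config$classes[[lbl]]
      active <- stats::rbinom(n, 1, p$active_fraction) == 1
      a <- numeric(n)
      a[active] <- stats::rlnorm(
        sum(active),
        log(p$activity_median_Pas), p$activity_sdlog
      )
      data.frame(
        cell_id = NA_character_,
        class_label = lbl,
        E_Pa = stats::rlnorm(n, log(p$E_median_Pa), p$E_sdlog),
        eta_Pas = stats::rlnorm(n, log(p$eta_median_Pas), p$eta_sdlog),
        activity_Pas = a,
        radius_um = stats::rlnorm(n, log(p$radius_median_um), p$radius_sdlog),
        init_ellipticity = pmax(
          1,
          stats::rnorm(n, p$ellipticity_mean, p$ellipticity_sd)
        ),
        brightness = stats::rlnorm(n, log(p$brightness_median), p$brightness_sdlog),
        rotation_dps = stats::rlnorm(n, log(p$rotation_median_dps), p$rotation_sdlog),
        poisson_ratio = p$poisson_ratio,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$tau_s <- out$eta_Pas / out$E_Pa
    out$cell_id <- sprintf("cell_%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, c(
      "cell_id", "class_label", "E_Pa", "eta_Pas", "tau_s", "activity_Pas",
      "radius_um", "init_ellipticity", "brightness", "rotation_dps",
      "poisson_ratio"
    )]
  })
}

empty_population <- function() {
  data.frame(
    cell_id = character(0), class_label = character(0), E_Pa = numeric(0),
    eta_Pas = numeric(0), tau_s = numeric(0), activity_Pas = numeric(0),
    radius_um = numeric(0), init_ellipticity = numeric(0),
    brightness = numeric(0), rotation_dps = numeric(0),
    poisson_ratio = numeric(0), stringsAsFactors = FALSE
  )
}

#' Simulate the axis trace of one cell
#'
#' Forward model: the long-axis strain follows the active Kelvin-Voigt creep
#' during the stretch phase and exponential recovery afterwards
#' ([kv_strain_profile()]); the short axis co-varies through the cell's
#' effective Poisson ratio (`S` strain = -nu * `L` strain). Resting axes are
#' set from the cell radius `r` and resting ellipticity `e0` so that the
#' resting area is `pi r^2`: `L0 = 2 r sqrt(e0)`, `S0 = 2 r / sqrt(e0)`.
#' I.i.d. Gaussian noise of sd `axis_noise_sd` is added to each per-frame axis
#' length; frames where noise inverts the axis order are re-ordered so that
#' `L >= S` always holds.
#'
#' @param truth One row of the data.frame returned by [sample_population()]
#'   (or a list with the same fields).
#' @param protocol A [stretch_protocol()].
#' @param axis_noise_sd Per-frame axis noise sd, micrometers.
#' @param seed Integer seed.
#' @return An [axis_trace()].
#' @export
simulate_trace <- function(truth, protocol, axis_noise_sd = 0.05, seed = 1) {
  if (axis_noise_sd < 0) stop("axis_noise_sd must be >= 0")
  tt <- protocol_times(protocol)
  withr::with_seed(seed, {
    gamma <- kv_strain_profile(
      tt, truth$E_Pa, truth$eta_Pas,
      protocol$step_stress, truth$activity_Pas, protocol
    )
    e0 <- truth$init_ellipticity
    L0 <- 2 * truth$radius_um * sqrt(e0)
    S0 <- 2 * truth$radius_um / sqrt(e0)
    L <- L0 * (1 + gamma)
    S <- S0 * pmax(1 - truth$poisson_ratio * gamma, 0.05)
    if (axis_noise_sd > 0) {
      L <- L + stats::rnorm(length(tt), 0, axis_noise_sd)
      S <- S + stats::rnorm(length(tt), 0, axis_noise_sd)
    }
    Lc <- pmax(L, S)
    Sc <- pmax(pmin(L, S), 0.01)
    theta0 <- stats::runif(1, 0, 180)
    orient <- (theta0 + truth$rotation_dps * tt) %% 180
    axis_trace(tt, Lc, Sc, orient, rep(truth$brightness, length(tt)),
      protocol = protocol, cell_id = truth$cell_id
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Samples a population ([sample_population()]) and simulates one axis trace
#' per cell. When several protocols are configured each cell is assigned one
#' protocol uniformly at random (mirroring a measurement design in which the
#' laser power is set in random order per cell); trace and ground-truth lists
#' are aligned by `cell_id`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the whole cohort is a pure function of
#'   `(config, seed)`.
#' @return A list with elements `traces` (list of [axis_trace()]), `truth`
#'   (data.frame from [sample_population()] with added `laser_power_mW` and
#'   `protocol_index` columns), and `protocols`.
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  if (length(config$protocols) == 0) stop("empty protocol list")
  truth <- sample_population(config, seed = seed)
  n <- nrow(truth)
  withr::with_seed(seed + 1L, {
    idx <- if (length(config$protocols) == 1L) {
      rep(1L, n)
    } else {
      sample.int(length(config$protocols), n, replace = TRUE)
    }
    trace_seeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  truth$protocol_index <- idx
  truth$laser_power_mW <- vapply(
    idx, function(i) config$protocols[[i]]$laser_power, numeric(1)
  )
  traces <- lapply(seq_len(n), function(i) {
    simulate_trace(truth[i, ], config$protocols[[idx[i]]],
      axis_noise_sd = config$axis_noise_sd, seed = trace_seeds[i]
    )
  })
  names(traces) <- truth$cell_id
  list(traces = traces, truth = truth, protocols = config$protocols)
}
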