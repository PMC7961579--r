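#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical cumulative
#' distribution functions; the p-value uses the asymptotic two-sample KS
#' distribution by default (the exact method is impractical at the sample
#' sizes in scope). Significance stars follow the usual mapping: `*` p <
#' 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @param exact Use the exact null distribution (small samples only).
#' @return A list of class `ks_result`: `D`, `p_value`, `n1`, `n2`, `stars`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples need at least 2 finite observations")
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  structure(
    list(
      D = unname(kt$statistic), p_value = kt$p.value,
      n1 = length(x), n2 = length(y),
      stars = significance_stars(kt$p.value)
    ),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "<ks_result> D = %.4f, p = %.3g %s (n1 = %d, n2 = %d)\n",
    x$D, x$p_value, x$stars, x$n1, x$n2
  ))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' @param p P-value(s).
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or `""`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 0.001) {
      "***"
    } else if (pp < 0.01) {
      "**"
    } else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Pointwise median deformation curve with interquartile band
#'
#' @param curves List of [relative_deformation()] / elliptic curves sharing
#'   one time grid.
#' @return A data.frame `time`, `median`, `q25`, `q75` of the grid length.
#' @export
median_curve <- function(curves) {
  if (length(curves) == 0) stop("no curves")
  tt <- curves[[1]]$time
  for (cu in curves) {
    if (length(cu$time) != length(tt) || max(abs(cu$time - tt)) > 1e-9) {
      stop("curves are on mixed time grids")
    }
  }
  V <- vapply(curves, function(cu) cu$value, numeric(length(tt)))
  V <- matrix(V, nrow = length(tt))
  data.frame(
    time = tt,
    median = apply(V, 1, stats::median),
    q25 = apply(V, 1, stats::quantile, 0.25, names = FALSE),
    q75 = apply(V, 1, stats::quantile, 0.75, names = FALSE)
  )
}

#' Fold enrichment of a proportion
#'
#' Ratio of a case proportion to a control proportion (e.g. the proportion
#' of CD45-negative, non-hematopoietic cells in patient versus healthy-donor
#' samples), with the integer-rounded headline value also reported.
#'
#' @param prop_case,prop_control Proportions (any common unit; `prop_control
#'   > 0`).
#' @return A list with `fold` (exact ratio) and `headline` (rounded).
#' @export
fold_enrichment <- function(prop_case, prop_control) {
  if (prop_control <= 0) stop("control proportion must be > 0")
  if (prop_case < 0) stop("case proportion must be >= 0")
  fold <- prop_case / prop_control
  list(fold = fold, headline = round(fold))
}

#' Per-class cohort summary
#'
#' Medians of the headline scalar metrics per class (end-of-stretch relative
#' and elliptic deformation, fitted activity, shape restoration), computed on
#' unmasked values only, plus the active : non-active cell ratio (activity
#' from the active fit to the relative deformation, full window, thresholded
#' at `activity_threshold`).
#'
#' @param matrix A `feature_matrix` with class labels.
#' @param activity_threshold Pa/s threshold for the active label.
#' @return A list of class `cohort_summary` with `medians` (data.frame, one
#'   row per class) and `active_ratio` (active / non-active over all
#'   converged fits).
#' @export
cohort_summary <- function(matrix, activity_threshold = 0.001) {
  stopifnot("class_label" %in% names(matrix))
  act_col <- "a_relative_full_active"
  cols <- c(
    rel_def_end = "rel_def_end", ell_def_end = "ell_def_end",
    activity = act_col, shape_restoration = "shape_restoration",
    radius_um = "radius_um"
  )
  cols <- cols[cols %in% names(matrix)]
  med <- do.call(rbind, lapply(split(matrix, matrix$class_label), function(d) {
    row <- lapply(cols, function(cn) stats::median(d[[cn]], na.rm = TRUE))
    as.data.frame(row)
  }))
  med <- cbind(class_label = rownames(med), med)
  rownames(med) <- NULL
  a <- matrix[[act_col]]
  a <- a[!is.na(a)]
  n_active <- sum(a > activity_threshold)
  n_non <- sum(a <= activity_threshold)
  structure(
    list(
      medians = med,
      active_ratio = if (n_non > 0) n_active / n_non else NA_real_,
      n_active = n_active, n_non_active = n_non
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$medians)
  cat(sprintf(
    "  active : non-active ratio = %.3f (%d : %d)\n",
    x$active_ratio, x$n_active, x$n_non_active
  ))
  invisible(x)
}

#' End-to-end pipeline: simulate, featurize, test, classify, summarise
#'
#' Chains the full analysis on a synthetic cohort: generates traces
#' ([generate_cohort()]), assembles the feature matrix
#' ([featurize_cohort()]), runs per-power and pooled two-sample KS tests on
#' the end-of-stretch relative deformation, end-of-stretch elliptic
#' deformation and shape restoration between the two classes, evaluates the
#' pooled random-forest classifier and computes the cohort summary. The whole
#' bundle is a pure function of `(config, rf, seed)`.
#'
#' @param config A [synth_config()].
#' @param rf An [rf_config()].
#' @param seed Integer seed for the cohort.
#' @param classify Run the random-forest stage (the slowest part).
#' @return A list of class `os_report`: `matrix`, `truth`, `ks` (data.frame
#'   of KS results per metric and power subset), `classification`,
#'   `summary`, `seed`.
#' @export
run_pipeline <- function(config, rf = rf_config(), seed = 1, classify = TRUE) {
  cohort <- generate_cohort(config, seed = seed)
  fm <- featurize_cohort(cohort$traces, class_labels = cohort$truth$class_label)
  classes <- unique(fm$class_label)
  ks_rows <- list()
  if (length(classes) == 2) {
    subsets <- c(
      list(pooled = seq_len(nrow(fm))),
      lapply(
        split(seq_len(nrow(fm)), fm$laser_power),
        identity
      )
    )
    names(subsets)[-1] <- paste0(names(subsets)[-1], "_mW")
    for (metric in c("rel_def_end", "ell_def_end", "shape_restoration")) {
      for (sn in names(subsets)) {
        d <- fm[subsets[[sn]], ]
        x <- d[[metric]][d$class_label == classes[1]]
        y <- d[[metric]][d$class_label == classes[2]]
        if (sum(is.finite(x)) >= 2 && sum(is.finite(y)) >= 2) {
          ks <- ks_two_sample(x, y)
          ks_rows[[length(ks_rows) + 1L]] <- data.frame(
            metric = metric, subset = sn, D = ks$D, p_value = ks$p_value,
            stars = ks$stars, n1 = ks$n1, n2 = ks$n2,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  report <- NULL
  if (classify && length(classes) >= 2) {
    report <- train_and_evaluate(fm, rf)
  }
  structure(
    list(
      matrix = fm, truth = cohort$truth,
      ks = if (length(ks_rows)) do.call(rbind, ks_rows) else NULL,
      classification = report,
      summary = cohort_summary(fm),
      seed = seed
    ),
    class = "os_report"
  )
}

#' @export
print.os_report <- function(x, ...) {
  cat(sprintf("<os_report> seed %d, %d cells\n", x$seed, nrow(x$matrix)))
  if (!is.null(x$ks)) {
    cat("KS tests:\n")
    print(x$ks, row.names = FALSE)
  }
  if (!is.null(x$classification)) print(x$classification)
  print(x$summary)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes the feature matrix and KS table as CSV and a JSON summary
#' (metrics, classification report, seed).
#'
#' @param report An `os_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$matrix),
    file.path(dir, "feature_matrix.csv"),
    row.names = FALSE
  )
  if (!is.null(report$ks)) {
    utils::write.csv(report$ks, file.path(dir, "ks_tests.csv"), row.names = FALSE)
  }
  summ <- list(
    seed = report$seed,
    n_cells = nrow(report$matrix),
    medians = report$summary$medians,
    active_ratio = report$summary$active_ratio
  )
  if (!is.null(report$classification)) {
    cl <- report$classification
    summ$classification <- list(
      accuracy = cl$accuracy, sensitivity = cl$sensitivity,
      specificity = cl$specificity, counts = cl$counts
    )
    utils::write.csv(cl$importance, file.path(dir, "importance.csv"),
      row.names = FALSE
    )
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
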