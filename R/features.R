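#' Default per-cell feature schema
#'
#' An ordered description of the per-cell feature vector assembled from
#' morphology, deformation curves, Kelvin-Voigt fits, shape restoration and
#' the protocol. Fit features cover every signal x window x model
#' combination (E, eta, tau, fit error; plus the activity for active
#' models). The schema is a plain data.frame and can be subset or extended
#' (e.g. loaded from JSON) as long as every descriptor resolves against the
#' upstream outputs.
#'
#' @return A data.frame of class `feature_schema` with columns `name`,
#'   `source` (`morphology`, `curve`, `fit`, `restoration`, `protocol`),
#'   `signal`, `window`, `model`, `param`, and attribute `version`.
#' @export
default_feature_schema <- function() {
  morph <- data.frame(
    name = c(
      "radius_um", "area_um2", "rel_brightness", "initial_ellipticity",
      "rotation_deg"
    ),
    source = "morphology", signal = NA, window = NA, model = NA,
    param = c(
      "effective_radius_um", "area_um2", "mean_brightness",
      "initial_ellipticity", "rotation_degree"
    ),
    stringsAsFactors = FALSE
  )
  curve <- data.frame(
    name = c("rel_def_end", "ell_def_end"),
    source = "curve", signal = c("relative", "elliptic"),
    window = NA, model = NA, param = "end_of_stretch",
    stringsAsFactors = FALSE
  )
  resto <- data.frame(
    name = "shape_restoration", source = "restoration", signal = "relative",
    window = NA, model = NA, param = "shape_restoration",
    stringsAsFactors = FALSE
  )
  proto <- data.frame(
    name = c("laser_power_mW", "step_stress_Pa"),
    source = "protocol", signal = NA, window = NA, model = NA,
    param = c("laser_power", "step_stress"),
    stringsAsFactors = FALSE
  )
  fits <- do.call(rbind, lapply(c("relative", "elliptic"), function(sig) {
    do.call(rbind, lapply(c("full", "first2s"), function(win) {
      do.call(rbind, lapply(c("passive", "active"), function(mod) {
        pars <- c("E", "eta", "tau", "fit_error")
        if (mod == "active") pars <- c(pars, "a")
        data.frame(
          name = paste(pars, sig, win, mod, sep = "_"),
          source = "fit", signal = sig, window = win, model = mod,
          param = pars, stringsAsFactors = FALSE
        )
      }))
    }))
  }))
  out <- rbind(morph, curve, resto, proto, fits)
  if (anyDuplicated(out$name)) stop("duplicate feature names in schema")
  rownames(out) <- NULL
  structure(out, version = "1", class = c("feature_schema", "data.frame"))
}

#' Build the feature row of one cell
#'
#' Resolves every schema descriptor against the cell's morphology, curves,
#' fits, restoration result and protocol. Features of non-converged fits are
#' `NA` (an explicit missing-value mask, never silent defaults); the row is
#' retained.
#'
#' @param morph A [compute_morphology()] result.
#' @param curves Named list with `relative` and `elliptic`
#'   [relative_deformation()] curves.
#' @param fits Named list of [fit_kv()] results as returned by [fit_cell()].
#' @param restoration A [shape_restoration()] result.
#' @param protocol The cell's [stretch_protocol()].
#' @param schema A feature schema; default [default_feature_schema()].
#' @return A named numeric vector ordered exactly as the schema.
#' @export
build_feature_vector <- function(morph, curves, fits, restoration, protocol,
                                 schema = default_feature_schema()) {
  vals <- vapply(seq_len(nrow(schema)), function(i) {
    d <- schema[i, ]
    switch(d$source,
      morphology = as.numeric(morph[[d$param]]),
      curve = {
        cu <- curves[[d$signal]]
        if (is.null(cu)) stop("schema references missing curve: ", d$signal)
        cu$value[cu$stretch_end]
      },
      restoration = as.numeric(restoration[[d$param]]),
      protocol = as.numeric(protocol[[d$param]]),
      fit = {
        f <- fits[[paste(d$signal, d$window, d$model, sep = "_")]]
        if (is.null(f)) {
          stop(
            "schema references missing fit: ",
            paste(d$signal, d$window, d$model, sep = "_")
          )
        }
        if (!isTRUE(f$converged)) NA_real_ else as.numeric(f[[kv_param_field(d$param)]])
      },
      stop("unknown feature source: ", d$source)
    )
  }, numeric(1))
  names(vals) <- schema$name
  vals
}

kv_param_field <- function(p) {
  switch(p,
    E = "E", eta = "eta", tau = "tau", a = "a", fit_error = "fit_error",
    stop("unknown fit parameter: ", p)
  )
}

#' Featurize a whole cohort of traces
#'
#' Runs the rheology stage (deformation curves, eight Kelvin-Voigt fits,
#' shape restoration) and the morphology stage on every valid trace and
#' stacks the feature rows into a feature matrix. Invalid traces are dropped
#' (and reported via a message).
#'
#' @param traces List of [axis_trace()] objects.
#' @param class_labels Optional character vector of class labels aligned with
#'   `traces` (or named by cell id).
#' @param schema Feature schema.
#' @return A data.frame of class `feature_matrix`: columns `cell_id`,
#'   `class_label`, `laser_power` then one column per schema feature, with
#'   the schema attached as attribute `schema`. `NA` entries mark masked
#'   (non-converged) fit features.
#' @export
featurize_cohort <- function(traces, class_labels = NULL,
                             schema = default_feature_schema()) {
  keep <- vapply(traces, function(tr) isTRUE(tr$valid), logical(1))
  if (any(!keep)) {
    message(sum(!keep), " invalid trace(s) excluded from the feature matrix")
  }
  traces <- traces[keep]
  if (!is.null(class_labels)) class_labels <- class_labels[keep]
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    curves <- list(
      relative = relative_deformation(tr),
      elliptic = elliptic_deformation(tr)
    )
    build_feature_vector(
      morph = compute_morphology(tr),
      curves = curves,
      fits = fit_cell(tr),
      restoration = shape_restoration(curves$relative),
      protocol = tr$protocol,
      schema = schema
    )
  })
  if (length(rows) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, nrow(schema)))
    names(out) <- schema$name
    out <- cbind(
      data.frame(
        cell_id = character(0), class_label = character(0),
        laser_power = numeric(0), stringsAsFactors = FALSE
      ),
      out
    )
    return(structure(out,
      schema = schema,
      class = c("feature_matrix", "data.frame")
    ))
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(
    data.frame(
      cell_id = vapply(traces, function(tr) as.character(tr$cell_id), character(1)),
      class_label = if (is.null(class_labels)) NA_character_ else as.character(class_labels),
      laser_power = vapply(traces, function(tr) tr$protocol$laser_power, numeric(1)),
      stringsAsFactors = FALSE
    ),
    out
  )
  rownames(out) <- NULL
  structure(out, schema = schema, class = c("feature_matrix", "data.frame"))
}

#' Assemble feature rows into per-power or pooled matrices
#'
#' @param rows A `feature_matrix` (or plain data.frame of feature rows
#'   sharing one schema).
#' @param mode `"pooled"` keeps one matrix with the laser power as a feature
#'   column; `"per_power"` partitions the rows by laser power.
#' @return The pooled `feature_matrix`, or a named list of per-power
#'   matrices.
#' @export
assemble_matrix <- function(rows, mode = c("pooled", "per_power")) {
  mode <- match.arg(mode)
  schema <- attr(rows, "schema")
  if (is.null(schema)) stop("rows carry no schema attribute")
  feat_cols <- setdiff(names(rows), c("cell_id", "class_label", "laser_power"))
  if (!identical(feat_cols, schema$name)) {
    stop("rows do not match their schema (mixed schemas?)")
  }
  if (mode == "pooled") {
    return(rows)
  }
  parts <- split(seq_len(nrow(rows)), rows$laser_power)
  out <- lapply(parts, function(ii) {
    structure(rows[ii, , drop = FALSE],
      schema = schema,
      class = c("feature_matrix", "data.frame")
    )
  })
  names(out) <- paste0("power_", names(parts))
  out
}

#' Median imputation with explicit missingness indicators
#'
#' Fills `NA` feature values with per-feature medians estimated on the
#' training split only (leakage-safe) and appends a 0/1 `<feature>_missing`
#' indicator column for every feature that is ever missing in the training
#' split. Used inside cross-validation.
#'
#' @param train,test Data.frames of feature columns only.
#' @return A list with imputed `train` and `test` data.frames.
#' @export
impute_median <- function(train, test = NULL) {
  med <- vapply(train, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  med[!is.finite(med)] <- 0
  has_na <- names(train)[vapply(train, anyNA, logical(1))]
  fill <- function(df) {
    for (nm in names(df)) {
      miss <- is.na(df[[nm]])
      if (any(miss)) df[[nm]][miss] <- med[[nm]]
    }
    df
  }
  add_ind <- function(df, raw) {
    for (nm in has_na) {
      df[[paste0(nm, "_missing")]] <- as.numeric(is.na(raw[[nm]]))
    }
    df
  }
  raw_train <- train
  train <- add_ind(fill(train), raw_train)
  if (!is.null(test)) {
    raw_test <- test
    test <- add_ind(fill(test), raw_test)
  }
  list(train = train, test = test)
}
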