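#' Per-cell axis trace
#'
#' The raw measurement of one cell in the optical stretcher: per-frame long
#' and short axis lengths, in-plane orientation and relative brightness, plus
#' the indices of the frames at which the step stress starts and ends.
#'
#' @param time Frame times in seconds, strictly increasing.
#' @param long_um Long-axis length per frame, micrometers.
#' @param short_um Short-axis length per frame, micrometers.
#' @param orient_deg In-plane orientation per frame, degrees in `[0, 180)`.
#' @param brightness Relative cell brightness per frame (interior intensity /
#'   background), dimensionless.
#' @param protocol The [stretch_protocol()] under which the trace was
#'   recorded.
#' @param cell_id Identifier of the cell.
#' @param stretch_start,stretch_end Frame indices (1-based) of the first and
#'   last frame of the stretch phase. Derived from `protocol` when `NULL`.
#' @param valid Logical flag; traces with too many tracking failures are
#'   marked invalid and excluded downstream.
#'
#' @return An object of class `axis_trace`.
#' @export
axis_trace <- function(time, long_um, short_um,
                       orient_deg = rep(0, length(time)),
                       brightness = rep(1, length(time)),
                       protocol = NULL, cell_id = NA_character_,
                       stretch_start = NULL, stretch_end = NULL,
                       valid = TRUE) {
  n <- length(time)
  stopifnot(
    length(long_um) == n, length(short_um) == n,
    length(orient_deg) == n, length(brightness) == n
  )
  if (n > 1 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (valid) {
    if (any(short_um <= 0)) stop("short axis must be > 0")
    if (any(long_um < short_um - 1e-12)) stop("long axis must be >= short axis")
  }
  if (is.null(stretch_start) || is.null(stretch_end)) {
    if (is.null(protocol)) stop("either phase marks or a protocol is required")
    t0 <- protocol$pre_stretch_duration
    t1 <- t0 + protocol$stretch_duration
    stretch_start <- which(time >= t0 - 1e-9)[1]
    stretch_end <- max(which(time <= t1 + 1e-9))
  }
  if (is.na(stretch_start) || is.na(stretch_end) ||
    stretch_start < 1 || stretch_end > n || stretch_start >= stretch_end) {
    stop("invalid stretch phase marks")
  }
  structure(
    list(
      time = as.numeric(time),
      long_um = as.numeric(long_um),
      short_um = as.numeric(short_um),
      orient_deg = as.numeric(orient_deg),
      brightness = as.numeric(brightness),
      protocol = protocol,
      cell_id = cell_id,
      stretch_start = as.integer(stretch_start),
      stretch_end = as.integer(stretch_end),
      valid = isTRUE(valid)
    ),
    class = "axis_trace"
  )
}

#' @export
print.axis_trace <- function(x, ...) {
  cat(sprintf(
    "<axis_trace> cell %s: %d frames, stretch frames [%d, %d]%s\n",
    x$cell_id, length(x$time), x$stretch_start, x$stretch_end,
    if (x$valid) "" else " (INVALID)"
  ))
  invisible(x)
}

#' @export
as.data.frame.axis_trace <- function(x, ...) {
  data.frame(
    cell_id = x$cell_id, t_s = x$time, long_um = x$long_um,
    short_um = x$short_um, orient_deg = x$orient_deg,
    brightness = x$brightness, stringsAsFactors = FALSE
  )
}

n_pre_stretch <- function(trace) trace$stretch_start - 1L

#' Read and write axis traces as CSV
#'
#' Traces are stored in long format with columns `cell_id`, `t_s`, `long_um`,
#' `short_um`, `orient_deg`, `brightness`; the schema is shared between the
#' synthetic generator and the tracking stage.
#'
#' @param traces A list of [axis_trace()] objects.
#' @param file Path to a CSV file.
#' @param protocol Protocol to attach to each trace on reading (single
#'   [stretch_protocol()] applied to all cells).
#' @return `write_axis_traces` returns `file` invisibly; `read_axis_traces`
#'   returns a list of [axis_trace()] objects.
#' @export
write_axis_traces <- function(traces, file) {
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_axis_traces
#' @export
read_axis_traces <- function(file, protocol) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))), function(d) {
    axis_trace(d$t_s, d$long_um, d$short_um, d$orient_deg, d$brightness,
      protocol = protocol, cell_id = d$cell_id[1]
    )
  })
}
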