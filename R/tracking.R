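#' Detect the cell contour in a grayscale frame
#'
#' Thresholds the frame halfway between the background level (median
#' intensity) and the object peak (0.999 intensity quantile) and extracts the
#' sub-pixel iso-intensity contour at that level by marching squares
#' ([grDevices::contourLines()]). Among all closed contours not touching the
#' frame border, the one enclosing the largest area is returned; if none
#' encloses at least `min_area_px` pixels the detection fails.
#'
#' @param frame Numeric matrix (rows = y, columns = x; pixel centers at
#'   integer coordinates, origin top-left).
#' @param threshold Iso-intensity level; computed from the frame when `NULL`.
#' @param min_area_px Minimal enclosed area, square pixels.
#' @return A data.frame with columns `x`, `y` (continuous pixel coordinates)
#'   and attribute `area_px`, or `NULL` (with attribute-free semantics) when
#'   detection fails.
#' @export
detect_contour <- function(frame, threshold = NULL, min_area_px = 9) {
  if (length(frame) == 0) stop("empty frame")
  if (is.null(threshold)) {
    bg <- stats::median(frame)
    peak <- stats::quantile(frame, 0.999, names = FALSE)
    if (!is.finite(bg) || !is.finite(peak) || peak <= bg) {
      return(NULL)
    }
    threshold <- bg + 0.5 * (peak - bg)
  }
  # transpose so that contour x follows matrix columns and y follows rows
  cl <- grDevices::contourLines(
    x = seq_len(ncol(frame)), y = seq_len(nrow(frame)),
    z = t(frame), levels = threshold
  )
  if (length(cl) == 0) {
    return(NULL)
  }
  closed <- Filter(function(cc) {
    n <- length(cc$x)
    n >= 5 &&
      abs(cc$x[1] - cc$x[n]) < 1e-8 && abs(cc$y[1] - cc$y[n]) < 1e-8
  }, cl)
  if (length(closed) == 0) {
    return(NULL)
  }
  areas <- vapply(closed, function(cc) abs(polygon_area(cc$x, cc$y)), numeric(1))
  best <- which.max(areas)
  if (areas[best] < min_area_px) {
    return(NULL)
  }
  cc <- closed[[best]]
  n <- length(cc$x)
  structure(
    data.frame(x = cc$x[-n], y = cc$y[-n]), # drop duplicated closing point
    area_px = areas[best], threshold = threshold
  )
}

polygon_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Direct least-squares ellipse fit to contour points
#'
#' Fits an ellipse to a set of contour points with the numerically stable
#' direct algebraic least-squares method (constraint `4AC - B^2 = 1`), then
#' converts the conic to geometric parameters.
#'
#' @param contour Data.frame or list with numeric `x` and `y` (pixel
#'   coordinates, at least 5 points).
#' @param pixel_scale Micrometers per pixel.
#' @return A list with `L_um`, `S_um` (full axis lengths, micrometers),
#'   `orientation_deg` (major-axis angle from the x axis, degrees in
#'   `[0, 180)`) and `center_px` (length-2 vector).
#' @export
fit_ellipse <- function(contour, pixel_scale = 1) {
  x <- as.numeric(contour$x)
  y <- as.numeric(contour$y)
  if (length(x) < 5) stop("at least 5 contour points are required")
  mx <- mean(x)
  my <- mean(y)
  xc <- x - mx
  yc <- y - my
  D1 <- cbind(xc^2, xc * yc, yc^2)
  D2 <- cbind(xc, yc, rep(1, length(xc)))
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("degenerate contour: points are collinear or nearly so")
  })
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("degenerate contour: no ellipse solution")
  a1 <- vecs[, ok[1]]
  a2 <- as.numeric(Tm %*% a1)
  conic_to_ellipse(a1[1], a1[2], a1[3], a2[1], a2[2], a2[3],
    offset = c(mx, my), pixel_scale = pixel_scale
  )
}

conic_to_ellipse <- function(A, B, C, D, E, F, offset, pixel_scale) {
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  semi <- sqrt(-F0 / eq$values)
  if (any(!is.finite(semi))) stop("degenerate conic")
  i_major <- which.max(semi) # conic sign is arbitrary; pick axes by length
  major <- semi[i_major]
  minor <- semi[-i_major]
  major_vec <- eq$vectors[, i_major]
  ang <- (atan2(major_vec[2], major_vec[1]) * 180 / pi) %% 180
  list(
    L_um = 2 * major * pixel_scale,
    S_um = 2 * minor * pixel_scale,
    orientation_deg = ang,
    center_px = c(x0 + offset[1], y0 + offset[2])
  )
}

#' Track cell axes through a frame stack
#'
#' Runs [detect_contour()] and [fit_ellipse()] on every frame, measures the
#' relative cell brightness (mean interior intensity / median background
#' intensity), linearly interpolates isolated detection failures (runs of at
#' most `max_interp_run` frames, not at the stack ends) and assembles an
#' [axis_trace()] with phase marks taken from the protocol. If more than
#' `max_failed_frac` of the frames fail, the trace is marked invalid.
#'
#' @param stack A `frame_stack` from [render_frames()] or any numeric 3-d
#'   array (rows x columns x frames).
#' @param protocol The [stretch_protocol()] the stack was recorded under.
#' @param pixel_scale Micrometers per pixel; taken from the stack attribute
#'   when available.
#' @param threshold Optional fixed iso-intensity level for all frames.
#' @param max_failed_frac Maximal tolerated fraction of failed frames.
#' @param max_interp_run Longest run of consecutive failures that is
#'   interpolated.
#' @param cell_id Identifier attached to the trace.
#' @return An [axis_trace()]; inspect its `valid` flag before use.
#' @export
trace_axes <- function(stack, protocol, pixel_scale = NULL, threshold = NULL,
                       max_failed_frac = 0.1, max_interp_run = 2,
                       cell_id = "tracked") {
  if (is.null(pixel_scale)) pixel_scale <- attr(stack, "pixel_scale")
  if (is.null(pixel_scale)) stop("pixel_scale is required")
  n <- dim(stack)[3]
  if (n == 0) stop("empty stack")
  L <- S <- th <- br <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    frame <- stack[, , k]
    cc <- detect_contour(frame, threshold = threshold)
    if (is.null(cc)) next
    fe <- tryCatch(fit_ellipse(cc, pixel_scale), error = function(e) NULL)
    if (is.null(fe)) next
    L[k] <- fe$L_um
    S[k] <- fe$S_um
    th[k] <- fe$orientation_deg
    thr <- attr(cc, "threshold")
    inner <- frame > thr + 0.6 * (max(frame) - thr)
    bg_med <- stats::median(frame[frame < thr])
    if (any(inner) && is.finite(bg_med) && bg_med > 0) {
      br[k] <- mean(frame[inner]) / bg_med
    }
  }
  failed <- !is.finite(L) | !is.finite(S)
  valid <- TRUE
  if (mean(failed) > max_failed_frac ||
    !interpolatable(failed, max_interp_run)) {
    valid <- FALSE
  } else if (any(failed)) {
    idx <- seq_len(n)
    L <- stats::approx(idx[!failed], L[!failed], idx)$y
    S <- stats::approx(idx[!failed], S[!failed], idx)$y
    th <- stats::approx(idx[!failed], th[!failed], idx)$y
    br <- stats::approx(idx[!failed], br[!failed], idx)$y
  }
  tt <- protocol_times(protocol)[seq_len(n)]
  if (!valid) {
    return(structure(
      list(
        time = tt, long_um = L, short_um = S, orient_deg = th,
        brightness = br, protocol = protocol, cell_id = cell_id,
        stretch_start = 1L, stretch_end = 2L, valid = FALSE
      ),
      class = "axis_trace"
    ))
  }
  axis_trace(tt, pmax(L, S), pmin(L, S), th, br,
    protocol = protocol, cell_id = cell_id
  )
}

interpolatable <- function(failed, max_run) {
  if (!any(failed)) {
    return(TRUE)
  }
  r <- rle(failed)
  runs <- r$lengths[r$values]
  if (failed[1] || failed[length(failed)]) {
    return(FALSE)
  }
  all(runs <= max_run)
}

#' Morphology descriptors of a traced cell
#'
#' Computed from the pre-stretch baseline and the stretch phase of an axis
#' trace: the area is the mean ellipse area over the pre-stretch window,
#' `effective_radius = sqrt(area / pi)`, `initial_ellipticity` is the mean
#' resting long/short axis ratio and `rotation_degree` is the cumulative
#' absolute in-plane orientation change over the stretch phase, unwrapped
#' modulo 180 degrees (invariant under a global orientation offset).
#'
#' @param trace A valid [axis_trace()] with at least one pre-stretch frame.
#' @return A list of class `morphology` with fields `effective_radius_um`,
#'   `area_um2`, `mean_brightness`, `initial_ellipticity`,
#'   `rotation_degree`.
#' @export
compute_morphology <- function(trace) {
  if (!isTRUE(trace$valid)) stop("trace is invalid")
  npre <- n_pre_stretch(trace)
  if (npre < 1) stop("no pre-stretch frames")
  pre <- seq_len(npre)
  area <- mean(pi * (trace$long_um[pre] / 2) * (trace$short_um[pre] / 2))
  stretch <- trace$stretch_start:trace$stretch_end
  dth <- diff(trace$orient_deg[stretch])
  dth <- dth - 180 * round(dth / 180) # unwrap to (-90, 90]
  structure(
    list(
      effective_radius_um = sqrt(area / pi),
      area_um2 = area,
      mean_brightness = mean(trace$brightness[pre]),
      initial_ellipticity = mean(trace$long_um[pre] / trace$short_um[pre]),
      rotation_degree = sum(abs(dth))
    ),
    class = "morphology"
  )
}
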