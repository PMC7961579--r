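#' Render a synthetic phase-contrast-like frame stack from an axis trace
#'
#' Draws, for every frame of the trace, one filled ellipse with the frame's
#' axes, orientation and brightness on a noisy uniform background. Edges are
#' anti-aliased with an approximate per-pixel coverage (signed-distance
#' smoothing over one pixel), so that the half-intensity iso-contour of a
#' noise-free frame coincides with the true ellipse boundary.
#'
#' Image convention: pixel centers at integer coordinates, origin top-left;
#' `x` increases along columns, `y` along rows. The ellipse is centered in
#' the frame. The cell interior level is `background_level * brightness`
#' (brightness is the trace's relative brightness).
#'
#' @param trace An [axis_trace()].
#' @param image_size Side length of the square frame, pixels.
#' @param pixel_scale Micrometers per pixel.
#' @param background_noise_sd Sd of i.i.d. Gaussian intensity noise added to
#'   every pixel.
#' @param seed Integer seed for the noise.
#' @param background_level Background intensity (arbitrary units).
#' @return A numeric array `image_size x image_size x n_frames` of class
#'   `frame_stack` (zero frames give a `image_size x image_size x 0` array).
#' @export
render_frames <- function(trace, image_size = 96, pixel_scale = 0.25,
                          background_noise_sd = 0.01, seed = 1,
                          background_level = 0.5) {
  if (background_noise_sd < 0) stop("background_noise_sd must be >= 0")
  n <- length(trace$time)
  fov_um <- image_size * pixel_scale
  if (n > 0) {
    max_ext <- max(trace$long_um) / 2
    if (max_ext + 2 * pixel_scale > fov_um / 2) {
      stop(sprintf(
        "ellipse exceeds frame bounds: semi-axis %.2f um in a %.2f um half-field",
        max_ext, fov_um / 2
      ))
    }
  }
  cx <- (image_size + 1) / 2
  xs <- (col(matrix(0, image_size, image_size)) - cx) * pixel_scale
  ys <- (row(matrix(0, image_size, image_size)) - cx) * pixel_scale
  stack <- array(0, dim = c(image_size, image_size, n))
  withr::with_seed(seed, {
    for (k in seq_len(n)) {
      stack[, , k] <- render_ellipse_frame(
        xs, ys,
        L = trace$long_um[k], S = trace$short_um[k],
        theta_deg = trace$orient_deg[k],
        level_in = background_level * trace$brightness[k],
        level_bg = background_level, pixel_scale = pixel_scale
      )
    }
    if (background_noise_sd > 0 && n > 0) {
      stack <- stack + array(
        stats::rnorm(length(stack), 0, background_noise_sd),
        dim = dim(stack)
      )
    }
  })
  structure(stack, class = c("frame_stack", class(stack)),
    pixel_scale = pixel_scale, background_level = background_level
  )
}

render_ellipse_frame <- function(xs, ys, L, S, theta_deg, level_in, level_bg,
                                 pixel_scale) {
  th <- theta_deg * pi / 180
  A <- L / 2
  B <- S / 2
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  rho <- sqrt((u / A)^2 + (v / B)^2)
  grad <- sqrt(u^2 / A^4 + v^2 / B^4) / pmax(rho, 1e-9)
  delta <- (1 - rho) / pmax(grad, 1e-9) # approx signed distance to boundary, um
  cover <- pmin(1, pmax(0, 0.5 + delta / pixel_scale))
  cover[rho < 1e-9] <- 1
  level_bg + (level_in - level_bg) * cover
}
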