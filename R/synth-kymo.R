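# Line-scan kymograph phantom: dark erythrocyte streaks crossing a bright
# plasma background at a known slope (pixels per line).

#' Kymograph container
#'
#' @param image numeric matrix, rows = scan lines (time), columns =
#'   positions along the line, a.u.
#' @param pixel_size micrometres per pixel along the line.
#' @param line_period milliseconds per scan line.
#' @param empty logical flag set by the generator when no streaks were laid
#'   down.
#' @return object of class `kymograph`.
#' @export
kymograph <- function(image, pixel_size, line_period, empty = FALSE) {
  image <- as.matrix(image)
  if (nrow(image) < 2L) stop_field("image", "need >= 2 scan lines")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(line_period, "line_period", positive = TRUE)
  structure(list(image = image, pixel_size = pixel_size,
                 line_period = line_period, empty = isTRUE(empty)),
            class = "kymograph")
}

#' Generate a kymograph with streaks of known velocity
#'
#' A cell moving at `true_velocity` (micrometres per millisecond) advances
#' `true_velocity * line_period / pixel_size` pixels per scan line, tracing
#' a diagonal dark streak: each streak is a Gaussian intensity dip of depth
#' `streak_contrast` and width `streak_width` pixels. Streak starting
#' offsets are drawn uniformly over an extended range so the expected
#' number of streaks crossing any line equals `streak_density`. A zero
#' density yields a uniform bright image flagged `empty` in metadata.
#'
#' @param spec a [kymograph_spec()].
#' @return a [kymograph()].
#' @export
generate_kymograph <- function(spec) {
  stopifnot(inherits(spec, "kymograph_spec"))
  np <- spec$n_positions; nl <- spec$n_lines
  slope_px <- spec$true_velocity * spec$line_period / spec$pixel_size
  img <- matrix(spec$background_intensity, nl, np)
  empty <- spec$streak_density == 0
  img <- with_seed(spec$seed, {
    if (!empty) {
      # offsets at line 0 span the window plus the total drift so that the
      # per-line crossing count is uniform across lines
      drift <- abs(slope_px) * (nl - 1)
      span <- np + drift + 8 * spec$streak_width
      n_streaks <- max(1L, round(spec$streak_density * span / np))
      x0 <- stats::runif(n_streaks,
                         min = -4 * spec$streak_width -
                           (if (slope_px > 0) drift else 0),
                         max = np - 1 + 4 * spec$streak_width +
                           (if (slope_px < 0) drift else 0))
      pos <- 0:(np - 1)
      for (t in seq_len(nl)) {
        centers <- x0 + slope_px * (t - 1)
        for (c0 in centers) {
          if (c0 < -4 * spec$streak_width ||
              c0 > np - 1 + 4 * spec$streak_width) next
          img[t, ] <- img[t, ] - spec$streak_contrast *
            exp(-(pos - c0)^2 / (2 * spec$streak_width^2))
        }
      }
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nl * np, 0, spec$noise_sd), nl, np)
    pmax(img, 0)
  })
  kymograph(img, spec$pixel_size, spec$line_period, empty = empty)
}
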