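# Erythrocyte velocimetry from line-scan kymographs: dominant streak
# orientation by Radon-style sheared projection variance maximization, the
# acetylcholine delta-velocity statistic, and per-animal aggregation.

#' Estimate blood velocity from a kymograph
#'
#' Streaks are intensity minima (dark cells in bright labelled plasma), so
#' the image is inverted and per-line medians are subtracted before
#' orientation analysis. For each candidate streak slope `s` (pixels per
#' line, `s = tan(theta)`), pixels are projected along the sheared
#' direction `b = x - s * t`; the true slope aligns the projection with the
#' streaks and maximizes the variance of the projection profile. The peak
#' over the angle grid is refined by parabolic interpolation, and velocity
#' is `tan(theta) * pixel_size / line_period` (micrometres per millisecond,
#' equivalently mm/s), signed by streak direction along the scan line.
#'
#' @param k a [kymograph()].
#' @param angle_step angle grid spacing, degrees.
#' @param max_angle largest |angle| searched, degrees; a peak at the grid
#'   edge is flagged unresolvable (cell faster than the scan).
#' @return object of class `velocity_estimate`: `velocity` (um/ms),
#'   `streak_angle` (degrees), `confidence` in \[0, 1\], `unresolvable`,
#'   `units`.
#' @export
estimate_velocity <- function(k, angle_step = 0.25, max_angle = 85) {
  stopifnot(inherits(k, "kymograph"))
  img <- k$image
  if (stats::sd(as.vector(img)) == 0)
    stop("velocimetry error: constant kymograph", call. = FALSE)
  work <- max(img) - img                       # dark streaks -> bright
  work <- work - apply(work, 1, stats::median) # per-line detrend
  nl <- nrow(work); np <- ncol(work)
  ts <- rep(0:(nl - 1), times = np)
  xs <- rep(0:(np - 1), each = nl)
  w <- as.vector(work)
  # variance of the sheared projection profile at streak slope s px/line;
  # pixel weight is splatted linearly between the two adjacent bins so the
  # profile (and hence the score) varies smoothly with angle
  shear_score <- function(th) {
    s <- tan(th * pi / 180)
    b <- xs - s * ts
    b0 <- floor(b)
    frac <- b - b0
    g <- as.integer(b0 - min(b0) + 1L)
    ng <- max(g) + 1L
    acc <- function(vals, idx) {
      r <- rowsum(vals, idx)
      out <- numeric(ng)
      out[as.integer(rownames(r))] <- r
      out
    }
    cnt <- acc(1 - frac, g) + acc(frac, g + 1L)
    sums <- acc(w * (1 - frac), g) + acc(w * frac, g + 1L)
    # count-weighted variance of the bin means: uses every pixel, so the
    # score stays stable at steep slopes where few bins are fully covered
    keep <- cnt > 1
    if (sum(keep) < 4L) return(-Inf)
    mu <- sums[keep] / cnt[keep]
    gm <- sum(sums[keep]) / sum(cnt[keep])
    sum(cnt[keep] * (mu - gm)^2) / sum(cnt[keep])
  }
  # coarse grid, then the fine grid in a window around the coarse peak
  coarse_step <- max(angle_step, 2)
  coarse <- seq(-max_angle, max_angle, by = coarse_step)
  cs <- vapply(coarse, shear_score, numeric(1))
  c0 <- coarse[which.max(cs)]
  thetas <- seq(max(-max_angle, c0 - 1.5 * coarse_step),
                min(max_angle, c0 + 1.5 * coarse_step), by = angle_step)
  score <- vapply(thetas, shear_score, numeric(1))
  i <- which.max(score)
  theta <- thetas[i]
  # parabolic refinement of the variance peak
  if (i > 1 && i < length(thetas) && all(is.finite(score[(i - 1):(i + 1)]))) {
    y1 <- score[i - 1]; y2 <- score[i]; y3 <- score[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) theta <- theta + 0.5 * (y1 - y3) / den * angle_step
  }
  unresolvable <- abs(theta) >= max_angle - angle_step
  score <- cs
  fin <- score[is.finite(score)]
  confidence <- if (length(fin) < 2 || max(fin) <= 0) 0 else
    min(1, max(0, 1 - stats::median(fin) / max(fin)))
  structure(list(velocity = tan(theta * pi / 180) * k$pixel_size /
                   k$line_period,
                 streak_angle = theta, confidence = confidence,
                 unresolvable = unresolvable, units = "um/ms"),
            class = "velocity_estimate")
}

#' Acetylcholine delta-velocity statistic
#'
#' `delta = stimulated - baseline`. A positive delta is the expected
#' vasodilation response of healthy endothelium to acetylcholine; a
#' negative delta (velocity falling during infusion) is the impaired
#' vasomotor response seen in cardiovascular disease.
#'
#' @param baseline,stimulated [estimate_velocity()] results from the same
#'   vessel (caller's responsibility).
#' @return object of class `delta_velocity`: `baseline`, `stimulated`,
#'   `delta` (um/ms).
#' @export
delta_velocity <- function(baseline, stimulated) {
  stopifnot(inherits(baseline, "velocity_estimate"),
            inherits(stimulated, "velocity_estimate"))
  if (!identical(baseline$units, stimulated$units))
    stop("delta-velocity error: mismatched units metadata", call. = FALSE)
  structure(list(baseline = baseline$velocity,
                 stimulated = stimulated$velocity,
                 delta = stimulated$velocity - baseline$velocity),
            class = "delta_velocity")
}

#' Aggregate per-vessel estimates to per-animal means
#'
#' Unweighted mean across the 2-6 arterioles typically scanned per animal.
#'
#' @param vessels data.frame with columns `animal`, `velocity` (um/ms) and
#'   optionally `delta` (um/ms), one row per vessel.
#' @return data.frame with one row per animal: `animal`, `n_vessels`,
#'   `mean_velocity`, and `mean_delta` when deltas were supplied.
#' @export
aggregate_vessels <- function(vessels) {
  if (!is.data.frame(vessels) || nrow(vessels) == 0)
    stop("aggregation error: empty input", call. = FALSE)
  if (!all(c("animal", "velocity") %in% names(vessels)))
    stop_field("vessels", "needs columns 'animal' and 'velocity'")
  ids <- unique(vessels$animal)
  out <- data.frame(
    animal = ids,
    n_vessels = vapply(ids, function(a) sum(vessels$animal == a),
                       integer(1)),
    mean_velocity = vapply(ids, function(a)
      mean(vessels$velocity[vessels$animal == a]), numeric(1)),
    stringsAsFactors = FALSE)
  if ("delta" %in% names(vessels))
    out$mean_delta <- vapply(ids, function(a)
      mean(vessels$delta[vessels$animal == a]), numeric(1))
  out
}
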