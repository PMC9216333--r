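# Vessel-scene phantoms: capsule rendering, leakage time-lapse stacks, and
# morphometry scenes with analytic ground truth.

# Distance (pixel units) from every pixel center to a segment. Pixel centers
# are at integer coordinates (x = column - 1, y = row - 1).
.seg_dist <- function(h, w, p0, p1) {
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((xs - p0[1])^2 + (ys - p0[2])^2))
  t <- ((xs - p0[1]) * dx + (ys - p0[2]) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((xs - (p0[1] + t * dx))^2 + (ys - (p0[2] + t * dy))^2)
}

# Even-odd ray-casting point-in-polygon mask for pixel centers.
.polygon_mask <- function(h, w, poly) {
  if (is.null(poly)) return(matrix(FALSE, h, w))
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  inside <- matrix(FALSE, h, w)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & is.finite(crosses))
    j <- i
  }
  inside
}

# Per-segment coverage in [0, 1]; antialias gives a 1-pixel soft edge,
# otherwise a hard cut at the capsule boundary.
.capsule_coverage <- function(h, w, seg, pixel_size, antialias) {
  d_um <- .seg_dist(h, w, seg$start, seg$end) * pixel_size
  if (antialias) {
    pmax(pmin((seg$radius + pixel_size / 2 - d_um) / pixel_size, 1), 0)
  } else {
    (d_um <= seg$radius) * 1
  }
}

# Render the vessel scene of a vessel_phantom_spec. Returns the image, the
# ground-truth vessel mask (capsule interior), and the osseous mask.
# Osseous pixels hold background only, regardless of vessel geometry.
render_vessel_scene <- function(spec, antialias = TRUE,
                                intensity_override = NULL) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  img <- matrix(spec$background_intensity, h, w)
  cov_max <- matrix(0, h, w)
  level <- matrix(0, h, w)
  for (seg in spec$vessel_segments) {
    inten <- if (is.null(intensity_override)) seg$intensity else
      intensity_override
    cov <- .capsule_coverage(h, w, seg, spec$pixel_size, antialias)
    take <- cov > cov_max
    level[take] <- inten
    cov_max <- pmax(cov_max, cov)
  }
  img <- spec$background_intensity +
    cov_max * (level - spec$background_intensity)
  mask <- cov_max >= 0.5
  osseous <- .polygon_mask(h, w, spec$osseous_polygon)
  img[osseous] <- spec$background_intensity
  mask[osseous] <- FALSE
  list(image = img, vessel_mask = mask, osseous = osseous)
}

#' Time-lapse stack container
#'
#' @param frames numeric array `height x width x n_frames`, a.u.
#' @param timestamps seconds, strictly increasing, one per frame.
#' @param pixel_size micrometres per pixel.
#' @param channel label for the imaged channel.
#' @return object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, timestamps, pixel_size,
                            channel = "albumin") {
  if (length(dim(frames)) != 3L) stop_field("frames", "must be a 3-d array")
  if (dim(frames)[3] < 2L) stop_field("frames", "need >= 2 frames")
  if (length(timestamps) != dim(frames)[3])
    stop_field("timestamps", "length must match frame count")
  if (any(diff(timestamps) <= 0))
    stop_field("timestamps", "must be strictly increasing")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 pixel_size = pixel_size, channel = channel),
            class = "timelapse_stack")
}

#' Region set: marrow ROI and osseous exclusion ROI
#'
#' @param marrow_roi logical matrix; pixels analysed.
#' @param osseous_roi logical matrix; bone background, always excluded.
#' @return object of class `region_set`.
#' @export
region_set <- function(marrow_roi, osseous_roi = NULL) {
  marrow_roi <- marrow_roi != 0
  if (is.null(osseous_roi))
    osseous_roi <- matrix(FALSE, nrow(marrow_roi), ncol(marrow_roi))
  osseous_roi <- osseous_roi != 0
  if (!identical(dim(marrow_roi), dim(osseous_roi)))
    stop_field("osseous_roi", "shape must match marrow_roi")
  if (any(marrow_roi & osseous_roi))
    stop_field("osseous_roi", "marrow and osseous ROIs must be disjoint")
  if (!any(marrow_roi)) stop_field("marrow_roi", "must be nonempty")
  structure(list(marrow_roi = marrow_roi, osseous_roi = osseous_roi),
            class = "region_set")
}

#' Generate an albumin-leakage time-lapse stack with known ground truth
#'
#' Frames before the injection frame contain vessels on background only;
#' from the injection frame on, the extravascular marrow intensity rises
#' linearly at `outside_slope` (a.u./s, clocked from the injection frame)
#' while the intravascular intensity stays at `inside_intensity`. The
#' osseous region holds background at all times. Vessels are rendered with
#' hard edges so the intravascular mean is exactly `inside_intensity`,
#' keeping the closed-form leak-rate check exact.
#'
#' @param spec a [leakage_phantom_spec()].
#' @return list with `stack` ([timelapse_stack()]), `vessel_mask` (logical
#'   ground-truth matrix), `regions` ([region_set()]: marrow = field minus
#'   osseous), and `spec`.
#' @export
generate_leakage_stack <- function(spec) {
  stopifnot(inherits(spec, "leakage_phantom_spec"))
  base <- spec$base
  scene <- render_vessel_scene(base, antialias = FALSE,
                               intensity_override = spec$inside_intensity)
  h <- base$image_shape[1]; w <- base$image_shape[2]
  ts <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  t_inj <- ts[spec$injection_frame]
  outside <- !scene$vessel_mask & !scene$osseous
  frames <- with_seed(base$seed, {
    fr <- array(0, dim = c(h, w, spec$n_frames))
    for (k in seq_len(spec$n_frames)) {
      f <- matrix(base$background_intensity, h, w)
      if (k >= spec$injection_frame) {
        f[scene$vessel_mask] <- spec$inside_intensity
        f[outside] <- base$background_intensity +
          spec$outside_slope * (ts[k] - t_inj)
      } else {
        f[scene$vessel_mask] <- spec$inside_intensity
      }
      if (base$noise_sd > 0)
        f <- pmax(f + matrix(stats::rnorm(h * w, 0, base$noise_sd), h, w), 0)
      fr[, , k] <- f
    }
    fr
  })
  regions <- region_set(marrow_roi = !scene$osseous,
                        osseous_roi = scene$osseous)
  list(stack = timelapse_stack(frames, ts, base$pixel_size),
       vessel_mask = scene$vessel_mask, regions = regions, spec = spec)
}

# Intersection point of two segments (each list(start, end)), or NULL.
.seg_intersection <- function(a, b) {
  p <- a$start; r <- a$end - a$start
  q <- b$start; s <- b$end - b$start
  rxs <- r[1] * s[2] - r[2] * s[1]
  if (abs(rxs) < 1e-12) return(NULL)     # parallel or collinear
  qp <- q - p
  t <- (qp[1] * s[2] - qp[2] * s[1]) / rxs
  u <- (qp[1] * r[2] - qp[2] * r[1]) / rxs
  if (t < -1e-9 || t > 1 + 1e-9 || u < -1e-9 || u > 1 + 1e-9) return(NULL)
  p + t * r
}

# Analytic branch-point count: pairwise centerline intersections, with
# coincident points (within 1 pixel) merged into one junction.
.analytic_branch_count <- function(segments) {
  pts <- list()
  n <- length(segments)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      x <- .seg_intersection(segments[[i]], segments[[j]])
      if (!is.null(x)) pts[[length(pts) + 1L]] <- x
    }
  }
  if (!length(pts)) return(0L)
  pts <- do.call(rbind, pts)
  merged <- 0L
  used <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (used[i]) next
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    used[d <= 1] <- TRUE
    merged <- merged + 1L
  }
  merged
}

#' Generate a multi-channel morphometry scene with analytic ground truth
#'
#' Renders the vessel segments of `spec` plus sprout protrusions, and a
#' myeloid-cell channel holding the listed cell pixels. Ground truth is
#' computed analytically: branch points from pairwise centerline
#' intersections, sprout lengths as stated, and each cell's true distance
#' to the nearest vessel surface (distance to the closest capsule
#' centerline minus its radius, clamped at zero).
#'
#' @param spec a [vessel_phantom_spec()] describing the trunk vessels.
#' @param sprouts list of sprouts, each `list(attachment = c(x, y) pixels,
#'   length = micrometres, angle = degrees)`; `angle` defaults to the
#'   outward normal of the attached segment. Attachment must lie on a
#'   vessel.
#' @param cell_pixels n x 2 matrix of cell pixel coordinates `c(x, y)`.
#' @param sprout_radius sprout capsule radius, micrometres.
#' @return list with `vessel_channel`, `cell_channel` (matrices), `regions`,
#'   `pixel_size`, and `truth` (`branch_points`, `sprout_lengths`,
#'   `cell_distances` in micrometres).
#' @export
generate_morphometry_scene <- function(spec, sprouts = list(),
                                       cell_pixels = NULL,
                                       sprout_radius = 1) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  px <- spec$pixel_size
  all_caps <- spec$vessel_segments
  sprout_lengths <- numeric(0)
  for (i in seq_along(sprouts)) {
    sp <- sprouts[[i]]
    if (is.null(sp$length) || sp$length <= 0)
      stop_field("sprouts", sprintf("sprout %d length must be > 0", i))
    att <- sp$attachment
    host <- NULL
    for (seg in spec$vessel_segments) {
      d <- .point_seg_dist(att, seg$start, seg$end) * px
      if (d <= seg$radius + px / 2) { host <- seg; break }
    }
    if (is.null(host))
      stop(sprintf("sprout %d attachment is not on any vessel", i),
           call. = FALSE)
    ang <- sp$angle
    if (is.null(ang)) {
      dv <- host$end - host$start
      ang <- atan2(dv[2], dv[1]) * 180 / pi + 90
    }
    len_px <- sp$length / px
    tip <- att + len_px * c(cos(ang * pi / 180), sin(ang * pi / 180))
    if (any(tip < 0) || tip[1] > w - 1 || tip[2] > h - 1)
      stop_field("sprouts", sprintf("sprout %d extends outside the image", i))
    all_caps[[length(all_caps) + 1L]] <-
      list(start = att, end = tip, radius = sprout_radius,
           intensity = host$intensity)
    sprout_lengths <- c(sprout_lengths, sp$length)
  }
  full <- spec
  full$vessel_segments <- all_caps
  scene <- render_vessel_scene(full, antialias = TRUE)
  vessel_channel <- with_seed(spec$seed, {
    img <- scene$image
    if (spec$noise_sd > 0)
      img <- pmax(img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w), 0)
    img
  })
  cell_channel <- matrix(spec$background_intensity / 10, h, w)
  cell_distances <- numeric(0)
  if (!is.null(cell_pixels)) {
    cell_pixels <- matrix(as.numeric(cell_pixels), ncol = 2)
    if (any(cell_pixels < 0) || any(cell_pixels[, 1] > w - 1) ||
        any(cell_pixels[, 2] > h - 1))
      stop_field("cell_pixels", "all cell pixels must lie inside the image")
    for (i in seq_len(nrow(cell_pixels))) {
      p <- cell_pixels[i, ]
      cell_channel[p[2] + 1, p[1] + 1] <- spec$background_intensity * 10
      d <- vapply(all_caps, function(seg)
        max(0, .point_seg_dist(p, seg$start, seg$end) * px - seg$radius),
        numeric(1))
      cell_distances <- c(cell_distances, min(d))
    }
  }
  regions <- region_set(marrow_roi = !scene$osseous,
                        osseous_roi = scene$osseous)
  list(vessel_channel = vessel_channel, cell_channel = cell_channel,
       regions = regions, pixel_size = px,
       truth = list(branch_points =
                      .analytic_branch_count(spec$vessel_segments),
                    sprout_lengths = sprout_lengths,
                    cell_distances = cell_distances))
}

# Scalar point-to-segment distance in pixel units.
.point_seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- min(1, max(0, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}
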