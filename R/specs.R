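# Phantom specifications. Each constructor validates its fields and returns
# a classed list; generators accept only validated specs. Seeds are explicit
# fields, never global state.

#' Vessel phantom specification
#'
#' Describes a static vessel scene: bright capsule-shaped vessel segments on
#' a dark marrow background, with an optional osseous (bone) polygon that is
#' excluded from all analyses and never receives vessel signal.
#'
#' @param image_shape integer vector `c(height, width)` in pixels.
#' @param pixel_size pixel edge length in micrometres.
#' @param vessel_segments list of segments, each a list with `start` and
#'   `end` (length-2 numeric, pixel coordinates `c(x, y)`), `radius`
#'   (micrometres) and `intensity` (arbitrary units).
#' @param osseous_polygon optional n x 2 matrix of polygon vertices (pixel
#'   coordinates) delimiting the osseous exclusion region.
#' @param background_intensity marrow background level, arbitrary units.
#' @param noise_sd standard deviation of additive Gaussian noise (clipped at
#'   zero), arbitrary units.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   images.
#' @return object of class `vessel_phantom_spec`.
#' @export
vessel_phantom_spec <- function(image_shape = c(128L, 128L),
                                pixel_size = 1,
                                vessel_segments = list(),
                                osseous_polygon = NULL,
                                background_intensity = 100,
                                noise_sd = 0,
                                seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop_field("image_shape", "must be c(height, width), each >= 8")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(background_intensity, "background_intensity", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  for (i in seq_along(vessel_segments)) {
    seg <- vessel_segments[[i]]
    if (!all(c("start", "end", "radius", "intensity") %in% names(seg)))
      stop_field("vessel_segments",
                 sprintf("segment %d needs start, end, radius, intensity", i))
    check_scalar(seg$radius, sprintf("vessel_segments[[%d]]$radius", i),
                 positive = TRUE)
    check_scalar(seg$intensity, sprintf("vessel_segments[[%d]]$intensity", i),
                 positive = TRUE)
  }
  if (!is.null(osseous_polygon)) {
    osseous_polygon <- as.matrix(osseous_polygon)
    if (ncol(osseous_polygon) != 2L || nrow(osseous_polygon) < 3L)
      stop_field("osseous_polygon", "must be an n x 2 matrix with n >= 3")
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 vessel_segments = vessel_segments,
                 osseous_polygon = osseous_polygon,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "vessel_phantom_spec")
}

#' Leakage phantom specification
#'
#' Time-lapse extension of [vessel_phantom_spec()]: frames before the
#' injection frame show vessels only; afterwards the extravascular mean
#' rises linearly at `outside_slope` while intravascular signal stays at
#' `inside_intensity`, emulating albumin extravasation. Defaults mirror the
#' intravital acquisition of 25 frames at 1.2 s per image.
#'
#' @param base a [vessel_phantom_spec()].
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames.
#' @param inside_intensity intravascular plasma intensity, a.u. (constant
#'   over time); overrides the per-segment intensities.
#' @param outside_slope true extravasation rate, a.u. per second.
#' @param injection_frame 1-based index of the first post-injection frame.
#' @return object of class `leakage_phantom_spec`.
#' @export
leakage_phantom_spec <- function(base = vessel_phantom_spec(),
                                 n_frames = 25L,
                                 frame_interval = 1.2,
                                 inside_intensity = 1000,
                                 outside_slope = 5,
                                 injection_frame = 1L) {
  stopifnot(inherits(base, "vessel_phantom_spec"))
  check_scalar(n_frames, "n_frames", integerish = TRUE)
  if (n_frames < 2) stop_field("n_frames", "must be >= 2")
  check_scalar(frame_interval, "frame_interval", positive = TRUE)
  check_scalar(inside_intensity, "inside_intensity", positive = TRUE)
  check_scalar(outside_slope, "outside_slope", nonneg = TRUE)
  check_scalar(injection_frame, "injection_frame", integerish = TRUE)
  if (injection_frame < 1 || injection_frame > n_frames - 1)
    stop_field("injection_frame", "must leave >= 2 post-injection frames")
  structure(list(base = base, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 inside_intensity = inside_intensity,
                 outside_slope = outside_slope,
                 injection_frame = as.integer(injection_frame)),
            class = "leakage_phantom_spec")
}

#' Kymograph phantom specification
#'
#' Line-scan space-by-time image with dark erythrocyte streaks on a bright
#' plasma background. A cell moving at `true_velocity` advances
#' `true_velocity * line_period / pixel_size` pixels per scan line.
#'
#' @param n_positions pixels along the scan line.
#' @param n_lines number of scan lines (rows of the kymograph).
#' @param pixel_size micrometres per pixel along the line.
#' @param line_period milliseconds per line.
#' @param true_velocity micrometres per millisecond (= mm/s); sign encodes
#'   direction along the line.
#' @param streak_density expected number of dark streaks crossing a line.
#' @param streak_contrast streak depth below background, a.u.
#' @param streak_width streak half-width (Gaussian sigma), pixels.
#' @param background_intensity plasma intensity, a.u.
#' @param noise_sd additive Gaussian noise sd, a.u.
#' @param seed integer seed.
#' @return object of class `kymograph_spec`.
#' @export
kymograph_spec <- function(n_positions = 128L, n_lines = 128L,
                           pixel_size = 1, line_period = 1,
                           true_velocity = 1,
                           streak_density = 3, streak_contrast = 500,
                           streak_width = 1.2,
                           background_intensity = 1000,
                           noise_sd = 0, seed = 1L) {
  check_scalar(n_positions, "n_positions", integerish = TRUE)
  check_scalar(n_lines, "n_lines", integerish = TRUE)
  if (n_lines < 2) stop_field("n_lines", "must be >= 2")
  if (n_positions < 4) stop_field("n_positions", "must be >= 4")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(line_period, "line_period", positive = TRUE)
  check_scalar(true_velocity, "true_velocity")
  check_scalar(streak_density, "streak_density", nonneg = TRUE)
  check_scalar(streak_contrast, "streak_contrast", nonneg = TRUE)
  check_scalar(streak_width, "streak_width", positive = TRUE)
  check_scalar(background_intensity, "background_intensity", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_positions = as.integer(n_positions),
                 n_lines = as.integer(n_lines), pixel_size = pixel_size,
                 line_period = line_period, true_velocity = true_velocity,
                 streak_density = streak_density,
                 streak_contrast = streak_contrast,
                 streak_width = streak_width,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "kymograph_spec")
}

#' DCE-MRI phantom specification
#'
#' Spoiled gradient-echo phantom for the macromolecular contrast chain.
#' Pre-contrast variable flip-angle signals encode `r1_pre`; post-contrast
#' signals encode the tissue concentration
#' `C(t) = (fbv + ps * t) * C_blood(t)` mapped through the contrast agent
#' relaxivity to R1(t) and then to signal. Defaults follow the published
#' femoral acquisition: flip angles 2, 6, 9, 15, 25, 50, 70 degrees
#' pre-contrast, 50 degrees post-contrast, TR 25 ms, dynamics every 25 s for
#' 4 min, relaxivity 145 per mM per s. The healthy-marrow cohort default is
#' a true fractional blood volume of 0.208 with a between-animal spread of
#' 0.044.
#'
#' @param true_fbv true fractional blood volume, in (0, 1).
#' @param true_ps true permeability-surface-area product, per minute.
#' @param blood_concentration mM; either a single value (constant blood
#'   pool) or a function of time in seconds.
#' @param sample_times seconds after contrast administration, strictly
#'   increasing.
#' @param flip_angles_pre pre-contrast flip angles, degrees.
#' @param flip_angle_post post-contrast flip angle, degrees.
#' @param tr repetition time, milliseconds.
#' @param r1_pre pre-contrast tissue relaxation rate, per second.
#' @param r1_blood_pre pre-contrast blood relaxation rate, per second.
#' @param relaxivity contrast agent relaxivity, per mM per second.
#' @param s0_tissue,s0_blood equilibrium signal scales, a.u.
#' @param noise_sd additive Gaussian signal noise sd, a.u.
#' @param cohort_fbv_sd between-phantom spread of true fractional blood
#'   volume when generating a cohort (truncated to (0, 1)).
#' @param seed integer seed.
#' @return object of class `dce_phantom_spec`.
#' @export
dce_phantom_spec <- function(true_fbv = 0.208, true_ps = 0.01,
                             blood_concentration = 0.3,
                             sample_times = seq(25, 240, by = 25),
                             flip_angles_pre = c(2, 6, 9, 15, 25, 50, 70),
                             flip_angle_post = 50, tr = 25,
                             r1_pre = 1.0, r1_blood_pre = 0.7,
                             relaxivity = 145,
                             s0_tissue = 1000, s0_blood = 1000,
                             noise_sd = 0, cohort_fbv_sd = 0.044,
                             seed = 1L) {
  check_scalar(true_fbv, "true_fbv")
  if (true_fbv <= 0 || true_fbv >= 1)
    stop_field("true_fbv", "must lie in (0, 1)")
  check_scalar(true_ps, "true_ps", nonneg = TRUE)
  if (!is.function(blood_concentration))
    check_scalar(blood_concentration, "blood_concentration", positive = TRUE)
  if (length(sample_times) < 2L || any(diff(sample_times) <= 0))
    stop_field("sample_times", "must be strictly increasing, length >= 2")
  if (any(sample_times < 0)) stop_field("sample_times", "must be >= 0")
  if (length(flip_angles_pre) < 3L)
    stop_field("flip_angles_pre", "need >= 3 distinct flip angles")
  if (any(flip_angles_pre <= 0 | flip_angles_pre > 90))
    stop_field("flip_angles_pre", "angles must lie in (0, 90] degrees")
  check_scalar(flip_angle_post, "flip_angle_post", positive = TRUE)
  if (flip_angle_post > 90) stop_field("flip_angle_post", "must be <= 90")
  check_scalar(tr, "tr", positive = TRUE)
  check_scalar(r1_pre, "r1_pre", positive = TRUE)
  check_scalar(r1_blood_pre, "r1_blood_pre", positive = TRUE)
  check_scalar(relaxivity, "relaxivity", positive = TRUE)
  check_scalar(s0_tissue, "s0_tissue", positive = TRUE)
  check_scalar(s0_blood, "s0_blood", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(cohort_fbv_sd, "cohort_fbv_sd", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(true_fbv = true_fbv, true_ps = true_ps,
                 blood_concentration = blood_concentration,
                 sample_times = as.numeric(sample_times),
                 flip_angles_pre = as.numeric(flip_angles_pre),
                 flip_angle_post = flip_angle_post, tr = tr,
                 r1_pre = r1_pre, r1_blood_pre = r1_blood_pre,
                 relaxivity = relaxivity, s0_tissue = s0_tissue,
                 s0_blood = s0_blood, noise_sd = noise_sd,
                 cohort_fbv_sd = cohort_fbv_sd, seed = as.integer(seed)),
            class = "dce_phantom_spec")
}
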