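# Spoiled gradient-echo DCE phantoms: variable flip-angle series plus
# dynamic post-contrast tissue and blood-pool signals with known
# (fractional blood volume, permeability) ground truth.

#' Spoiled gradient-echo (FLASH) steady-state signal
#'
#' `S(alpha) = s0 * sin(alpha) * (1 - E) / (1 - E * cos(alpha))` with
#' `E = exp(-TR * R1)`.
#'
#' @param r1 longitudinal relaxation rate, per second.
#' @param s0 equilibrium signal scale, a.u.
#' @param flip_angle_deg flip angle(s), degrees.
#' @param tr repetition time, milliseconds.
#' @return signal(s), a.u.
#' @export
spgr_signal <- function(r1, s0, flip_angle_deg, tr) {
  a <- flip_angle_deg * pi / 180
  e1 <- exp(-(tr / 1000) * r1)
  s0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Variable flip-angle series container
#'
#' @param signals numeric vector of ROI-mean signals, one per flip angle
#'   (a.u., >= 0), or a matrix with one row per pixel.
#' @param flip_angles degrees; >= 3 distinct values.
#' @param tr repetition time, milliseconds.
#' @return object of class `vfa_series`.
#' @export
vfa_series <- function(signals, flip_angles, tr) {
  if (is.matrix(signals)) {
    if (ncol(signals) != length(flip_angles))
      stop_field("signals", "one column per flip angle required")
  } else if (length(signals) != length(flip_angles)) {
    stop_field("signals", "one signal per flip angle required")
  }
  if (length(unique(flip_angles)) < 3L)
    stop_field("flip_angles", "need >= 3 distinct flip angles")
  if (any(signals < 0)) stop_field("signals", "must be >= 0")
  check_scalar(tr, "tr", positive = TRUE)
  structure(list(signals = signals, flip_angles = as.numeric(flip_angles),
                 tr = tr), class = "vfa_series")
}

#' Dynamic post-contrast series container
#'
#' @param tissue_signals a.u. vs time (vector, or matrix one row per pixel).
#' @param blood_signals a.u. vs time from the vena-cava blood ROI.
#' @param times seconds after contrast administration, strictly increasing.
#' @param flip_angle_post degrees.
#' @param tr milliseconds.
#' @return object of class `dce_series`.
#' @export
dce_series <- function(tissue_signals, blood_signals, times,
                       flip_angle_post, tr) {
  nt <- length(times)
  if (nt < 2L || any(diff(times) <= 0) || times[1] < 0)
    stop_field("times", "must be strictly increasing with times[1] >= 0")
  len <- if (is.matrix(tissue_signals)) ncol(tissue_signals) else
    length(tissue_signals)
  if (len != nt) stop_field("tissue_signals", "length must match times")
  if (length(blood_signals) != nt)
    stop_field("blood_signals", "length must match times")
  check_scalar(flip_angle_post, "flip_angle_post", positive = TRUE)
  check_scalar(tr, "tr", positive = TRUE)
  structure(list(tissue_signals = tissue_signals,
                 blood_signals = as.numeric(blood_signals),
                 times = as.numeric(times),
                 flip_angle_post = flip_angle_post, tr = tr),
            class = "dce_series")
}

.blood_conc_at <- function(spec, t) {
  if (is.function(spec$blood_concentration)) spec$blood_concentration(t)
  else rep(spec$blood_concentration, length(t))
}

#' Generate a VFA + DCE phantom pair (tissue and blood ROI)
#'
#' Pre-contrast variable flip-angle signals follow the spoiled gradient-echo
#' model at `r1_pre` (tissue) and `r1_blood_pre` (blood). Post-contrast
#' tissue concentration follows the two-compartment macromolecular model
#' `C(t) = (fbv + ps * t / 60) * C_blood(t)` (`ps` per minute, `t` in
#' seconds); concentrations are mapped through the relaxivity to R1(t) and
#' then to signal at the single post-contrast flip angle.
#'
#' @param spec a [dce_phantom_spec()].
#' @param fbv_override optional true fractional blood volume replacing
#'   `spec$true_fbv` (used by [generate_dce_cohort()]).
#' @return list with `vfa_tissue`, `vfa_blood` ([vfa_series()]), `dce`
#'   ([dce_series()]), and `truth` (list of the generating parameters).
#' @export
generate_vfa_dce <- function(spec, fbv_override = NULL) {
  stopifnot(inherits(spec, "dce_phantom_spec"))
  fbv <- if (is.null(fbv_override)) spec$true_fbv else fbv_override
  if (fbv <= 0 || fbv >= 1) stop_field("true_fbv", "must lie in (0, 1)")
  t <- spec$sample_times
  cb <- .blood_conc_at(spec, t)
  ct <- (fbv + spec$true_ps * t / 60) * cb
  r1_tissue_t <- spec$r1_pre + spec$relaxivity * ct
  r1_blood_t <- spec$r1_blood_pre + spec$relaxivity * cb
  s_vfa_tissue <- spgr_signal(spec$r1_pre, spec$s0_tissue,
                              spec$flip_angles_pre, spec$tr)
  s_vfa_blood <- spgr_signal(spec$r1_blood_pre, spec$s0_blood,
                             spec$flip_angles_pre, spec$tr)
  s_dyn_tissue <- spgr_signal(r1_tissue_t, spec$s0_tissue,
                              spec$flip_angle_post, spec$tr)
  s_dyn_blood <- spgr_signal(r1_blood_t, spec$s0_blood,
                             spec$flip_angle_post, spec$tr)
  if (spec$noise_sd > 0) {
    noisy <- with_seed(spec$seed, {
      list(vt = pmax(0, s_vfa_tissue + stats::rnorm(length(s_vfa_tissue),
                                                    0, spec$noise_sd)),
           vb = pmax(0, s_vfa_blood + stats::rnorm(length(s_vfa_blood),
                                                   0, spec$noise_sd)),
           dt = pmax(0, s_dyn_tissue + stats::rnorm(length(t), 0,
                                                    spec$noise_sd)),
           db = pmax(0, s_dyn_blood + stats::rnorm(length(t), 0,
                                                   spec$noise_sd)))
    })
    s_vfa_tissue <- noisy$vt; s_vfa_blood <- noisy$vb
    s_dyn_tissue <- noisy$dt; s_dyn_blood <- noisy$db
  }
  list(vfa_tissue = vfa_series(s_vfa_tissue, spec$flip_angles_pre, spec$tr),
       vfa_blood = vfa_series(s_vfa_blood, spec$flip_angles_pre, spec$tr),
       dce = dce_series(s_dyn_tissue, s_dyn_blood, t,
                        spec$flip_angle_post, spec$tr),
       truth = list(fbv = fbv, ps = spec$true_ps, r1_pre = spec$r1_pre,
                    r1_blood_pre = spec$r1_blood_pre,
                    relaxivity = spec$relaxivity))
}

#' Generate a cohort of DCE phantoms with between-animal FBV spread
#'
#' Per-phantom true fractional blood volume is drawn from
#' `Normal(true_fbv, cohort_fbv_sd)` truncated to (0, 1) under the cohort
#' seed; phantom `i` receives measurement-noise seed `seed + i`.
#'
#' @param spec a [dce_phantom_spec()]; `spec$seed` seeds the cohort draw.
#' @param n number of phantoms.
#' @return list of [generate_vfa_dce()] results, one per phantom.
#' @export
generate_dce_cohort <- function(spec, n = 6L) {
  stopifnot(inherits(spec, "dce_phantom_spec"))
  check_scalar(n, "n", integerish = TRUE, positive = TRUE)
  fbvs <- with_seed(spec$seed, {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        x <- stats::rnorm(1, spec$true_fbv, spec$cohort_fbv_sd)
        if (x > 0 && x < 1) break
      }
      out[i] <- x
    }
    out
  })
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i
    generate_vfa_dce(sp, fbv_override = fbvs[i])
  })
}
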