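# Macromolecular DCE-MRI chain: variable flip-angle R1 fitting, single-angle
# post-contrast R1 inversion, relaxivity-based concentration conversion,
# blood-pool normalization, and the two-parameter linear model whose
# intercept is fractional blood volume and whose slope is the
# permeability-surface-area product (per minute).

#' Fit R1 and S0 from a variable flip-angle series
#'
#' Nonlinear least squares of the spoiled gradient-echo model
#' `S(alpha) = s0 sin(alpha) (1 - E) / (1 - E cos(alpha))`,
#' `E = exp(-TR * R1)`, initialized from the DESPOT1 linearization
#' (`S/sin` vs `S/tan`) and refined by bounded optimization with up to
#' three perturbed restarts.
#'
#' @param series a [vfa_series()] with vector signals.
#' @return object of class `r1_fit`: `r1` (per second), `s0` (a.u.),
#'   `residual_norm`.
#' @export
fit_vfa_r1 <- function(series) {
  stopifnot(inherits(series, "vfa_series"))
  s <- as.numeric(series$signals)
  a <- series$flip_angles * pi / 180
  tr_s <- series$tr / 1000
  if (all(s <= 0)) stop("VFA fit error: all signals are zero", call. = FALSE)
  if (stats::sd(s) <= 1e-9 * mean(s))
    stop("VFA fit error: flat signal across flip angles is inconsistent ",
         "with the spoiled gradient-echo model", call. = FALSE)
  # DESPOT1 linearization for the starting point
  y <- s / sin(a); x <- s / tan(a)
  ln <- ols_line(x, y)
  e_init <- min(0.999, max(1e-4, ln[["slope"]]))
  r1_init <- -log(e_init) / tr_s
  s0_init <- max(ln[["intercept"]] / (1 - e_init), max(s))
  ssr <- function(p) {
    pred <- spgr_signal(exp(p[1]), exp(p[2]), series$flip_angles, series$tr)
    sum((pred - s)^2)
  }
  best <- NULL
  start <- c(log(r1_init), log(s0_init))
  # fixed perturbations keep the fit fully deterministic
  perturb <- list(c(0, 0), c(0.3, -0.1), c(-0.3, 0.1), c(0.6, 0.2))
  for (k in seq_along(perturb)) {
    p0 <- start + perturb[[k]]
    fit <- tryCatch(stats::optim(p0, ssr, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
    if (!is.null(best) &&
        best$value <= (1e-12 * sum(s^2) + 1e-20)) break
  }
  if (is.null(best))
    stop("VFA fit error: optimization failed after restarts", call. = FALSE)
  structure(list(r1 = exp(best$par[1]), s0 = exp(best$par[2]),
                 residual_norm = sqrt(best$value)),
            class = "r1_fit")
}

#' Invert the spoiled gradient-echo model at a single flip angle
#'
#' Uses the equilibrium scale `s0` from the pre-contrast fit to map a
#' post-contrast signal back to R1(t). The closed-form inverse is
#' `E = (s0 sin(a) - S) / (s0 sin(a) - S cos(a))`, `R1 = -log(E)/TR`.
#'
#' @param signal_t post-contrast signal(s), a.u.
#' @param precontrast an [fit_vfa_r1()] result.
#' @param flip_angle degrees.
#' @param tr milliseconds.
#' @return R1(t), per second.
#' @export
post_contrast_r1 <- function(signal_t, precontrast, flip_angle, tr) {
  stopifnot(inherits(precontrast, "r1_fit"))
  a <- flip_angle * pi / 180
  sat <- precontrast$s0 * sin(a)
  if (any(signal_t <= 0))
    stop("post-contrast inversion error: non-positive signal", call. = FALSE)
  if (any(signal_t >= sat))
    stop(sprintf(paste0("post-contrast inversion error: signal exceeds the",
                        " saturation level s0*sin(alpha) = %.6g"), sat),
         call. = FALSE)
  e1 <- (sat - signal_t) / (sat - signal_t * cos(a))
  -log(e1) / (tr / 1000)
}

#' Convert an R1 change to contrast-agent concentration
#'
#' `C = (R1(t) - R1_pre) / relaxivity`; negative differences (noise) are
#' clamped to zero and counted.
#'
#' @param r1_t post-contrast R1 value(s), per second.
#' @param r1_pre pre-contrast R1, per second.
#' @param relaxivity per mM per second (default 145, the macromolecular
#'   albumin-GdDTPA value).
#' @return list with `concentration` (mM) and `n_clamped`.
#' @export
concentration_from_r1 <- function(r1_t, r1_pre, relaxivity = 145) {
  check_scalar(relaxivity, "relaxivity", positive = TRUE)
  conc <- (r1_t - r1_pre) / relaxivity
  n_clamped <- sum(conc < 0)
  conc[conc < 0] <- 0
  list(concentration = conc, n_clamped = n_clamped)
}

#' Tissue/blood concentration curve with blood-pool normalization
#'
#' The normalized curve `C_tissue / C_blood` is defined only where
#' `C_blood > 0`; other time points are dropped from downstream regression,
#' not imputed.
#'
#' @param c_tissue mM vs time.
#' @param c_blood mM vs time.
#' @param relaxivity per mM per second (carried as metadata).
#' @return object of class `concentration_curve`.
#' @export
concentration_curve <- function(c_tissue, c_blood, relaxivity = 145) {
  if (length(c_tissue) != length(c_blood))
    stop_field("c_blood", "lengths of tissue and blood curves must match")
  check_scalar(relaxivity, "relaxivity", positive = TRUE)
  normalized <- ifelse(c_blood > 0, c_tissue / c_blood, NA_real_)
  structure(list(c_tissue = c_tissue, c_blood = c_blood,
                 normalized = normalized, relaxivity = relaxivity),
            class = "concentration_curve")
}

#' Fit fractional blood volume and permeability from a normalized curve
#'
#' Ordinary least squares of the blood-normalized tissue concentration
#' against time; the intercept extrapolated to the time of contrast
#' administration (t = 0) is the fractional blood volume, and the slope,
#' expressed per minute, is the permeability-surface-area product.
#'
#' @param curve a [concentration_curve()] (or a numeric vector of
#'   normalized concentrations).
#' @param times time after contrast administration, in `time_unit`.
#' @param time_unit `"s"` (default) or `"min"`; the reported `ps` is per
#'   minute either way.
#' @return object of class `permeability_fit`: `fbv` (fraction), `ps`
#'   (per minute), `r_squared`, `n_points`.
#' @export
fit_permeability <- function(curve, times, time_unit = c("s", "min")) {
  time_unit <- match.arg(time_unit)
  y <- if (inherits(curve, "concentration_curve")) curve$normalized
  else as.numeric(curve)
  if (length(y) != length(times))
    stop_field("times", "length must match the normalized curve")
  t_min <- if (time_unit == "s") times / 60 else as.numeric(times)
  keep <- is.finite(y) & is.finite(t_min)
  if (sum(keep) < 2L)
    stop("permeability fit error: need >= 2 finite normalized points",
         call. = FALSE)
  if (diff(range(t_min[keep])) == 0)
    stop("permeability fit error: all time points identical", call. = FALSE)
  co <- ols_line(t_min[keep], y[keep])
  structure(list(fbv = unname(co[["intercept"]]),
                 ps = unname(co[["slope"]]),
                 r_squared = r_squared(t_min[keep], y[keep], co),
                 n_points = sum(keep)),
            class = "permeability_fit")
}

#' Run the full ROI-level DCE chain
#'
#' Pre-contrast R1 fits for tissue and blood, closed-form post-contrast R1
#' inversion per time point, relaxivity conversion to concentration,
#' blood-pool normalization, and the linear permeability fit.
#'
#' @param vfa_tissue,vfa_blood [vfa_series()] for the tissue and blood ROI.
#' @param dce a [dce_series()].
#' @param relaxivity per mM per second.
#' @return list with `fit` ([fit_permeability()] result), `r1_tissue`,
#'   `r1_blood` (pre-contrast fits), `curve`, and `n_clamped`.
#' @export
dce_analyze <- function(vfa_tissue, vfa_blood, dce, relaxivity = 145) {
  stopifnot(inherits(dce, "dce_series"))
  fit_t <- fit_vfa_r1(vfa_tissue)
  fit_b <- fit_vfa_r1(vfa_blood)
  r1_t <- post_contrast_r1(dce$tissue_signals, fit_t,
                           dce$flip_angle_post, dce$tr)
  r1_b <- post_contrast_r1(dce$blood_signals, fit_b,
                           dce$flip_angle_post, dce$tr)
  ct <- concentration_from_r1(r1_t, fit_t$r1, relaxivity)
  cb <- concentration_from_r1(r1_b, fit_b$r1, relaxivity)
  curve <- concentration_curve(ct$concentration, cb$concentration,
                               relaxivity)
  fit <- fit_permeability(curve, dce$times, time_unit = "s")
  list(fit = fit, r1_tissue = fit_t, r1_blood = fit_b, curve = curve,
       n_clamped = ct$n_clamped + cb$n_clamped)
}

#' Pixelwise parametric maps of fractional blood volume and permeability
#'
#' Applies the ROI chain independently to every pixel inside the marrow
#' mask, sharing the blood-pool curve. Pixels whose fit fails (for example
#' a post-contrast signal beyond saturation) are flagged, excluded from the
#' mask means, and counted.
#'
#' @param vfa_pixels matrix, one row per pixel, one column per flip angle.
#' @param dce_pixels matrix, one row per pixel, one column per time point.
#' @param vfa_blood [vfa_series()] for the blood ROI.
#' @param blood_signals blood dynamic signals, a.u. vs time.
#' @param times seconds after contrast administration.
#' @param flip_angles pre-contrast flip angles, degrees.
#' @param flip_angle_post degrees.
#' @param tr milliseconds.
#' @param mask logical matrix; TRUE pixels are analysed (row-major pairing:
#'   pixel `i` of the matrices corresponds to `which(mask)[i]`).
#' @param relaxivity per mM per second.
#' @return list with `fbv_map`, `ps_map` (matrices, NA outside mask and at
#'   failed pixels), `failed` (logical matrix), `mean_fbv`, `mean_ps`,
#'   `n_failed`.
#' @export
parametric_map <- function(vfa_pixels, dce_pixels, vfa_blood, blood_signals,
                           times, flip_angles, flip_angle_post, tr, mask,
                           relaxivity = 145) {
  mask <- mask != 0
  if (!any(mask)) stop("parametric map error: empty mask", call. = FALSE)
  idx <- which(mask)
  if (nrow(vfa_pixels) != length(idx) || nrow(dce_pixels) != length(idx))
    stop_field("mask", "pixel matrices must have one row per mask pixel")
  fit_b <- fit_vfa_r1(vfa_blood)
  r1_b <- post_contrast_r1(blood_signals, fit_b, flip_angle_post, tr)
  cb <- concentration_from_r1(r1_b, fit_b$r1, relaxivity)$concentration
  fbv_map <- ps_map <- matrix(NA_real_, nrow(mask), ncol(mask))
  failed <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_along(idx)) {
    res <- tryCatch({
      fit_t <- fit_vfa_r1(vfa_series(vfa_pixels[i, ], flip_angles, tr))
      r1_t <- post_contrast_r1(dce_pixels[i, ], fit_t, flip_angle_post, tr)
      ct <- concentration_from_r1(r1_t, fit_t$r1, relaxivity)$concentration
      fit_permeability(concentration_curve(ct, cb, relaxivity), times,
                       time_unit = "s")
    }, error = function(e) NULL)
    if (is.null(res)) failed[idx[i]] <- TRUE
    else { fbv_map[idx[i]] <- res$fbv; ps_map[idx[i]] <- res$ps }
  }
  ok <- mask & !failed
  list(fbv_map = fbv_map, ps_map = ps_map, failed = failed,
       mean_fbv = mean(fbv_map[ok]), mean_ps = mean(ps_map[ok]),
       n_failed = sum(failed))
}
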