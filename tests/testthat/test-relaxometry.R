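# DCE-MRI chain: VFA fitting, single-angle inversion, concentration
# conversion, permeability regression, and pixelwise maps.

paper_angles <- c(2, 6, 9, 15, 25, 50, 70)

test_that("noiseless VFA fit recovers (R1, S0) to 1e-6 relative", {
  for (r1 in c(0.5, 1.0, 2.5)) {
    s <- spgr_signal(r1, 1000, paper_angles, 25)
    fit <- fit_vfa_r1(vfa_series(s, paper_angles, 25))
    expect_equal(fit$r1, r1, tolerance = 1e-6)
    expect_equal(fit$s0, 1000, tolerance = 1e-6)
  }
})

test_that("degenerate VFA inputs raise fit errors", {
  expect_error(fit_vfa_r1(vfa_series(rep(0, 7), paper_angles, 25)),
               "all signals are zero")
  expect_error(fit_vfa_r1(vfa_series(rep(50, 7), paper_angles, 25)),
               "flat signal")
})

test_that("noisy VFA fits match the grid-search oracle", {
  # 1% noise at the signal scale, 200 replicates; the median recovered R1
  # stays within 2% of truth and tracks the independent grid search
  set.seed(20)
  n_rep <- 200
  truth <- 1.0
  clean <- spgr_signal(truth, 1000, paper_angles, 25)
  fits <- numeric(n_rep); oracle <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- pmax(clean + rnorm(7, 0, 0.01 * mean(clean)), 1e-9)
    fits[i] <- fit_vfa_r1(vfa_series(s, paper_angles, 25))$r1
    oracle[i] <- oracle_vfa_grid(s, paper_angles, 25)$r1
  }
  expect_lt(abs(median(fits) - truth) / truth, 0.02)
  expect_lt(abs(median(fits) - median(oracle)) / truth, 0.005)
  expect_lt(median(abs(fits - oracle)) / truth, 0.005)
})

test_that("post-contrast inversion is exact and guards its domain", {
  fit <- fit_vfa_r1(vfa_series(spgr_signal(1, 1000, paper_angles, 25),
                               paper_angles, 25))
  # identity: the model-predicted precontrast signal inverts to r1_pre
  s_pre <- spgr_signal(1, 1000, 50, 25)
  expect_equal(post_contrast_r1(s_pre, fit, 50, 25), 1, tolerance = 1e-9)
  # round trip at a contrast-enhanced R1
  s_post <- spgr_signal(2.5, 1000, 50, 25)
  expect_equal(post_contrast_r1(s_post, fit, 50, 25), 2.5,
               tolerance = 1e-9)
  # zero signal and beyond-saturation signal are non-physical
  expect_error(post_contrast_r1(0, fit, 50, 25), "non-positive")
  expect_error(post_contrast_r1(1000 * sin(50 * pi / 180) * 1.01, fit,
                                50, 25), "saturation")
  # monotone in signal below saturation
  ss <- seq(10, 700, by = 10)
  expect_true(all(diff(post_contrast_r1(ss, fit, 50, 25)) > 0))
})

test_that("concentration conversion applies the relaxivity and clamp", {
  # delta-R1 of 1.45/s at relaxivity 145 /mM/s -> 0.01 mM
  expect_equal(concentration_from_r1(2.45, 1.0, 145)$concentration, 0.01)
  expect_equal(concentration_from_r1(1.0, 1.0, 145)$concentration, 0)
  neg <- concentration_from_r1(c(0.9, 1.1, 0.95), 1.0, 145)
  expect_equal(neg$n_clamped, 2)
  expect_true(all(neg$concentration >= 0))
  expect_error(concentration_from_r1(1, 1, relaxivity = -1), "relaxivity")
})

test_that("permeability fit recovers exact linear inputs", {
  t_s <- seq(25, 240, by = 25)
  y <- 0.208 + (0.01 / 60) * t_s
  fit <- fit_permeability(y, t_s, time_unit = "s")
  expect_equal(fit$fbv, 0.208, tolerance = 1e-12)
  expect_equal(fit$ps, 0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant curve: fbv = level, ps = 0
  fit0 <- fit_permeability(rep(0.15, 9), seq(0, 200, 25), time_unit = "s")
  expect_equal(fit0$fbv, 0.15)
  expect_equal(fit0$ps, 0)
  # unit safety: seconds and minutes give identical ps in min^-1
  fit_min <- fit_permeability(y, t_s / 60, time_unit = "min")
  expect_equal(fit$ps, fit_min$ps, tolerance = 1e-12)
  expect_error(fit_permeability(c(0.2, NA), c(0, 25)), "finite")
  expect_error(fit_permeability(c(0.2, 0.3), c(10, 10)), "identical")
})

test_that("full chain round-trips generator truth at zero noise", {
  for (ps in c(0, 0.005, 0.02)) {
    sp <- dce_phantom_spec(true_fbv = 0.15, true_ps = ps, noise_sd = 0,
                           blood_concentration = function(t)
                             0.05 * exp(-t / 600))
    ph <- generate_vfa_dce(sp)
    res <- dce_analyze(ph$vfa_tissue, ph$vfa_blood, ph$dce)
    expect_equal(res$fit$fbv, 0.15, tolerance = 1e-6)
    expect_equal(res$fit$ps, ps, tolerance = 1e-6 * max(ps, 1e-3))
  }
})

test_that("estimated ps increases strictly with true ps", {
  ests <- vapply(c(0.002, 0.01, 0.03, 0.08), function(ps) {
    ph <- generate_vfa_dce(dce_phantom_spec(true_ps = ps, noise_sd = 0))
    dce_analyze(ph$vfa_tissue, ph$vfa_blood, ph$dce)$fit$ps
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("estimated fbv is invariant to common signal rescaling", {
  ph <- generate_vfa_dce(dce_phantom_spec(noise_sd = 0))
  res1 <- dce_analyze(ph$vfa_tissue, ph$vfa_blood, ph$dce)
  scale_vfa <- function(v, f) vfa_series(v$signals * f, v$flip_angles, v$tr)
  dce2 <- dce_series(ph$dce$tissue_signals * 3, ph$dce$blood_signals * 3,
                     ph$dce$times, ph$dce$flip_angle_post, ph$dce$tr)
  res2 <- dce_analyze(scale_vfa(ph$vfa_tissue, 3), scale_vfa(ph$vfa_blood, 3),
                      dce2)
  expect_equal(res2$fit$fbv, res1$fit$fbv, tolerance = 1e-6)
})

test_that("parametric maps recover regional truth and summarize cleanly", {
  set.seed(42)
  h <- 8; w <- 8; npx <- h * w
  mask <- matrix(TRUE, h, w)
  times <- seq(25, 240, 25); tr <- 25
  ps_true <- matrix(rep(c(0, 0.02), each = npx / 2), h, w)
  cb <- 0.05; noise <- 2.3  # SNR ~ 50 at the dynamic tissue signal
  vfa_px <- matrix(0, npx, 7); dce_px <- matrix(0, npx, length(times))
  for (i in seq_len(npx)) {
    ct <- (0.208 + ps_true[i] * times / 60) * cb
    vfa_px[i, ] <- pmax(spgr_signal(1, 1000, paper_angles, tr) +
                          rnorm(7, 0, noise), 1e-6)
    dce_px[i, ] <- pmax(spgr_signal(1 + 145 * ct, 1000, 50, tr) +
                          rnorm(length(times), 0, noise), 1e-6)
  }
  vfab <- vfa_series(spgr_signal(0.7, 1000, paper_angles, tr),
                     paper_angles, tr)
  bsig <- rep(spgr_signal(0.7 + 145 * cb, 1000, 50, tr), length(times))
  pm <- parametric_map(vfa_px, dce_px, vfab, bsig, times, paper_angles,
                       50, tr, mask)
  expect_equal(pm$n_failed, 0)
  expect_lt(abs(mean(pm$ps_map[, 1:4])), 0.001)
  expect_equal(mean(pm$ps_map[, 5:8]), 0.02, tolerance = 0.05)
  # mask-mean equals the mean over unflagged pixels, by definition
  expect_equal(pm$mean_fbv, mean(pm$fbv_map[mask & !pm$failed]))
  # uniform noiseless phantom: map constant at the scalar-chain answer
  vfa_u <- matrix(rep(spgr_signal(1, 1000, paper_angles, tr), each = 4),
                  4, 7)
  dce_u <- matrix(rep(spgr_signal(1 + 145 * 0.208 * cb, 1000, 50, tr),
                      4 * length(times)), 4, length(times))
  m2 <- matrix(TRUE, 2, 2)
  pm_u <- parametric_map(vfa_u, dce_u, vfab, bsig, times, paper_angles,
                         50, tr, m2)
  expect_equal(var(as.vector(pm_u$fbv_map)), 0, tolerance = 1e-16)
  expect_equal(pm_u$mean_fbv, 0.208, tolerance = 1e-6)
  expect_error(parametric_map(vfa_u, dce_u, vfab, bsig, times,
                              paper_angles, 50, tr,
                              matrix(FALSE, 2, 2)), "empty mask")
})
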