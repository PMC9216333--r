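# Phantom generators: determinism, closed-form pixel statistics, analytic
# ground truth, and validation.

test_that("leakage stack follows the stated extravasation dynamics", {
  sim <- make_leakage_sim(outside_slope = 10)
  st <- sim$stack
  expect_equal(dim(st$frames)[3], 25L)
  expect_equal(diff(st$timestamps), rep(1.2, 24))
  outside <- !sim$vessel_mask & !sim$regions$osseous_roi
  # mean outside intensity at the final frame: initial + slope * elapsed
  expect_equal(mean(st$frames[, , 25][outside]), 100 + 10 * (24 * 1.2))
  # intravascular signal constant at inside_intensity
  for (k in c(1, 13, 25))
    expect_equal(mean(st$frames[, , k][sim$vessel_mask]), 1000)
  # osseous region holds background only, at every frame
  for (k in c(1, 25))
    expect_true(all(st$frames[, , k][sim$regions$osseous_roi] == 100))
})

test_that("zero-leak stacks are constant outside the mask", {
  sim <- make_leakage_sim(outside_slope = 0)
  outside <- !sim$vessel_mask & !sim$regions$osseous_roi
  ref <- sim$stack$frames[, , 1][outside]
  for (k in 2:25) expect_identical(sim$stack$frames[, , k][outside], ref)
})

test_that("generators are bit-identical per seed", {
  a <- make_leakage_sim(noise_sd = 20, seed = 7)
  b <- make_leakage_sim(noise_sd = 20, seed = 7)
  expect_identical(a$stack$frames, b$stack$frames)
  c <- make_leakage_sim(noise_sd = 20, seed = 8)
  expect_false(identical(a$stack$frames, c$stack$frames))

  k1 <- generate_kymograph(kymograph_spec(noise_sd = 50, seed = 3))
  k2 <- generate_kymograph(kymograph_spec(noise_sd = 50, seed = 3))
  expect_identical(k1$image, k2$image)

  d1 <- generate_vfa_dce(dce_phantom_spec(noise_sd = 1, seed = 5))
  d2 <- generate_vfa_dce(dce_phantom_spec(noise_sd = 1, seed = 5))
  expect_identical(d1$dce$tissue_signals, d2$dce$tissue_signals)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_kymograph(kymograph_spec(noise_sd = 50, seed = 1)))
  invisible(make_leakage_sim(noise_sd = 5, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("kymograph streaks advance at the specified pixel slope", {
  # pixel_size 1 um, line_period 1 ms, velocity 2 um/ms -> 2 px per line,
  # verified by locating one streak's minimum row by row
  sp <- kymograph_spec(n_positions = 256, n_lines = 40, true_velocity = 2,
                       streak_density = 0.8, seed = 11)
  k <- generate_kymograph(sp)
  mins <- apply(k$image, 1, which.min)
  steps <- diff(mins)
  steps <- steps[abs(steps) <= 4]  # same-streak continuations only
  expect_true(length(steps) > 10)
  expect_equal(median(steps), 2)
  # stationary cells give vertical streaks
  k0 <- generate_kymograph(kymograph_spec(true_velocity = 0, seed = 11))
  expect_equal(var(apply(k0$image, 1, which.min)), 0)
})

test_that("zero streak density yields a flagged uniform image", {
  k <- generate_kymograph(kymograph_spec(streak_density = 0, seed = 1))
  expect_true(k$empty)
  expect_equal(var(as.vector(k$image)), 0)
})

test_that("morphometry scene ground truth is analytic", {
  # two perpendicular crossing segments -> 1 branch point
  expect_equal(generate_morphometry_scene(plus_sign_spec())$truth$
                 branch_points, 1L)
  # 3 horizontal x 4 vertical full-width segments -> 12 crossings
  expect_equal(generate_morphometry_scene(grid_spec())$truth$branch_points,
               12L)
  # sprout lengths recorded as constructed; off-vessel attachment errors
  sc <- generate_morphometry_scene(
    plus_sign_spec(),
    sprouts = list(list(attachment = c(40, 64), length = 10, angle = -90),
                   list(attachment = c(90, 64), length = 5, angle = 90)))
  expect_equal(sc$truth$sprout_lengths, c(10, 5))
  expect_error(
    generate_morphometry_scene(
      plus_sign_spec(),
      sprouts = list(list(attachment = c(5, 5), length = 10, angle = 0))),
    "not on any vessel")
  # cell distances: cell at (64, 30) is 34 px above the horizontal
  # centerline at y = 64, minus radius 2 -> 32; vertical vessel at x = 64
  # is 0 px away horizontally... use a cell well away from it
  sc2 <- generate_morphometry_scene(
    vessel_phantom_spec(vessel_segments = list(
      list(start = c(0, 64), end = c(127, 64), radius = 2,
           intensity = 1000))),
    cell_pixels = rbind(c(50, 30), c(20, 70)))
  expect_equal(sc2$truth$cell_distances, c(34 - 2, 6 - 2))
})

test_that("VFA/DCE phantom encodes the two-compartment model exactly", {
  # pure blood-volume case: ps = 0 gives a flat normalized curve at fbv
  sp <- dce_phantom_spec(true_ps = 0, noise_sd = 0)
  ph <- generate_vfa_dce(sp)
  res <- dce_analyze(ph$vfa_tissue, ph$vfa_blood, ph$dce)
  expect_equal(res$curve$normalized, rep(0.208, length(sp$sample_times)),
               tolerance = 1e-9)
  # cohort: distinct truths, reproducible per seed
  c1 <- generate_dce_cohort(dce_phantom_spec(seed = 0), 6)
  c2 <- generate_dce_cohort(dce_phantom_spec(seed = 0), 6)
  f1 <- vapply(c1, function(p) p$truth$fbv, numeric(1))
  expect_identical(f1, vapply(c2, function(p) p$truth$fbv, numeric(1)))
  expect_equal(length(unique(f1)), 6L)
  expect_true(all(f1 > 0 & f1 < 1))
})

test_that("spec validation errors name the offending field", {
  expect_error(vessel_phantom_spec(pixel_size = -1), "pixel_size")
  expect_error(vessel_phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(vessel_phantom_spec(
    vessel_segments = list(list(start = c(0, 0), end = c(1, 1),
                                radius = -2, intensity = 1))), "radius")
  expect_error(leakage_phantom_spec(n_frames = 1), "n_frames")
  expect_error(leakage_phantom_spec(outside_slope = -1), "outside_slope")
  expect_error(kymograph_spec(n_lines = 1), "n_lines")
  expect_error(kymograph_spec(line_period = 0), "line_period")
  expect_error(dce_phantom_spec(true_fbv = 1.2), "true_fbv")
  expect_error(dce_phantom_spec(relaxivity = -5), "relaxivity")
  expect_error(dce_phantom_spec(sample_times = c(5, 5, 10)), "sample_times")
  expect_error(dce_phantom_spec(flip_angles_pre = c(10, 20)), "flip_angles")
})
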