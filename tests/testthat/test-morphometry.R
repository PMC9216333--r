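# Branch points, sprouts, and cell-to-vessel proximity.

test_that("branch counting matches analytic phantom truth", {
  reg <- full_region()
  sc <- generate_morphometry_scene(plus_sign_spec())
  res <- count_branch_points(sc$vessel_channel, morphometry_config(), reg)
  expect_equal(res$branch_points, 1L)
  expect_gt(res$vessel_area_fraction, 0)
  sc2 <- generate_morphometry_scene(grid_spec())
  res2 <- count_branch_points(sc2$vessel_channel, morphometry_config(), reg)
  expect_equal(res2$branch_points, 12L)
})

test_that("blank images give a warned zero-count result", {
  reg <- full_region(64, 64)
  expect_warning(
    res <- count_branch_points(matrix(FALSE, 64, 64),
                               morphometry_config(), reg),
    "empty")
  expect_equal(res$branch_points, 0L)
  expect_equal(res$vessel_area_fraction, 0)
})

test_that("branch counts are invariant under rotation and reflection", {
  sc <- generate_morphometry_scene(grid_spec())
  img <- sc$vessel_channel
  reg <- full_region()
  base <- count_branch_points(img, morphometry_config(), reg)$branch_points
  rot90 <- t(img)[ncol(img):1, ]
  expect_equal(count_branch_points(rot90, morphometry_config(),
                                   reg)$branch_points, base)
  refl <- img[, ncol(img):1]
  expect_equal(count_branch_points(refl, morphometry_config(),
                                   reg)$branch_points, base)
})

test_that("area fraction is invariant under intensity scaling (Otsu)", {
  sc <- generate_morphometry_scene(plus_sign_spec())
  reg <- full_region()
  a1 <- count_branch_points(sc$vessel_channel, morphometry_config(),
                            reg)$vessel_area_fraction
  a2 <- count_branch_points(sc$vessel_channel * 5.5, morphometry_config(),
                            reg)$vessel_area_fraction
  expect_equal(a1, a2)
})

test_that("the sprout rule is strict at the 8 um threshold", {
  trunk <- vessel_phantom_spec(vessel_segments = list(
    list(start = c(0, 64), end = c(127, 64), radius = 2, intensity = 1000)))
  sc <- generate_morphometry_scene(
    trunk,
    sprouts = list(list(attachment = c(40, 64), length = 10, angle = -90),
                   list(attachment = c(80, 64), length = 5, angle = 90),
                   list(attachment = c(60, 64), length = 8, angle = -90)))
  res <- detect_sprouts(sc$vessel_channel, morphometry_config(),
                        full_region())
  expect_equal(res$sprout_count, 1L)           # only the 10 um sprout
  expect_equal(res$sprout_lengths, 10, tolerance = 0.1)
  expect_equal(sort(res$candidate_lengths), c(5, 8, 10), tolerance = 0.1)
})

test_that("sprout counts match generator truth on random phantoms", {
  reg <- full_region()
  for (s in 1:20) {
    set.seed(s)
    n_sp <- sample(0:3, 1)
    lens <- c(4, 6, 10, 12, 14)[sample(5, n_sp)]
    atts <- sort(sample(seq(20, 108, by = 12), n_sp))
    spr <- lapply(seq_len(n_sp), function(i)
      list(attachment = c(atts[i], 64), length = lens[i],
           angle = if (i %% 2) -90 else 90))
    spx <- vessel_phantom_spec(vessel_segments = list(
      list(start = c(0, 64), end = c(127, 64), radius = 2,
           intensity = 1000)), seed = s)
    scx <- generate_morphometry_scene(spx, sprouts = spr)
    r <- detect_sprouts(scx$vessel_channel, morphometry_config(), reg)
    expect_equal(r$sprout_count, sum(lens > 8),
                 info = sprintf("seed %d", s))
  }
})

test_that("sprout counts are monotone non-increasing in the threshold", {
  trunk <- vessel_phantom_spec(vessel_segments = list(
    list(start = c(0, 64), end = c(127, 64), radius = 2, intensity = 1000)))
  sc <- generate_morphometry_scene(
    trunk,
    sprouts = list(list(attachment = c(30, 64), length = 6, angle = -90),
                   list(attachment = c(60, 64), length = 10, angle = 90),
                   list(attachment = c(95, 64), length = 14, angle = -90)))
  counts <- vapply(c(2, 5, 8, 12, 20), function(thr)
    detect_sprouts(sc$vessel_channel,
                   morphometry_config(sprout_min_length = thr),
                   full_region())$sprout_count, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[[1]], 3L)
  expect_equal(counts[[5]], 0L)
})

test_that("distance transform equals brute force on random scenes", {
  set.seed(77)
  for (i in 1:50) {
    h <- sample(32:128, 1); w <- sample(32:128, 1)
    m <- matrix(runif(h * w) < runif(1, 0.002, 0.05), h, w)
    if (!any(m)) m[sample(h * w, 1)] <- TRUE
    dt <- distance_transform(m)
    cells <- sample(h * w, 10)
    expect_equal(dt[cells], oracle_brute_distance(m, cells),
                 tolerance = 1e-12)
  }
})

test_that("proximity distances follow axis-aligned geometry", {
  h <- 128; w <- 128
  vmask <- matrix(FALSE, h, w); vmask[, 51] <- TRUE   # column x = 50
  cmask <- matrix(FALSE, h, w); cmask[31, 61] <- TRUE # cell at x = 60
  res <- proximity_distances(cmask, list(cd31 = vmask), full_region(),
                             pixel_size = 1)
  expect_equal(res$distances$cd31, 10)
  # micrometre calibration
  res2 <- proximity_distances(cmask, list(cd31 = vmask), full_region(),
                              pixel_size = 0.5)
  expect_equal(res2$distances$cd31, 5)
})

test_that("osseous cells are excluded and empty channels are named", {
  h <- 64; w <- 64
  vmask <- matrix(FALSE, h, w); vmask[, 11] <- TRUE
  cmask <- matrix(FALSE, h, w); cmask[10, 40] <- TRUE; cmask[50, 40] <- TRUE
  oss <- matrix(FALSE, h, w); oss[40:64, ] <- TRUE
  reg <- region_set(!oss, oss)
  res <- proximity_distances(cmask, list(zsgreen = vmask), reg, 1)
  expect_equal(res$n_cell_pixels, 1L)  # the osseous cell is dropped
  expect_error(
    proximity_distances(cmask, list(bad = matrix(FALSE, h, w)), reg, 1),
    "'bad'")
})

test_that("proximity bins are consistent with the raw distances", {
  set.seed(5)
  h <- 128; w <- 128
  vmask <- matrix(FALSE, h, w); vmask[64, 5] <- TRUE
  cmask <- matrix(runif(h * w) < 0.01, h, w)
  res <- proximity_distances(cmask, list(v = vmask), full_region(), 1)
  d <- res$distances$v
  expect_equal(res$bin_summary$n_below, sum(d < 40))
  expect_equal(res$bin_summary$n_above, sum(d >= 40))
  expect_equal(res$bin_summary$n_below + res$bin_summary$n_above,
               res$n_cell_pixels)
})
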