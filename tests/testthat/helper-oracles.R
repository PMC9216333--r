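# Independent oracles used to cross-check the analysis implementations.
# These deliberately avoid the code paths they validate.

# Grid search over R1 with the profiled (closed-form least-squares) S0 at
# each candidate; two passes, the second zoomed around the first optimum.
oracle_vfa_grid <- function(signals, flip_angles, tr,
                            r1_range = c(0.1, 10), n_grid = 2000) {
  a <- flip_angles * pi / 180
  search <- function(lo, hi) {
    r1s <- seq(lo, hi, length.out = n_grid)
    best <- c(Inf, NA, NA)
    for (r1 in r1s) {
      e <- exp(-(tr / 1000) * r1)
      f <- sin(a) * (1 - e) / (1 - e * cos(a))
      s0 <- sum(f * signals) / sum(f * f)
      ssr <- sum((s0 * f - signals)^2)
      if (ssr < best[1]) best <- c(ssr, r1, s0)
    }
    best
  }
  b <- search(r1_range[1], r1_range[2])
  span <- diff(r1_range) / n_grid * 4
  b <- search(max(r1_range[1], b[2] - span), b[2] + span)
  list(r1 = b[2], s0 = b[3])
}

# Centroid streak tracking: per scan line, locate dark streak minima,
# refine each to an intensity-weighted centroid, link nearest neighbours
# across consecutive lines, and report the mean displacement per line.
oracle_track_streaks <- function(img, pixel_size, line_period,
                                 max_jump = 8) {
  nl <- nrow(img); np <- ncol(img)
  sm <- t(apply(img, 1, function(r)
    as.numeric(stats::filter(r, rep(1 / 3, 3), sides = 2))))
  bg <- stats::median(sm, na.rm = TRUE)
  sm[is.na(sm)] <- bg
  depth <- bg - min(sm)
  find_centroids <- function(v) {
    n <- length(v)
    cand <- which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n]) + 1
    cand <- cand[v[cand] < bg - 0.5 * depth]
    vapply(cand, function(p) {
      win <- max(1, p - 2):min(n, p + 2)
      w <- pmax(bg - v[win], 0)
      if (sum(w) == 0) return(as.numeric(p))
      sum(win * w) / sum(w)
    }, numeric(1))
  }
  disps <- numeric(0)
  prev <- find_centroids(sm[1, ])
  for (t in 2:nl) {
    cur <- find_centroids(sm[t, ])
    if (length(cur) && length(prev)) {
      for (p in prev) {
        j <- which.min(abs(cur - p))
        if (abs(cur[j] - p) <= max_jump) disps <- c(disps, cur[j] - p)
      }
    }
    prev <- cur
  }
  mean(disps) * pixel_size / line_period
}

# Exhaustive nearest-vessel-pixel search (center-to-center), pixel units.
oracle_brute_distance <- function(vessel_mask, cell_idx) {
  h <- nrow(vessel_mask)
  vidx <- which(vessel_mask)
  vr <- (vidx - 1) %% h; vc <- (vidx - 1) %/% h
  vapply(cell_idx, function(q) {
    r <- (q - 1) %% h; cc <- (q - 1) %/% h
    sqrt(min((vr - r)^2 + (vc - cc)^2))
  }, numeric(1))
}

# Standard phantom builders shared across test files -----------------------

make_leakage_sim <- function(outside_slope = 5, noise_sd = 0, seed = 1L,
                             inside = 1000) {
  base <- vessel_phantom_spec(
    vessel_segments = list(
      list(start = c(20, 30), end = c(108, 30), radius = 4,
           intensity = inside),
      list(start = c(30, 90), end = c(100, 100), radius = 3,
           intensity = inside)),
    osseous_polygon = rbind(c(0, 110), c(127, 110), c(127, 127),
                            c(0, 127)),
    noise_sd = noise_sd, seed = seed)
  generate_leakage_stack(leakage_phantom_spec(
    base, inside_intensity = inside, outside_slope = outside_slope))
}

plus_sign_spec <- function(radius = 2) {
  vessel_phantom_spec(vessel_segments = list(
    list(start = c(0, 64), end = c(127, 64), radius = radius,
         intensity = 1000),
    list(start = c(64, 0), end = c(64, 127), radius = radius,
         intensity = 1000)))
}

grid_spec <- function() {
  segs <- c(
    lapply(c(30, 64, 98), function(y)
      list(start = c(0, y), end = c(127, y), radius = 2, intensity = 1000)),
    lapply(c(20, 52, 84, 116), function(x)
      list(start = c(x, 0), end = c(x, 127), radius = 2, intensity = 1000)))
  vessel_phantom_spec(vessel_segments = segs)
}

full_region <- function(h = 128, w = 128) {
  region_set(matrix(TRUE, h, w))
}
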