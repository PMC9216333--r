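# Vessel morphometry on projections: Otsu segmentation, Zhang-Suen
# skeletonization, branch-point counting with junction clustering, sprout
# detection under the >8 um protrusion rule, and cell-to-vessel proximity
# via an exact Euclidean distance transform.

# Shift a logical matrix by (dy, dx), padding with FALSE.
.shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  sr <- max(1, 1 + dy):min(h, h + dy)
  sc <- max(1, 1 + dx):min(w, w + dx)
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

# 8-neighbourhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW).
.neighbours <- function(m) {
  list(.shift(m, 1, 0), .shift(m, 1, -1), .shift(m, 0, -1),
       .shift(m, -1, -1), .shift(m, -1, 0), .shift(m, -1, 1),
       .shift(m, 0, 1), .shift(m, 1, 1))
}

#' Zhang-Suen morphological skeleton of a binary mask
#'
#' Iterative thinning to one-pixel-wide centerlines.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m <- mask != 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- .neighbours(m)
      b <- Reduce(`+`, nb)
      a <- Reduce(`+`, lapply(1:8, function(i)
        (!nb[[i]]) & nb[[if (i == 8) 1 else i + 1]]))
      cond <- m & a == 1 & b >= 2 & b <= 6
      if (step == 1) {
        cond <- cond & !(nb[[1]] & nb[[3]] & nb[[5]]) &
          !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- cond & !(nb[[1]] & nb[[3]] & nb[[7]]) &
          !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Count of 8-connected skeleton neighbours at each skeleton pixel.
.neighbour_count <- function(skel) {
  Reduce(`+`, .neighbours(skel)) * skel
}

# 8-connected component labelling of a logical matrix (BFS flood fill).
.label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(mask)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p; lab[p] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1L) %% h + 1L; cc <- (q - 1L) %/% h + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dy[k]; cc2 <- cc + offs$dx[k]
        if (rr < 1 || rr > h || cc2 < 1 || cc2 > w) next
        q2 <- (cc2 - 1L) * h + rr
        if (mask[q2] && lab[q2] == 0L) { lab[q2] <- cur; queue <- c(queue, q2) }
      }
    }
  }
  list(labels = lab, n = cur)
}

#' Morphometry configuration
#'
#' @param vessel_threshold `"otsu"` or a fixed numeric threshold.
#' @param sprout_min_length minimum protrusion length in micrometres;
#'   sprouts are counted iff strictly longer (default 8, the published
#'   rule).
#' @param min_object_area smallest object kept after thresholding, um^2
#'   (0 disables cleanup, the default).
#' @return object of class `morphometry_config`.
#' @export
morphometry_config <- function(vessel_threshold = "otsu",
                               sprout_min_length = 8,
                               min_object_area = 0) {
  if (!identical(vessel_threshold, "otsu"))
    check_scalar(vessel_threshold, "vessel_threshold")
  check_scalar(sprout_min_length, "sprout_min_length", positive = TRUE)
  check_scalar(min_object_area, "min_object_area", nonneg = TRUE)
  structure(list(vessel_threshold = vessel_threshold,
                 sprout_min_length = sprout_min_length,
                 min_object_area = min_object_area),
            class = "morphometry_config")
}

# Threshold a channel to a binary mask within the marrow ROI.
.vessel_mask_from <- function(image, config, regions) {
  roi <- regions$marrow_roi & !regions$osseous_roi
  thr <- if (identical(config$vessel_threshold, "otsu"))
    otsu_threshold(image[roi]) else config$vessel_threshold
  mask <- image > thr & roi
  if (config$min_object_area > 0 && any(mask)) {
    lab <- .label_components(mask)
    sizes <- tabulate(lab$labels[lab$labels > 0], lab$n)
    drop <- which(sizes < config$min_object_area)
    mask[lab$labels %in% drop] <- FALSE
  }
  mask
}

#' Count vessel branch points and area fraction on a projection
#'
#' Thresholds the vessel channel, skeletonizes, and counts junctions:
#' skeleton pixels with >= 3 skeleton neighbours (8-connectivity), with
#' adjacent branch pixels merged into a single junction. Projected vessel
#' crossings are counted as junctions without superimposition correction.
#'
#' @param image vessel-channel matrix (a.u.) or a logical mask.
#' @param config a [morphometry_config()].
#' @param regions a [region_set()].
#' @param pixel_size micrometres per pixel.
#' @return object of class `morphometry_result`: `branch_points`,
#'   `vessel_area_fraction`, `skeleton`, `vessel_mask`.
#' @export
count_branch_points <- function(image, config = morphometry_config(),
                                regions, pixel_size = 1) {
  stopifnot(inherits(regions, "region_set"))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  mask <- if (is.logical(image)) image & regions$marrow_roi else
    .vessel_mask_from(image, config, regions)
  roi_n <- sum(regions$marrow_roi)
  if (!any(mask)) {
    warning("empty vessel mask; zero-count result")
    return(structure(list(branch_points = 0L, vessel_area_fraction = 0,
                          skeleton = mask, vessel_mask = mask),
                     class = "morphometry_result"))
  }
  skel <- skeletonize(mask)
  nb <- .neighbour_count(skel)
  branch_px <- skel & nb >= 3
  n_branch <- if (any(branch_px)) .label_components(branch_px)$n else 0L
  structure(list(branch_points = n_branch,
                 vessel_area_fraction = sum(mask & regions$marrow_roi) /
                   roi_n,
                 skeleton = skel, vessel_mask = mask),
            class = "morphometry_result")
}

#' Detect vessel sprouts longer than the protrusion threshold
#'
#' Skeleton endpoints are traced back along the skeleton to the nearest
#' junction; the protrusion length is the geodesic length of that path
#' (diagonal steps sqrt(2) * pixel size) plus the local vessel half-width
#' at the tip (thinning retracts stroke tips by about the capsule radius,
#' so the distance from the skeleton tip to the mask boundary is added
#' back). A sprout is counted iff its length strictly exceeds
#' `config$sprout_min_length` (the ">8 um" rule). Free-floating segments
#' (no junction on either end) are not sprouts, and endpoints within 2
#' pixels of the image border are treated as vessels leaving the field of
#' view, not sprouts.
#'
#' @param image vessel-channel matrix or logical mask.
#' @param config a [morphometry_config()].
#' @param regions a [region_set()].
#' @param pixel_size micrometres per pixel.
#' @return list with `sprout_count`, `sprout_lengths` (um, counted sprouts
#'   only), `candidate_lengths` (all endpoint protrusions).
#' @export
detect_sprouts <- function(image, config = morphometry_config(), regions,
                           pixel_size = 1) {
  stopifnot(inherits(regions, "region_set"))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  mask <- if (is.logical(image)) image & regions$marrow_roi else
    .vessel_mask_from(image, config, regions)
  if (!any(mask)) stop("sprout detection error: empty vessel mask",
                       call. = FALSE)
  skel <- skeletonize(mask)
  nb <- .neighbour_count(skel)
  h <- nrow(skel); w <- ncol(skel)
  endpoints <- which(skel & nb == 1)
  junction <- skel & nb >= 3
  # local half-width at each pixel: distance to the nearest background
  # pixel, used to restore the tip length removed by thinning
  half_width <- distance_transform(!mask)
  # drop endpoints near the field-of-view border (within the tip's own
  # half-width plus the thinning retraction): truncated vessels, not
  # sprouts
  ep_r <- (endpoints - 1L) %% h + 1L
  ep_c <- (endpoints - 1L) %/% h + 1L
  border_d <- pmin(ep_r - 1L, h - ep_r, ep_c - 1L, w - ep_c)
  endpoints <- endpoints[border_d > half_width[endpoints] + 2]
  lengths <- numeric(0)
  for (e in endpoints) {
    len <- half_width[e] * pixel_size
    cur <- e
    visited <- e
    reached <- FALSE
    for (step in seq_len(h * w)) {
      r <- (cur - 1L) %% h + 1L; cc <- (cur - 1L) %/% h + 1L
      nxt <- integer(0); diag <- logical(0)
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        rr <- r + dy; c2 <- cc + dx
        if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
        q <- (c2 - 1L) * h + rr
        if (skel[q] && !(q %in% visited)) {
          nxt <- c(nxt, q); diag <- c(diag, dy != 0 & dx != 0)
        }
      }
      if (length(nxt) == 0L) break              # isolated tip
      # prefer a junction neighbour if present, else continue along path
      j <- which(junction[nxt])
      pick <- if (length(j)) j[1] else 1L
      if (length(nxt) > 1L && !length(j)) break # ambiguous: stop trace
      len <- len + (if (diag[pick]) sqrt(2) else 1) * pixel_size
      if (junction[nxt[pick]]) { reached <- TRUE; break }
      cur <- nxt[pick]
      visited <- c(visited, cur)
    }
    if (reached) lengths <- c(lengths, len)
  }
  counted <- lengths[lengths > config$sprout_min_length]
  list(sprout_count = length(counted), sprout_lengths = counted,
       candidate_lengths = lengths)
}

# Felzenszwalb-Huttenlocher 1-d squared distance transform.
.dt1d <- function(f) {
  n <- length(f)
  big <- 1e12
  f <- pmin(f, big)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  if (n > 1) for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform of a binary mask
#'
#' Distance from every pixel to the nearest TRUE pixel (center-to-center),
#' in pixel units.
#'
#' @param mask logical matrix; must contain at least one TRUE pixel.
#' @return numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  m <- mask != 0
  if (!any(m)) stop("distance transform error: empty mask", call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  d2 <- matrix(ifelse(m, 0, 1e12), h, w)
  for (j in seq_len(w)) d2[, j] <- .dt1d(d2[, j])
  for (i in seq_len(h)) d2[i, ] <- .dt1d(d2[i, ])
  sqrt(d2)
}

#' Cell-to-vessel proximity distances excluding osseous areas
#'
#' Thresholds the myeloid-cell channel, then for each vessel channel
#' computes the Euclidean distance transform of its vessel mask and samples
#' it at the cell pixels; distances are reported in micrometres with
#' below/above 40 um bin counts. Cell pixels inside the osseous ROI are
#' excluded.
#'
#' @param cell_channel matrix (a.u.) or logical cell mask.
#' @param vessel_channels named list of vessel-channel matrices or masks.
#' @param regions a [region_set()].
#' @param pixel_size micrometres per pixel.
#' @param config a [morphometry_config()] (thresholding).
#' @param bin_threshold bin boundary, micrometres (default 40).
#' @return object of class `proximity_result`: `distances` (named list of
#'   um vectors), `bin_summary` (data.frame: channel, n_below, n_above),
#'   `n_cell_pixels`.
#' @export
proximity_distances <- function(cell_channel, vessel_channels, regions,
                                pixel_size, config = morphometry_config(),
                                bin_threshold = 40) {
  stopifnot(inherits(regions, "region_set"))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(bin_threshold, "bin_threshold", positive = TRUE)
  if (is.null(names(vessel_channels)) || any(names(vessel_channels) == ""))
    stop_field("vessel_channels", "must be a named list")
  cell_mask <- if (is.logical(cell_channel))
    cell_channel & regions$marrow_roi & !regions$osseous_roi
  else .vessel_mask_from(cell_channel, config, regions)
  cell_idx <- which(cell_mask & !regions$osseous_roi)
  dists <- list()
  bins <- data.frame(channel = character(0), n_below = integer(0),
                     n_above = integer(0))
  for (ch in names(vessel_channels)) {
    vm <- vessel_channels[[ch]]
    vmask <- if (is.logical(vm)) vm & !regions$osseous_roi else
      .vessel_mask_from(vm, config, regions)
    if (!any(vmask))
      stop(sprintf("proximity error: empty vessel mask for channel '%s'",
                   ch), call. = FALSE)
    dt <- distance_transform(vmask) * pixel_size
    d <- dt[cell_idx]
    dists[[ch]] <- d
    bins <- rbind(bins, data.frame(channel = ch,
                                   n_below = sum(d < bin_threshold),
                                   n_above = sum(d >= bin_threshold)))
  }
  structure(list(distances = dists, bin_summary = bins,
                 n_cell_pixels = length(cell_idx)),
            class = "proximity_result")
}
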