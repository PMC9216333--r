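# Intravital vascular-leakage quantification (I_out/I_in over time) and
# target-to-background ratios on maximum-intensity projections.

#' Segment the vasculature from the first post-injection frame
#'
#' Otsu thresholding of the designated first post-injection frame,
#' restricted to the marrow ROI; the osseous ROI is always excluded. Later
#' frames never influence the mask.
#'
#' @param stack a [timelapse_stack()].
#' @param injection_frame 1-based index of the first post-injection frame.
#' @param regions a [region_set()].
#' @param threshold optional fixed threshold overriding Otsu.
#' @return list with `mask` (logical matrix) and `threshold` (a.u.).
#' @export
segment_vessels_first_frame <- function(stack, injection_frame, regions,
                                        threshold = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"),
            inherits(regions, "region_set"))
  nf <- dim(stack$frames)[3]
  check_scalar(injection_frame, "injection_frame", integerish = TRUE)
  if (injection_frame < 1 || injection_frame > nf)
    stop_field("injection_frame", "outside the stack")
  frame <- stack$frames[, , injection_frame]
  if (!identical(dim(frame), dim(regions$marrow_roi)))
    stop_field("regions", "mask shape must match frames")
  vals <- frame[regions$marrow_roi]
  if (length(vals) == 0) stop_field("marrow_roi", "must be nonempty")
  if (stats::sd(vals) == 0)
    stop("segmentation error: first post-injection frame is flat within ",
         "the marrow ROI", call. = FALSE)
  thr <- if (is.null(threshold)) otsu_threshold(vals) else threshold
  mask <- frame > thr & regions$marrow_roi & !regions$osseous_roi
  list(mask = mask, threshold = thr)
}

#' Quantify vascular leakage as the slope of I_out/I_in over time
#'
#' For each post-injection frame, `i_in` is the mean intensity over the
#' vessel mask within the marrow ROI and `i_out` the mean over the marrow
#' ROI outside both the mask and the osseous ROI. The leak rate is the
#' ordinary-least-squares slope of `i_out/i_in` against time, per minute.
#'
#' @param stack a [timelapse_stack()].
#' @param vessel_mask logical matrix (e.g. from
#'   [segment_vessels_first_frame()]).
#' @param regions a [region_set()].
#' @param injection_frame 1-based index of the first post-injection frame.
#' @param dilate_mask if TRUE, expand the vessel mask by one pixel before
#'   defining the out-region (off by default).
#' @return object of class `leakage_result`: `time` (s), `i_in`, `i_out`,
#'   `ratio`, `leak_rate` (per minute), `n_frames_used`.
#' @export
leakage_rate <- function(stack, vessel_mask, regions, injection_frame,
                         dilate_mask = FALSE) {
  stopifnot(inherits(stack, "timelapse_stack"),
            inherits(regions, "region_set"))
  vessel_mask <- vessel_mask != 0
  if (!any(vessel_mask)) stop("leakage error: empty vessel mask",
                              call. = FALSE)
  nf <- dim(stack$frames)[3]
  if (injection_frame > nf - 1)
    stop("leakage error: need >= 2 post-injection frames", call. = FALSE)
  out_excl <- if (dilate_mask) .dilate1(vessel_mask) else vessel_mask
  in_region <- vessel_mask & regions$marrow_roi
  out_region <- regions$marrow_roi & !out_excl & !regions$osseous_roi
  if (!any(out_region)) stop("leakage error: empty out-region",
                             call. = FALSE)
  if (!any(in_region)) stop("leakage error: vessel mask misses marrow ROI",
                            call. = FALSE)
  ks <- injection_frame:nf
  i_in <- vapply(ks, function(k) mean(stack$frames[, , k][in_region]),
                 numeric(1))
  i_out <- vapply(ks, function(k) mean(stack$frames[, , k][out_region]),
                  numeric(1))
  ratio <- ifelse(i_in > 0, i_out / i_in, NA_real_)
  tt <- stack$timestamps[ks]
  co <- ols_line(tt / 60, ratio)
  structure(list(time = tt, i_in = i_in, i_out = i_out, ratio = ratio,
                 leak_rate = unname(co[["slope"]]),
                 n_frames_used = length(ks)),
            class = "leakage_result")
}

# One-pixel 8-connected binary dilation.
.dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  for (i in seq_len(nrow(shifts))) {
    dy <- shifts$dy[i]; dx <- shifts$dx[i]
    if (dy == 0 && dx == 0) next
    src_r <- max(1, 1 - dy):min(h, h - dy)
    src_c <- max(1, 1 - dx):min(w, w - dx)
    out[src_r + dy, src_c + dx] <- out[src_r + dy, src_c + dx] |
      m[src_r, src_c]
  }
  out
}

#' Target-to-background ratio on a maximum-intensity projection
#'
#' Projects up to `projection_depth` slices by maximum intensity and
#' returns the ratio of the mean projected intensity over the marrow
#' (target) ROI to the mean over the osseous (background) ROI.
#'
#' @param zstack 3-d array (height x width x slices) or a single matrix.
#' @param regions a [region_set()] whose osseous ROI is nonempty.
#' @param projection_depth number of slices to project (default: all).
#' @return object of class `tbr_result`: `tbr`, `target_mean`,
#'   `background_mean`, `projection_depth`.
#' @export
target_to_background <- function(zstack, regions, projection_depth = NULL) {
  stopifnot(inherits(regions, "region_set"))
  if (is.matrix(zstack)) zstack <- array(zstack, dim = c(dim(zstack), 1L))
  ns <- dim(zstack)[3]
  if (ns < 1) stop("TBR error: need >= 1 slice", call. = FALSE)
  depth <- if (is.null(projection_depth)) ns else
    min(ns, check_scalar(projection_depth, "projection_depth",
                         positive = TRUE, integerish = TRUE))
  mip <- apply(zstack[, , seq_len(depth), drop = FALSE], c(1, 2), max)
  if (!any(regions$osseous_roi))
    stop("TBR error: empty background (osseous) ROI", call. = FALSE)
  bg <- mean(mip[regions$osseous_roi])
  if (bg <= 0) stop("TBR error: background mean is zero", call. = FALSE)
  tg <- mean(mip[regions$marrow_roi])
  structure(list(tbr = tg / bg, target_mean = tg, background_mean = bg,
                 projection_depth = depth),
            class = "tbr_result")
}
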