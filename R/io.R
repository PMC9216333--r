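# Image and metadata I/O: a minimal baseline TIFF codec (uncompressed,
# grayscale, little-endian, multi-page; 32-bit float for intensities and
# 8-bit for masks) plus the project's JSON sidecar dialect. No TIFF reader
# is available in the target R environment, so the codec is part of the
# package; it writes strictly baseline files that standard readers accept.

.tiff_tag <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {                    # SHORT packed into 4-byte field
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a multi-page grayscale TIFF
#'
#' Baseline little-endian TIFF, one page per frame, single strip per page.
#'
#' @param frames matrix or 3-d array (height x width x pages).
#' @param path output path.
#' @param bits 32 (IEEE float intensities) or 8 (unsigned byte masks).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path, bits = 32) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, bits %in% c(8L, 32L))
  h <- dim(frames)[1]; w <- dim(frames)[2]; np <- dim(frames)[3]
  bpp <- bits / 8
  strip_bytes <- h * w * bpp
  n_tags <- 10L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  first_ifd <- 8L + np * strip_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (p in seq_len(np)) {
    v <- as.vector(t(frames[, , p]))     # TIFF is row-major
    if (bits == 32L) writeBin(as.numeric(v), con, size = 4,
                              endian = "little")
    else writeBin(as.raw(pmin(255, pmax(0, round(v)))), con)
  }
  for (p in seq_len(np)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    .tiff_tag(con, 256, 4, 1, w)                     # ImageWidth
    .tiff_tag(con, 257, 4, 1, h)                     # ImageLength
    .tiff_tag(con, 258, 3, 1, bits)                  # BitsPerSample
    .tiff_tag(con, 259, 3, 1, 1)                     # Compression: none
    .tiff_tag(con, 262, 3, 1, 1)                     # BlackIsZero
    .tiff_tag(con, 273, 4, 1, 8L + (p - 1L) * strip_bytes)  # StripOffsets
    .tiff_tag(con, 277, 3, 1, 1)                     # SamplesPerPixel
    .tiff_tag(con, 278, 4, 1, h)                     # RowsPerStrip
    .tiff_tag(con, 279, 4, 1, strip_bytes)           # StripByteCounts
    .tiff_tag(con, 339, 3, 1, if (bits == 32L) 3 else 1)  # SampleFormat
    nxt <- if (p < np) first_ifd + p * ifd_bytes else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_u <- function(raw, off, size) {
  # little-endian unsigned integer at 1-based byte offset off
  sum(as.integer(raw[off + seq_len(size) - 1L]) * 256^(seq_len(size) - 1L))
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed little-endian grayscale pages with 8-bit unsigned
#' or 32-bit float samples (the format written by [write_tiff()]).
#'
#' @param path TIFF file path.
#' @return 3-d array height x width x pages.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || .read_u(raw, 3, 2) != 42)
    stop("TIFF read error: not a little-endian TIFF", call. = FALSE)
  ifd <- .read_u(raw, 5, 4)
  pages <- list()
  while (ifd != 0) {
    n_tags <- .read_u(raw, ifd + 1, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd + 2L + (i - 1L) * 12L
      tag <- .read_u(raw, base + 1, 2)
      type <- .read_u(raw, base + 3, 2)
      count <- .read_u(raw, base + 5, 4)
      val <- if (type == 3L) .read_u(raw, base + 9, 2)
      else .read_u(raw, base + 9, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val)
    }
    need <- function(t, default = NULL) {
      x <- tags[[as.character(t)]]
      if (is.null(x)) {
        if (is.null(default)) stop(sprintf("TIFF read error: missing tag %d",
                                           t), call. = FALSE)
        return(default)
      }
      x$value
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 1)
    if (need(259, 1) != 1)
      stop("TIFF read error: compressed TIFF not supported", call. = FALSE)
    fmt <- need(339, 1)
    so_tag <- tags[["273"]]; bc_tag <- tags[["279"]]
    if (is.null(so_tag)) stop("TIFF read error: missing strip offsets",
                              call. = FALSE)
    offs <- if (so_tag$count == 1L) so_tag$value else
      vapply(seq_len(so_tag$count), function(i)
        .read_u(raw, so_tag$value + 1L + (i - 1L) * 4L, 4L), numeric(1))
    counts <- if (is.null(bc_tag)) h * w * bits / 8
    else if (bc_tag$count == 1L) bc_tag$value else
      vapply(seq_len(bc_tag$count), function(i)
        .read_u(raw, bc_tag$value + 1L + (i - 1L) * 4L, 4L), numeric(1))
    buf <- unlist(lapply(seq_along(offs), function(i)
      raw[offs[i] + seq_len(counts[i])]))
    v <- if (bits == 32L && fmt == 3L)
      readBin(buf, what = "numeric", size = 4, n = h * w,
              endian = "little")
    else if (bits == 8L) as.numeric(buf)
    else stop(sprintf("TIFF read error: unsupported %d-bit format %d",
                      bits, fmt), call. = FALSE)
    pages[[length(pages) + 1L]] <- t(matrix(v, nrow = w, ncol = h))
    ifd <- .read_u(raw, ifd + 2L + n_tags * 12L + 1L, 4)
  }
  if (!length(pages)) stop("TIFF read error: no pages", call. = FALSE)
  array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                               length(pages)))
}

#' Write the JSON metadata sidecar for an image file
#'
#' @param meta named list; must include a `kind` field (one of
#'   `"timelapse"`, `"zstack"`, `"kymograph"`, `"vfa"`, `"dce"`,
#'   `"projection"`, `"mask"`).
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(meta, path) {
  if (is.null(meta$kind)) stop_field("kind", "sidecar must declare a kind")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Load an image file with its sidecar into a typed object
#'
#' Dispatches on the sidecar `kind`. Missing optional metadata is filled
#' with documented defaults and warned about; metadata required by the
#' kind (for example `pixel_size_um` for morphometry inputs) raises an
#' error naming the field.
#'
#' @param path TIFF path.
#' @param sidecar sidecar JSON path; defaults to `path` with a `.json`
#'   extension.
#' @return a [timelapse_stack()], [kymograph()], [vfa_series()],
#'   [dce_series()], plain array (`zstack`/`projection`), or logical
#'   matrix (`mask`), with the sidecar attached as attribute `"sidecar"`.
#' @export
load_stack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar))
    stop(sprintf("sidecar not found: %s", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  arr <- read_tiff(path)
  obj <- switch(
    as.character(meta$kind),
    timelapse = {
      ts <- meta$timestamps_s
      if (is.null(ts)) {
        warning("sidecar missing timestamps_s; assuming 1.2 s spacing")
        ts <- (seq_len(dim(arr)[3]) - 1) * 1.2
      }
      px <- meta$pixel_size_um
      if (is.null(px)) { warning("missing pixel_size_um; assuming 1"); px <- 1 }
      timelapse_stack(arr, ts, px,
                      channel = meta$channel %||% "albumin")
    },
    kymograph = {
      if (is.null(meta$pixel_size_um))
        stop_field("pixel_size_um", "required for kymograph inputs")
      if (is.null(meta$line_period_ms))
        stop_field("line_period_ms", "required for kymograph inputs")
      kymograph(arr[, , 1], meta$pixel_size_um, meta$line_period_ms)
    },
    vfa = {
      if (is.null(meta$flip_angles_deg))
        stop_field("flip_angles_deg", "required for VFA inputs")
      if (is.null(meta$tr_ms)) stop_field("tr_ms", "required for VFA inputs")
      sig <- apply(arr, 3, mean)
      vfa_series(sig, meta$flip_angles_deg, meta$tr_ms)
    },
    dce = {
      for (f in c("times_s", "flip_angle_post_deg", "tr_ms"))
        if (is.null(meta[[f]])) stop_field(f, "required for DCE inputs")
      # page layout: odd pages tissue ROI, even pages blood ROI is not
      # used; instead mean signals carried in the sidecar when present
      if (!is.null(meta$tissue_signals) && !is.null(meta$blood_signals)) {
        dce_series(meta$tissue_signals, meta$blood_signals, meta$times_s,
                   meta$flip_angle_post_deg, meta$tr_ms)
      } else {
        sig <- apply(arr, 3, mean)
        if (is.null(meta$blood_signals))
          stop_field("blood_signals", "required for DCE inputs")
        dce_series(sig, meta$blood_signals, meta$times_s,
                   meta$flip_angle_post_deg, meta$tr_ms)
      }
    },
    zstack = ,
    projection = {
      if (is.null(meta$pixel_size_um))
        stop_field("pixel_size_um", "required for morphometry inputs")
      arr
    },
    mask = arr[, , 1] > 0,
    stop(sprintf("unknown sidecar kind '%s'", meta$kind), call. = FALSE)
  )
  attr(obj, "sidecar") <- meta
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CSV with unit-carrying headers
#'
#' Deterministic CSV output: UTF-8, period decimal separator, header row,
#' no row names, 15 significant digits.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_units_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
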