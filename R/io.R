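#' Read a microscopy image and normalize it to \[0,1\]
#'
#' Reads TIFF, PNG or JPEG, selects a channel if the file is multi-channel,
#' and min-max normalizes the intensities to \[0,1\]. Normalization uses the
#' observed minimum and maximum, not the dtype range, so a dim 16-bit frame
#' still spans the full unit interval (the downstream intensity feature is
#' scale-dependent, so every image is brought to a common scale).
#'
#' @param path Path to a TIFF (single- or multi-page), PNG or JPEG file.
#' @param channel Optional channel index (e.g. 2 for the green plane of an RGB
#'   image, or a page of a multi-page TIFF). Required when the file holds more
#'   than one channel.
#' @return An `intensity_image`: a list with `pixels` (numeric matrix, rows =
#'   image rows, values in \[0,1\]), `height`, `width`, `source_path`, and
#'   `bit_depth_original` (8, 16, or NA when the container does not say).
#' @details A constant image (zero dynamic range) is refused with an error:
#'   there is nothing to segment and the pipeline's normalization and
#'   self-tuning are undefined on it.
#' @export
read_image <- function(path, channel = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop("cannot read image, file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  bit_depth <- NA_integer_
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, info = TRUE, all = TRUE)
    bps <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bps)) bit_depth <- as.integer(bps[1])
    if (length(pages) == 1) {
      raw <- pages[[1]]
    } else {
      if (is.null(channel))
        stop(sprintf("multi-page TIFF with %d pages, specify channel: %s",
                     length(pages), path))
      if (channel < 1 || channel > length(pages))
        stop(sprintf("channel %d out of range (1..%d): %s", channel,
                     length(pages), path))
      raw <- pages[[channel]]
      channel <- NULL  # consumed by page selection
    }
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    bit_depth <- 8L  # png package rescales to [0,1]; 16-bit files keep precision
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package")
    raw <- jpeg::readJPEG(path)
    bit_depth <- 8L
  } else {
    stop("unsupported image format '", ext, "' (expected TIFF/PNG/JPEG): ", path)
  }
  px <- select_channel(raw, channel, path)
  new_intensity_image(px, source_path = path, bit_depth = bit_depth)
}

select_channel <- function(raw, channel, path) {
  if (length(dim(raw)) == 3) {
    nch <- dim(raw)[3]
    if (is.null(channel)) {
      if (nch == 1) channel <- 1
      else stop(sprintf("image has %d channels, specify channel: %s", nch, path))
    }
    if (channel < 1 || channel > nch)
      stop(sprintf("channel %d out of range (1..%d): %s", channel, nch, path))
    raw <- raw[, , channel]
  } else if (!is.null(channel) && channel != 1) {
    stop("channel requested but image is single-channel: ", path)
  }
  raw
}

# Construct + validate the core image container.
new_intensity_image <- function(pixels, source_path = "<memory>", bit_depth = NA_integer_,
                                normalize = TRUE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 32 || ncol(pixels) < 32)
    stop("image too small: need at least 32x32 pixels for windowed entropy and pyramidal flow")
  if (any(!is.finite(pixels))) stop("image contains non-finite pixel values")
  if (normalize) pixels <- normalize_minmax(pixels)
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 source_path = source_path, bit_depth_original = bit_depth),
            class = "intensity_image")
}

#' Min-max normalize a pixel matrix to \[0,1\]
#'
#' Idempotent: an image already spanning \[0,1\] is returned unchanged.
#' A constant input raises a degenerate-input error.
#' @param pixels Numeric matrix.
#' @return Numeric matrix with min 0 and max 1.
#' @export
normalize_minmax <- function(pixels) {
  lo <- min(pixels); hi <- max(pixels)
  if (hi == lo)
    stop("degenerate input: constant image (zero dynamic range), nothing to segment")
  if (lo == 0 && hi == 1) return(pixels)
  (pixels - lo) / (hi - lo)
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("intensity_image %dx%d (rows x cols), range [%.4g, %.4g]\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  cat(sprintf("  source: %s (bit depth %s)\n", x$source_path,
              ifelse(is.na(x$bit_depth_original), "?", x$bit_depth_original)))
  invisible(x)
}

#' Write segmentation outputs for one image
#'
#' Writes (a) the binary mask as an 8-bit TIFF (0/255), (b) a boundary-overlay
#' PNG (grayscale rendering of the image with mask boundaries in yellow) and
#' (c) optionally the per-image classifier model as plain text. Filenames are
#' derived deterministically from `stem`.
#'
#' @param mask Binary matrix (0 background / 1 cell), same shape as the image.
#' @param image An `intensity_image` (or numeric matrix in \[0,1\]).
#' @param out_dir Output directory (created if missing).
#' @param stem Base name for the output files; defaults to the image's source
#'   file name without extension.
#' @param model Optional classifier model (see [train_classifier()]) to write
#'   alongside as `<stem>_model.txt`.
#' @return Named character vector of the files written (`mask`, `overlay`,
#'   and `model` when given), invisibly.
#' @export
write_outputs <- function(mask, image, out_dir, stem = NULL, model = NULL) {
  px <- as_pixels(image)
  mask <- as_binary_mask(mask)
  stopifnot_same_shape(mask, px, "mask and image")
  if (is.null(stem)) {
    src <- if (inherits(image, "intensity_image")) image$source_path else "image"
    stem <- tools::file_path_sans_ext(basename(src))
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  mask_path <- file.path(out_dir, paste0(stem, "_mask.tif"))
  overlay_path <- file.path(out_dir, paste0(stem, "_overlay.png"))
  tiff::writeTIFF(mask * 1.0, mask_path, bits.per.sample = 8)
  png::writePNG(render_overlay(px, mask), overlay_path)
  files <- c(mask = mask_path, overlay = overlay_path)
  if (!is.null(model)) {
    model_path <- file.path(out_dir, paste0(stem, "_model.txt"))
    write_model(model, model_path)
    files <- c(files, model = model_path)
  }
  invisible(files)
}

# grayscale RGB array with yellow mask boundaries burned in
render_overlay <- function(px, mask) {
  arr <- array(pmin(pmax(px, 0), 1), dim = c(nrow(px), ncol(px), 3))
  b <- boundary_pixels(mask)
  if (any(b)) {
    r <- arr[, , 1]; g <- arr[, , 2]; bl <- arr[, , 3]
    r[b] <- 1; g[b] <- 1; bl[b] <- 0
    arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- bl
  }
  arr
}

# foreground pixels with at least one 4-neighbour outside the mask
boundary_pixels <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  m & !inner
}

# coerce to 0/1 integer matrix
as_binary_mask <- function(mask) {
  if (inherits(mask, "labeled_mask")) mask <- mask$labels
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  m <- as.matrix(mask)
  out <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  out
}

#' Read a binary mask written by [write_outputs()]
#' @param path Path to a mask TIFF/PNG (non-zero = cell).
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}
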