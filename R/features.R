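#' Sobel gradient magnitude
#'
#' Per-pixel gradient magnitude from the 3x3 Sobel operator, normalized so
#' that a linear intensity ramp of slope `s` per pixel measures `s` in the
#' interior (the raw Sobel response is 8 times the slope). Reflective
#' boundary handling.
#'
#' @param image An `intensity_image` or numeric matrix.
#' @return Non-negative numeric matrix, same shape.
#' @export
gradient_magnitude <- function(image) {
  px <- as_pixels(image)
  smooth <- c(1, 2, 1) / 4
  deriv <- c(-1, 0, 1) / 2
  gx <- conv1_reflect(conv1_reflect(px, smooth, 1L), deriv, 2L)
  gy <- conv1_reflect(conv1_reflect(px, deriv, 1L), smooth, 2L)
  sqrt(gx^2 + gy^2)
}

#' Extract (entropy, gradient, intensity) features at self-labelled pixels
#'
#' Builds the training table for the per-image classifier: one row per
#' labelled (cell or background) pixel, carrying the local entropy `e`,
#' gradient magnitude `g` and normalized intensity `i` at that pixel.
#' Unlabelled pixels are excluded.
#'
#' The feature fields are computed once on the full original image and read
#' out at the labelled coordinates. The class masks select *where* features
#' are taken from, never what they are computed on: computing windowed
#' texture on a zero-masked product would contaminate every window that
#' straddles a mask border.
#'
#' @param image An `intensity_image` or numeric matrix (the normalized image;
#'   supplies the intensity feature).
#' @param labels A `pixel_labels` object from [label_pixels()].
#' @param entropy_field Matrix from [local_entropy()].
#' @param gradient_field Matrix from [gradient_magnitude()].
#' @return A `feature_table` data frame with columns `row`, `col`, `e`, `g`,
#'   `i`, and `label` (factor: background/cell), ordered by pixel column-major
#'   index.
#' @export
extract_features <- function(image, labels, entropy_field, gradient_field) {
  px <- as_pixels(image)
  lab <- labels$labels
  stopifnot_same_shape(lab, px, "labels and image")
  stopifnot_same_shape(entropy_field, px, "entropy field and image")
  stopifnot_same_shape(gradient_field, px, "gradient field and image")
  idx <- which(!is.na(lab))
  if (length(idx) == 0) stop("empty label set: nothing to extract")
  nr <- nrow(px)
  out <- data.frame(
    row = ((idx - 1L) %% nr) + 1L,
    col = ((idx - 1L) %/% nr) + 1L,
    e = entropy_field[idx],
    g = gradient_field[idx],
    i = px[idx],
    label = factor(ifelse(lab[idx] == 1L, "cell", "background"),
                   levels = c("background", "cell")))
  class(out) <- c("feature_table", "data.frame")
  out
}
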