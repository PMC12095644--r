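#' Fit a self-supervised per-image segmentation model
#'
#' The main entry point. One call runs the whole per-image pipeline on a
#' single image: normalize, blur, dense optical flow against the blurred
#' copy, entropy-based self-tuning of the flow thresholds, sparse
#' self-labelling, (e, g, i) feature extraction, Gaussian naive Bayes
#' training with stratified cross-validation, whole-image classification,
#' and mask cleanup (plus optional watershed declumping). The image trains
#' its own classifier - no curated training data, no per-image parameter
#' tuning - so every image gets a uniquely associated model.
#'
#' @param image A file path, numeric matrix, or `intensity_image`.
#' @param config A [flowseg_config()]; the same configuration (including the
#'   threshold candidate grid and seed) can be applied verbatim to a whole
#'   batch while each image still self-tunes its own thresholds.
#' @param channel Optional channel index forwarded to [read_image()].
#' @param keep_fields Keep the entropy/gradient/flow-magnitude fields in the
#'   returned object (needed by `predict(..., type = "posterior")`; default
#'   `TRUE`).
#' @return An object of class `flowseg`: list with `mask` (cleaned binary
#'   mask), `mask_raw`, `model` (the `nb_model`), `tuning` (threshold
#'   self-tuning result), `labels` (the sparse self-labels), `labeled`
#'   (a `labeled_mask` when declumping is enabled, else `NULL`), `image`,
#'   `fields`, `config`, `call`. Methods: `print`, `summary`, `coef`,
#'   `fitted`, `predict`, `plot`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 5, size = c(96, 96), n_cells = 2,
#'                                     radius_range = c(14, 20)))
#' fit <- flowseg(fx$image, flowseg_config(min_object_area = 16))
#' fit
#' confusion_counts(fitted(fit), fx$mask)$f1
flowseg <- function(image, config = flowseg_config(), channel = NULL,
                    keep_fields = TRUE) {
  stopifnot(inherits(config, "flowseg_config"))
  img <- if (inherits(image, "intensity_image")) image
  else if (is.character(image)) read_image(image, channel = channel)
  else new_intensity_image(image)
  px <- normalize_minmax(img$pixels)  # idempotent if already normalized
  img$pixels <- px

  blurred <- gaussian_blur(px, config$blur_sigma)
  flow <- farneback_flow(px, blurred, config$flow)
  entropy <- local_entropy(px, config$entropy_radius, config$entropy_bins)
  gradient <- gradient_magnitude(px)

  tuning <- tune_thresholds(flow$magnitude, entropy,
                            grid_upper = config$grid_upper,
                            grid_lower = config$grid_lower,
                            objective = config$objective)
  labels <- label_pixels(flow$magnitude, tuning$t_cell, tuning$t_bg)
  feats <- extract_features(px, labels, entropy, gradient)
  model <- train_classifier(feats, folds = config$cv_folds,
                            seed = config$rng_seed,
                            max_per_class = config$max_train_per_class,
                            empirical_priors = config$empirical_priors)
  mask_raw <- predict_mask(model, entropy, gradient, px)
  mask <- clean_mask(mask_raw, config$min_object_area, config$fill_holes)
  labeled <- if (isTRUE(config$declump$enabled) && any(mask != 0))
    declump(mask, config$declump$min_distance, config$declump$footprint_radius)
  else NULL

  structure(list(
    mask = mask, mask_raw = mask_raw, model = model, tuning = tuning,
    labels = labels, labeled = labeled, image = img,
    fields = if (keep_fields) list(entropy = entropy, gradient = gradient,
                                   magnitude = flow$magnitude) else NULL,
    config = config, call = match.call()),
    class = "flowseg")
}

#' @export
print.flowseg <- function(x, ...) {
  cat("Self-supervised segmentation fit (flowseg)\n")
  cat(sprintf("  image: %dx%d  (%s)\n", x$image$height, x$image$width,
              x$image$source_path))
  cat(sprintf("  self-labels: %d cell / %d background px (t_cell=%.3g, t_bg=%.3g)\n",
              x$labels$n_cell, x$labels$n_background,
              x$tuning$t_cell, x$tuning$t_bg))
  cat(sprintf("  %d-fold CV accuracy: %.4f\n",
              length(x$model$cv$fold_accuracy), x$model$cv$mean))
  cat(sprintf("  confluency: %.1f%% of pixels classified as cell\n",
              100 * mean(x$mask)))
  if (!is.null(x$labeled))
    cat(sprintf("  declumped into %d object(s)\n", x$labeled$n_objects))
  invisible(x)
}

#' @export
summary.flowseg <- function(object, ...) {
  n_obj <- label_mask(object$mask)$n_objects
  structure(list(
    image = object$image$source_path,
    dim = c(object$image$height, object$image$width),
    thresholds = c(t_cell = unname(object$tuning$t_cell),
                   t_bg = unname(object$tuning$t_bg)),
    objective = object$tuning$report$objective[object$tuning$report$selected],
    n_cell_labels = object$labels$n_cell,
    n_bg_labels = object$labels$n_background,
    cv = object$model$cv,
    priors = object$model$priors,
    mu = object$model$mu, var = object$model$var,
    confluency = mean(object$mask),
    n_objects = n_obj,
    n_declumped = if (!is.null(object$labeled)) object$labeled$n_objects else NA_integer_),
    class = "summary.flowseg")
}

#' @export
print.summary.flowseg <- function(x, ...) {
  cat("Self-supervised segmentation summary\n")
  cat(sprintf("  image: %s (%dx%d)\n", x$image, x$dim[1], x$dim[2]))
  cat(sprintf("  selected thresholds: t_cell=%.4g, t_bg=%.4g (entropy margin %.3f bits)\n",
              x$thresholds[1], x$thresholds[2], x$objective))
  cat(sprintf("  training labels: %d cell, %d background\n",
              x$n_cell_labels, x$n_bg_labels))
  cat(sprintf("  CV accuracy: %.4f (sd %.4f) over %d folds\n",
              x$cv$mean, x$cv$sd, length(x$cv$fold_accuracy)))
  cat("  class feature means (e, g, i):\n")
  for (k in rownames(x$mu))
    cat(sprintf("    %-10s %s\n", k,
                paste(sprintf("%s=%.4f", colnames(x$mu), x$mu[k, ]), collapse = "  ")))
  cat(sprintf("  confluency: %.2f%%, %d object(s)\n", 100 * x$confluency, x$n_objects))
  invisible(x)
}

#' @export
coef.flowseg <- function(object, ...) {
  m <- object$model
  out <- rbind(prior = m$priors,
               t(m$mu), t(m$var))
  rownames(out) <- c("prior", paste0("mu.", colnames(m$mu)),
                     paste0("var.", colnames(m$mu)))
  out
}

#' @export
fitted.flowseg <- function(object, ...) object$mask

#' Predict with a fitted per-image model
#'
#' By default returns the fitted cleaned mask. With `newimage`, applies this
#' image's classifier to another image (features are recomputed there) -
#' note the method's premise is one model per image, so cross-image
#' prediction is a diagnostic, not the recommended use.
#'
#' @param object A `flowseg` fit.
#' @param newimage Optional image (path/matrix/`intensity_image`).
#' @param type `"mask"` (cleaned), `"raw"` (pre-cleanup), or `"posterior"`
#'   (matrix of cell-class posterior probabilities).
#' @param ... Unused.
#' @return A matrix of the requested type.
#' @export
predict.flowseg <- function(object, newimage = NULL,
                            type = c("mask", "raw", "posterior"), ...) {
  type <- match.arg(type)
  if (is.null(newimage)) {
    if (type == "mask") return(object$mask)
    if (type == "raw") return(object$mask_raw)
    if (is.null(object$fields))
      stop("fit was built with keep_fields = FALSE; refit or supply newimage")
    px <- object$image$pixels
    e <- object$fields$entropy; g <- object$fields$gradient
  } else {
    img <- if (inherits(newimage, "intensity_image")) newimage
    else if (is.character(newimage)) read_image(newimage)
    else new_intensity_image(newimage)
    px <- normalize_minmax(img$pixels)
    e <- local_entropy(px, object$config$entropy_radius, object$config$entropy_bins)
    g <- gradient_magnitude(px)
  }
  if (type == "posterior") {
    post <- nb_posterior(object$model,
                         cbind(e = as.vector(e), g = as.vector(g), i = as.vector(px)))
    return(matrix(post[, "cell"], nrow(px), ncol(px)))
  }
  raw <- predict_mask(object$model, e, g, px)
  if (type == "raw") raw
  else clean_mask(raw, object$config$min_object_area, object$config$fill_holes)
}

#' Plot a segmentation fit as a boundary overlay
#'
#' Renders the (normalized) image in grayscale with the mask boundaries in
#' yellow; declumped object boundaries are drawn per object when available.
#'
#' @param x A `flowseg` fit.
#' @param which `"mask"` or `"declumped"`.
#' @param ... Passed to [graphics::title()].
#' @return `x`, invisibly.
#' @export
plot.flowseg <- function(x, which = c("mask", "declumped"), ...) {
  which <- match.arg(which)
  m <- if (which == "declumped" && !is.null(x$labeled)) x$labeled else x$mask
  arr <- render_overlay(x$image$pixels, as_binary_mask(m))
  op <- par(mar = c(1, 1, 2, 1))
  on.exit(par(op))
  plot.new()
  plot.window(xlim = c(0, ncol(x$image$pixels)), ylim = c(0, nrow(x$image$pixels)),
              asp = 1)
  rasterImage(arr, 0, 0, ncol(x$image$pixels), nrow(x$image$pixels))
  title(main = sprintf("%s (confluency %.1f%%)", basename(x$image$source_path),
                       100 * mean(x$mask)), ...)
  invisible(x)
}
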