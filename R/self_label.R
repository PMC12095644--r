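#' Local Shannon entropy of image texture
#'
#' Per-pixel Shannon entropy (bits) of the binned intensity histogram inside a
#' disk window, with reflective boundary handling. Entropy is the texture
#' measure of the pipeline: cell interiors are textured by organelles and the
#' cytoskeleton and score high, smooth background scores low.
#'
#' @param image An `intensity_image` or numeric matrix with values in \[0,1\].
#' @param window_radius Disk radius in pixels (>= 1).
#' @param bins Histogram bins on \[0,1\] (default 64).
#' @return Numeric matrix of entropies (>= 0), same shape as the image.
#' @export
#' @examples
#' e <- local_entropy(matrix(runif(64 * 64), 64), window_radius = 4)
#' range(e)
local_entropy <- function(image, window_radius = 4, bins = 64) {
  if (window_radius < 1) stop("window_radius must be >= 1")
  px <- as_pixels(image)
  local_entropy_cpp(px, as.integer(window_radius), as.integer(bins))
}

#' Self-tune the flow-magnitude thresholds by entropy contrast
#'
#' The unsupervised stage: candidate threshold pairs are drawn from a grid of
#' magnitude percentiles (upper percentile -> provisional cell label, lower
#' percentile -> provisional background label). Each candidate is scored by
#' the difference in class-wise local entropy (cell minus background); the
#' pair maximising that difference is selected. Using percentiles makes the
#' tuning scale-free: the absolute flow magnitudes vary over orders of
#' magnitude with the blur sigma and the imaging modality, but the *ranking*
#' of pixels by magnitude is what carries the signal.
#'
#' Ties on the objective resolve to the smallest upper percentile, then the
#' largest lower percentile (the most inclusive labelling), deterministically.
#'
#' @param magnitude Flow-magnitude matrix (from [farneback_flow()]).
#' @param entropy Local-entropy matrix (from [local_entropy()]), same shape.
#' @param grid_upper,grid_lower Percentile candidates (see [flowseg_config()]).
#' @param objective `"mean"` or `"median"` class-entropy statistic.
#' @return List with `t_cell`, `t_bg` (selected thresholds in flow-magnitude
#'   units), and `report`: a `tuning_report` data frame with one row per
#'   candidate pair (`p_cell`, `p_bg`, `t_cell`, `t_bg`, `n_cell`, `n_bg`,
#'   `objective`, `selected`).
#' @export
tune_thresholds <- function(magnitude, entropy,
                            grid_upper = c(80, 85, 90, 95),
                            grid_lower = c(20, 30, 40, 50),
                            objective = c("mean", "median")) {
  objective <- match.arg(objective)
  stopifnot_same_shape(magnitude, entropy, "magnitude and entropy")
  if (length(grid_upper) == 0 || length(grid_lower) == 0)
    stop("threshold percentile grid must be non-empty")
  if (max(magnitude) == min(magnitude))
    stop("self-tuning failure: flow magnitude is constant (degenerate image)")
  stat <- if (objective == "mean") mean else stats::median
  mag <- as.vector(magnitude)
  ent <- as.vector(entropy)
  qu <- stats::quantile(mag, grid_upper / 100, names = FALSE)
  ql <- stats::quantile(mag, grid_lower / 100, names = FALSE)
  rows <- expand.grid(iu = seq_along(grid_upper), il = seq_along(grid_lower))
  n <- nrow(rows)
  obj <- rep(NA_real_, n)
  n_cell <- n_bg <- integer(n)
  for (k in seq_len(n)) {
    tc <- qu[rows$iu[k]]; tb <- ql[rows$il[k]]
    cell <- mag >= tc; bg <- mag <= tb
    n_cell[k] <- sum(cell); n_bg[k] <- sum(bg)
    if (n_cell[k] > 0 && n_bg[k] > 0)
      obj[k] <- stat(ent[cell]) - stat(ent[bg])
  }
  if (all(is.na(obj)))
    stop("self-tuning failure: every candidate threshold pair left a class empty")
  best <- max(obj, na.rm = TRUE)
  cand <- which(!is.na(obj) & obj == best)
  # tie-break: smallest upper percentile, then largest lower percentile
  ord <- order(grid_upper[rows$iu[cand]], -grid_lower[rows$il[cand]])
  sel <- cand[ord[1]]
  report <- data.frame(
    p_cell = grid_upper[rows$iu], p_bg = grid_lower[rows$il],
    t_cell = qu[rows$iu], t_bg = ql[rows$il],
    n_cell = n_cell, n_bg = n_bg, objective = obj,
    selected = seq_len(n) == sel)
  class(report) <- c("tuning_report", "data.frame")
  list(t_cell = qu[rows$iu[sel]], t_bg = ql[rows$il[sel]], report = report)
}

#' Assign sparse self-labels from flow magnitude
#'
#' Pixels with magnitude `>= t_cell` are labelled cell, pixels with magnitude
#' `<= t_bg` background; pixels in between stay unlabelled. The unlabelled
#' band is deliberate: the self-labels are meant to be high-precision seeds,
#' and the ambiguous middle of the magnitude distribution is left for the
#' supervised classifier to decide. Setting `t_cell == t_bg` recovers a
#' single-threshold labelling with no unlabelled band.
#'
#' @param magnitude Flow-magnitude matrix.
#' @param t_cell,t_bg Thresholds in magnitude units, `t_cell >= t_bg`.
#' @return A `pixel_labels` object: list with `labels` (integer matrix, 1 =
#'   cell, 0 = background, NA = unlabelled), `n_cell`, `n_background`, and
#'   `thresholds = c(t_cell, t_bg)`.
#' @export
label_pixels <- function(magnitude, t_cell, t_bg) {
  if (t_cell < t_bg) stop("t_cell must be >= t_bg")
  magnitude <- as.matrix(magnitude)
  labels <- matrix(NA_integer_, nrow(magnitude), ncol(magnitude))
  labels[magnitude >= t_cell] <- 1L
  labels[magnitude <= t_bg] <- 0L
  n_cell <- sum(labels == 1L, na.rm = TRUE)
  n_bg <- sum(labels == 0L, na.rm = TRUE)
  if (n_cell < 1 || n_bg < 1)
    stop(sprintf("labelling failure: empty class (n_cell=%d, n_background=%d)",
                 n_cell, n_bg))
  structure(list(labels = labels, n_cell = n_cell, n_background = n_bg,
                 thresholds = c(t_cell = t_cell, t_bg = t_bg)),
            class = "pixel_labels")
}

#' @export
print.pixel_labels <- function(x, ...) {
  total <- length(x$labels)
  cat(sprintf("pixel_labels: %d cell, %d background, %d unlabelled (of %d)\n",
              x$n_cell, x$n_background,
              total - x$n_cell - x$n_background, total))
  cat(sprintf("  thresholds: t_cell=%.4g, t_bg=%.4g\n",
              x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' Write a threshold-tuning report as plain text
#'
#' One line per candidate pair plus the selection, supporting traceability of
#' the unsupervised stage.
#' @param tuning Result of [tune_thresholds()] (or its `report` component).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tuning_report <- function(tuning, path) {
  report <- if (is.data.frame(tuning)) tuning else tuning$report
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# flow-threshold self-tuning report (objective = entropy(cell) - entropy(bg))", con)
  writeLines(sprintf("%6s %6s %14s %14s %9s %9s %14s %s",
                     "p_cell", "p_bg", "t_cell", "t_bg", "n_cell", "n_bg",
                     "objective", "selected"), con)
  for (k in seq_len(nrow(report)))
    writeLines(sprintf("%6g %6g %14.6e %14.6e %9d %9d %14.8f %s",
                       report$p_cell[k], report$p_bg[k], report$t_cell[k],
                       report$t_bg[k], report$n_cell[k], report$n_bg[k],
                       ifelse(is.na(report$objective[k]), NaN, report$objective[k]),
                       ifelse(report$selected[k], "*", "")), con)
  invisible(path)
}
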