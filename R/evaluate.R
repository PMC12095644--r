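#' Pixel-level confusion counts between predicted and reference masks
#'
#' Cell (non-zero) is the positive class. Returns counts plus precision,
#' recall and the F1 score `TP / (TP + (FN + FP)/2)`.
#'
#' When both masks are empty there are no positives anywhere and the F1
#' formula is 0/0; this is reported as perfect agreement (`f1 = 1`) with
#' `degenerate = TRUE`.
#'
#' @param pred,truth Binary matrices of equal shape.
#' @return A `seg_eval` object: list with `TP`, `FP`, `FN`, `TN`,
#'   `precision`, `recall`, `f1`, `degenerate`.
#' @export
#' @examples
#' truth <- matrix(c(1, 0, 1, 0), 2)
#' confusion_counts(truth, truth)$f1  # 1
confusion_counts <- function(pred, truth) {
  p <- as_binary_mask(pred)
  t <- as_binary_mask(truth)
  stopifnot_same_shape(p, t, "predicted and reference masks")
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  tn <- sum(p == 0L & t == 0L)
  degenerate <- (tp + fp + fn) == 0
  f1 <- if (degenerate) 1 else tp / (tp + 0.5 * (fn + fp))
  structure(list(
    TP = tp, FP = fp, FN = fn, TN = tn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = f1, degenerate = degenerate), class = "seg_eval")
}

#' F1 score from confusion counts
#'
#' `F1 = TP / (TP + (FN + FP)/2)`, the harmonic mean of precision and recall.
#' @param result A `seg_eval` from [confusion_counts()], or a list/vector with
#'   `TP`, `FN`, `FP` entries.
#' @return F1 in \[0,1\] (1 for the degenerate both-empty case).
#' @export
#' @examples
#' f1_score(list(TP = 50, FN = 50, FP = 0))  # 2/3
f1_score <- function(result) {
  tp <- result[["TP"]]; fn <- result[["FN"]]; fp <- result[["FP"]]
  if (tp + fn + fp == 0) return(1)
  tp / (tp + 0.5 * (fn + fp))
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("pixel evaluation: TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  precision=%.4f recall=%.4f F1=%.4f%s\n",
              x$precision, x$recall, x$f1,
              if (isTRUE(x$degenerate)) " (degenerate: both masks empty)" else ""))
  invisible(x)
}

#' Batch mask evaluation with a summary row
#'
#' Pools confusion counts per image (the default evaluation mode) and
#' reports one row per image plus mean and standard deviation of the
#' per-image F1 scores, the standard "average F1 (+/- s.d.)" summary.
#'
#' @param pred List of predicted masks (matrices) or a directory of mask
#'   files.
#' @param truth List of reference masks or a directory; matched to `pred` by
#'   position (or by sorted file name when directories are given).
#' @param names Optional image names for the report rows.
#' @param out_csv Optional path: write the report as CSV.
#' @return Data frame with columns `name`, `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `f1`; the last two rows are `mean` and `sd` summaries (counts
#'   NA). Attribute `per_image` holds the raw rows.
#' @export
evaluate_masks <- function(pred, truth, names = NULL, out_csv = NULL) {
  load_dir <- function(x) {
    if (is.character(x) && length(x) == 1 && dir.exists(x)) {
      # prefer the pipeline's mask naming; fall back to any image file
      files <- sort(list.files(x, pattern = "_mask\\.(tif|tiff|png)$",
                               full.names = TRUE))
      if (length(files) == 0)
        files <- sort(list.files(x, pattern = "\\.(tif|tiff|png)$",
                                 full.names = TRUE))
      lapply(files, read_mask)
    } else if (is.list(x)) x else list(x)
  }
  pred <- load_dir(pred); truth <- load_dir(truth)
  if (length(pred) != length(truth))
    stop(sprintf("got %d predicted vs %d reference masks", length(pred), length(truth)))
  if (is.null(names)) names <- sprintf("image_%03d", seq_along(pred))
  rows <- lapply(seq_along(pred), function(k) {
    ev <- confusion_counts(pred[[k]], truth[[k]])
    data.frame(name = names[k], TP = ev$TP, FP = ev$FP, FN = ev$FN,
               precision = ev$precision, recall = ev$recall, f1 = ev$f1)
  })
  per_image <- do.call(rbind, rows)
  summary <- data.frame(
    name = c("mean", "sd"), TP = NA_integer_, FP = NA_integer_, FN = NA_integer_,
    precision = c(mean(per_image$precision), stats::sd(per_image$precision)),
    recall = c(mean(per_image$recall), stats::sd(per_image$recall)),
    f1 = c(mean(per_image$f1), stats::sd(per_image$f1)))
  out <- rbind(per_image, summary)
  attr(out, "per_image") <- per_image
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Per-object F1 scores
#'
#' The alternative evaluation mode: for each reference object, precision and
#' recall are computed inside the object's bounding box expanded by `margin`
#' pixels, approximating a per-cell comparison of a hand-drawn mask against
#' the automated one.
#'
#' @param pred Binary predicted mask.
#' @param truth_labeled A `labeled_mask` of the reference objects (or a
#'   binary mask, which is first labelled).
#' @param margin Bounding-box expansion in pixels.
#' @return Numeric vector of per-object F1 scores.
#' @export
f1_per_object <- function(pred, truth_labeled, margin = 10) {
  p <- as_binary_mask(pred)
  lab <- if (inherits(truth_labeled, "labeled_mask")) truth_labeled$labels
  else label_components_cpp(as_binary_mask(truth_labeled), 8L)
  n <- max(lab)
  if (n == 0) return(numeric(0))
  vapply(seq_len(n), function(o) {
    idx <- which(lab == o, arr.ind = TRUE)
    r <- max(1, min(idx[, 1]) - margin):min(nrow(p), max(idx[, 1]) + margin)
    cl <- max(1, min(idx[, 2]) - margin):min(ncol(p), max(idx[, 2]) + margin)
    confusion_counts(p[r, cl, drop = FALSE],
                     matrix(as.integer(lab[r, cl] == o), length(r)))$f1
  }, numeric(1))
}
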