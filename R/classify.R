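#' Train the per-image Gaussian naive Bayes pixel classifier
#'
#' Fits a two-class Gaussian naive Bayes model on the self-labelled feature
#' table: per class and per feature (e, g, i) a mean and a variance-floored
#' Gaussian, plus class priors. Stratified k-fold cross-validation accuracies
#' are recorded first (the validation report), then the deployed model is
#' refit on all labelled rows - cross-validation measures quality, it does
#' not pick the deployed parameters.
#'
#' To bound memory on large images each class is subsampled (seeded) to at
#' most `max_per_class` rows before fitting; priors are computed after this
#' balancing (hence ~0.5/0.5) unless `empirical_priors = TRUE`, in which case
#' the pre-subsample label frequencies are used.
#'
#' @param table A `feature_table` from [extract_features()].
#' @param folds Number of CV folds (default 10). Each class must have at
#'   least `folds` rows.
#' @param seed Integer seed for fold shuffling and subsampling.
#' @param max_per_class Per-class training-row cap.
#' @param empirical_priors Use pre-subsample class frequencies as priors?
#' @return An `nb_model`: list with `priors` (named, sums to 1), `mu` and
#'   `var` (2 x 3 matrices, rows background/cell, columns e/g/i), `n_train`
#'   (rows used per class), `n_labelled` (pre-subsample counts) and `cv`
#'   (list: `fold_accuracy` of length `folds`, `mean`, `sd`).
#' @export
train_classifier <- function(table, folds = 10, seed = 0,
                             max_per_class = 50000, empirical_priors = FALSE) {
  stopifnot(is.data.frame(table), all(c("e", "g", "i", "label") %in% names(table)))
  y <- table$label
  counts <- table(y)
  if (any(counts < folds))
    stop(sprintf(
      "training failure: class '%s' has %d rows, need >= %d (degenerate self-labelling)",
      names(counts)[which.min(counts)], min(counts), folds))
  X <- as.matrix(table[, c("e", "g", "i")])

  with_local_seed(seed, {
    keep <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      if (length(idx) > max_per_class) sort(sample(idx, max_per_class)) else idx
    }), use.names = FALSE)
    Xs <- X[keep, , drop = FALSE]
    ys <- droplevels(y[keep])

    # stratified folds, shuffled
    fold_id <- integer(length(ys))
    for (cl in levels(ys)) {
      idx <- sample(which(ys == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- nb_fit(Xs[tr, , drop = FALSE], ys[tr], empirical = TRUE)
      pred <- nb_classify(m, Xs[!tr, , drop = FALSE])
      mean(pred == ys[!tr])
    }, numeric(1))

    pri <- if (empirical_priors) as.vector(counts) / sum(counts) else NULL
    model <- nb_fit(Xs, ys, empirical = is.null(pri), priors = pri)
    model$cv <- list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc))
    model$n_labelled <- stats::setNames(as.vector(counts), names(counts))
    model
  })
}

# core Gaussian NB fit; variance floor guards quantized inputs with
# zero within-class spread
nb_fit <- function(X, y, empirical = TRUE, priors = NULL, var_floor = 1e-9) {
  classes <- levels(y)
  mu <- var <- matrix(NA_real_, length(classes), ncol(X),
                      dimnames = list(classes, colnames(X)))
  n <- integer(length(classes))
  for (k in seq_along(classes)) {
    Xi <- X[y == classes[k], , drop = FALSE]
    n[k] <- nrow(Xi)
    mu[k, ] <- colMeans(Xi)
    v <- apply(Xi, 2, stats::var)
    v[!is.finite(v)] <- 0
    var[k, ] <- pmax(v, var_floor)
  }
  pri <- if (!is.null(priors)) priors else if (empirical) n / sum(n) else rep(1 / length(classes), length(classes))
  pri <- pri / sum(pri)
  structure(list(priors = stats::setNames(pri, classes), mu = mu, var = var,
                 n_train = stats::setNames(n, classes)),
            class = "nb_model")
}

# log-space joint log-likelihood matrix (rows = observations, cols = classes)
nb_log_joint <- function(model, X) {
  X <- as.matrix(X)
  out <- matrix(0, nrow(X), nrow(model$mu))
  for (k in seq_len(nrow(model$mu))) {
    lj <- log(model$priors[k])
    for (j in seq_len(ncol(X)))
      lj <- lj - 0.5 * (log(2 * pi * model$var[k, j]) +
                          (X[, j] - model$mu[k, j])^2 / model$var[k, j])
    out[, k] <- lj
  }
  colnames(out) <- rownames(model$mu)
  out
}

#' Posterior class probabilities of a naive Bayes model
#'
#' Computed in log space (log-prior plus summed per-feature log-Gaussian
#' densities, normalized by log-sum-exp), so extreme feature values cannot
#' underflow. Rows sum to 1.
#'
#' @param model An `nb_model` from [train_classifier()].
#' @param X Matrix or data frame with columns `e`, `g`, `i`.
#' @return Numeric matrix, one row per observation, one column per class.
#' @export
nb_posterior <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X[, colnames(model$mu)])
  lj <- nb_log_joint(model, X)
  mx <- apply(lj, 1, max)
  p <- exp(lj - mx)
  p / rowSums(p)
}

nb_classify <- function(model, X) {
  lj <- nb_log_joint(model, X)
  # ties resolve to the first class (background)
  factor(colnames(lj)[max.col(lj, ties.method = "first")], levels = colnames(lj))
}

#' Classify every pixel of an image into the final binary mask
#'
#' Applies a trained per-image model to all pixels: each pixel is assigned
#' the class with the larger posterior, ties going to background. This is the
#' raw mask, before any cleanup.
#'
#' @param model An `nb_model`.
#' @param entropy_field,gradient_field Feature fields on the image grid.
#' @param image The normalized `intensity_image` (or matrix) supplying the
#'   intensity feature.
#' @return Integer 0/1 matrix (1 = cell), same shape as the image.
#' @export
predict_mask <- function(model, entropy_field, gradient_field, image) {
  px <- as_pixels(image)
  stopifnot_same_shape(entropy_field, px, "entropy field and image")
  stopifnot_same_shape(gradient_field, px, "gradient field and image")
  X <- cbind(e = as.vector(entropy_field), g = as.vector(gradient_field),
             i = as.vector(px))
  lj <- nb_log_joint(model, X)
  cell <- lj[, "cell"] > lj[, "background"]  # tie -> background
  matrix(as.integer(cell), nrow(px), ncol(px))
}

#' @export
print.nb_model <- function(x, ...) {
  cat("Gaussian naive Bayes pixel classifier (per-image)\n")
  cat(sprintf("  priors: %s\n",
              paste(sprintf("%s=%.3f", names(x$priors), x$priors), collapse = ", ")))
  cat(sprintf("  trained on %s rows\n",
              paste(sprintf("%s=%d", names(x$n_train), x$n_train), collapse = ", ")))
  if (!is.null(x$cv))
    cat(sprintf("  %d-fold CV accuracy: %.4f (sd %.4f)\n",
                length(x$cv$fold_accuracy), x$cv$mean, x$cv$sd))
  invisible(x)
}

#' Serialize / restore a per-image classifier model as plain text
#'
#' The per-image model is an inspectable artifact: priors, per-class feature
#' means and variances, training-row counts and the cross-validation report
#' are written as flat key=value lines at full precision, and
#' `read_model()` reconstructs a numerically identical model.
#'
#' @param model An `nb_model`.
#' @param path File path.
#' @return `write_model`: `path` invisibly. `read_model`: an `nb_model`.
#' @export
write_model <- function(model, path) {
  cl <- rownames(model$mu)
  ft <- colnames(model$mu)
  lines <- c(
    "# flowseg per-image Gaussian naive Bayes model",
    paste0("classes=", paste(cl, collapse = ",")),
    paste0("features=", paste(ft, collapse = ",")),
    paste0("priors=", paste(fmt_num(model$priors), collapse = ",")),
    paste0("n_train=", paste(model$n_train, collapse = ",")))
  for (k in seq_along(cl)) {
    lines <- c(lines,
               paste0("mu.", cl[k], "=", paste(fmt_num(model$mu[k, ]), collapse = ",")),
               paste0("var.", cl[k], "=", paste(fmt_num(model$var[k, ]), collapse = ",")))
  }
  if (!is.null(model$cv))
    lines <- c(lines,
               paste0("cv_accuracy=", paste(fmt_num(model$cv$fold_accuracy), collapse = ",")),
               paste0("cv_mean=", fmt_num(model$cv$mean)),
               paste0("cv_sd=", fmt_num(model$cv$sd)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                          vapply(kv, `[`, "", 1))
  cl <- strsplit(vals[["classes"]], ",")[[1]]
  ft <- strsplit(vals[["features"]], ",")[[1]]
  num <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1]])
  mu <- var <- matrix(NA_real_, length(cl), length(ft), dimnames = list(cl, ft))
  for (k in seq_along(cl)) {
    mu[k, ] <- num(paste0("mu.", cl[k]))
    var[k, ] <- num(paste0("var.", cl[k]))
  }
  model <- structure(list(
    priors = stats::setNames(num("priors"), cl), mu = mu, var = var,
    n_train = stats::setNames(as.integer(num("n_train")), cl)),
    class = "nb_model")
  if ("cv_accuracy" %in% names(vals))
    model$cv <- list(fold_accuracy = num("cv_accuracy"),
                     mean = as.numeric(vals[["cv_mean"]]),
                     sd = as.numeric(vals[["cv_sd"]]))
  model
}
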