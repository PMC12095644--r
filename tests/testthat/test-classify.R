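make_table <- function(e, g, i, label) {
  out <- data.frame(row = seq_along(e), col = 1L, e = e, g = g, i = i,
                    label = factor(label, levels = c("background", "cell")))
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("perfectly separated classes give fold accuracy 1 in every fold", {
  set.seed(3)
  n <- 60
  tab <- make_table(e = c(rnorm(n, 0, 0.1), rnorm(n, 5, 0.1)),
                    g = rep(0.5, 2 * n), i = rep(0.5, 2 * n),
                    label = rep(c("background", "cell"), each = n))
  model <- train_classifier(tab, folds = 10, seed = 1)
  expect_equal(model$cv$fold_accuracy, rep(1, 10))
  expect_equal(sum(model$priors), 1)
  expect_true(all(model$var > 0))
})

test_that("posteriors match e1071's Gaussian naive Bayes on random data", {
  set.seed(9)
  n <- 80
  tab <- make_table(e = c(rnorm(n, 1), rnorm(n, 2)),
                    g = c(rnorm(n, 0.5, 0.2), rnorm(n, 0.8, 0.3)),
                    i = runif(2 * n),
                    label = rep(c("background", "cell"), each = n))
  model <- train_classifier(tab, folds = 5, seed = 1)
  Xnew <- cbind(e = rnorm(20, 1.5), g = rnorm(20, 0.6, 0.2), i = runif(20))
  mine <- nb_posterior(model, Xnew)
  ref <- e1071::naiveBayes(label ~ e + g + i, data = tab)
  # align the reference's variance convention (e1071 stores sd of each class)
  theirs <- predict(ref, as.data.frame(Xnew), type = "raw")
  expect_equal(mine[, "cell"], unname(theirs[, "cell"]), tolerance = 1e-6)
})

test_that("posterior rows are normalized even at extreme feature values", {
  set.seed(5)
  tab <- make_table(e = c(rnorm(30, 1, 0.01), rnorm(30, 2, 0.01)),
                    g = runif(60), i = runif(60),
                    label = rep(c("background", "cell"), each = 30))
  model <- train_classifier(tab, folds = 5, seed = 1)
  X <- cbind(e = c(1, 2, 500, -500), g = c(0.5, 0.5, 1e6, 0), i = c(0, 1, 1, 0))
  post <- nb_posterior(model, X)
  expect_equal(rowSums(post), rep(1, 4), tolerance = 1e-12)
  expect_true(all(is.finite(post)))
})

test_that("indistinguishable classes cross-validate near chance", {
  set.seed(11)
  n <- 400
  tab <- make_table(e = rnorm(2 * n), g = rnorm(2 * n), i = runif(2 * n),
                    label = rep(c("background", "cell"), each = n))
  model <- train_classifier(tab, folds = 10, seed = 2)
  expect_gt(model$cv$mean, 0.4)
  expect_lt(model$cv$mean, 0.6)
})

test_that("a degenerate all-cell prior predicts an all-cell mask; ties go to background", {
  m1 <- structure(list(
    priors = c(background = 0, cell = 1),
    mu = matrix(0.5, 2, 3, dimnames = list(c("background", "cell"), c("e", "g", "i"))),
    var = matrix(1, 2, 3, dimnames = list(c("background", "cell"), c("e", "g", "i"))),
    n_train = c(background = 10L, cell = 10L)), class = "nb_model")
  x <- matrix(runif(32 * 32), 32)
  expect_true(all(predict_mask(m1, x, x, x) == 1L))
  # exactly symmetric classes: every pixel ties, background wins
  m2 <- m1
  m2$priors <- c(background = 0.5, cell = 0.5)
  expect_true(all(predict_mask(m2, x, x, x) == 0L))
})

test_that("a pixel at the cell feature means is classified cell under equal priors", {
  cl <- c("background", "cell")
  m <- structure(list(
    priors = c(background = 0.5, cell = 0.5),
    mu = matrix(c(0.2, 0.8, 0.2, 0.8, 0.2, 0.8), 2, 3,
                dimnames = list(cl, c("e", "g", "i"))),
    var = matrix(0.01, 2, 3, dimnames = list(cl, c("e", "g", "i"))),
    n_train = c(background = 10L, cell = 10L)), class = "nb_model")
  post <- nb_posterior(m, cbind(e = 0.8, g = 0.8, i = 0.8))
  expect_gt(post[, "cell"], 0.99)
})

test_that("training is deterministic given the seed and refuses tiny classes", {
  set.seed(13)
  tab <- make_table(e = rnorm(60), g = rnorm(60), i = runif(60),
                    label = rep(c("background", "cell"), each = 30))
  m1 <- train_classifier(tab, folds = 10, seed = 7)
  m2 <- train_classifier(tab, folds = 10, seed = 7)
  expect_identical(m1, m2)
  tiny <- make_table(e = rnorm(12), g = rnorm(12), i = runif(12),
                     label = c(rep("background", 9), rep("cell", 3)))
  expect_error(train_classifier(tiny, folds = 10, seed = 1), "training failure")
})

test_that("zero within-class variance is floored, not propagated", {
  tab <- make_table(e = rep(c(0.25, 0.75), each = 20), g = rep(0.5, 40),
                    i = rep(0.5, 40), label = rep(c("background", "cell"), each = 20))
  model <- train_classifier(tab, folds = 5, seed = 1)
  expect_true(all(model$var >= 1e-9))
  post <- nb_posterior(model, cbind(e = 0.25, g = 0.5, i = 0.5))
  expect_true(all(is.finite(post)))
  expect_gt(post[, "background"], 0.99)
})

test_that("subsampling caps the per-class training rows", {
  set.seed(17)
  n <- 500
  tab <- make_table(e = c(rnorm(n, 0), rnorm(n, 3)), g = rnorm(2 * n),
                    i = runif(2 * n), label = rep(c("background", "cell"), each = n))
  model <- train_classifier(tab, folds = 5, seed = 1, max_per_class = 100)
  expect_equal(unname(model$n_train), c(100L, 100L))
  expect_equal(unname(model$n_labelled), c(500L, 500L))
  expect_equal(unname(model$priors), c(0.5, 0.5))
})

test_that("model text serialization round-trips numerically", {
  set.seed(19)
  tab <- make_table(e = rnorm(60), g = rnorm(60), i = runif(60),
                    label = rep(c("background", "cell"), each = 30))
  model <- train_classifier(tab, folds = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$priors, model$priors)
  expect_equal(back$mu, model$mu)
  expect_equal(back$var, model$var)
  expect_equal(back$cv$fold_accuracy, model$cv$fold_accuracy)
})
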