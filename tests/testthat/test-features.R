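test_that("gradient of a constant image is zero", {
  expect_equal(gradient_magnitude(matrix(0.2, 40, 40)), matrix(0, 40, 40))
})

test_that("gradient responds maximally at a step edge and vanishes away from it", {
  n <- 40
  step <- matrix(0, n, n)
  step[, 21:n] <- 1
  g <- gradient_magnitude(step)
  expect_true(all(g[, c(20, 21)] > 0.4))
  expect_equal(max(g[, c(1:15, 26:n)]), 0)
})

test_that("gradient of a linear ramp measures the slope", {
  n <- 40
  s <- 0.013
  ramp <- matrix(s * (1:n), n, n, byrow = TRUE)
  g <- gradient_magnitude(ramp)
  interior <- g[5:(n - 4), 5:(n - 4)]
  expect_equal(max(abs(interior - s)), 0, tolerance = 1e-12)
})

test_that("feature extraction is an exact per-pixel lookup", {
  fx <- small_fx()
  px <- fx$image$pixels
  e <- local_entropy(px, 4)
  g <- gradient_magnitude(px)
  lab <- matrix(NA_integer_, 128, 128)
  lab[5, 7] <- 1L   # one cell pixel
  lab[100, 40] <- 0L  # one background pixel
  labels <- structure(list(labels = lab, n_cell = 1L, n_background = 1L,
                           thresholds = c(t_cell = 1, t_bg = 0)),
                      class = "pixel_labels")
  tab <- extract_features(px, labels, e, g)
  expect_equal(nrow(tab), 2)
  cellrow <- tab[tab$label == "cell", ]
  expect_identical(c(cellrow$row, cellrow$col), c(5L, 7L))
  expect_identical(cellrow$e, e[5, 7])
  expect_identical(cellrow$g, g[5, 7])
  expect_identical(cellrow$i, px[5, 7])
  expect_true(all(tab$e >= 0) && all(tab$g >= 0) &&
                all(tab$i >= 0 & tab$i <= 1))
})

test_that("feature extraction is pure and covers every labelled pixel", {
  fx <- small_fx()
  px <- fx$image$pixels
  e <- local_entropy(px, 4)
  g <- gradient_magnitude(px)
  m <- farneback_flow(px, gaussian_blur(px, 0.5))$magnitude
  tt <- tune_thresholds(m, e)
  lab <- label_pixels(m, tt$t_cell, tt$t_bg)
  t1 <- extract_features(px, lab, e, g)
  t2 <- extract_features(px, lab, e, g)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), lab$n_cell + lab$n_background)
  expect_gt(mean(t1$e[t1$label == "cell"]), mean(t1$e[t1$label == "background"]))
  # table values equal field values at the recorded coordinates
  idx <- cbind(t1$row, t1$col)
  expect_identical(t1$e, e[idx])
  expect_identical(t1$g, g[idx])
})

test_that("empty label sets are refused", {
  lab <- structure(list(labels = matrix(NA_integer_, 32, 32), n_cell = 0L,
                        n_background = 0L, thresholds = c(1, 0)),
                   class = "pixel_labels")
  x <- matrix(runif(32 * 32), 32)
  expect_error(extract_features(x, lab, x, x), "empty label set")
})
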