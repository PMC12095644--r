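test_that("local entropy of a constant image is zero", {
  expect_equal(local_entropy(matrix(0.5, 40, 40), 4), matrix(0, 40, 40))
})

test_that("two-value checkerboard entropy matches the closed form in the interior", {
  n <- 40
  cb <- 0.25 + 0.5 * outer(1:n, 1:n, function(i, j) (i + j) %% 2)
  e <- local_entropy(cb, window_radius = 4, bins = 64)
  # disk of radius 4 holds 49 pixels: 24 of one value, 25 of the other
  expected <- -(24 / 49) * log2(24 / 49) - (25 / 49) * log2(25 / 49)
  interior <- e[6:(n - 5), 6:(n - 5)]
  expect_equal(max(abs(interior - expected)), 0, tolerance = 1e-10)
})

test_that("fixture entropy is higher inside cells than outside", {
  fx <- small_fx()
  e <- local_entropy(fx$image$pixels, 4)
  expect_gt(mean(e[fx$mask == 1]), mean(e[fx$mask == 0]) + 0.5)
})

test_that("threshold tuning is argmax-consistent and reports the whole grid", {
  fx <- small_fx()
  px <- fx$image$pixels
  e <- local_entropy(px, 4)
  m <- farneback_flow(px, gaussian_blur(px, 0.5))$magnitude
  gu <- c(80, 85, 90, 95); gl <- c(20, 30, 40, 50)
  tt <- tune_thresholds(m, e, gu, gl)
  expect_equal(nrow(tt$report), length(gu) * length(gl))
  expect_equal(sum(tt$report$selected), 1)
  sel_obj <- tt$report$objective[tt$report$selected]
  expect_identical(sel_obj, max(tt$report$objective, na.rm = TRUE))
  # independent brute force over the same grid
  best <- -Inf
  for (pu in gu) for (pl in gl) {
    tc <- stats::quantile(m, pu / 100, names = FALSE)
    tb <- stats::quantile(m, pl / 100, names = FALSE)
    if (sum(m >= tc) > 0 && sum(m <= tb) > 0)
      best <- max(best, mean(e[m >= tc]) - mean(e[m <= tb]))
  }
  expect_equal(sel_obj, best, tolerance = 1e-12)
})

test_that("tuning ties resolve to smallest upper then largest lower percentile", {
  # magnitude == entropy makes several pairs score identically when the
  # distributions are flat; construct an exactly symmetric field
  m <- matrix(rep(c(0, 1), each = 800), 40, 40)
  e <- m
  tt <- tune_thresholds(m, e, grid_upper = c(80, 90), grid_lower = c(10, 20))
  sel <- tt$report[tt$report$selected, ]
  same <- tt$report$objective == max(tt$report$objective, na.rm = TRUE)
  same[is.na(same)] <- FALSE
  expect_equal(sel$p_cell, min(tt$report$p_cell[same]))
  expect_equal(sel$p_bg, max(tt$report$p_bg[same & tt$report$p_cell == sel$p_cell]))
})

test_that("constant magnitude is a self-tuning failure", {
  expect_error(tune_thresholds(matrix(1, 30, 30), matrix(runif(900), 30)),
               "self-tuning failure")
})

test_that("pixel labelling applies the two thresholds with an unlabelled band", {
  m <- matrix(c(0, 1, 2, 3), 1)
  lab <- label_pixels(m, t_cell = 2.5, t_bg = 0.5)
  expect_identical(as.vector(lab$labels), c(0L, NA, NA, 1L))
  expect_equal(lab$n_cell, 1)
  expect_equal(lab$n_background, 1)
  # zero-width band classes every pixel
  med <- stats::median(m)
  lab2 <- label_pixels(m, med, med)
  expect_false(anyNA(lab2$labels))
  expect_error(label_pixels(m, 10, 9), "empty class")
  expect_error(label_pixels(m, 1, 2), "t_cell")
})

test_that("raising t_cell never increases n_cell; lowering t_bg never increases n_background", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(stats::rexp(400), 20)
    qs <- stats::quantile(m, c(0.5, 0.7, 0.9))
    n_cell <- sapply(qs, function(t) sum(m >= t))
    expect_true(all(diff(n_cell) <= 0))
    qs2 <- stats::quantile(m, c(0.4, 0.25, 0.1))
    n_bg <- sapply(qs2, function(t) sum(m <= t))
    expect_true(all(diff(n_bg) <= 0))
  }
})

test_that("self-labels are sparse and entropy-separated on a fixture", {
  fx <- small_fx()
  px <- fx$image$pixels
  e <- local_entropy(px, 4)
  m <- farneback_flow(px, gaussian_blur(px, 0.1))$magnitude
  tt <- tune_thresholds(m, e)
  lab <- label_pixels(m, tt$t_cell, tt$t_bg)
  expect_lt(lab$n_cell + lab$n_background, length(px))
  expect_gt(mean(e[which(lab$labels == 1L)]), mean(e[which(lab$labels == 0L)]))
  # high-confidence cell seeds localize at the cells: nearly all lie inside
  # or within half a flow-integration window (7 px) of the true cell region,
  # and they hit true cells well above the area-fraction base rate
  dist_out <- EBImage::distmap(1 - fx$mask)
  seeds <- which(lab$labels == 1L)
  expect_gt(mean(dist_out[seeds] <= 7), 0.9)
  expect_gt(mean(fx$mask[seeds]), 1.2 * mean(fx$mask))
})

test_that("tuning report serializes to readable text", {
  fx <- small_fx()
  px <- fx$image$pixels
  e <- local_entropy(px, 4)
  m <- farneback_flow(px, gaussian_blur(px, 0.5))$magnitude
  tt <- tune_thresholds(m, e)
  path <- withr::local_tempfile(fileext = ".txt")
  write_tuning_report(tt, path)
  txt <- readLines(path)
  expect_length(txt, nrow(tt$report) + 2)
  expect_true(any(grepl("\\*$", txt)))
})
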