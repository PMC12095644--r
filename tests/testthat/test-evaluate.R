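test_that("confusion counts on hand-enumerable masks", {
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, byrow = TRUE)  # [[1,1],[0,0]]
  pred <- matrix(c(1L, 0L, 1L, 0L), 2, byrow = TRUE)   # [[1,0],[1,0]]
  ev <- confusion_counts(pred, truth)
  expect_equal(c(ev$TP, ev$FN, ev$FP, ev$TN), c(1, 1, 1, 1))
  expect_equal(ev$TP + ev$FP + ev$FN + ev$TN, 4)

  m <- disk_mask(30, 30, 15, 15, 4)
  same <- confusion_counts(m, m)
  expect_equal(same$TP, sum(m))
  expect_equal(same$FP + same$FN, 0)
  expect_equal(same$f1, 1)
  none <- confusion_counts(matrix(0L, 30, 30), m)
  expect_equal(none$TP, 0)
  expect_equal(none$FN, sum(m))
  expect_equal(none$f1, 0)
  expect_error(confusion_counts(matrix(0L, 3, 3), matrix(0L, 3, 4)), "shape")
})

test_that("the F1 formula evaluates TP/(TP + (FN+FP)/2)", {
  expect_equal(f1_score(list(TP = 50, FN = 50, FP = 0)), 2 / 3)
  expect_equal(f1_score(list(TP = 10, FN = 0, FP = 0)), 1)
  expect_equal(f1_score(list(TP = 0, FN = 5, FP = 7)), 0)
})

test_that("F1 equals the harmonic mean of precision and recall and is FP/FN symmetric", {
  set.seed(29)
  for (rep in 1:100) {
    tp <- sample(1:500, 1); fp <- sample(0:300, 1); fn <- sample(0:300, 1)
    f1 <- f1_score(list(TP = tp, FN = fn, FP = fp))
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    expect_equal(f1, 2 * p * r / (p + r), tolerance = 1e-12)
    expect_equal(f1, f1_score(list(TP = tp, FN = fp, FP = fn)), tolerance = 1e-15)
  }
})

test_that("both-empty masks evaluate as degenerate perfect agreement", {
  ev <- confusion_counts(matrix(0L, 10, 10), matrix(0L, 10, 10))
  expect_true(ev$degenerate)
  expect_equal(ev$f1, 1)
})

test_that("batch evaluation reports per-image rows plus mean/sd summary", {
  t1 <- disk_mask(40, 40, 20, 20, 8)
  p1 <- disk_mask(40, 40, 20, 21, 8)
  t2 <- disk_mask(40, 40, 12, 30, 6)
  out <- withr::local_tempfile(fileext = ".csv")
  res <- evaluate_masks(list(p1, t2), list(t1, t2), names = c("a", "b"),
                        out_csv = out)
  expect_equal(nrow(res), 4)
  per <- attr(res, "per_image")
  expect_equal(res$f1[res$name == "mean"], mean(per$f1))
  expect_equal(res$f1[res$name == "sd"], stats::sd(per$f1))
  expect_equal(per$f1[2], 1)
  expect_true(file.exists(out))
  back <- utils::read.csv(out)
  expect_equal(back$f1, res$f1, tolerance = 1e-12)
})

test_that("per-object F1 scores one value per reference object", {
  truth <- matrix(0L, 60, 60)
  truth[disk_mask(60, 60, 15, 15, 8) == 1L] <- 1L
  truth[disk_mask(60, 60, 45, 45, 8) == 1L] <- 1L
  pred <- truth
  pred[disk_mask(60, 60, 45, 45, 8) == 1L] <- 0L  # miss the second object
  f1s <- f1_per_object(pred, truth)
  expect_length(f1s, 2)
  expect_equal(f1s[1], 1)
  expect_equal(f1s[2], 0)
})
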