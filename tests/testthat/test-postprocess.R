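test_that("cleanup removes specks, fills holes, and no-ops when disabled", {
  m <- matrix(0L, 40, 40)
  m[5:6, 5] <- 1L  # 3-px speck
  m[5, 6] <- 1L
  expect_true(all(clean_mask(m, min_object_area = 10, fill_holes = FALSE) == 0L))
  disk <- disk_mask(40, 40, 20, 20, 10)
  holey <- disk
  holey[20, 20] <- 0L
  expect_identical(clean_mask(holey, 0, fill_holes = TRUE), disk)
  expect_identical(clean_mask(holey, 0, fill_holes = FALSE), holey)
})

test_that("cleanup is monotone in the area threshold", {
  set.seed(23)
  m <- matrix(as.integer(runif(80 * 80) > 0.6), 80)
  n_obj <- sapply(c(0, 2, 5, 10, 25), function(a)
    label_mask(clean_mask(m, a, fill_holes = FALSE))$n_objects)
  expect_true(all(diff(n_obj) <= 0))
})

test_that("an isolated disk survives declumping unchanged", {
  m <- disk_mask(64, 64, 32, 32, 15)
  d <- declump(m, 10, 7)
  expect_equal(d$n_objects, 1)
  expect_identical(matrix(as.integer(d$labels > 0), 64), m)
})

test_that("two overlapping disks split into two objects along the midline", {
  r <- 20; sep <- 30
  nr <- 100; nc <- 120
  m <- matrix(0L, nr, nc)
  m[disk_mask(nr, nc, 50, 45, r) == 1L] <- 1L
  m[disk_mask(nr, nc, 50, 75, r) == 1L] <- 1L
  d <- declump(m, 10, 7)
  expect_equal(d$n_objects, 2)
  # exact foreground conservation
  expect_identical(matrix(as.integer(d$labels > 0L), nr), m)
  # split line perpendicular to the centre line, within +/- 2 px of the midpoint
  cols1 <- which(d$labels == 1L, arr.ind = TRUE)[, 2]
  cols2 <- which(d$labels == 2L, arr.ind = TRUE)[, 2]
  mid <- (45 + 75) / 2
  expect_lte(max(cols1), mid + 2)
  expect_gte(min(cols2), mid - 2)
})

test_that("a three-lobed yeast fixture declumps into three objects", {
  ys <- acceptance_suite()$declump$yeast
  d <- declump(ys$mask, 10, 7)
  expect_equal(d$n_objects, 3)
  expect_identical(as.integer(d$labels > 0L), as.integer(ys$mask == 1L))
})

test_that("declump labelling is deterministic with canonical raster ids", {
  ys <- acceptance_suite()$declump$yeast
  d1 <- declump(ys$mask, 10, 7)
  d2 <- declump(ys$mask, 10, 7)
  expect_identical(d1$labels, d2$labels)
  ids <- d1$labels[d1$labels > 0]
  expect_identical(unique(ids[order(which(d1$labels > 0))])[1], 1L)
  expect_setequal(unique(ids), seq_len(d1$n_objects))
})

test_that("an empty mask declumps to zero objects and no contours", {
  empty <- matrix(0L, 40, 40)
  d <- declump(empty, 10, 7)
  expect_equal(d$n_objects, 0)
  expect_length(extract_boundaries(empty), 0)
})

test_that("boundary extraction returns one closed contour per object", {
  sq <- matrix(0L, 50, 50)
  sq[10:20, 15:30] <- 1L
  b <- extract_boundaries(sq)
  expect_length(b, 1)
  expect_true(all(b[[1]][, "row"] %in% 10:20))
  expect_true(all(b[[1]][, "col"] %in% 15:30))
  m2 <- sq
  m2[35:45, 5:12] <- 1L
  m2[30:40, 35:48] <- 1L
  lb <- label_mask(m2)
  expect_length(extract_boundaries(lb), lb$n_objects)
})

test_that("connected components use 8-connectivity for objects", {
  m <- matrix(0L, 10, 10)
  m[3, 3] <- 1L
  m[4, 4] <- 1L  # diagonal neighbour -> one object
  expect_equal(label_mask(m)$n_objects, 1)
})
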