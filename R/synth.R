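#' Specification of a synthetic microscopy fixture
#'
#' Describes one seeded synthetic image with known ground truth. The
#' generator emulates the statistical structure the segmentation method
#' relies on - textured (high local entropy) cell interiors on a smooth,
#' noisy background - not the optics of any particular modality.
#'
#' @param seed Integer RNG seed; the fixture is fully reproducible from it.
#' @param size `c(rows, cols)` of the image (>= 32 each).
#' @param n_cells Number of cells (>= 0).
#' @param shape Cell shape family: `"ellipse"`, `"blob"` (Fourier-perturbed
#'   ellipse), `"yeast"` (lobed, budding-yeast-like), `"nucleus"` (disk).
#' @param radius_range Min/max equivalent radius in pixels.
#' @param texture_amplitude Standard deviation of the correlated speckle
#'   texture painted inside cells (intensity units).
#' @param texture_scale Correlation length (pixels) of the cell texture.
#' @param background_level Mean background intensity.
#' @param noise_sd Additive Gaussian noise sd (whole image).
#' @param contrast Mean intensity offset of cells above background; set it
#'   below `noise_sd` for a texture-only (invisible-by-eye) fixture.
#' @param allow_touching If `FALSE`, cells are placed with a 4 px clearance;
#'   if `TRUE`, cells may overlap (for declumping fixtures).
#' @param n_lobes Lobe count for the yeast shape (default 3).
#' @return A `fixture_spec` (validated named list).
#' @export
fixture_spec <- function(seed = 1, size = c(512, 512), n_cells = 8,
                         shape = c("blob", "ellipse", "yeast", "nucleus"),
                         radius_range = c(30, 55), texture_amplitude = 0.18,
                         texture_scale = 3, background_level = 0.25,
                         noise_sd = 0.03, contrast = 0.2,
                         allow_touching = FALSE, n_lobes = 3) {
  shape <- match.arg(shape)
  stopifnot(length(size) == 2, all(size >= 32), n_cells >= 0,
            length(radius_range) == 2, all(radius_range > 0),
            radius_range[1] <= radius_range[2],
            texture_amplitude >= 0, texture_scale > 0, noise_sd >= 0)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_cells = as.integer(n_cells), shape = shape,
                 radius_range = as.numeric(radius_range),
                 texture_amplitude = texture_amplitude,
                 texture_scale = texture_scale,
                 background_level = background_level, noise_sd = noise_sd,
                 contrast = contrast, allow_touching = isTRUE(allow_touching),
                 n_lobes = as.integer(n_lobes)),
            class = "fixture_spec")
}

#' Generate a synthetic microscopy image with exact ground truth
#'
#' Paints the background as a constant plus Gaussian noise, places
#' non-overlapping (or optionally touching) random cell shapes, fills each
#' with correlated speckle texture (Gaussian-filtered white noise at the
#' spec's correlation length) on top of the intensity contrast, quantizes to
#' the 16-bit grid and clips to \[0,1\]. The binary and labelled ground-truth
#' masks derive from the very geometry that painted the image, so they are
#' exact by construction.
#'
#' @param spec A [fixture_spec()].
#' @return List with `image` (`intensity_image`), `mask` (0/1 matrix),
#'   `labels` (`labeled_mask` of the individual cells) and `spec`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 3, size = c(128, 128), n_cells = 2,
#'                                     radius_range = c(18, 26)))
#' mean(fx$mask)
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    img <- spec$background_level + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    lab <- matrix(0L, nr, nc)

    if (spec$n_cells > 0) {
      cells <- place_cells(spec)
      for (k in seq_len(spec$n_cells)) {
        inside <- rasterize_cell(cells[[k]], nr, nc, spec)
        lab[inside] <- k
      }
      mask_idx <- which(lab > 0L)
      if (length(mask_idx)) {
        tex <- matrix(rnorm(nr * nc), nr, nc)
        tex <- gaussian_blur(tex, spec$texture_scale)
        tex <- tex / stats::sd(tex)
        img[mask_idx] <- img[mask_idx] + spec$contrast +
          spec$texture_amplitude * tex[mask_idx]
      }
    }
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 65535) / 65535  # emulate a 16-bit camera
    list(image = new_intensity_image(img, source_path = sprintf("<synthetic seed=%d>", spec$seed),
                                     bit_depth = 16L, normalize = FALSE),
         mask = matrix(as.integer(lab > 0L), nr, nc),
         labels = structure(list(labels = lab, n_objects = spec$n_cells,
                                 areas = if (spec$n_cells > 0) tabulate(lab[lab > 0], spec$n_cells)
                                 else integer(0)),
                            class = "labeled_mask"),
         spec = spec)
  })
}

# rejection-sample cell centres/geometries; largest placed first so dense
# packings still succeed
place_cells <- function(spec, max_tries = 50000) {
  nr <- spec$size[1]; nc <- spec$size[2]
  r <- sort(runif(spec$n_cells, spec$radius_range[1], spec$radius_range[2]),
            decreasing = TRUE)
  margin <- if (spec$allow_touching) 0 else 4
  cells <- list()
  tries <- 0
  ext <- if (spec$shape == "yeast") 2.45 else 1  # lobed shapes reach further
  for (k in seq_len(spec$n_cells)) {
    repeat {
      tries <- tries + 1
      if (tries > max_tries)
        stop("fixture generation error: cannot pack ", spec$n_cells,
             " non-touching cells of this size into ", nr, "x", nc)
      cy <- runif(1, ext * r[k] + 2, nr - ext * r[k] - 1)
      cx <- runif(1, ext * r[k] + 2, nc - ext * r[k] - 1)
      ok <- spec$allow_touching || all(vapply(cells, function(c0) {
        sqrt((c0$cy - cy)^2 + (c0$cx - cx)^2) > ext * (c0$r + r[k]) + margin
      }, logical(1)))
      if (ok) break
    }
    cell <- list(cy = cy, cx = cx, r = r[k], theta = runif(1, 0, pi),
                 aspect = runif(1, 0.8, 1.25))
    if (spec$shape == "blob") {
      cell$harm_amp <- rnorm(4, sd = 0.06)
      cell$harm_phase <- runif(4, 0, 2 * pi)
    } else if (spec$shape == "yeast") {
      ang <- runif(1, 0, 2 * pi)
      scl <- c(1, 0.72, 0.5)[seq_len(spec$n_lobes)]
      off <- c(0, 1.0, 1.9)[seq_len(spec$n_lobes)]
      cell$lobes <- lapply(seq_len(spec$n_lobes), function(l) {
        list(cy = cy + off[l] * r[k] * sin(ang), cx = cx + off[l] * r[k] * cos(ang),
             r = scl[l] * r[k])
      })
    }
    cells[[k]] <- cell
  }
  cells
}

# indices (column-major) of pixels inside one cell
rasterize_cell <- function(cell, nr, nc, spec) {
  pad <- cell$r * 2.6 + 4
  rows <- max(1, floor(cell$cy - pad)):min(nr, ceiling(cell$cy + pad))
  cols <- max(1, floor(cell$cx - pad)):min(nc, ceiling(cell$cx + pad))
  ry <- rows - cell$cy
  cx <- cols - cell$cx
  Y <- matrix(ry, length(rows), length(cols))
  X <- matrix(cx, length(rows), length(cols), byrow = TRUE)
  inside <- switch(spec$shape,
    nucleus = (X^2 + Y^2) <= cell$r^2,
    ellipse = {
      xr <- X * cos(cell$theta) + Y * sin(cell$theta)
      yr <- -X * sin(cell$theta) + Y * cos(cell$theta)
      # area-preserving anisotropy: axes r*aspect and r/aspect
      (xr / (cell$r * cell$aspect))^2 + (yr / (cell$r / cell$aspect))^2 <= 1
    },
    blob = {
      xr <- X * cos(cell$theta) + Y * sin(cell$theta)
      yr <- -X * sin(cell$theta) + Y * cos(cell$theta)
      rho <- sqrt((xr / cell$aspect)^2 + (yr * cell$aspect)^2)
      phi <- atan2(yr * cell$aspect, xr / cell$aspect)
      rloc <- cell$r * (1 + Reduce(`+`, lapply(1:4, function(h)
        cell$harm_amp[h] * cos((h + 1) * phi + cell$harm_phase[h]))))
      rho <= rloc
    },
    yeast = {
      acc <- matrix(FALSE, length(rows), length(cols))
      for (lb in cell$lobes) {
        acc <- acc | ((X + cell$cx - lb$cx)^2 + (Y + cell$cy - lb$cy)^2) <= lb$r^2
      }
      acc
    })
  idx <- which(inside, arr.ind = TRUE)
  (cols[idx[, 2]] - 1L) * nr + rows[idx[, 1]]
}

#' Generate the standard synthetic acceptance suite
#'
#' Emits the fixed set of fixtures exercised by the package's tests:
#' \describe{
#'   \item{sparse}{20 sparse-cell 512x512 images whose cell-area fractions
#'     span roughly 6-33%, alternating blob and ellipse shapes.}
#'   \item{low_contrast}{5 images whose cell/background mean-intensity gap
#'     (0.01) is below the noise sd (0.03): the signal is texture only.}
#'   \item{declump}{A touching-disk pair and a lobed-yeast fixture for the
#'     watershed declumping checks.}
#'   \item{nuclei}{2 images of plain nuclear disks.}
#' }
#' Each fixture draws its own RNG stream from `(seed, index)` so any single
#' fixture is reproducible in isolation.
#'
#' @param seed Suite seed.
#' @param dir Optional directory: write each fixture as 16-bit image TIFF +
#'   8-bit ground-truth mask TIFF plus a `manifest.csv` (name, seed, shape,
#'   n_cells, area fraction, file hashes).
#' @param n_sparse,n_low_contrast Number of images in the two main groups
#'   (defaults 20 and 5).
#' @return Named list of fixture groups; each group is a list of
#'   [generate_fixture()] results. When `dir` is given, the manifest data
#'   frame is attached as attribute `manifest`.
#' @export
generate_suite <- function(seed = 0, dir = NULL, n_sparse = 20, n_low_contrast = 5) {
  sparse <- lapply(seq_len(n_sparse), function(i) {
    frac <- 0.06 + 0.27 * (i - 1) / max(1, n_sparse - 1)  # target area fraction
    n_cells <- if (frac < 0.12) 5L else if (frac < 0.22) 9L else 14L
    rbar <- sqrt(frac * 512^2 / (n_cells * pi))
    generate_fixture(fixture_spec(
      seed = derive_seed(seed, i), size = c(512, 512), n_cells = n_cells,
      shape = if (i %% 2 == 0) "ellipse" else "blob",
      radius_range = c(0.88, 1.12) * rbar))
  })
  low_contrast <- lapply(seq_len(n_low_contrast), function(i) {
    # zero mean contrast; mid-range background level keeps the symmetric
    # texture clear of the [0,1] clip, which would otherwise bias the cell
    # mean and reintroduce an intensity cue
    generate_fixture(fixture_spec(
      seed = derive_seed(seed, 100 + i), size = c(512, 512), n_cells = 7L,
      shape = "blob", radius_range = c(34, 52), background_level = 0.5,
      contrast = 0, noise_sd = 0.03, texture_amplitude = 0.2))
  })
  declump <- list(
    disks = two_disk_fixture(seed = derive_seed(seed, 201)),
    yeast = generate_fixture(fixture_spec(
      seed = derive_seed(seed, 202), size = c(256, 256), n_cells = 1L,
      shape = "yeast", radius_range = c(28, 32), n_lobes = 3L)))
  nuclei <- lapply(1:2, function(i) {
    generate_fixture(fixture_spec(
      seed = derive_seed(seed, 300 + i), size = c(512, 512), n_cells = 12L,
      shape = "nucleus", radius_range = c(16, 26), texture_amplitude = 0.12,
      contrast = 0.3))
  })
  suite <- list(sparse = sparse, low_contrast = low_contrast,
                declump = declump, nuclei = nuclei)
  if (!is.null(dir)) attr(suite, "manifest") <- write_suite(suite, dir)
  suite
}

# deterministic two-overlapping-disk geometry (centres 30 px apart, r = 20)
# with the usual noise/texture rendering
two_disk_fixture <- function(seed, size = c(128, 160), r = 20, sep = 30) {
  with_local_seed(seed, {
    nr <- size[1]; nc <- size[2]
    cy <- nr / 2
    cx1 <- nc / 2 - sep / 2; cx2 <- nc / 2 + sep / 2
    Y <- matrix(seq_len(nr), nr, nc)
    X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    in1 <- (X - cx1)^2 + (Y - cy)^2 <= r^2
    in2 <- (X - cx2)^2 + (Y - cy)^2 <= r^2
    lab <- matrix(0L, nr, nc)
    lab[in1] <- 1L; lab[in2 & !in1] <- 2L
    img <- 0.25 + matrix(rnorm(nr * nc, sd = 0.03), nr, nc)
    tex <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), 3)
    tex <- tex / stats::sd(tex)
    img[lab > 0] <- img[lab > 0] + 0.2 + 0.18 * tex[lab > 0]
    img <- round(pmin(pmax(img, 0), 1) * 65535) / 65535
    list(image = new_intensity_image(img, source_path = sprintf("<synthetic seed=%d>", seed),
                                     bit_depth = 16L, normalize = FALSE),
         mask = matrix(as.integer(lab > 0L), nr, nc),
         labels = structure(list(labels = lab, n_objects = 2L,
                                 areas = tabulate(lab[lab > 0], 2L)),
                            class = "labeled_mask"),
         centres = cbind(row = c(cy, cy), col = c(cx1, cx2)), r = r)
  })
}

write_suite <- function(suite, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (grp in names(suite)) {
    fxs <- suite[[grp]]
    for (i in seq_along(fxs)) {
      fx <- fxs[[i]]
      stem <- sprintf("%s_%02d", grp, i)
      img_path <- file.path(dir, paste0(stem, ".tif"))
      mask_path <- file.path(dir, paste0(stem, "_truth.tif"))
      tiff::writeTIFF(fx$image$pixels, img_path, bits.per.sample = 16)
      tiff::writeTIFF(fx$mask * 1.0, mask_path, bits.per.sample = 8)
      rows[[stem]] <- data.frame(
        name = stem, group = grp,
        seed = if (!is.null(fx$spec)) fx$spec$seed else NA_integer_,
        shape = if (!is.null(fx$spec)) fx$spec$shape else "disks",
        n_cells = fx$labels$n_objects,
        area_fraction = mean(fx$mask),
        image = basename(img_path), truth = basename(mask_path),
        md5_image = unname(tools::md5sum(img_path)),
        md5_truth = unname(tools::md5sum(mask_path)))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
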