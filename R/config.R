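#' Pipeline configuration
#'
#' Collects every tunable of the self-supervised segmentation pipeline in one
#' validated object. The defaults are the recommended fully-automated
#' settings: they are applied unchanged to every image (per-image adaptation
#' happens through self-tuning, not through per-image parameter edits).
#'
#' @param blur_sigma Standard deviation (pixels) of the Gaussian blur that
#'   plays the role of surrogate motion. The default 0.1 is deliberately tiny:
#'   the blur only has to perturb the image enough that the optical-flow field
#'   is textured where the image is textured; the flow thresholds are
#'   percentile-based and therefore insensitive to the absolute displacement
#'   scale. See [gaussian_blur()] for how sub-pixel sigmas are handled.
#' @param flow Named list of Farneback parameters: `pyr_scale` (pyramid
#'   downscale factor per level), `levels`, `winsize` (integration window for
#'   the displacement solve), `iterations` (warp/refine passes per level),
#'   `poly_n` (polynomial-expansion neighbourhood half-width), `poly_sigma`
#'   (Gaussian applicability sd of the expansion), and `regularization`
#'   (ridge fraction of the displacement solve: the normal equations are
#'   damped by this fraction of the image-mean structure energy, so
#'   structureless background yields near-zero displacement instead of
#'   amplified noise).
#' @param entropy_radius Disk radius (pixels) of the local-entropy window.
#' @param entropy_bins Number of histogram bins on \[0,1\] for local entropy.
#' @param grid_upper,grid_lower Percentile candidates (strictly increasing)
#'   for the cell (upper) and background (lower) flow-magnitude thresholds
#'   explored by [tune_thresholds()].
#' @param objective `"mean"` (default) or `"median"`: the statistic of the
#'   class-wise local entropies whose difference is maximised during
#'   self-tuning.
#' @param cv_folds Number of stratified cross-validation folds recorded when
#'   training the per-image classifier (default 10).
#' @param rng_seed Integer seed controlling fold shuffling and training-set
#'   subsampling; fixing it makes the whole pipeline bit-reproducible.
#' @param max_train_per_class Cap on labelled pixels per class used to fit the
#'   classifier (class-balanced subsample; bounds memory on megapixel images).
#' @param empirical_priors If `TRUE`, class priors are the pre-subsample label
#'   frequencies; by default priors are computed after balancing (~0.5/0.5).
#' @param min_object_area Connected components smaller than this many pixels
#'   are removed by [clean_mask()].
#' @param fill_holes Fill interior holes during cleanup?
#' @param declump Named list: `enabled` (default `FALSE`; declumping targets
#'   non-adherent cells and nuclei), `min_distance` and `footprint_radius`
#'   (pixels) for the watershed seed detection.
#'
#' @return An object of class `flowseg_config` (a validated named list).
#' @seealso [write_config()], [read_config()]
#' @export
#' @examples
#' cfg <- flowseg_config(blur_sigma = 1, rng_seed = 7)
#' cfg$flow$winsize
flowseg_config <- function(blur_sigma = 0.1,
                           flow = list(pyr_scale = 0.5, levels = 3, winsize = 15,
                                       iterations = 3, poly_n = 5, poly_sigma = 1.1,
                                       regularization = 0.1),
                           entropy_radius = 4,
                           entropy_bins = 64,
                           grid_upper = c(80, 85, 90, 95),
                           grid_lower = c(20, 30, 40, 50),
                           objective = c("mean", "median"),
                           cv_folds = 10,
                           rng_seed = 0,
                           max_train_per_class = 50000,
                           empirical_priors = FALSE,
                           min_object_area = 64,
                           fill_holes = TRUE,
                           declump = list(enabled = FALSE, min_distance = 10,
                                          footprint_radius = 7)) {
  objective <- match.arg(objective)
  flow_def <- list(pyr_scale = 0.5, levels = 3, winsize = 15,
                   iterations = 3, poly_n = 5, poly_sigma = 1.1,
                   regularization = 0.1)
  flow <- utils::modifyList(flow_def, as.list(flow))
  declump_def <- list(enabled = FALSE, min_distance = 10, footprint_radius = 7)
  declump <- utils::modifyList(declump_def, as.list(declump))

  cfg <- structure(list(
    blur_sigma = as.numeric(blur_sigma), flow = flow,
    entropy_radius = as.integer(entropy_radius),
    entropy_bins = as.integer(entropy_bins),
    grid_upper = as.numeric(grid_upper), grid_lower = as.numeric(grid_lower),
    objective = objective, cv_folds = as.integer(cv_folds),
    rng_seed = as.integer(rng_seed),
    max_train_per_class = as.integer(max_train_per_class),
    empirical_priors = isTRUE(empirical_priors),
    min_object_area = as.integer(min_object_area),
    fill_holes = isTRUE(fill_holes), declump = declump),
    class = "flowseg_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!(cfg$blur_sigma > 0)) stop("blur_sigma must be > 0")
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  if (length(cfg$grid_upper) == 0 || length(cfg$grid_lower) == 0)
    stop("threshold percentile grids must be non-empty")
  if (is.unsorted(cfg$grid_upper, strictly = TRUE) ||
      is.unsorted(cfg$grid_lower, strictly = TRUE))
    stop("threshold percentile grids must be strictly increasing")
  if (any(cfg$grid_upper <= 0 | cfg$grid_upper >= 100) ||
      any(cfg$grid_lower <= 0 | cfg$grid_lower >= 100))
    stop("percentile candidates must lie in (0, 100)")
  if (min(cfg$grid_upper) <= max(cfg$grid_lower))
    stop("every upper percentile must exceed every lower percentile")
  if (cfg$entropy_radius < 1) stop("entropy_radius must be >= 1")
  if (cfg$entropy_bins < 2) stop("entropy_bins must be >= 2")
  with(cfg$flow, {
    if (!(pyr_scale > 0 && pyr_scale < 1)) stop("flow$pyr_scale must be in (0,1)")
    if (levels < 1) stop("flow$levels must be >= 1")
    if (winsize < 3 || winsize %% 2 == 0) stop("flow$winsize must be odd and >= 3")
    if (poly_n < 3 || poly_n %% 2 == 0) stop("flow$poly_n must be odd and >= 3")
    if (!(poly_sigma > 0)) stop("flow$poly_sigma must be > 0")
    if (regularization < 0) stop("flow$regularization must be >= 0")
  })
  invisible(cfg)
}

#' Write / read a configuration as a flat key=value text file
#'
#' Nested fields are flattened with a dot (`flow.winsize=15`). Round-tripping
#' through a file reproduces the configuration exactly.
#'
#' @param cfg A [flowseg_config()] object.
#' @param path File to write to / read from.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `flowseg_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "flowseg_config"))
  flat <- c(
    blur_sigma = fmt_num(cfg$blur_sigma),
    "flow.pyr_scale" = fmt_num(cfg$flow$pyr_scale),
    "flow.levels" = cfg$flow$levels,
    "flow.winsize" = cfg$flow$winsize,
    "flow.iterations" = cfg$flow$iterations,
    "flow.poly_n" = cfg$flow$poly_n,
    "flow.poly_sigma" = fmt_num(cfg$flow$poly_sigma),
    "flow.regularization" = fmt_num(cfg$flow$regularization),
    entropy_radius = cfg$entropy_radius,
    entropy_bins = cfg$entropy_bins,
    grid_upper = paste(cfg$grid_upper, collapse = ","),
    grid_lower = paste(cfg$grid_lower, collapse = ","),
    objective = cfg$objective,
    cv_folds = cfg$cv_folds,
    rng_seed = cfg$rng_seed,
    max_train_per_class = cfg$max_train_per_class,
    empirical_priors = cfg$empirical_priors,
    min_object_area = cfg$min_object_area,
    fill_holes = cfg$fill_holes,
    "declump.enabled" = cfg$declump$enabled,
    "declump.min_distance" = fmt_num(cfg$declump$min_distance),
    "declump.footprint_radius" = cfg$declump$footprint_radius)
  writeLines(paste0(names(flat), "=", unname(flat)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  g <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  num_vec <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  flowseg_config(
    blur_sigma = as.numeric(g("blur_sigma", "0.1")),
    flow = list(pyr_scale = as.numeric(g("flow.pyr_scale", "0.5")),
                levels = as.integer(g("flow.levels", "3")),
                winsize = as.integer(g("flow.winsize", "15")),
                iterations = as.integer(g("flow.iterations", "3")),
                poly_n = as.integer(g("flow.poly_n", "5")),
                poly_sigma = as.numeric(g("flow.poly_sigma", "1.1")),
                regularization = as.numeric(g("flow.regularization", "0.1"))),
    entropy_radius = as.integer(g("entropy_radius", "4")),
    entropy_bins = as.integer(g("entropy_bins", "64")),
    grid_upper = num_vec(g("grid_upper", "80,85,90,95")),
    grid_lower = num_vec(g("grid_lower", "20,30,40,50")),
    objective = g("objective", "mean"),
    cv_folds = as.integer(g("cv_folds", "10")),
    rng_seed = as.integer(g("rng_seed", "0")),
    max_train_per_class = as.integer(g("max_train_per_class", "50000")),
    empirical_priors = as.logical(g("empirical_priors", "FALSE")),
    min_object_area = as.integer(g("min_object_area", "64")),
    fill_holes = as.logical(g("fill_holes", "TRUE")),
    declump = list(enabled = as.logical(g("declump.enabled", "FALSE")),
                   min_distance = as.numeric(g("declump.min_distance", "10")),
                   footprint_radius = as.integer(g("declump.footprint_radius", "7"))))
}

#' @export
print.flowseg_config <- function(x, ...) {
  cat("flowseg pipeline configuration\n")
  cat(sprintf("  blur sigma: %g px | entropy window: disk r=%d, %d bins\n",
              x$blur_sigma, x$entropy_radius, x$entropy_bins))
  cat(sprintf("  flow: %d levels, winsize %d, %d iterations, poly_n %d\n",
              x$flow$levels, x$flow$winsize, x$flow$iterations, x$flow$poly_n))
  cat(sprintf("  threshold grid: upper {%s} x lower {%s} (%s-entropy objective)\n",
              paste(x$grid_upper, collapse = ","),
              paste(x$grid_lower, collapse = ","), x$objective))
  cat(sprintf("  classifier: %d-fold CV, <= %d px/class, seed %d\n",
              x$cv_folds, x$max_train_per_class, x$rng_seed))
  cat(sprintf("  cleanup: min area %d px, fill holes %s | declump %s\n",
              x$min_object_area, x$fill_holes,
              if (x$declump$enabled) "on" else "off"))
  invisible(x)
}
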