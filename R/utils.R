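# internal helpers shared across modules

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-task 32-bit seed from a base seed and an index, deterministic
# and always inside R's integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(index)) %% 2147483647)
}

# Accept an intensity_image, a plain matrix, or a file path; return the pixel
# matrix (rows = image rows).
as_pixels <- function(image) {
  if (inherits(image, "intensity_image")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  if (is.character(image) && length(image) == 1) return(read_image(image)$pixels)
  stop("expected an intensity_image, a numeric matrix, or a file path")
}

stopifnot_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share the same shape (got %s vs %s)",
                 what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

fmt_num <- function(x) sprintf("%.17g", x)
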