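# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally-set RNG state, restoring the caller's stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmax/pmin keep its dims

# 0-based pixel-center coordinate grids for an h x w image.
# X varies along columns (rightward), Y along rows (downward).
coord_grid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

img_gray <- function(image) {
  (image[, , 1] + image[, , 2] + image[, , 3]) / 3
}

is_rgb_image <- function(image) {
  is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L
}

assert_rgb <- function(image, what = "image") {
  if (!is_rgb_image(image))
    stop(what, " must be an RGB array [rows, cols, 3]", call. = FALSE)
}

# Population (divisor n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Names of the nine pallor outcome measures, in the reporting order.
#' Pallor outcome measure names
#'
#' The nine outcome measures produced by [compute_pallor()] and used
#' throughout the cohort generator and the statistical models: global pallor,
#' the six peripapillary sectors, the papillomacular bundle (PMB) and the
#' nasal/temporal ratio.
#'
#' @return Character vector of length nine.
#' @export
pallor_measures <- function() {
  c("global", "temporal", "temporal_inferior", "nasal_inferior", "nasal",
    "nasal_superior", "temporal_superior", "pmb", "nt_ratio")
}

# Sector code -> measure name (sector codes as used in zone label masks).
zone_levels <- function() c("T", "TS", "NS", "N", "NI", "TI")

zone_measure_name <- function(code) {
  c(T = "temporal", TS = "temporal_superior", NS = "nasal_superior",
    N = "nasal", NI = "nasal_inferior", TI = "temporal_inferior")[code]
}
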