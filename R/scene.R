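#' Describe a synthetic fundus scene
#'
#' A `fundus_scene` fully specifies a 45-degree-field fundus-like image with an
#' elliptical optic disc, a fovea landmark, vessels radiating from the disc,
#' a low-order illumination gain field and sensor noise. Because the per-zone
#' green/red rim contrast is a scene parameter, the quantity the pallor
#' measure estimates is known exactly, which makes every geometric and
#' photometric operation testable without real photographs.
#'
#' On a vessel-free, noise-free, flat-illumination scene the measured zone
#' pallor equals `zone_contrast` by construction: the background has constant
#' green/red chromaticity `background_rg`, and the rim in each zone has
#' chromaticity `background_rg * zone_contrast[zone]`.
#'
#' @param image_size Side of the square image in pixels.
#' @param disc A [disc_ellipse()]; default places a typical disc nasally.
#' @param fovea Fovea (x, y) in pixels; default 2.5 disc diameters temporal to
#'   the disc center. Must lie outside the disc and inside the image.
#' @param laterality `"right"` or `"left"`; left-eye scenes are generated as a
#'   horizontal mirror of the equivalent right-eye scene.
#' @param background_rg Green/red chromaticity of the retinal background
#'   (dimensionless).
#' @param zone_contrast Named multiplicative green/red contrast of the rim per
#'   zone (`T`, `TS`, `NS`, `N`, `NI`, `TI`), relative to background; all > 0.
#'   Higher contrast means a paler rim. Defaults approximate a typical healthy
#'   disc (temporal palest).
#' @param n_vessels Number of vessels radiating from the disc center.
#' @param illumination Numeric `c(gx, gy, gr)`: linear x/y and radial
#'   coefficients of a multiplicative gain field (0 = flat).
#' @param noise_sd Additive Gaussian noise SD per channel, on the [0, 1]
#'   intensity scale.
#' @param bit_depth `"8bit"` (camera-like, default) or `"float"` (exact).
#' @param degradation `"none"`, `"under"`, `"over"` or `"gradient"`:
#'   deliberate quality defects used to exercise quality control.
#' @param seed Integer seed making the rendered image fully reproducible.
#' @return An object of class `fundus_scene`.
#' @seealso [generate_fundus()], [generate_batch()]
#' @export
fundus_scene <- function(image_size = 512,
                         disc = NULL,
                         fovea = NULL,
                         laterality = c("right", "left"),
                         background_rg = 0.55,
                         zone_contrast = c(T = 1.41, TS = 1.25, NS = 1.17,
                                           N = 1.17, NI = 1.12, TI = 1.26),
                         n_vessels = 7,
                         illumination = c(0, 0, 0),
                         noise_sd = 0.003,
                         bit_depth = c("8bit", "float"),
                         degradation = c("none", "under", "over", "gradient"),
                         seed = 1L) {
  laterality <- match.arg(laterality)
  bit_depth <- match.arg(bit_depth)
  degradation <- match.arg(degradation)
  S <- as.integer(image_size)
  if (is.null(disc))
    disc <- disc_ellipse(0.28 * S, 0.5 * S, 65 * S / 512, 60 * S / 512, 0)
  if (is.null(fovea))
    fovea <- c(disc$cx + 2.5 * 2 * disc$semi_major, disc$cy)
  fovea <- as.numeric(fovea)

  ext <- ellipse_extent(disc)
  if (disc$cx - ext["x"] < 0 || disc$cx + ext["x"] > S - 1 ||
      disc$cy - ext["y"] < 0 || disc$cy + ext["y"] > S - 1)
    stop("disc must lie entirely inside the image", call. = FALSE)
  if (any(fovea < 0) || any(fovea > S - 1))
    stop("fovea must lie inside the image", call. = FALSE)
  if (ellipse_norm_radius(disc, fovea[1], fovea[2]) <= 1)
    stop("fovea must lie outside the disc", call. = FALSE)
  if (!all(zone_levels() %in% names(zone_contrast)))
    stop("zone_contrast must name all six zones: ",
         paste(zone_levels(), collapse = ", "), call. = FALSE)
  zone_contrast <- zone_contrast[zone_levels()]
  if (any(zone_contrast <= 0)) stop("zone_contrast values must be > 0", call. = FALSE)
  if (background_rg <= 0) stop("background_rg must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  illumination <- rep_len(as.numeric(illumination), 3)

  structure(list(image_size = S, disc = disc, fovea = fovea,
                 laterality = laterality, background_rg = background_rg,
                 zone_contrast = zone_contrast, n_vessels = n_vessels,
                 illumination = illumination, noise_sd = noise_sd,
                 bit_depth = bit_depth, degradation = degradation,
                 seed = as.integer(seed)),
            class = "fundus_scene")
}

#' @export
print.fundus_scene <- function(x, ...) {
  cat(sprintf("fundus scene: %dpx %s eye, disc (%.0f, %.0f) axes %.0fx%.0f, %d vessels, %s\n",
              x$image_size, x$laterality, x$disc$cx, x$disc$cy,
              x$disc$semi_major, x$disc$semi_minor, x$n_vessels, x$degradation))
  cat("  zone contrasts:",
      paste(sprintf("%s=%.2f", names(x$zone_contrast), x$zone_contrast), collapse = " "), "\n")
  invisible(x)
}

# Signed angle (degrees) of pixels relative to the disc-fovea axis:
# 0 toward the fovea, negative superior (up in a right-eye image).
pixel_angles <- function(x, y, cx, cy, ux, uy) {
  vx <- -uy; vy <- ux
  dx <- x - cx; dy <- y - cy
  atan2(dx * vx + dy * vy, dx * ux + dy * uy) * 180 / pi
}

# Zone code (1..6 = T TS NS N NI TI) from the signed angle in degrees.
# Boundary ties follow half-open intervals; the closed temporal interval
# [-45, +45] wins at both of its endpoints.
zone_from_angle <- function(ang) {
  z <- integer(length(ang))
  z[ang >= -45 & ang <= 45] <- 1L                 # T
  z[ang >= -90 & ang < -45] <- 2L                 # TS
  z[ang >= -135 & ang < -90] <- 3L                # NS
  z[ang >= 135 | ang < -135] <- 4L                # N (90-degree nasal sector)
  z[ang >= 90 & ang < 135] <- 5L                  # NI
  z[ang > 45 & ang < 90] <- 6L                    # TI
  z
}
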