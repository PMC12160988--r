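#' Render a synthetic fundus image with ground truth
#'
#' Renders the scene as an RGB image together with a truth bundle (disc
#' ellipse, fovea, vessel mask, zone contrasts). The image model is:
#' background = base chromaticity x illumination field; disc rim = background
#' chromaticity x per-zone contrast, blended over a 2-px soft edge placed just
#' outside the disc boundary so that every pixel strictly inside the ellipse
#' carries the exact zone chromaticity. Vessels are dark curvilinear strokes
#' (green attenuated more than red) radiating from the disc center.
#' Deterministic given `scene$seed`.
#'
#' @param scene A [fundus_scene()].
#' @return List with elements `image` (h x w x 3 array in [0, 1]) and `truth`
#'   (disc, fovea, vessel_mask, zone_contrast, background_rg, laterality,
#'   degradation, scene).
#' @export
generate_fundus <- function(scene) {
  if (!inherits(scene, "fundus_scene")) stop("scene must be a fundus_scene")
  local_seed(scene$seed, render_scene(scene))
}

render_scene <- function(scene) {
  S <- scene$image_size
  disc <- scene$disc
  fovea <- scene$fovea
  g <- coord_grid(S, S)

  R0 <- 0.72
  Gb <- R0 * scene$background_rg
  B0 <- 0.14

  dfo <- fovea - c(disc$cx, disc$cy)
  u <- dfo / sqrt(sum(dfo^2))
  ang <- pixel_angles(g$x, g$y, disc$cx, disc$cy, u[1], u[2])
  zc <- scene$zone_contrast[zone_from_angle(ang)]
  dim(zc) <- c(S, S)

  rho <- ellipse_norm_radius(disc, g$x, g$y)
  # soft edge strictly outside the boundary: ~2 px wide along the minor axis
  t_out <- (rho - 1) * disc$semi_minor
  w_disc <- ifelse(rho <= 1, 1, pmax(0, 1 - t_out / 2))

  gain_disc <- 1 + 0.30 * w_disc        # the disc is brighter than background
  Rch <- R0 * gain_disc
  Gch <- (Gb * (1 - w_disc) + Gb * zc * w_disc) * gain_disc
  Bch <- B0 + 0.22 * w_disc

  vessel_mask <- matrix(FALSE, S, S)
  if (scene$n_vessels > 0) {
    vessel_mask <- draw_vessels(S, disc, scene$n_vessels)
    # blood absorbs green far more strongly than red
    Rch[vessel_mask] <- Rch[vessel_mask] * 0.55
    Gch[vessel_mask] <- Gch[vessel_mask] * 0.20
    Bch[vessel_mask] <- Bch[vessel_mask] * 0.45
  }

  il <- scene$illumination
  xs <- g$x / S - 0.5; ys <- g$y / S - 0.5
  gain <- 1 + il[1] * xs + il[2] * ys + il[3] * (xs^2 + ys^2)
  if (scene$degradation == "gradient") gain <- gain * (1 + 2.2 * xs)
  gain <- pmax(gain, 0.02)
  expo <- switch(scene$degradation, under = 0.02, over = 1.8, 1)

  img <- array(0, c(S, S, 3))
  img[, , 1] <- Rch * gain * expo
  img[, , 2] <- Gch * gain * expo
  img[, , 3] <- Bch * gain * expo

  if (scene$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, scene$noise_sd), dim(img))
  img <- clamp01(img)
  if (scene$bit_depth == "8bit") img <- round(img * 255) / 255

  truth <- list(disc = disc, fovea = fovea, vessel_mask = vessel_mask,
                zone_contrast = scene$zone_contrast,
                background_rg = scene$background_rg,
                laterality = scene$laterality,
                degradation = scene$degradation, scene = scene)

  if (scene$laterality == "left") {
    img <- img[, S:1, , drop = FALSE]
    truth$vessel_mask <- truth$vessel_mask[, S:1]
    truth$fovea <- c(S - 1 - fovea[1], fovea[2])
    truth$disc <- disc_ellipse(S - 1 - disc$cx, disc$cy,
                               disc$semi_major, disc$semi_minor, -disc$tilt)
  }
  list(image = img, truth = truth)
}

# Curved vessel strokes from the disc center outward, rasterized by stamping
# small discs along each polyline; uses the current RNG stream.
draw_vessels <- function(S, disc, n_vessels) {
  mask <- matrix(FALSE, S, S)
  base_dirs <- seq(0, 2 * pi, length.out = n_vessels + 1)[-1]
  for (i in seq_len(n_vessels)) {
    th0 <- base_dirs[i] + stats::runif(1, -0.25, 0.25)
    kap <- stats::runif(1, -0.0025, 0.0025)
    len <- stats::runif(1, 0.40, 0.70) * S
    w0 <- stats::runif(1, 2.5, 4.5)
    r <- seq(0, len, by = 0.8)
    th <- th0 + kap * r
    px <- disc$cx + r * cos(th)
    py <- disc$cy + r * sin(th)
    rad <- w0 / 2 * (1 - 0.4 * r / len)
    keep <- px > -4 & px < S + 3 & py > -4 & py < S + 3
    px <- px[keep]; py <- py[keep]; rad <- rad[keep]
    rcl <- round(rad * 2) / 2
    for (rr in unique(rcl)) {
      sel <- rcl == rr
      off <- expand.grid(dx = -3:3, dy = -3:3)
      off <- off[off$dx^2 + off$dy^2 <= rr^2 + 0.25, , drop = FALSE]
      cx_i <- rep(round(px[sel]), each = nrow(off)) + off$dx
      cy_i <- rep(round(py[sel]), each = nrow(off)) + off$dy
      ok <- cx_i >= 0 & cx_i < S & cy_i >= 0 & cy_i < S
      mask[cbind(cy_i[ok] + 1, cx_i[ok] + 1)] <- TRUE
    }
  }
  mask
}

#' Generate a batch of synthetic fundus images
#'
#' Samples scenes uniformly within parameter ranges and renders each one. A
#' stated fraction of images is deliberately degraded (under-exposed,
#' over-exposed or gradient-illuminated, cycled in that order) to exercise
#' quality control; which images are degraded is part of the returned truth.
#'
#' @param n Number of images (>= 1).
#' @param param_ranges Named list of `c(lo, hi)` ranges overriding
#'   [batch_param_ranges()].
#' @param degraded_frac Fraction of images rendered with a quality defect;
#'   exactly `round(n * degraded_frac)` images are degraded.
#' @param image_size Image side in pixels.
#' @param seed Integer seed; two calls with the same seed produce identical
#'   images and truth.
#' @return List of `n` elements, each as returned by [generate_fundus()] with
#'   an added `truth$id`. The scene table is available via [batch_truth()].
#' @export
generate_batch <- function(n, param_ranges = list(), degraded_frac = 0,
                           image_size = 512, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (degraded_frac < 0 || degraded_frac > 1)
    stop("degraded_frac must be in [0, 1]", call. = FALSE)
  pr <- utils::modifyList(batch_param_ranges(), param_ranges)
  bad <- vapply(pr, function(r) length(r) != 2 || any(!is.finite(r)) || r[2] < r[1],
                logical(1))
  if (any(bad))
    stop("invalid/empty parameter range: ", paste(names(pr)[bad], collapse = ", "),
         call. = FALSE)

  local_seed(seed, {
    n_deg <- round(n * degraded_frac)
    deg_idx <- if (n_deg > 0) sort(sample.int(n, n_deg)) else integer(0)
    deg_types <- rep(c("under", "over", "gradient"), length.out = n_deg)
    seeds <- sample.int(.Machine$integer.max - 1, n)
    ru <- function(r) stats::runif(1, r[1], r[2])
    lapply(seq_len(n), function(i) {
      S <- image_size
      a <- ru(pr$semi_major) * S / 512
      b <- a * ru(pr$axis_ratio)
      disc <- disc_ellipse(ru(pr$center_x) * S, ru(pr$center_y) * S, a, b, ru(pr$tilt))
      elev <- ru(pr$fovea_elev_deg) * pi / 180
      fd <- 2.5 * 2 * a
      fovea <- c(disc$cx + fd * cos(elev), disc$cy + fd * sin(elev))
      zc <- c(T = 1.41, TS = 1.25, NS = 1.17, N = 1.17, NI = 1.12, TI = 1.26) +
        stats::runif(6, pr$zone_contrast_delta[1], pr$zone_contrast_delta[2])
      deg <- if (i %in% deg_idx) deg_types[match(i, deg_idx)] else "none"
      sc <- fundus_scene(image_size = S, disc = disc, fovea = fovea,
                         background_rg = ru(pr$background_rg),
                         zone_contrast = zc,
                         n_vessels = round(ru(pr$n_vessels)),
                         illumination = c(ru(pr$illum), ru(pr$illum), 0),
                         noise_sd = ru(pr$noise_sd),
                         degradation = deg, seed = seeds[i])
      out <- generate_fundus(sc)
      out$truth$id <- sprintf("img%04d", i)
      out
    })
  })
}

#' Default scene-sampling ranges for [generate_batch()]
#'
#' Proportions follow 45-degree-field fundus photographs: disc semi-axes
#' 55-75 px in a 512-px image, fovea 2.5 disc diameters temporal at up to
#' +/-15 degrees elevation, mild illumination gradients and sensor noise.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
batch_param_ranges <- function() {
  list(semi_major = c(55, 75), axis_ratio = c(0.85, 1.0), tilt = c(-0.35, 0.35),
       center_x = c(0.20, 0.25), center_y = c(0.46, 0.54),
       fovea_elev_deg = c(-15, 15),
       zone_contrast_delta = c(-0.12, 0.12), background_rg = c(0.48, 0.62),
       n_vessels = c(5, 9), illum = c(-0.10, 0.10), noise_sd = c(0.002, 0.006))
}

#' Scene truth table for a generated batch
#'
#' @param batch Result of [generate_batch()].
#' @return Data frame, one row per image: scene parameters, zone contrasts,
#'   degradation flag.
#' @export
batch_truth <- function(batch) {
  do.call(rbind, lapply(batch, function(el) {
    tr <- el$truth
    d <- tr$disc
    data.frame(id = tr$id %||% NA_character_,
               laterality = tr$laterality,
               cx = d$cx, cy = d$cy, semi_major = d$semi_major,
               semi_minor = d$semi_minor, tilt = d$tilt,
               fovea_x = tr$fovea[1], fovea_y = tr$fovea[2],
               background_rg = tr$background_rg,
               contrast_T = tr$zone_contrast[["T"]],
               contrast_TS = tr$zone_contrast[["TS"]],
               contrast_NS = tr$zone_contrast[["NS"]],
               contrast_N = tr$zone_contrast[["N"]],
               contrast_NI = tr$zone_contrast[["NI"]],
               contrast_TI = tr$zone_contrast[["TI"]],
               degradation = tr$degradation,
               degraded = tr$degradation != "none",
               stringsAsFactors = FALSE)
  }))
}
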