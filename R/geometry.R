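# Coordinate work: rotation along the disc-fovea axis, disc cropping, and the
# measurement / control / zone-label region geometry.

# Bilinear sampling of a single-channel matrix at 0-based coordinates.
bilinear_sample <- function(m, xs, ys, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  inside <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
  cl <- function(v, lo, hi) pmin(hi, pmax(lo, v))
  gx0 <- cl(x0, 0, w - 1); gx1 <- cl(x0 + 1, 0, w - 1)
  gy0 <- cl(y0, 0, h - 1); gy1 <- cl(y0 + 1, 0, h - 1)
  v00 <- m[cbind(gy0 + 1, gx0 + 1)]
  v01 <- m[cbind(gy0 + 1, gx1 + 1)]
  v10 <- m[cbind(gy1 + 1, gx0 + 1)]
  v11 <- m[cbind(gy1 + 1, gx1 + 1)]
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  out[!inside] <- fill
  out
}

# Rigid rotation transform about a fixed center (angle in radians, applied in
# the image's y-down coordinate frame).
rigid_transform <- function(center, angle) {
  structure(list(center = as.numeric(center), angle = angle),
            class = "rigid_transform")
}

#' Apply or invert a rigid transform on points
#'
#' @param transform A transform as returned by [rotate_to_disc_fovea_axis()].
#' @param pts Two-column matrix (or length-2 vector) of (x, y) pixel points.
#' @param inverse Map output coordinates back to input coordinates.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(transform, pts, inverse = FALSE) {
  one <- is.null(dim(pts))
  p <- if (one) matrix(pts, 1) else as.matrix(pts)
  a <- if (inverse) -transform$angle else transform$angle
  ct <- cos(a); st <- sin(a)
  dx <- p[, 1] - transform$center[1]
  dy <- p[, 2] - transform$center[2]
  out <- cbind(transform$center[1] + ct * dx - st * dy,
               transform$center[2] + st * dx + ct * dy)
  if (one) drop(out) else out
}

# Resample an image (or matrix) under a rigid transform; output has the input
# size. interp = "bilinear" for images, "nearest" for masks.
transform_image <- function(transform, image, interp = c("bilinear", "nearest"),
                            fill = NA) {
  interp <- match.arg(interp)
  chan <- function(m) {
    h <- nrow(m); w <- ncol(m)
    g <- coord_grid(h, w)
    src <- transform_points(transform, cbind(as.vector(g$x), as.vector(g$y)),
                            inverse = TRUE)
    f <- if (is.na(fill)) stats::median(m) else fill
    if (interp == "nearest") {
      xs <- round(src[, 1]); ys <- round(src[, 2])
      ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
      v <- rep(f, length(xs))
      v[ok] <- m[cbind(ys[ok] + 1, xs[ok] + 1)]
      matrix(v, h, w)
    } else {
      matrix(bilinear_sample(m, src[, 1], src[, 2], fill = f), h, w)
    }
  }
  if (is.matrix(image)) return(chan(image))
  out <- image
  for (k in seq_len(dim(image)[3])) out[, , k] <- chan(image[, , k])
  out
}

#' Rotate an image along the disc-fovea axis
#'
#' Rotates the image about the disc center so that, in output coordinates, the
#' fovea lies on the horizontal ray from the disc center toward the temporal
#' side (+x). This puts the 0-degree direction of the zone layout on the
#' disc-fovea axis. The transform is returned and invertible.
#'
#' @param image RGB array or single-channel matrix.
#' @param disc A [disc_ellipse()].
#' @param fovea Fovea (x, y), pixels; must be at least one disc radius
#'   (semi-major axis) from the disc center.
#' @param fill Fill value for pixels rotated in from outside the frame
#'   (default: image median).
#' @return List: `image`, `disc` (tilt re-expressed), `fovea` (rotated),
#'   `transform`, `angle` (radians rotated by).
#' @export
rotate_to_disc_fovea_axis <- function(image, disc, fovea, fill = NA) {
  fovea <- as.numeric(fovea)
  d <- fovea - c(disc$cx, disc$cy)
  if (sqrt(sum(d^2)) < disc$semi_major)
    stop("fovea too close to disc center (< 1 disc radius)", call. = FALSE)
  phi <- atan2(d[2], d[1])
  tr <- rigid_transform(c(disc$cx, disc$cy), -phi)
  out_img <- if (abs(phi) < 1e-12) image else transform_image(tr, image, fill = fill)
  tilt <- disc$tilt - phi
  tilt <- atan2(sin(tilt), cos(tilt))
  if (tilt > pi / 2) tilt <- tilt - pi
  if (tilt <= -pi / 2) tilt <- tilt + pi
  list(image = out_img,
       disc = disc_ellipse(disc$cx, disc$cy, disc$semi_major, disc$semi_minor, tilt),
       fovea = transform_points(tr, fovea),
       transform = tr, angle = -phi)
}

#' Crop the optic disc with a margin
#'
#' The crop is the disc's bounding box expanded by `margin` on all sides,
#' clipped to the image. The control region (a 50-px frame inside the crop
#' border) must fit, hence the margin floor.
#'
#' @param image RGB array or matrix.
#' @param disc A [disc_ellipse()].
#' @param margin Margin in pixels (>= 50).
#' @return List: `image` (crop), `disc` (in crop coordinates), `offset`
#'   (0-based (x, y) of the crop origin in the source), `warnings` (character;
#'   non-empty when the crop was clipped by more than `margin / 2` on a side).
#' @export
crop_disc <- function(image, disc, margin = 60) {
  if (margin < 50) stop("margin must be >= 50 so the control region fits", call. = FALSE)
  h <- if (is.matrix(image)) nrow(image) else dim(image)[1]
  w <- if (is.matrix(image)) ncol(image) else dim(image)[2]
  ext <- ellipse_extent(disc)
  x0 <- floor(disc$cx - ext["x"] - margin); x1 <- ceiling(disc$cx + ext["x"] + margin)
  y0 <- floor(disc$cy - ext["y"] - margin); y1 <- ceiling(disc$cy + ext["y"] + margin)
  cx0 <- max(x0, 0); cx1 <- min(x1, w - 1)
  cy0 <- max(y0, 0); cy1 <- min(y1, h - 1)
  if (cx0 > cx1 || cy0 > cy1) stop("crop falls fully outside the image", call. = FALSE)
  clip <- c(left = cx0 - x0, right = x1 - cx1, top = cy0 - y0, bottom = y1 - cy1)
  warnings <- character(0)
  if (any(clip > margin / 2)) {
    warnings <- sprintf("crop clipped by more than margin/2 on side(s): %s",
                        paste(names(clip)[clip > margin / 2], collapse = ", "))
    warning(warnings, call. = FALSE)
  }
  crop <- if (is.matrix(image)) image[(cy0 + 1):(cy1 + 1), (cx0 + 1):(cx1 + 1)]
          else image[(cy0 + 1):(cy1 + 1), (cx0 + 1):(cx1 + 1), , drop = FALSE]
  list(image = crop,
       disc = disc_ellipse(disc$cx - cx0, disc$cy - cy0,
                           disc$semi_major, disc$semi_minor, disc$tilt),
       offset = c(x = cx0, y = cy0), warnings = warnings)
}

#' Build the measurement, control and zone-label regions
#'
#' The measurement region is the band of pixels inside the disc ellipse whose
#' inward distance from the boundary is at most `measurement_depth` (computed
#' on the normalized ellipse metric: the ellipse is shrunk by the depth on
#' each semi-axis, keeping the annulus width visually uniform). The control
#' region is the frame of pixels within `control_depth` of the crop's outer
#' border, excluding any disc-interior pixel. Every measurement pixel is
#' assigned an angle relative to the disc-fovea axis (0 toward the fovea,
#' negative superior) and a sector label: temporal `[-45, +45]`, temporal
#' superior `[-90, -45)`, nasal superior `[-135, -90)`, nasal (the 90-degree
#' sector through 180), nasal inferior `[+90, +135)`, temporal inferior
#' `(+45, +90)`; the papillomacular bundle is the `[-15, +15]` temporal
#' sub-sector.
#'
#' @param shape `c(rows, cols)` of the crop (or an image/matrix to take it from).
#' @param disc A [disc_ellipse()] in crop coordinates.
#' @param fovea_angle Direction of the fovea in radians in the crop frame
#'   (0 after [rotate_to_disc_fovea_axis()]).
#' @param measurement_depth Inward depth of the measurement band, px.
#' @param control_depth Depth of the control frame from the crop border, px.
#' @return An object of class `region_masks`: logical `measurement`,
#'   `control`, `pmb`; integer `zone_labels` (0 = none, 1..6 = T, TS, NS, N,
#'   NI, TI); numeric `angle_map` (degrees); plus geometry metadata.
#' @export
build_regions <- function(shape, disc, fovea_angle = 0,
                          measurement_depth = 30, control_depth = 50) {
  if (is.array(shape) || is.matrix(shape))
    shape <- c(if (is.matrix(shape)) nrow(shape) else dim(shape)[1],
               if (is.matrix(shape)) ncol(shape) else dim(shape)[2])
  h <- shape[1]; w <- shape[2]
  if (measurement_depth <= 0 || control_depth <= 0)
    stop("depths must be > 0", call. = FALSE)
  if (measurement_depth >= disc$semi_minor)
    stop("measurement_depth >= semi-minor axis: annulus would close", call. = FALSE)
  g <- coord_grid(h, w)
  rho_out <- ellipse_norm_radius(disc, g$x, g$y)
  rho_in <- ellipse_norm_radius(disc, g$x, g$y, shrink = measurement_depth)
  inside <- rho_out <= 1
  measurement <- inside & rho_in > 1

  border_dist <- pmin(g$x, g$y, (w - 1) - g$x, (h - 1) - g$y)
  control <- border_dist < control_depth & !inside

  ang <- pixel_angles(g$x, g$y, disc$cx, disc$cy, cos(fovea_angle), sin(fovea_angle))
  zone_labels <- matrix(0L, h, w)
  zone_labels[measurement] <- zone_from_angle(ang[measurement])
  pmb <- measurement & ang >= -15 & ang <= 15

  structure(list(measurement = measurement, control = control,
                 zone_labels = zone_labels, pmb = pmb, angle_map = ang,
                 disc = disc, measurement_depth = measurement_depth,
                 control_depth = control_depth,
                 shape = c(h, w)),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  counts <- table(factor(x$zone_labels[x$measurement], levels = 1:6,
                         labels = zone_levels()))
  cat(sprintf("region masks %dx%d: measurement %d px, control %d px, PMB %d px\n",
              x$shape[1], x$shape[2], sum(x$measurement), sum(x$control), sum(x$pmb)))
  cat("  zones:", paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
  invisible(x)
}
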