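#' Parametric optic disc ellipse
#'
#' The disc boundary is represented as an ellipse in image pixel coordinates
#' (0-based, x rightward, y downward), the anchor of all region geometry.
#'
#' @param cx,cy Center, pixels.
#' @param semi_major,semi_minor Semi-axes in pixels; `semi_major >= semi_minor > 0`.
#' @param tilt Major-axis angle from the x-axis, radians.
#' @return An object of class `disc_ellipse`.
#' @export
disc_ellipse <- function(cx, cy, semi_major, semi_minor, tilt = 0) {
  if (!is.finite(cx) || !is.finite(cy))
    stop("ellipse center must be finite", call. = FALSE)
  if (!(semi_major >= semi_minor && semi_minor > 0))
    stop("require semi_major >= semi_minor > 0", call. = FALSE)
  structure(list(cx = cx, cy = cy, semi_major = semi_major,
                 semi_minor = semi_minor, tilt = tilt),
            class = "disc_ellipse")
}

#' @export
print.disc_ellipse <- function(x, ...) {
  cat(sprintf("disc ellipse: center (%.1f, %.1f), axes %.1f x %.1f px, tilt %.1f deg\n",
              x$cx, x$cy, x$semi_major, x$semi_minor, x$tilt * 180 / pi))
  invisible(x)
}

# Normalized elliptical radius of points (x, y): 1 on the boundary.
# `shrink` subtracts a per-axis depth (used for the inward-eroded annulus,
# keeping the annulus width visually uniform on anisotropic discs).
ellipse_norm_radius <- function(disc, x, y, shrink = 0) {
  a <- disc$semi_major - shrink
  b <- disc$semi_minor - shrink
  if (a <= 0 || b <= 0) stop("shrink exceeds a semi-axis", call. = FALSE)
  dx <- x - disc$cx
  dy <- y - disc$cy
  ct <- cos(disc$tilt); st <- sin(disc$tilt)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  sqrt((u / a)^2 + (v / b)^2)
}

# Rasterize the filled ellipse into an h x w logical mask.
ellipse_mask <- function(disc, h, w, shrink = 0) {
  g <- coord_grid(h, w)
  ellipse_norm_radius(disc, g$x, g$y, shrink) <= 1
}

# Axis-aligned half-extents of the ellipse bounding box.
ellipse_extent <- function(disc) {
  ct <- cos(disc$tilt); st <- sin(disc$tilt)
  c(x = sqrt((disc$semi_major * ct)^2 + (disc$semi_minor * st)^2),
    y = sqrt((disc$semi_major * st)^2 + (disc$semi_minor * ct)^2))
}

# Point on the boundary at parametric angle psi, optionally radially scaled.
ellipse_point <- function(disc, psi, scale = 1) {
  ct <- cos(disc$tilt); st <- sin(disc$tilt)
  u <- scale * disc$semi_major * cos(psi)
  v <- scale * disc$semi_minor * sin(psi)
  cbind(x = disc$cx + u * ct - v * st, y = disc$cy + u * st + v * ct)
}

#' Fit an ellipse to a binary optic disc mask
#'
#' Least-squares (direct conic, Halir-Flusser stabilisation) ellipse fit to the
#' boundary pixels of the mask's single connected component. Stands in for a
#' hand-corrected disc segmentation: the mask is trusted, only its parametric
#' form is recovered.
#'
#' @param mask Logical or 0/1 matrix; foreground is the disc.
#' @param min_pixels Minimum foreground size (default 500).
#' @return A [disc_ellipse()].
#' @details Errors on an empty, fragmented (more than one connected component),
#'   too-small, or image-border-touching mask, naming the failure. The fitted
#'   area must lie in `[min_pixels, image area / 4]`.
#' @export
fit_ellipse <- function(mask, min_pixels = 500) {
  if (is.array(mask) && length(dim(mask)) == 3L) mask <- mask[, , 1]
  m <- matrix(as.numeric(mask > 0.5), nrow(mask), ncol(mask))
  n_fg <- sum(m)
  if (n_fg == 0) stop("disc mask is empty", call. = FALSE)
  if (n_fg < min_pixels)
    stop("disc mask too small: ", n_fg, " < ", min_pixels, " pixels", call. = FALSE)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1L)
    stop("disc mask is fragmented: ", max(lab), " connected components", call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  if (any(m[1, ] > 0) || any(m[h, ] > 0) || any(m[, 1] > 0) || any(m[, w] > 0))
    stop("disc mask touches the image border", call. = FALSE)

  # boundary: foreground pixels with at least one 4-neighbour background pixel
  inner <- m[2:(h - 1), 2:(w - 1)] > 0 &
    (m[1:(h - 2), 2:(w - 1)] == 0 | m[3:h, 2:(w - 1)] == 0 |
     m[2:(h - 1), 1:(w - 2)] == 0 | m[2:(h - 1), 3:w] == 0)
  idx <- which(inner, arr.ind = TRUE)
  # window position (i, j) is image pixel (i+1, j+1) 1-based, i.e. (j, i) 0-based
  x <- idx[, 2]
  y <- idx[, 1]
  fit <- fit_conic_ellipse(x, y)
  disc <- conic_to_ellipse(fit)
  # boundary pixel centers sit ~half a pixel inside the continuous boundary
  disc <- disc_ellipse(disc$cx, disc$cy, disc$semi_major + 0.5,
                       disc$semi_minor + 0.5, disc$tilt)
  area <- pi * disc$semi_major * disc$semi_minor
  if (area < min_pixels || area > h * w / 4)
    stop("fitted ellipse area ", round(area), " outside plausible range", call. = FALSE)
  disc
}

# Direct least-squares ellipse-specific conic fit (Halir & Flusser partition).
# Returns conic coefficients (A, B, C, D, E, F) for Ax^2+Bxy+Cy^2+Dx+Ey+F=0.
fit_conic_ellipse <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0) stop("conic fit is not an ellipse", call. = FALSE)
  a1 <- V[, k[1]]
  a2 <- Tm %*% a1
  co <- c(a1, a2)        # A B C D E F in centered coordinates
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; Fc <- co[6]
  # shift back to original coordinates
  D0 <- D - 2 * A * mx - B * my
  E0 <- E - 2 * C * my - B * mx
  F0 <- Fc + A * mx^2 + B * mx * my + C * my^2 - D * mx - E * my
  c(A = A, B = B, C = C, D = D0, E = E0, F = F0)
}

conic_to_ellipse <- function(co) {
  co <- unname(co)
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; Fc <- co[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse", call. = FALSE)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  s <- sqrt((A - C)^2 + B^2)
  a <- -sqrt(num * (A + C + s)) / den
  b <- -sqrt(num * (A + C - s)) / den
  tilt <- if (abs(B) < 1e-12 && A <= C) 0 else atan2(C - A - s, B)
  if (a < b) { tmp <- a; a <- b; b <- tmp; tilt <- tilt + pi / 2 }
  tilt <- atan2(sin(tilt), cos(tilt))
  if (tilt > pi / 2) tilt <- tilt - pi
  if (tilt <= -pi / 2) tilt <- tilt + pi
  disc_ellipse(cx, cy, a, b, tilt)
}
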