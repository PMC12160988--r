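# Vessel-excluded zonal pallor metrics.

#' Exclude vessel pixels from region masks
#'
#' Removes (dilated) vessel pixels from the measurement region, the control
#' region, the zone labels and the PMB mask. A zone left with fewer than
#' `min_zone_pixels` valid pixels is flagged invalid rather than silently
#' measured on too few pixels.
#'
#' @param regions A [build_regions()] result, aligned to the crop.
#' @param vessel_mask Logical matrix aligned to the crop.
#' @param dilation Dilation radius applied to the vessel mask, px.
#' @param min_zone_pixels Minimum valid pixels per zone.
#' @return The region masks with vessels removed; `$valid_pixel_counts` holds
#'   the remaining per-zone counts and `$invalid_zones` the flagged names.
#' @export
exclude_vessels <- function(regions, vessel_mask, dilation = 2,
                            min_zone_pixels = 50) {
  if (!inherits(regions, "region_masks")) stop("regions must be region_masks")
  vm <- matrix(as.logical(vessel_mask), nrow(vessel_mask), ncol(vessel_mask))
  if (!all(dim(vm) == regions$shape))
    stop("vessel mask is not aligned to the crop", call. = FALSE)
  if (any(vm) && dilation > 0) {
    brush <- EBImage::makeBrush(2 * dilation + 1, shape = "disc")
    vm <- EBImage::dilate(matrix(as.numeric(vm), nrow(vm)), brush) > 0.5
  }
  regions$measurement <- regions$measurement & !vm
  regions$control <- regions$control & !vm
  regions$zone_labels[vm] <- 0L
  regions$pmb <- regions$pmb & !vm
  regions$vessel_excluded <- TRUE
  counts <- region_pixel_counts(regions)
  regions$valid_pixel_counts <- counts
  regions$invalid_zones <- names(counts)[counts < min_zone_pixels]
  regions
}

region_pixel_counts <- function(regions) {
  zc <- tabulate(regions$zone_labels[regions$measurement], nbins = 6)
  counts <- c(sum(regions$measurement), zc, sum(regions$pmb), sum(regions$control))
  names(counts) <- c("global", unname(zone_measure_name(zone_levels())), "pmb", "control")
  counts
}

#' Zonal pallor of one pixel set
#'
#' Pallor is the green/red reflectance ratio of the zone relative to the
#' control region: `[mean(G)/mean(R)]_zone / [mean(G)/mean(R)]_control`
#' (ratio of means; both regions vessel-excluded). Higher values mean a paler
#' (greener, less blood-attenuated) rim. The inverse orientation, with paler
#' discs scoring lower, is available via `inverse = TRUE`.
#'
#' @param image RGB array (crop).
#' @param zone_mask,control_mask Logical matrices selecting the pixels.
#' @param min_pixels Minimum valid pixels required in each set.
#' @param inverse Report red/green over green/red instead.
#' @return Dimensionless pallor, strictly positive.
#' @export
zone_pallor <- function(image, zone_mask, control_mask, min_pixels = 50,
                        inverse = FALSE) {
  assert_rgb(image)
  nz <- sum(zone_mask); nc <- sum(control_mask)
  if (nz < min_pixels || nc < min_pixels)
    stop("fewer than ", min_pixels, " valid pixels in zone (", nz,
         ") or control (", nc, ")", call. = FALSE)
  R <- image[, , 1]; G <- image[, , 2]
  mRz <- mean(R[zone_mask]); mGz <- mean(G[zone_mask])
  mRc <- mean(R[control_mask]); mGc <- mean(G[control_mask])
  if (mRz <= 0 || mRc <= 0)
    stop("zero mean red reflectance: saturated or defective image", call. = FALSE)
  if (mGz <= 0 || mGc <= 0)
    stop("zero mean green reflectance: saturated or defective image", call. = FALSE)
  p <- (mGz / mRz) / (mGc / mRc)
  if (inverse) 1 / p else p
}

#' Compute all pallor outcome measures for a cropped disc
#'
#' Produces global pallor (the whole measurement annulus), the six sector
#' pallors, PMB pallor, the nasal/temporal ratio and the angular pallor
#' profile. A zone flagged invalid after vessel exclusion yields `NA` for its
#' measure (and for the NT ratio if either constituent is missing), listed in
#' the result's `invalid_zones`.
#'
#' @param image RGB crop.
#' @param regions Region masks (after [exclude_vessels()] where vessels exist).
#' @param profile_bins Number of angular bins of the pallor profile.
#' @param min_bin_pixels Minimum valid pixels for a profile bin to be scored.
#' @param min_zone_pixels Minimum valid pixels per zone.
#' @param inverse Ratio orientation switch, see [zone_pallor()].
#' @return An object of class `pallor_result`.
#' @export
compute_pallor <- function(image, regions, profile_bins = 360,
                           min_bin_pixels = 20, min_zone_pixels = 50,
                           inverse = FALSE) {
  assert_rgb(image)
  counts <- regions$valid_pixel_counts %||% region_pixel_counts(regions)
  invalid <- regions$invalid_zones %||% names(counts)[counts < min_zone_pixels]

  ctrl <- regions$control
  zp <- function(mask, name) {
    if (name %in% invalid || "control" %in% invalid) return(NA_real_)
    zone_pallor(image, mask, ctrl, min_pixels = min_zone_pixels, inverse = inverse)
  }
  res <- list(global = zp(regions$measurement, "global"))
  for (k in 1:6) {
    nm <- unname(zone_measure_name(zone_levels()[k]))
    res[[nm]] <- zp(regions$zone_labels == k, nm)
  }
  res$pmb <- zp(regions$pmb, "pmb")
  res$nt_ratio <- if (is.na(res$nasal) || is.na(res$temporal)) NA_real_
                  else res$nasal / res$temporal

  # angular profile: per-bin pallor over the measurement band
  width <- 360 / profile_bins
  ang <- regions$angle_map[regions$measurement]
  bin <- pmin(profile_bins, floor((ang + 180) / width) + 1)
  R <- image[, , 1][regions$measurement]
  G <- image[, , 2][regions$measurement]
  nR <- tapply(R, factor(bin, levels = seq_len(profile_bins)), mean)
  nG <- tapply(G, factor(bin, levels = seq_len(profile_bins)), mean)
  nb <- tabulate(bin, nbins = profile_bins)
  cr <- mean(image[, , 1][ctrl]); cg <- mean(image[, , 2][ctrl])
  prof <- as.numeric((nG / nR) / (cg / cr))
  if (inverse) prof <- 1 / prof
  prof[nb < min_bin_pixels] <- NA_real_
  names(prof) <- sprintf("%.1f", seq(-180 + width / 2, 180 - width / 2, by = width))

  structure(c(res[pallor_measures()],
              list(profile = prof, valid_pixel_counts = counts,
                   invalid_zones = invalid, inverse = inverse)),
            class = "pallor_result")
}

#' @export
print.pallor_result <- function(x, digits = 3, ...) {
  cat("optic disc pallor (zone G/R relative to control):\n")
  v <- unlist(x[pallor_measures()])
  print(round(v, digits))
  if (length(x$invalid_zones))
    cat("invalid zones (too few valid pixels):",
        paste(x$invalid_zones, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pallor_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- as.data.frame(as.list(unlist(x[pallor_measures()])))
  cnt <- x$valid_pixel_counts
  names(cnt) <- paste0("n_", names(cnt))
  cbind(out, as.data.frame(as.list(cnt)))
}

#' Measure optic disc pallor in one image
#'
#' The full measurement chain: (for a left eye) mirror horizontally so one
#' angular convention serves both eyes, rotate along the disc-fovea axis,
#' crop the disc with a margin, build the measurement/control/zone regions,
#' exclude vessels, and compute all pallor measures.
#'
#' @param image RGB array (full frame).
#' @param disc A [disc_ellipse()] in image coordinates (e.g. from
#'   [fit_ellipse()] on a disc mask).
#' @param fovea Fovea (x, y), pixels.
#' @param vessel_mask Optional logical matrix of vessel pixels (full frame).
#' @param laterality `"right"` or `"left"`.
#' @param margin Crop margin, px.
#' @param measurement_depth,control_depth Region depths, px.
#' @param dilation Vessel dilation, px.
#' @param ... Passed on to [compute_pallor()].
#' @return A `pallor_result`; `attr(, "provenance")` records the mirroring,
#'   rotation angle, crop offset and any crop warnings.
#' @export
measure_pallor <- function(image, disc, fovea, vessel_mask = NULL,
                           laterality = "right", margin = 60,
                           measurement_depth = 30, control_depth = 50,
                           dilation = 2, ...) {
  assert_rgb(image)
  S <- ncol(image)
  mirrored <- identical(laterality, "left")
  if (mirrored) {
    image <- image[, S:1, , drop = FALSE]
    if (!is.null(vessel_mask)) vessel_mask <- vessel_mask[, S:1]
    fovea <- c(S - 1 - fovea[1], fovea[2])
    disc <- disc_ellipse(S - 1 - disc$cx, disc$cy, disc$semi_major,
                         disc$semi_minor, -disc$tilt)
  }
  rot <- rotate_to_disc_fovea_axis(image, disc, fovea)
  vm <- if (is.null(vessel_mask)) NULL
        else transform_image(rot$transform, matrix(as.numeric(vessel_mask),
                                                   nrow(vessel_mask)),
                             interp = "nearest", fill = 0) > 0.5
  cr <- withCallingHandlers(
    crop_disc(rot$image, rot$disc, margin = margin),
    warning = function(w) invokeRestart("muffleWarning"))
  regions <- build_regions(cr$image, cr$disc, fovea_angle = 0,
                           measurement_depth = measurement_depth,
                           control_depth = control_depth)
  if (!is.null(vm)) {
    ox <- cr$offset["x"]; oy <- cr$offset["y"]
    h <- nrow(cr$image); w <- ncol(cr$image)
    vm_crop <- vm[(oy + 1):(oy + h), (ox + 1):(ox + w)]
    regions <- exclude_vessels(regions, vm_crop, dilation = dilation)
  }
  res <- compute_pallor(cr$image, regions, ...)
  attr(res, "provenance") <- list(mirrored = mirrored, rotation_angle = rot$angle,
                                  crop_offset = cr$offset,
                                  crop_warnings = cr$warnings)
  res
}

#' Measure a generated batch
#'
#' Runs [measure_pallor()] over a [generate_batch()] result using the truth
#' geometry (the stand-in for a hand-corrected segmentation), optionally
#' refitting the disc ellipse from the rasterized truth mask.
#'
#' @param batch A [generate_batch()] result.
#' @param use_fitted_ellipse Refit the disc from the rasterized truth ellipse
#'   instead of using truth parameters directly.
#' @param ... Passed to [measure_pallor()].
#' @return Data frame: id plus the nine measures and valid-pixel counts.
#' @export
measure_batch <- function(batch, use_fitted_ellipse = FALSE, ...) {
  rows <- lapply(batch, function(el) {
    tr <- el$truth
    disc <- tr$disc
    if (use_fitted_ellipse) {
      S <- nrow(el$image)
      disc <- fit_ellipse(ellipse_mask(disc, S, S))
    }
    res <- measure_pallor(el$image, disc, tr$fovea, vessel_mask = tr$vessel_mask,
                          laterality = tr$laterality, ...)
    cbind(data.frame(id = tr$id %||% NA_character_), as.data.frame(res))
  })
  do.call(rbind, rows)
}
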