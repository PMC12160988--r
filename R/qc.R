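# Automated quantitative proxies for manual image-rejection rules.
# The original rejection criteria were a human annotator's judgement; these
# thresholds are explicit, configurable proxies, not reproductions.

#' Quality-control thresholds
#'
#' @param exposure_frac Maximum tolerated fraction of near-black or
#'   near-saturated pixels in the measurement-plus-control region.
#' @param dark_level Per-channel level below which a pixel counts as
#'   near-black (all channels), on the [0, 1] scale.
#' @param sat_level Level above which any channel counts as near-saturated.
#' @param illum_ratio Maximum max/min ratio of the fitted low-order gain
#'   field over the crop background.
#' @param border_grad Minimum median luminance step across the disc boundary.
#' @param chroma_z Batch-level |z| threshold on background chromaticity for
#'   the abnormal-retina proxy.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(exposure_frac = 0.20, dark_level = 5 / 255,
                          sat_level = 250 / 255, illum_ratio = 1.5,
                          border_grad = 0.02, chroma_z = 4) {
  list(exposure_frac = exposure_frac, dark_level = dark_level,
       sat_level = sat_level, illum_ratio = illum_ratio,
       border_grad = border_grad, chroma_z = chroma_z)
}

#' Assess the quality of one fundus image
#'
#' Computes quantitative diagnostics behind each rejection category:
#' under/over-exposure (fraction of near-black / near-saturated pixels in the
#' measurement-plus-control region), uneven illumination (max/min ratio of a
#' quadratic gain field fitted to the crop background), unclear disc border
#' (median luminance step across the ellipse boundary) and a missing fovea.
#' The abnormal-retina proxy needs batch context and is computed by
#' [qc_batch()] only. Always returns a report; never errors on image content.
#'
#' @param image RGB array (full frame).
#' @param disc A [disc_ellipse()] in image coordinates.
#' @param fovea Fovea (x, y) or `NULL`/`NA` when localization failed.
#' @param margin Crop margin, px.
#' @param measurement_depth,control_depth Region depths, px.
#' @param thresholds See [qc_thresholds()].
#' @return An object of class `qc_report`: `flags` (character), `metrics`
#'   (named numerics), `pass` (no flags raised).
#' @export
assess_quality <- function(image, disc, fovea = NULL, margin = 60,
                           measurement_depth = 30, control_depth = 50,
                           thresholds = qc_thresholds()) {
  assert_rgb(image)
  th <- thresholds
  cr <- withCallingHandlers(
    crop_disc(image, disc, margin = margin),
    warning = function(w) invokeRestart("muffleWarning"))
  crop <- cr$image
  regions <- build_regions(crop, cr$disc, fovea_angle = 0,
                           measurement_depth = measurement_depth,
                           control_depth = control_depth)
  roi <- regions$measurement | regions$control

  R <- crop[, , 1]; G <- crop[, , 2]; B <- crop[, , 3]
  near_black <- R < th$dark_level & G < th$dark_level & B < th$dark_level
  near_sat <- R > th$sat_level | G > th$sat_level | B > th$sat_level
  frac_black <- mean(near_black[roi])
  frac_sat <- mean(near_sat[roi])

  # quadratic gain field fitted to the crop background (disc excluded)
  gray <- img_gray(crop)
  g <- coord_grid(nrow(crop), ncol(crop))
  bg <- ellipse_norm_radius(cr$disc, g$x, g$y) > 1.05
  sub <- which(bg)
  if (length(sub) > 4000) sub <- sub[seq(1, length(sub), length.out = 4000)]
  xs <- g$x[sub] / ncol(crop); ys <- g$y[sub] / nrow(crop)
  fit <- stats::lm.fit(cbind(1, xs, ys, xs^2, ys^2, xs * ys), gray[sub])
  fitted <- fit$fitted.values
  illum_ratio <- if (min(fitted) <= 1e-6) Inf else max(fitted) / min(fitted)

  # luminance step across the ellipse boundary
  psi <- seq(0, 2 * pi, length.out = 73)[-73]
  p_in <- ellipse_point(cr$disc, psi, scale = 0.85)
  p_out <- ellipse_point(cr$disc, psi, scale = 1.18)
  g_in <- bilinear_sample(gray, p_in[, 1], p_in[, 2], fill = NA)
  g_out <- bilinear_sample(gray, p_out[, 1], p_out[, 2], fill = NA)
  border_step <- stats::median(abs(g_in - g_out), na.rm = TRUE)

  fovea_missing <- is.null(fovea) || any(is.na(fovea))

  metrics <- c(frac_near_black = frac_black, frac_near_saturated = frac_sat,
               illumination_ratio = illum_ratio, border_step = border_step)
  flags <- character(0)
  if (frac_black > th$exposure_frac) flags <- c(flags, "under_exposure")
  if (frac_sat > th$exposure_frac) flags <- c(flags, "over_exposure")
  if (illum_ratio > th$illum_ratio) flags <- c(flags, "uneven_illumination")
  if (is.finite(border_step) && border_step < th$border_grad)
    flags <- c(flags, "border_unclear")
  if (fovea_missing) flags <- c(flags, "fovea_missing")

  structure(list(flags = flags, metrics = metrics, pass = length(flags) == 0L),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", if (x$pass) "PASS" else paste("FAIL --", paste(x$flags, collapse = ", ")), "\n")
  print(round(x$metrics, 4))
  invisible(x)
}

qc_flag_names <- function() {
  c("under_exposure", "over_exposure", "uneven_illumination",
    "border_unclear", "abnormal_retina", "fovea_missing")
}

#' Quality control over a generated batch
#'
#' Applies [assess_quality()] per image and adds the batch-level
#' abnormal-retina proxy: an image whose background green/red chromaticity is
#' more than `chroma_z` SDs from the batch mean is flagged.
#'
#' @param batch A [generate_batch()] result (or a list with `image` and
#'   `truth$disc`, `truth$fovea` per element).
#' @param thresholds See [qc_thresholds()].
#' @param ... Passed to [assess_quality()].
#' @return Data frame: id, one logical column per flag, the metric columns,
#'   and `pass`.
#' @export
qc_batch <- function(batch, thresholds = qc_thresholds(), ...) {
  reports <- lapply(batch, function(el)
    assess_quality(el$image, el$truth$disc, el$truth$fovea,
                   thresholds = thresholds, ...))
  chroma <- vapply(batch, function(el) {
    S <- nrow(el$image)
    d <- el$truth$disc
    g <- coord_grid(S, S)
    bg <- ellipse_norm_radius(d, g$x, g$y) > 1.3
    stats::median(el$image[, , 2][bg] / pmax(el$image[, , 1][bg], 1e-4))
  }, numeric(1))
  # robust z: a gross outlier must not mask itself by inflating the batch SD
  md <- stats::mad(chroma)
  z <- if (length(chroma) > 2 && md > 0)
    (chroma - stats::median(chroma)) / md else rep(0, length(chroma))

  out <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    flags <- qc_flag_names() %in% r$flags
    if (abs(z[i]) > thresholds$chroma_z) flags[5] <- TRUE
    df <- as.data.frame(as.list(stats::setNames(flags, qc_flag_names())))
    cbind(data.frame(id = batch[[i]]$truth$id %||% sprintf("img%04d", i)),
          df, as.data.frame(as.list(r$metrics)),
          data.frame(chroma_z = z[i], pass = !any(flags)))
  }))
  out
}

#' Per-group rejection summary
#'
#' @param reports Data frame from [qc_batch()] (needs the flag columns and
#'   `pass`), or any data frame with a logical `pass` column.
#' @param group Grouping vector (one value per report); a single group is
#'   assumed when omitted.
#' @return Data frame of counts and percentages per group: total, rejected,
#'   rejection percentage, and per-category counts.
#' @export
qc_summary <- function(reports, group = NULL) {
  if (NROW(reports) == 0) stop("no QC reports supplied", call. = FALSE)
  if (is.null(group)) group <- rep("all", NROW(reports))
  sp <- split(seq_len(NROW(reports)), group)
  do.call(rbind, lapply(names(sp), function(gname) {
    idx <- sp[[gname]]
    res <- data.frame(group = gname, n = length(idx),
                      rejected = sum(!reports$pass[idx]),
                      pct_rejected = 100 * mean(!reports$pass[idx]))
    for (fl in intersect(qc_flag_names(), names(reports)))
      res[[paste0("n_", fl)]] <- sum(reports[[fl]][idx])
    res
  }))
}
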