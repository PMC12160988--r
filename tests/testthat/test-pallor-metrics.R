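# Pallor computation: ratio closed forms, vessel exclusion, invariances.

make_flat_image <- function(h, w, r, g, b = 0.1) {
  img <- array(0, c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

test_that("zone_pallor matches its closed form on constructed images", {
  zone <- matrix(FALSE, 100, 100); zone[30:60, 30:60] <- TRUE
  ctrl <- matrix(FALSE, 100, 100); ctrl[1:10, ] <- TRUE

  img <- make_flat_image(100, 100, r = 0.6, g = 0.4)
  expect_identical(zone_pallor(img, zone, ctrl), 1.0)

  # zone green scaled x1.2 relative to control, red equal
  img2 <- img
  img2[, , 2][zone] <- 0.4 * 1.2
  expect_equal(zone_pallor(img2, zone, ctrl), 1.2, tolerance = 1e-9)
  expect_equal(zone_pallor(img2, zone, ctrl, inverse = TRUE), 1 / 1.2,
               tolerance = 1e-9)

  # uniform brightness gain on the control region cancels
  img3 <- img2
  img3[, , 1][ctrl] <- 2 * img3[, , 1][ctrl]
  img3[, , 2][ctrl] <- 2 * img3[, , 2][ctrl]
  expect_equal(zone_pallor(img3, zone, ctrl), 1.2, tolerance = 1e-9)

  img4 <- img2; img4[, , 1][zone] <- 0
  expect_error(zone_pallor(img4, zone, ctrl), "red")
  expect_error(zone_pallor(img, zone & FALSE, ctrl), "50")
})

test_that("vessel exclusion restores the closed-form pallor", {
  zc <- distinct_contrasts()
  sc <- fundus_scene(zone_contrast = zc, n_vessels = 16, noise_sd = 0,
                     bit_depth = "float", seed = 9)
  out <- generate_fundus(sc)
  with_ex <- measure_pallor(out$image, out$truth$disc, out$truth$fovea,
                            vessel_mask = out$truth$vessel_mask)
  no_ex <- measure_pallor(out$image, out$truth$disc, out$truth$fovea)
  truth <- contrast_vector(zc)
  expect_equal(unname(measured_vector(with_ex)), unname(truth), tolerance = 0.01)
  # without exclusion the dense vasculature biases the global measure hard
  expect_gt(abs(no_ex$global - with_ex$global), 0.05)
  expect_gt(max(abs(measured_vector(no_ex) - truth)),
            max(abs(measured_vector(with_ex) - truth)))
})

test_that("an empty vessel mask changes nothing; a buried sector is flagged", {
  out <- generate_fundus(clean_scene(distinct_contrasts()))
  d <- out$truth$disc
  rot <- rotate_to_disc_fovea_axis(out$image, d, out$truth$fovea)
  cr <- crop_disc(rot$image, rot$disc, margin = 60)
  rg <- build_regions(cr$image, cr$disc)

  rg_same <- exclude_vessels(rg, matrix(FALSE, nrow(cr$image), ncol(cr$image)))
  expect_identical(rg_same$measurement, rg$measurement)
  expect_identical(rg_same$zone_labels, rg$zone_labels)
  expect_length(rg_same$invalid_zones, 0)

  # vessels covering the whole nasal sector
  vm <- rg$zone_labels == 4L
  rg_nasal <- exclude_vessels(rg, vm)
  expect_true("nasal" %in% rg_nasal$invalid_zones)
  res <- compute_pallor(cr$image, rg_nasal)
  expect_true(is.na(res$nasal))
  expect_true(is.na(res$nt_ratio))
  expect_false(is.na(res$temporal))
})

test_that("NT ratio and profile are consistent with the sector measures", {
  zc <- c(T = 1.4, TS = 1.2, NS = 1.1, N = 1.1, NI = 1.1, TI = 1.2)
  out <- generate_fundus(clean_scene(zc))
  res <- measure_pallor(out$image, out$truth$disc, out$truth$fovea)
  expect_equal(res$nt_ratio, res$nasal / res$temporal, tolerance = 1e-9)
  expect_equal(res$nt_ratio, 1.1 / 1.4, tolerance = 0.01)
  # mean of profile bins falling in the temporal sector tracks temporal pallor
  ang <- seq(-179.5, 179.5, by = 1)
  in_t <- ang >= -45 & ang <= 45
  expect_equal(mean(res$profile[in_t], na.rm = TRUE), res$temporal,
               tolerance = 0.02)
})

test_that("pallor is invariant to a global gain and monotone in contrast", {
  out <- generate_fundus(clean_scene(distinct_contrasts()))
  base <- measure_pallor(out$image, out$truth$disc, out$truth$fovea)
  scaled <- measure_pallor(out$image * 0.55, out$truth$disc, out$truth$fovea)
  for (m in pallor_measures())
    expect_equal(scaled[[m]], base[[m]], tolerance = 1e-6)

  zc2 <- distinct_contrasts(); zc2[["T"]] <- zc2[["T"]] + 0.2
  out2 <- generate_fundus(clean_scene(zc2))
  res2 <- measure_pallor(out2$image, out2$truth$disc, out2$truth$fovea)
  expect_gt(res2$temporal, base$temporal + 0.1)
  expect_equal(res2$nasal, base$nasal, tolerance = 0.01)
  expect_equal(res2$nasal_superior, base$nasal_superior, tolerance = 0.01)
})

test_that("default synthetic batches stay inside the plausible pallor range", {
  b <- generate_batch(14, degraded_frac = 0, seed = 23)
  tab <- measure_batch(b)
  expect_true(all(tab$global > 0.6 & tab$global < 2.0))
  expect_true(all(tab$nt_ratio > 0))
})
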