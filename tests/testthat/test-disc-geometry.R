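# Ellipse fitting, rotation, cropping and region construction.

test_that("fit_ellipse recovers generating parameters of rasterized discs", {
  circ <- pallorkit:::ellipse_mask(disc_ellipse(250, 250, 60, 60), 512, 512)
  f <- fit_ellipse(circ)
  expect_equal(f$cx, 250, tolerance = 0.5)
  expect_equal(f$cy, 250, tolerance = 0.5)
  expect_equal(f$semi_major, 60, tolerance = 0.5)
  expect_equal(f$semi_minor, 60, tolerance = 0.5)

  d <- disc_ellipse(200, 240, 70, 55, 30 * pi / 180)
  f2 <- fit_ellipse(pallorkit:::ellipse_mask(d, 512, 512))
  expect_equal(f2$cx, 200, tolerance = 2)
  expect_equal(f2$cy, 240, tolerance = 2)
  expect_equal(f2$semi_major, 70, tolerance = 2)
  expect_equal(f2$semi_minor, 55, tolerance = 2)
  expect_lt(abs(f2$tilt - 30 * pi / 180) * 180 / pi, 2)
})

test_that("degenerate disc masks are rejected with named failures", {
  expect_error(fit_ellipse(matrix(0, 100, 100)), "empty")
  small <- matrix(0, 200, 200); small[90:110, 90:110] <- 1
  expect_error(fit_ellipse(small), "too small")
  frag <- pallorkit:::ellipse_mask(disc_ellipse(100, 100, 40, 40), 400, 400) |
    pallorkit:::ellipse_mask(disc_ellipse(300, 300, 40, 40), 400, 400)
  expect_error(fit_ellipse(frag), "fragmented")
  touching <- pallorkit:::ellipse_mask(disc_ellipse(30, 100, 40, 40), 400, 400)
  expect_error(fit_ellipse(touching), "border")
})

test_that("rotation maps the fovea onto the temporal horizontal ray", {
  d <- disc_ellipse(150, 256, 65, 60)
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))

  horiz <- rotate_to_disc_fovea_axis(img, d, c(475, 256))
  expect_equal(horiz$angle, 0, tolerance = 1e-6)
  expect_identical(horiz$image, img)

  # fovea 30 degrees above the horizontal (superior): rotated fovea ends on y = cy
  fv <- c(150 + 325 * cos(-pi / 6), 256 + 325 * sin(-pi / 6))
  rot <- rotate_to_disc_fovea_axis(img, d, fv)
  expect_equal(rot$fovea[2], 256, tolerance = 0.5)
  expect_gt(rot$fovea[1], d$cx)
  # transform round-trips
  back <- transform_points(rot$transform, rot$fovea, inverse = TRUE)
  expect_equal(as.numeric(back), fv, tolerance = 1e-9)

  expect_error(rotate_to_disc_fovea_axis(img, d, c(150, 256)), "too close")
})

test_that("crop geometry: size arithmetic, clipping warning, invariance", {
  img <- array(0.5, c(800, 800, 3))
  d <- disc_ellipse(400, 400, 60, 50, 0)
  cr <- crop_disc(img, d, margin = 60)
  expect_equal(ncol(cr$image), 2 * (60 + 60) + 1)
  expect_equal(nrow(cr$image), 2 * (50 + 60) + 1)
  expect_length(cr$warnings, 0)
  expect_equal(cr$disc$cx, 400 - cr$offset[["x"]])

  d2 <- disc_ellipse(70, 70, 60, 55, 0)
  expect_warning(crop_disc(img, d2, margin = 60), "clipped")
  expect_error(crop_disc(img, d, margin = 30), ">= 50")

  # measuring on a pre-cropped sub-image gives the same pallor as the full frame
  out <- generate_fundus(clean_scene(distinct_contrasts()))
  full <- measure_pallor(out$image, out$truth$disc, out$truth$fovea, margin = 60)
  pre <- crop_disc(out$image, out$truth$disc, margin = 80)
  fovea_crop <- out$truth$fovea - c(pre$offset[["x"]], pre$offset[["y"]])
  sub <- measure_pallor(pre$image, pre$disc, fovea_crop, margin = 60)
  for (m in pallor_measures())
    expect_equal(sub[[m]], full[[m]], tolerance = 1e-6)
})

test_that("zone assignment follows the angular layout", {
  expect_equal(pallorkit:::zone_from_angle(0), 1L)       # temporal, on-axis
  expect_equal(pallorkit:::zone_from_angle(-60), 2L)     # temporal superior
  expect_equal(pallorkit:::zone_from_angle(-100), 3L)    # nasal superior
  expect_equal(pallorkit:::zone_from_angle(180), 4L)     # nasal
  expect_equal(pallorkit:::zone_from_angle(-150), 4L)    # nasal wraps
  expect_equal(pallorkit:::zone_from_angle(100), 5L)     # nasal inferior
  expect_equal(pallorkit:::zone_from_angle(60), 6L)      # temporal inferior
  # closed temporal interval wins its endpoints
  expect_equal(pallorkit:::zone_from_angle(c(-45, 45)), c(1L, 1L))
  # sector angular spans: 90/45/45/90/45/45
  a <- seq(-179.5, 179.5, by = 1)
  expect_equal(as.vector(table(pallorkit:::zone_from_angle(a))),
               c(90, 45, 45, 90, 45, 45))
})

test_that("region masks partition the annulus and avoid the disc", {
  d <- disc_ellipse(160, 160, 100, 100, 0)
  rg <- build_regions(c(321, 321), d, measurement_depth = 30)
  n_meas <- sum(rg$measurement)
  expect_equal(n_meas, pi * (100^2 - 70^2), tolerance = 0.02)
  # zone labels cover exactly the measurement band
  expect_equal(sum(rg$zone_labels > 0), n_meas)
  expect_equal(sum(tabulate(rg$zone_labels[rg$measurement], 6)), n_meas)
  expect_false(any(rg$measurement & rg$control))
  # control excludes the disc interior
  g <- pallorkit:::coord_grid(321, 321)
  inside <- pallorkit:::ellipse_norm_radius(d, g$x, g$y) <= 1
  expect_false(any(rg$control & inside))
  # PMB is inside the temporal sector
  expect_true(all(rg$zone_labels[rg$pmb] == 1L))

  expect_error(build_regions(c(321, 321), d, measurement_depth = 100),
               "annulus")
})

test_that("pre-rotating the photograph does not move zone pallor", {
  zc <- distinct_contrasts()
  out <- generate_fundus(clean_scene(zc))
  base <- measure_pallor(out$image, out$truth$disc, out$truth$fovea)
  for (deg in c(25, 130)) {
    th <- deg * pi / 180
    tr <- pallorkit:::rigid_transform(c(255.5, 255.5), th)
    img_r <- pallorkit:::transform_image(tr, out$image)
    d0 <- out$truth$disc
    c_r <- transform_points(tr, c(d0$cx, d0$cy))
    f_r <- transform_points(tr, out$truth$fovea)
    d_r <- disc_ellipse(c_r[1], c_r[2], d0$semi_major, d0$semi_minor,
                        d0$tilt + th)
    res <- measure_pallor(img_r, d_r, f_r)
    for (m in setdiff(pallor_measures(), "nt_ratio"))
      expect_equal(res[[m]], base[[m]], tolerance = 0.01)
  }
})
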