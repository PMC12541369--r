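test_that("generators are deterministic under a fixed seed", {
  e <- ellipse_params(full_major_axis = 65, full_minor_axis = 35)
  c1 <- gen_focus_localizations("hollow", e, n_loc = 200, seed = 11)
  c2 <- gen_focus_localizations("hollow", e, n_loc = 200, seed = 11)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "seed"), 11)

  g1 <- gen_genotype_cohort(50, c(0.1, 0.2, 0.05, 0.15), missing_rate = 0.1,
                            seed = 3)
  g2 <- gen_genotype_cohort(50, c(0.1, 0.2, 0.05, 0.15), missing_rate = 0.1,
                            seed = 3)
  expect_identical(as.data.frame(g1), as.data.frame(g2))

  z1 <- gen_zone_counts(c(0.5, 4, 10, 6.5), 30, seed = 5)
  z2 <- gen_zone_counts(c(0.5, 4, 10, 6.5), 30, seed = 5)
  expect_identical(as.data.frame(z1), as.data.frame(z2))

  s1 <- gen_spot_field(data.frame(x_nm = 500, y_nm = 500, sigma_x_nm = 60,
                                  sigma_y_nm = 60, amplitude = 100),
                       pixel_size = 65, image_shape = c(16, 16),
                       noise_sd = 2, seed = 9)
  s2 <- gen_spot_field(data.frame(x_nm = 500, y_nm = 500, sigma_x_nm = 60,
                                  sigma_y_nm = 60, amplitude = 100),
                       pixel_size = 65, image_shape = c(16, 16),
                       noise_sd = 2, seed = 9)
  expect_identical(s1$image, s2$image)
})

test_that("background-only clouds are uniform in the ROI and ignore the ellipse", {
  e1 <- ellipse_params(full_major_axis = 65, full_minor_axis = 35)
  e2 <- ellipse_params(full_major_axis = 120, full_minor_axis = 20)
  c1 <- gen_focus_localizations("filled", e1, n_loc = 400,
                                background_frac = 1, roi_halfwidth = 200,
                                seed = 21)
  c2 <- gen_focus_localizations("filled", e2, n_loc = 400,
                                background_frac = 1, roi_halfwidth = 200,
                                seed = 21)
  expect_identical(c1$x_nm, c2$x_nm)
  expect_identical(c1$y_nm, c2$y_nm)
  expect_true(all(abs(c1$x_nm) <= 200) && all(abs(c1$y_nm) <= 200))
  # both ROI halves equally occupied (uniformity sanity check)
  expect_gt(min(sum(c1$x_nm > 0), sum(c1$x_nm <= 0)), 140)
})

test_that("hollow clouds without background stay near the perimeter", {
  e <- ellipse_params(full_major_axis = 65, full_minor_axis = 35)
  cl <- gen_focus_localizations("hollow", e, n_loc = 500, precision_xy = 5,
                                precision_z = 10, background_frac = 0,
                                seed = 31)
  d <- oracle_dist_to_perimeter(e, cl$x_nm, cl$y_nm)
  expect_true(all(d <= 5 * 5))
})

test_that("generator rejects invalid parameters", {
  expect_error(ellipse_params(full_major_axis = 30, full_minor_axis = 40),
               "major")
  expect_error(ellipse_params(full_major_axis = 30, full_minor_axis = -1),
               "minor")
  expect_error(gen_focus_localizations("filled", background_frac = 1.2),
               "background_frac")
  expect_error(gen_genotype_cohort(10, c(0.1, 0.2, 1.4, 0)), "probabilities")
  expect_error(gen_zone_counts(c(-1, 2), 10), "rates")
  expect_error(
    gen_spot_field(data.frame(x_nm = 1e6, y_nm = 10, sigma_x_nm = 60,
                              sigma_y_nm = 60, amplitude = 1),
                   pixel_size = 65, image_shape = c(16, 16)),
    "outside")
})

test_that("genotype cohorts recover their interval probabilities", {
  probs <- c(0.098, 0.278, 0.014, 0.181)
  n <- 10000
  g <- gen_genotype_cohort(n, probs, seed = 41)
  r <- cohort_recombination(g, marker_map())
  sds <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(r$per_interval$frequency - probs) <= 3 * sds))
})

test_that("all-zero interval probabilities give fully parental chromatids", {
  g <- gen_genotype_cohort(300, c(0, 0, 0, 0), seed = 51)
  r <- cohort_recombination(g, marker_map())
  expect_equal(r$overall$n_recombinant, 0)
  expect_equal(sum(r$per_interval$n_co), 0)
  # each chromatid is a single parental haplotype
  expect_true(all(g$A == g$E))
})

test_that("zone-count generator recovers its rates and honors rate zero", {
  rates <- c(0.5, 4, 10, 6.5)
  z <- gen_zone_counts(rates, 300, seed = 61)
  zs <- zone_summary(z)$summary
  se <- zs$sd / sqrt(zs$n)
  expect_true(all(abs(zs$mean - rates) <= 3 * se))

  z0 <- gen_zone_counts(c(0, 5), 50, seed = 62)
  expect_true(all(z0$count[z0$zone == 1] == 0))
})

test_that("noiseless empty spot field is flat at the offset", {
  sf <- gen_spot_field(NULL, pixel_size = 65, image_shape = c(16, 16),
                       noise_sd = 0, offset = 100, seed = 1)
  expect_true(all(sf$image == 100))
  expect_identical(nrow(detect_spots(sf, min_amplitude = 10,
                                     expected_sigma = 60)), 0L)
})
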