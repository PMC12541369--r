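test_that("detection recovers an isolated emitter within tolerance", {
  em <- data.frame(x_nm = 2081, y_nm = 2013, sigma_x_nm = 60,
                   sigma_y_nm = 60, amplitude = 500)
  sf <- gen_spot_field(em, pixel_size = 65, image_shape = c(64, 64),
                       noise_sd = 5, seed = 7)
  sp <- detect_spots(sf, min_amplitude = 250, expected_sigma = 60)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x_nm - 2081), 0.5 * 65)
  expect_lt(abs(sp$y_nm - 2013), 0.5 * 65)
  expect_lt(abs(sp$sigma_x_fit_nm - 60) / 60, 0.1)
  expect_lt(abs(sp$sigma_y_fit_nm - 60) / 60, 0.1)
})

test_that("well-separated emitters are detected individually", {
  em <- data.frame(x_nm = c(1800, 2200), y_nm = 2080, sigma_x_nm = 60,
                   sigma_y_nm = 60, amplitude = 500)
  sf <- gen_spot_field(em, pixel_size = 65, image_shape = c(64, 64),
                       noise_sd = 5, seed = 8)
  sp <- detect_spots(sf, min_amplitude = 250, expected_sigma = 60)
  expect_identical(nrow(sp), 2L)
  expect_equal(sort(sp$x_nm), c(1800, 2200), tolerance = 0.02)
})

test_that("detection has high recall and few false positives on spot fields", {
  # emitters kept >= 400 nm apart: performance is about detection, not
  # resolving overlapping pairs
  spaced_positions <- function(n, min_d = 400) {
    pos <- matrix(runif(2, 500, 3600), 1)
    while (nrow(pos) < n) {
      cand <- runif(2, 500, 3600)
      if (min(sqrt(colSums((t(pos) - cand)^2))) >= min_d) {
        pos <- rbind(pos, cand)
      }
    }
    pos
  }
  n_found <- 0; n_true <- 0; n_extra <- 0
  for (s in 1:25) {
    set.seed(1000 + s)
    pos <- spaced_positions(5)
    em <- data.frame(
      x_nm = pos[, 1], y_nm = pos[, 2],
      sigma_x_nm = 60, sigma_y_nm = 60, amplitude = 300)
    sf <- gen_spot_field(em, pixel_size = 65, image_shape = c(64, 64),
                         noise_sd = 10, seed = s)
    sp <- detect_spots(sf, min_amplitude = 150, expected_sigma = 60)
    d <- outer(sp$x_nm, em$x_nm, "-")^2 + outer(sp$y_nm, em$y_nm, "-")^2
    matched <- sqrt(apply(d, 2, min)) < 65
    n_true <- n_true + nrow(em)
    n_found <- n_found + sum(matched)
    n_extra <- n_extra + max(0, nrow(sp) - sum(matched))
  }
  expect_gte(n_found / n_true, 0.95)
  expect_lte(n_extra / n_true, 0.05)
})

test_that("spot shape rule is inclusive at the sigma threshold in either axis", {
  sp <- data.frame(sigma_x_fit_nm = c(75.12, 70, 60, 75.11),
                   sigma_y_fit_nm = c(50, 70, 80, 75.11))
  expect_identical(classify_spot_shape(sp),
                   c("elongated_singlet", "singlet", "elongated_singlet",
                     "singlet"))
})

test_that("anchor assignment is inclusive at the radius with index tie-break", {
  sole <- data.frame(x_nm = 0, y_nm = 0)
  # 149 nm counted, 151 nm not
  expect_identical(
    nrow(assign_to_anchor(data.frame(x_nm = 149, y_nm = 0), sole, 150)), 1L)
  expect_identical(
    nrow(assign_to_anchor(data.frame(x_nm = 151, y_nm = 0), sole, 150)), 0L)
  # equidistant spot (100 nm from both) goes to the lower anchor index;
  # otherwise the nearest anchor wins
  anchors <- data.frame(x_nm = c(0, 200), y_nm = 0)
  spots <- data.frame(x_nm = c(100, 130), y_nm = 0)
  asn <- assign_to_anchor(spots, anchors, radius = 150)
  expect_identical(asn$anchor_id, c(1L, 2L))
  # no spot is counted twice
  expect_lte(nrow(asn), nrow(spots))
})

test_that("site categories follow multiplicity and shape rules", {
  mk <- function(n, sx = 60, sy = 60) {
    data.frame(x_nm = seq_len(n) * 10, y_nm = rep(0, n),
               sigma_x_fit_nm = rep(sx, n), sigma_y_fit_nm = rep(sy, n))
  }
  expect_identical(categorize_site(mk(1), "multiplicity"), "singlet")
  expect_identical(categorize_site(mk(2), "multiplicity"), "doublet")
  expect_identical(categorize_site(mk(3), "multiplicity"), "triplet")
  expect_identical(categorize_site(mk(4), "multiplicity"), "multi")
  expect_identical(categorize_site(mk(1, sx = 80), "shape"),
                   "elongated_singlet")
  expect_identical(categorize_site(mk(1), "shape"), "singlet")
  expect_identical(categorize_site(mk(3), "shape"), "doublet")
  expect_error(categorize_site(mk(0), "multiplicity"), "empty")
})

test_that("constructed close pair categorizes as a doublet at its anchor", {
  em <- data.frame(x_nm = c(600, 700), y_nm = 640, sigma_x_nm = 25,
                   sigma_y_nm = 25, amplitude = 800)
  sf <- gen_spot_field(em, anchors = data.frame(x_nm = 650, y_nm = 640),
                       pixel_size = 20, image_shape = c(64, 64),
                       noise_sd = 4, seed = 2)
  sp <- detect_spots(sf, min_amplitude = 200, expected_sigma = 25)
  sites <- categorize_sites(assign_to_anchor(sp, sf$anchors, 150),
                            "multiplicity")
  expect_identical(sites$category, "doublet")
})

test_that("doublet span is the member distance and rejects non-doublets", {
  expect_equal(doublet_span(data.frame(x_nm = c(0, 100), y_nm = 0)), 100)
  expect_equal(doublet_span(data.frame(x_nm = c(0, 60), y_nm = c(0, 80))),
               100)
  expect_error(doublet_span(data.frame(x_nm = 1:3, y_nm = 0)), "exactly 2")
  # symmetric and rigid-motion invariant
  m <- data.frame(x_nm = c(10, 70), y_nm = c(5, 85))
  expect_equal(doublet_span(m), doublet_span(m[2:1, ]))
  phi <- 0.7
  m2 <- data.frame(x_nm = cos(phi) * m$x_nm - sin(phi) * m$y_nm + 50,
                   y_nm = sin(phi) * m$x_nm + cos(phi) * m$y_nm - 20)
  expect_equal(doublet_span(m2), doublet_span(m))
})

test_that("zone partition uses half-open bins with a closed last bin", {
  expect_identical(zone_partition(c(0, 0.25, 0.5, 0.75, 1), 4),
                   c(1L, 2L, 3L, 4L, 4L))
  expect_identical(zone_partition(0.999, 4), 4L)
  expect_identical(zone_partition(c(0, 1), 7), c(1L, 7L))
  expect_error(zone_partition(1.01, 4), "\\[0, 1\\]")
})

test_that("zone summary reports n-1 SD and pairwise Mann-Whitney", {
  counts <- data.frame(group = rep(c("wt", "mut"), each = 3),
                       zone = 1, count = c(5, 6, 7, 6, 6, 6))
  zs <- zone_summary(counts)
  wt <- zs$summary[zs$summary$group == "wt", ]
  expect_equal(wt$mean, 6)
  expect_equal(wt$sd, 1)
  mut <- zs$summary[zs$summary$group == "mut", ]
  expect_equal(mut$sd, 0)
  expect_identical(nrow(zs$pairwise), 1L)
})

test_that("site member counts never exceed total detected spots", {
  set.seed(42)
  spots <- data.frame(x_nm = runif(40, 0, 2000), y_nm = runif(40, 0, 2000))
  anchors <- data.frame(x_nm = runif(8, 0, 2000), y_nm = runif(8, 0, 2000))
  asn <- assign_to_anchor(spots, anchors, radius = 300)
  sites <- categorize_sites(asn, "multiplicity")
  expect_lte(sum(sites$n_members), nrow(spots))
  expect_identical(anyDuplicated(rownames(asn)), 0L)
  # category frequencies over the cohort account for every site
  expect_equal(sum(table(sites$category)), nrow(sites))
})
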