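make_cloud <- function(x, y, prec_xy = 5, prec_z = 10, z = 0) {
  tibble::tibble(focus_id = "f", x_nm = x, y_nm = y, z_nm = z,
                 locprec_nm = prec_xy, locprec_z_nm = prec_z,
                 channel = "MSH-5")
}

test_that("localization filter applies inclusive bounds and preserves order", {
  cl <- make_cloud(x = 1:5, y = 1:5,
                   prec_xy = c(15.0, 15.1, 5, 5, 5),
                   prec_z = c(10, 10, 25.0, 25.1, 10),
                   z = c(0, 0, 0, 0, 400))
  out <- filter_localizations(cl, z_halfwindow = 300, z_center = 0)
  # 15.0 kept, 15.1 dropped; 25.0 kept, 25.1 dropped; z = 400 dropped
  expect_identical(out$x_nm, c(1L, 3L))
  expect_identical(nrow(filter_localizations(cl[0, ])), 0L)
})

test_that("z window centers on the cloud median by default", {
  cl <- make_cloud(x = 1:3, y = 1:3, z = c(1000, 1100, 1300))
  out <- filter_localizations(cl, z_halfwindow = 300)
  expect_identical(nrow(out), 3L)  # median 1100, all within 300
  out2 <- filter_localizations(cl, z_halfwindow = 300, z_center = 0)
  expect_identical(nrow(out2), 0L)
})

test_that("filled-model density matches the uniform-ellipse closed form", {
  e <- ellipse_params(full_major_axis = 65, full_minor_axis = 35)
  expect_equal(model_density("filled", e, 0, 0, precision = 0),
               1 / (pi * 32.5 * 17.5))
  expect_equal(model_density("filled", e, 40, 0, precision = 0), 0)
  # rotation respected: point on the rotated major axis
  er <- ellipse_params(full_major_axis = 65, full_minor_axis = 35,
                       theta = pi / 2)
  expect_equal(model_density("filled", er, 0, 30, precision = 0),
               1 / (pi * 32.5 * 17.5))
  expect_equal(model_density("filled", er, 30, 0, precision = 0), 0)
})

test_that("model densities integrate to one and the ring is peaked at the perimeter", {
  e <- ellipse_params(full_major_axis = 65, full_minor_axis = 35)
  g <- expand.grid(x = seq(-130, 130, by = 2), y = seq(-130, 130, by = 2))
  for (kind in c("hollow", "filled")) {
    dens <- model_density(kind, e, g$x, g$y, precision = 5)
    expect_equal(sum(dens) * 4, 1, tolerance = 0.01)
  }
  ratio <- model_density("hollow", e, 32.5, 0, precision = 2) /
    model_density("hollow", e, 0, 0, precision = 2)
  expect_gt(ratio, 10)
  expect_error(model_density("hollow", e, 0, 0, precision = 0), "precision")
})

test_that("AICc follows the small-sample formula and its monotonicity", {
  expect_equal(aicc(-500, 5, 100), 1010.6383, tolerance = 1e-7)
  expect_equal(norm_aicc(-500, 5, 100), 10.106383, tolerance = 1e-8)
  # strictly decreasing in log-likelihood at fixed k, n
  lls <- c(-520, -510, -501, -500.5)
  expect_true(all(diff(sapply(lls, norm_aicc, k_params = 5, n_used = 80)) < 0))
  expect_error(norm_aicc(-10, 5, 6), "n_used")
})

test_that("hollow fit recovers ellipse parameters from perimeter clouds", {
  e <- ellipse_params(cx = 12, cy = -8, full_major_axis = 80,
                      full_minor_axis = 40, theta = 0.3)
  cl <- gen_focus_localizations("hollow", e, n_loc = 1000, precision_xy = 1,
                                precision_z = 5, seed = 71)
  fit <- fit_shape_model(filter_localizations(cl), "hollow")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$full_major_axis - 80) / 80, 0.05)
  expect_lt(abs(fit$params$full_minor_axis - 40) / 40, 0.05)
  expect_lt(abs(fit$params$theta - 0.3), 0.05)
})

test_that("fit refuses clouds too small for the parameter count", {
  cl <- make_cloud(x = 1:4, y = 1:4)
  expect_error(fit_shape_model(cl, "hollow"), "too few")
  cl6 <- make_cloud(x = 1:6, y = 1:6)
  expect_error(fit_shape_model(cl6, "filled"), "too few")
})

test_that("default initialization uses median center and 65/35 axes", {
  cl <- make_cloud(x = c(rnorm(20, 100, 10), 1e4), y = rnorm(21, -50, 10))
  init <- meiofoci:::default_shape_init(cl)
  expect_equal(init$full_major_axis, 65)
  expect_equal(init$full_minor_axis, 35)
  expect_equal(init$cx, median(cl$x_nm))
  expect_equal(init$cy, median(cl$y_nm))
})

test_that("log-likelihood never decreases from initialization", {
  for (s in 1:3) {
    cl <- gen_focus_localizations("filled", n_loc = 300, precision_xy = 5,
                                  precision_z = 10, seed = 80 + s)
    for (kind in c("hollow", "filled")) {
      fit <- fit_shape_model(filter_localizations(cl), kind, maxit = 200)
      expect_gte(fit$log_likelihood, fit$init_log_likelihood)
    }
  }
})

test_that("classification labels synthetic clouds by their generating model", {
  hol <- gen_focus_localizations("hollow", n_loc = 500, precision_xy = 5,
                                 precision_z = 10, seed = 91)
  fil <- gen_focus_localizations("filled", n_loc = 500, precision_xy = 5,
                                 precision_z = 10, seed = 92)
  ch <- classify_focus(hol)
  cf <- classify_focus(fil)
  expect_identical(ch$label, "hollow")
  expect_identical(cf$label, "filled")
  # with equal k and n the normAICc decision reduces to likelihood order
  for (cl in list(ch, cf)) {
    expect_identical(cl$fit_hollow$n_used, cl$fit_filled$n_used)
    expect_identical(
      cl$label,
      if (cl$fit_filled$log_likelihood > cl$fit_hollow$log_likelihood)
        "filled" else "hollow")
  }
})

test_that("exact normAICc ties are labeled hollow", {
  expect_identical(meiofoci:::shape_label_from_aicc(2.5, 2.5), "hollow")
  expect_identical(meiofoci:::shape_label_from_aicc(2.5, 2.4), "filled")
  expect_identical(meiofoci:::shape_label_from_aicc(2.4, 2.5), "hollow")
})

test_that("fits are equivariant under rigid motion of the cloud", {
  e <- ellipse_params(full_major_axis = 80, full_minor_axis = 40,
                      theta = 0.2)
  cl <- gen_focus_localizations("hollow", e, n_loc = 600, precision_xy = 3,
                                precision_z = 5, seed = 101)
  fit0 <- fit_shape_model(cl, "hollow")
  phi <- 0.4; dx <- 300; dy <- -150
  cl2 <- cl
  cl2$x_nm <- cos(phi) * cl$x_nm - sin(phi) * cl$y_nm + dx
  cl2$y_nm <- sin(phi) * cl$x_nm + cos(phi) * cl$y_nm + dy
  fit1 <- fit_shape_model(cl2, "hollow")
  c0 <- c(cos(phi) * fit0$params$cx - sin(phi) * fit0$params$cy + dx,
          sin(phi) * fit0$params$cx + cos(phi) * fit0$params$cy + dy)
  expect_lt(abs(fit1$params$cx - c0[1]), 1)
  expect_lt(abs(fit1$params$cy - c0[2]), 1)
  expect_lt(abs(fit1$params$full_major_axis - fit0$params$full_major_axis) /
              fit0$params$full_major_axis, 0.01)
  dtheta <- abs(((fit1$params$theta - fit0$params$theta - phi) + pi / 2) %%
                  pi - pi / 2)
  expect_lt(dtheta, 0.02)
})

test_that("axis recovery improves with more localizations", {
  e <- ellipse_params(full_major_axis = 80, full_minor_axis = 40)
  err <- function(n_loc, seeds) {
    mean(sapply(seeds, function(s) {
      cl <- gen_focus_localizations("hollow", e, n_loc = n_loc,
                                    precision_xy = 5, precision_z = 10,
                                    seed = s)
      f <- fit_shape_model(filter_localizations(cl), "hollow")
      abs(f$params$full_major_axis - 80) / 80 +
        abs(f$params$full_minor_axis - 40) / 40
    }))
  }
  expect_lt(err(1000, 111:115), err(250, 111:115))
})

test_that("hollow_fraction reports printed-style percentages and Fisher pairs", {
  df <- data.frame(
    genotype = rep(c("wt", "K275R"), c(21, 15)),
    label = c(rep("hollow", 13), rep("filled", 8),
              rep("hollow", 4), rep("filled", 11)))
  hf <- hollow_fraction(df)
  expect_equal(hf$summary$pct_hollow[hf$summary$genotype == "wt"], 61.9)
  expect_equal(hf$summary$pct_hollow[hf$summary$genotype == "K275R"], 26.7)
  expect_equal(round(hf$pairwise$p_value, 3), 0.049)
  df0 <- data.frame(genotype = "g", label = rep("filled", 5))
  expect_equal(hollow_fraction(df0)$summary$pct_hollow, 0)
})
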