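#' Filter SMLM localizations by z-window and localization precision
#'
#' Keeps localizations whose z coordinate lies inside a window of total width
#' `2 * z_halfwindow` and whose lateral/axial localization precisions do not
#' exceed the stated bounds. All comparisons are inclusive: a localization at
#' exactly the precision bound is retained (exclusion is strictly "greater
#' than"). Input order is preserved.
#'
#' @param cloud A localization table (data frame) with columns `x_nm`,
#'   `y_nm`, `z_nm`, `locprec_nm` (lateral precision) and `locprec_z_nm`
#'   (axial precision). See [gen_focus_localizations()] and
#'   [read_localizations()].
#' @param z_halfwindow Half-width of the accepted z window, nm (default 300,
#'   i.e. a 600 nm window).
#' @param max_precision_xy Maximum lateral localization precision, nm.
#' @param max_precision_z Maximum axial localization precision, nm.
#' @param z_center Center of the z window; defaults to the median z of the
#'   cloud (the window is not anchored to an absolute focal plane).
#'
#' @return The filtered localization table (possibly zero rows).
#' @export
filter_localizations <- function(cloud, z_halfwindow = 300,
                                 max_precision_xy = 15,
                                 max_precision_z = 25,
                                 z_center = NULL) {
  stopifnot(z_halfwindow > 0, max_precision_xy > 0, max_precision_z > 0)
  cloud <- as_tibble(cloud)
  if (nrow(cloud) == 0L) return(cloud)
  if (is.null(z_center)) z_center <- stats::median(cloud$z_nm)
  keep <- abs(cloud$z_nm - z_center) <= z_halfwindow &
    cloud$locprec_nm <= max_precision_xy &
    cloud$locprec_z_nm <= max_precision_z
  cloud[keep, , drop = FALSE]
}

#' Shape-model probability density
#'
#' Evaluates the 2-D probability density of the two geometric focus models at
#' one or more points. The hollow model places uniform line density along the
#' ellipse perimeter; the filled model places uniform area density over the
#' ellipse interior. Either is convolved with an isotropic Gaussian whose SD
#' is the localization precision of the evaluated point. Perimeter
#' convolution uses arc-length quadrature (`n_perim` nodes); interior
#' convolution uses a tensor Gauss-Legendre grid (`n_r` x `n_phi` nodes).
#' With `precision = 0` the filled density has the closed form
#' `1 / (pi * a * b)` inside the ellipse (semi-axes `a`, `b`) and 0 outside;
#' the hollow model is singular at zero precision and requires
#' `precision > 0`. The density integrates to 1 over the plane.
#'
#' @param model_kind `"hollow"` or `"filled"`.
#' @param params An [ellipse_params()] object.
#' @param x,y Point coordinates, nm (vectorized).
#' @param precision Localization precision(s), nm; scalar or one per point.
#' @param n_perim Number of perimeter quadrature nodes (hollow model).
#' @param n_r,n_phi Interior quadrature grid size (filled model).
#'
#' @return Numeric vector of densities, nm^-2.
#' @export
#' @examples
#' e <- ellipse_params(full_major_axis = 65, full_minor_axis = 35)
#' model_density("filled", e, 0, 0, precision = 0)  # 1 / (pi * 32.5 * 17.5)
model_density <- function(model_kind = c("hollow", "filled"), params, x, y,
                          precision, n_perim = 256, n_r = 32, n_phi = 32) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(params, "ellipse_params"), length(x) == length(y))
  if (any(precision < 0)) stop("precision must be >= 0", call. = FALSE)
  precision <- rep_len(as.numeric(precision), length(x))

  if (model_kind == "filled" && all(precision == 0)) {
    dens <- ifelse(inside_ellipse(params, x, y),
                   1 / (pi * params$a * params$b), 0)
    return(dens)
  }
  if (any(precision == 0)) {
    if (model_kind == "hollow") {
      stop("hollow model density requires precision > 0", call. = FALSE)
    }
    out <- numeric(length(x))
    z <- precision == 0
    out[z] <- model_density("filled", params, x[z], y[z], 0)
    out[!z] <- model_density("filled", params, x[!z], y[!z], precision[!z],
                             n_perim, n_r, n_phi)
    return(out)
  }

  q <- if (model_kind == "hollow") {
    ellipse_perimeter_quadrature(params, n_perim)
  } else {
    ellipse_interior_quadrature(params, n_r, n_phi)
  }
  gauss_mixture_density_cpp(as.numeric(x), as.numeric(y), precision,
                            q$x, q$y, q$w)
}

#' Corrected AIC and its normalized form
#'
#' `aicc()` computes the small-sample corrected Akaike Information Criterion,
#' `AICc = -2 * logLik + 2k + 2k(k + 1)/(n - k - 1)`; `norm_aicc()` divides it
#' by the number of localizations used, making fits on clouds of different
#' sizes comparable on a per-localization scale. Lower values indicate a
#' better model. Both require `n_used > k_params + 1`.
#'
#' @param log_likelihood Maximized log-likelihood, nats.
#' @param k_params Number of free model parameters.
#' @param n_used Number of observations (localizations) used in the fit.
#'
#' @return A single number.
#' @export
#' @examples
#' aicc(-500, 5, 100)       # 1010.6383
#' norm_aicc(-500, 5, 100)  # 10.106383
aicc <- function(log_likelihood, k_params, n_used) {
  if (n_used <= k_params + 1) {
    stop("AICc undefined: n_used must exceed k_params + 1", call. = FALSE)
  }
  -2 * log_likelihood + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_used - k_params - 1)
}

#' @rdname aicc
#' @export
norm_aicc <- function(log_likelihood, k_params, n_used) {
  aicc(log_likelihood, k_params, n_used) / n_used
}

# Default initialization: center at coordinate-wise median, full axes
# init_full_axes, orientation from the principal direction of the
# coordinates.
default_shape_init <- function(cloud, init_full_axes = c(65, 35)) {
  cx <- stats::median(cloud$x_nm)
  cy <- stats::median(cloud$y_nm)
  theta <- 0
  if (nrow(cloud) >= 3) {
    cc <- stats::cov(cbind(cloud$x_nm, cloud$y_nm))
    ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
    theta <- atan2(ev[2], ev[1])
  }
  ellipse_params(cx, cy, max(init_full_axes), min(init_full_axes), theta)
}

# Canonical (a >= b, theta in [0, pi)) version of a raw parameter vector.
canonical_ellipse <- function(cx, cy, a, b, theta) {
  if (b > a) { tmp <- a; a <- b; b <- tmp; theta <- theta + pi / 2 }
  ellipse_params(cx, cy, 2 * a, 2 * b, theta)
}

#' Fit a geometric shape model to a localization cloud
#'
#' Maximum-likelihood fit of the hollow-ring or filled-ellipse model to the
#' lateral (x, y) coordinates of a filtered localization cloud, with each
#' localization's own lateral precision as the Gaussian convolution width.
#' The fit is initialized at the coordinate-wise median center, full axes of
#' 65 and 35 nm, and the principal direction of the coordinates, then refined
#' by derivative-free (Nelder-Mead) search with semi-axes bounded to
#' [5, 500] nm. Fitting is 2-D: z is used only by [filter_localizations()].
#'
#' @param cloud Filtered localization table (columns `x_nm`, `y_nm`,
#'   `locprec_nm`); must contain more than `k + 1 = 6` localizations.
#' @param model_kind `"hollow"` or `"filled"`.
#' @param init Optional [ellipse_params()] initialization overriding the
#'   default.
#' @param init_full_axes Full axis lengths used by the default
#'   initialization, nm.
#' @param maxit Maximum Nelder-Mead iterations.
#'
#' @return An object of class `shape_fit`: list with `model_kind`, `params`
#'   (fitted [ellipse_params()]), `log_likelihood`, `init_log_likelihood`,
#'   `n_used`, `k_params` (= 5), `norm_aicc`, and `converged`.
#' @export
fit_shape_model <- function(cloud, model_kind = c("hollow", "filled"),
                            init = NULL, init_full_axes = c(65, 35),
                            maxit = 500) {
  model_kind <- match.arg(model_kind)
  cloud <- as_tibble(cloud)
  k <- 5L
  n <- nrow(cloud)
  if (n <= k + 1L) {
    stop(sprintf("too few localizations for a %d-parameter fit: n = %d (need > %d)",
                 k, n, k + 1L), call. = FALSE)
  }
  if (is.null(init)) init <- default_shape_init(cloud, init_full_axes)

  x <- cloud$x_nm; y <- cloud$y_nm; prec <- cloud$locprec_nm
  semi_lo <- 5; semi_hi <- 500

  negll <- function(par) {
    a <- par[3]; b <- par[4]
    if (min(a, b) < semi_lo || max(a, b) > semi_hi) return(1e10)
    p <- canonical_ellipse(par[1], par[2], a, b, par[5])
    d <- model_density(model_kind, p, x, y, prec)
    -sum(log(pmax(d, 1e-300)))
  }

  par0 <- c(init$cx, init$cy, init$a, init$b, init$theta)
  ll0 <- -negll(par0)
  opt <- stats::optim(par0, negll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8,
                                     parscale = c(10, 10, 10, 10, 0.3)))
  ll <- -opt$value
  # Guard: never report a fit worse than its initialization.
  if (ll < ll0) {
    opt$par <- par0
    ll <- ll0
  }
  params <- canonical_ellipse(opt$par[1], opt$par[2], opt$par[3], opt$par[4],
                              opt$par[5])
  structure(
    list(model_kind = model_kind,
         params = params,
         log_likelihood = ll,
         init_log_likelihood = ll0,
         n_used = n,
         k_params = k,
         norm_aicc = norm_aicc(ll, k, n),
         converged = opt$convergence == 0L),
    class = "shape_fit"
  )
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf(
    "<shape_fit: %s> n = %d, logLik = %.2f, normAICc = %.4f, axes %.1f x %.1f nm, theta %.3f\n",
    x$model_kind, x$n_used, x$log_likelihood, x$norm_aicc,
    x$params$full_major_axis, x$params$full_minor_axis, x$params$theta))
  invisible(x)
}

# Decision rule shared by classify_focus and documented directly: a focus is
# "filled" only when the filled model's normAICc is strictly smaller; exact
# ties go to "hollow".
shape_label_from_aicc <- function(norm_aicc_hollow, norm_aicc_filled) {
  ifelse(norm_aicc_filled < norm_aicc_hollow, "filled", "hollow")
}

#' Classify a focus as hollow ring or filled ellipse
#'
#' Fits both geometric models to the same filtered localization set and
#' labels the focus by normAICc comparison: `"filled"` when the filled
#' model's normAICc is strictly smaller than the hollow model's, otherwise
#' `"hollow"` (exact ties go to hollow). With both models sharing `k = 5`
#' parameters and the same `n`, the decision is equivalent to comparing
#' log-likelihoods.
#'
#' @param cloud Localization table for a single focus.
#' @param filter Apply [filter_localizations()] first (default `TRUE`).
#' @param focus_id Label for the focus; defaults to the table's `focus_id`
#'   column if present.
#' @inheritParams filter_localizations
#' @inheritParams fit_shape_model
#'
#' @return An object of class `focus_classification`: list with `focus_id`,
#'   `label` (`"hollow"` or `"filled"`), `fit_hollow` and `fit_filled`.
#' @export
classify_focus <- function(cloud, filter = TRUE, focus_id = NULL,
                           z_halfwindow = 300, max_precision_xy = 15,
                           max_precision_z = 25, init_full_axes = c(65, 35),
                           maxit = 500) {
  cloud <- as_tibble(cloud)
  if (is.null(focus_id)) {
    focus_id <- if ("focus_id" %in% names(cloud)) as.character(cloud$focus_id[1]) else NA_character_
  }
  if (filter) {
    cloud <- filter_localizations(cloud, z_halfwindow, max_precision_xy,
                                  max_precision_z)
  }
  fit_h <- fit_shape_model(cloud, "hollow", init_full_axes = init_full_axes,
                           maxit = maxit)
  fit_f <- fit_shape_model(cloud, "filled", init_full_axes = init_full_axes,
                           maxit = maxit)
  structure(
    list(focus_id = focus_id,
         label = shape_label_from_aicc(fit_h$norm_aicc, fit_f$norm_aicc),
         fit_hollow = fit_h,
         fit_filled = fit_f),
    class = "focus_classification"
  )
}

#' @export
print.focus_classification <- function(x, ...) {
  cat(sprintf("<focus_classification> %s: %s (normAICc hollow %.4f, filled %.4f)\n",
              x$focus_id, x$label, x$fit_hollow$norm_aicc,
              x$fit_filled$norm_aicc))
  invisible(x)
}

#' Classify every focus in a localization table
#'
#' Driver over [classify_focus()] for a table holding several foci
#' distinguished by a `focus_id` column (and optionally a grouping column
#' such as genotype, carried through to the output).
#'
#' @param localizations Localization table with a `focus_id` column.
#' @param group_col Optional name of a per-focus grouping column (e.g.
#'   `"genotype"`) carried into the result.
#' @inheritParams classify_focus
#'
#' @return A tibble with one row per focus: `focus_id`, optional group
#'   column, `label`, `norm_aicc_hollow`, `norm_aicc_filled`, fitted full
#'   axes and orientation of the winning model.
#' @export
classify_foci <- function(localizations, group_col = NULL, filter = TRUE,
                          z_halfwindow = 300, max_precision_xy = 15,
                          max_precision_z = 25, init_full_axes = c(65, 35),
                          maxit = 500) {
  localizations <- as_tibble(localizations)
  stopifnot("focus_id" %in% names(localizations))
  ids <- unique(localizations$focus_id)
  rows <- lapply(ids, function(id) {
    sub <- localizations[localizations$focus_id == id, , drop = FALSE]
    cl <- classify_focus(sub, filter = filter, focus_id = as.character(id),
                         z_halfwindow = z_halfwindow,
                         max_precision_xy = max_precision_xy,
                         max_precision_z = max_precision_z,
                         init_full_axes = init_full_axes, maxit = maxit)
    win <- if (cl$label == "hollow") cl$fit_hollow else cl$fit_filled
    out <- tibble(
      focus_id = as.character(id),
      label = cl$label,
      norm_aicc_hollow = cl$fit_hollow$norm_aicc,
      norm_aicc_filled = cl$fit_filled$norm_aicc,
      full_major_axis_nm = win$params$full_major_axis,
      full_minor_axis_nm = win$params$full_minor_axis,
      theta_rad = win$params$theta,
      n_used = win$n_used
    )
    if (!is.null(group_col)) out[[group_col]] <- sub[[group_col]][1]
    out
  })
  dplyr::bind_rows(rows)
}

#' Hollow-focus fraction per group with pairwise Fisher tests
#'
#' Summarizes focus classifications per group (typically genotype) as the
#' count and percentage of hollow foci, and compares every pair of groups
#' with the two-sided Fisher's exact test on the hollow / not-hollow counts.
#'
#' @param classifications Data frame with columns `label` (`"hollow"` /
#'   `"filled"`) and the grouping column.
#' @param group_col Name of the grouping column (default `"genotype"`).
#'
#' @return A list with `summary` (tibble: group, `n`, `n_hollow`,
#'   `pct_hollow` rounded to 1 decimal) and `pairwise` (tibble: both groups,
#'   odds ratio, two-sided p).
#' @export
#' @examples
#' df <- data.frame(
#'   genotype = rep(c("wt", "mut"), c(21, 15)),
#'   label = c(rep("hollow", 13), rep("filled", 8),
#'             rep("hollow", 4), rep("filled", 11)))
#' hollow_fraction(df)
hollow_fraction <- function(classifications, group_col = "genotype") {
  classifications <- as_tibble(classifications)
  stopifnot(group_col %in% names(classifications),
            "label" %in% names(classifications))
  g <- classifications[[group_col]]
  groups <- unique(g)
  summary <- dplyr::bind_rows(lapply(groups, function(gr) {
    lab <- classifications$label[g == gr]
    n <- length(lab)
    if (n == 0L) stop("empty group: ", gr, call. = FALSE)
    nh <- sum(lab == "hollow")
    row <- tibble(group = gr, n = n, n_hollow = nh,
                  pct_hollow = round(100 * nh / n, 1))
    names(row)[1] <- group_col
    row
  }))
  pairwise <- NULL
  if (length(groups) >= 2L) {
    prs <- utils::combn(as.character(groups), 2, simplify = FALSE)
    pairwise <- dplyr::bind_rows(lapply(prs, function(pr) {
      s1 <- summary[summary[[group_col]] == pr[1], ]
      s2 <- summary[summary[[group_col]] == pr[2], ]
      ft <- fisher_exact(matrix(c(s1$n_hollow, s1$n - s1$n_hollow,
                                  s2$n_hollow, s2$n - s2$n_hollow),
                                nrow = 2, byrow = TRUE))
      tibble(group_1 = pr[1], group_2 = pr[2],
             odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }))
  }
  list(summary = summary, pairwise = pairwise)
}
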