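#' Classification label-recovery benchmark
#'
#' Generates seeded synthetic clouds from each shape model under the
#' standard benchmark conditions (500 localizations, 5 nm lateral
#' precision, no background, 65 x 35 nm full axes) and reports how often
#' [classify_focus()] recovers the generating label.
#'
#' @param n_per_class Clouds per shape class.
#' @param n_loc,precision_xy,precision_z,background_frac Generator settings
#'   per cloud.
#' @param ellipse Generating [ellipse_params()].
#' @param seed Base seed; cloud `i` of class `k` uses `seed*1000 +
#'   k*n_per_class + i`.
#'
#' @return A tibble per class: `shape_kind`, `n`, `n_correct`,
#'   `agreement_pct`.
#' @export
label_recovery_benchmark <- function(n_per_class = 100, n_loc = 500,
                                     precision_xy = 5, precision_z = 10,
                                     background_frac = 0,
                                     ellipse = ellipse_params(),
                                     seed = 1) {
  kinds <- c("hollow", "filled")
  rows <- lapply(seq_along(kinds), function(k) {
    correct <- vapply(seq_len(n_per_class), function(i) {
      cl <- gen_focus_localizations(
        kinds[k], ellipse, n_loc = n_loc, precision_xy = precision_xy,
        precision_z = precision_z, background_frac = background_frac,
        seed = seed * 1000L + k * n_per_class + i)
      classify_focus(cl)$label == kinds[k]
    }, logical(1))
    tibble(shape_kind = kinds[k], n = n_per_class,
           n_correct = sum(correct),
           agreement_pct = 100 * mean(correct))
  })
  dplyr::bind_rows(rows)
}

#' Hollow-fit parameter-recovery benchmark
#'
#' Fits the hollow-ring model to near-noiseless perimeter clouds (1 nm
#' precision) and reports the worst-case relative axis errors and absolute
#' rotation error across seeds.
#'
#' @param n_seeds Number of independent clouds.
#' @param n_loc Localizations per cloud.
#' @param precision_xy Lateral precision, nm.
#' @param ellipse Generating [ellipse_params()] (default 80 x 40 nm at
#'   theta 0.3).
#' @param seed Base seed.
#'
#' @return A tibble per seed: fitted axes, theta, and error columns
#'   `err_major`, `err_minor` (relative), `err_theta` (rad).
#' @export
axis_recovery_benchmark <- function(n_seeds = 20, n_loc = 1000,
                                    precision_xy = 1,
                                    ellipse = ellipse_params(
                                      full_major_axis = 80,
                                      full_minor_axis = 40, theta = 0.3),
                                    seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cl <- gen_focus_localizations("hollow", ellipse, n_loc = n_loc,
                                  precision_xy = precision_xy,
                                  precision_z = 5,
                                  seed = seed * 1000L + i)
    fit <- fit_shape_model(filter_localizations(cl), "hollow")
    dtheta <- abs(((fit$params$theta - ellipse$theta) + pi / 2) %% pi -
                    pi / 2)
    tibble(seed = seed * 1000L + i,
           full_major_axis = fit$params$full_major_axis,
           full_minor_axis = fit$params$full_minor_axis,
           theta = fit$params$theta,
           err_major = abs(fit$params$full_major_axis -
                             ellipse$full_major_axis) /
             ellipse$full_major_axis,
           err_minor = abs(fit$params$full_minor_axis -
                             ellipse$full_minor_axis) /
             ellipse$full_minor_axis,
           err_theta = dtheta)
  })
  dplyr::bind_rows(rows)
}
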