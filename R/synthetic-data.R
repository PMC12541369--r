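#' Localization-precision distribution specification
#'
#' Localization precisions in the simulator are drawn from a lognormal
#' distribution with a given median, truncated (by resampling) at an upper
#' bound so that most simulated localizations survive the analysis filters.
#' A plain number may be used instead anywhere a `precision_spec` is
#' accepted, giving every localization that constant precision.
#'
#' @param median Median precision, nm.
#' @param sdlog SD of the underlying normal on the log scale.
#' @param max Upper truncation bound, nm.
#'
#' @return A list of class `precision_spec`.
#' @export
precision_spec <- function(median = 8, sdlog = 0.35, max = 15) {
  stopifnot(median > 0, sdlog >= 0, max > median)
  structure(list(median = median, sdlog = sdlog, max = max),
            class = "precision_spec")
}

draw_precision <- function(n, spec) {
  if (is.numeric(spec)) return(rep_len(spec, n))
  stopifnot(inherits(spec, "precision_spec"))
  out <- stats::rlnorm(n, meanlog = log(spec$median), sdlog = spec$sdlog)
  while (any(bad <- out > spec$max)) {
    out[bad] <- stats::rlnorm(sum(bad), meanlog = log(spec$median),
                              sdlog = spec$sdlog)
  }
  out
}

#' Simulate an SMLM localization cloud for a single focus
#'
#' Draws localizations from one of the two geometric focus models. Each
#' localization is, with probability `1 - background_frac`, a model point --
#' uniform along the ellipse perimeter (`"hollow"`) or uniform over the
#' interior (`"filled"`) -- displaced laterally by a Gaussian with that
#' localization's drawn precision; otherwise it is background, uniform over
#' a square ROI of half-width `roi_halfwidth` centered on the ellipse
#' center. z coordinates of model points sit in a Gaussian slab (SD
#' `z_slab_sd` around 0) plus axial localization error; background z is
#' uniform across the analysis z-window. The same configuration and seed
#' always reproduce the identical cloud.
#'
#' @param shape_kind `"hollow"` or `"filled"`: the generating model.
#' @param ellipse An [ellipse_params()] object (default 65 x 35 nm full
#'   axes at the origin).
#' @param n_loc Number of localizations (>= 1).
#' @param precision_xy,precision_z Lateral/axial precision: a constant (nm)
#'   or a [precision_spec()]. Defaults: lognormal, median 8 nm truncated at
#'   15 nm laterally; median 15 nm truncated at 25 nm axially.
#' @param background_frac Fraction of localizations drawn from the uniform
#'   background, in `[0, 1]`.
#' @param roi_halfwidth Half-width of the square background ROI, nm.
#' @param z_slab_sd SD of the z slab for model points, nm.
#' @param seed Integer seed; recorded in the output's attributes.
#' @param focus_id,channel Labels written into the table.
#'
#' @return A tibble with columns `focus_id`, `x_nm`, `y_nm`, `z_nm`,
#'   `locprec_nm`, `locprec_z_nm`, `channel`, and attributes `seed` and
#'   `truth` (the generating label and ellipse).
#' @export
#' @examples
#' cl <- gen_focus_localizations("hollow", n_loc = 200, precision_xy = 5,
#'                               precision_z = 10, seed = 1)
gen_focus_localizations <- function(shape_kind = c("hollow", "filled"),
                                    ellipse = ellipse_params(),
                                    n_loc = 500,
                                    precision_xy = precision_spec(8, 0.35, 15),
                                    precision_z = precision_spec(15, 0.35, 25),
                                    background_frac = 0,
                                    roi_halfwidth = 200,
                                    z_slab_sd = 30,
                                    seed = 1,
                                    focus_id = "focus_1",
                                    channel = "MSH-5") {
  shape_kind <- match.arg(shape_kind)
  stopifnot(inherits(ellipse, "ellipse_params"), n_loc >= 1,
            roi_halfwidth > 0)
  if (background_frac < 0 || background_frac > 1) {
    stop("background_frac must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    prec_xy <- draw_precision(n_loc, precision_xy)
    prec_z <- draw_precision(n_loc, precision_z)
    is_bg <- runif(n_loc) < background_frac
    n_mod <- sum(!is_bg)

    x <- y <- z <- numeric(n_loc)
    if (n_mod > 0) {
      if (shape_kind == "hollow") {
        t <- sample_perimeter_param(ellipse, n_mod)
        p <- ellipse_to_world(ellipse, ellipse$a * cos(t), ellipse$b * sin(t))
      } else {
        r <- sqrt(runif(n_mod)); phi <- runif(n_mod, 0, 2 * pi)
        p <- ellipse_to_world(ellipse, ellipse$a * r * cos(phi),
                              ellipse$b * r * sin(phi))
      }
      x[!is_bg] <- p$x + rnorm(n_mod, 0, prec_xy[!is_bg])
      y[!is_bg] <- p$y + rnorm(n_mod, 0, prec_xy[!is_bg])
      z[!is_bg] <- rnorm(n_mod, 0, z_slab_sd) +
        rnorm(n_mod, 0, prec_z[!is_bg])
    }
    if (any(is_bg)) {
      n_bg <- sum(is_bg)
      x[is_bg] <- runif(n_bg, ellipse$cx - roi_halfwidth,
                        ellipse$cx + roi_halfwidth)
      y[is_bg] <- runif(n_bg, ellipse$cy - roi_halfwidth,
                        ellipse$cy + roi_halfwidth)
      z[is_bg] <- runif(n_bg, -300, 300)
    }
    out <- tibble(
      focus_id = focus_id,
      x_nm = x, y_nm = y, z_nm = z,
      locprec_nm = prec_xy, locprec_z_nm = prec_z,
      channel = channel
    )
    attr(out, "seed") <- seed
    attr(out, "truth") <- list(shape_kind = shape_kind, ellipse = ellipse,
                               background_frac = background_frac,
                               roi_halfwidth = roi_halfwidth)
    out
  })
}

#' Simulate a 2-D image of point emitters with anchor ground truth
#'
#' Renders anisotropic Gaussian emitters onto a pixel grid, adds a constant
#' offset and Gaussian read noise, and returns the image together with the
#' ground-truth emitter and anchor tables for oracle comparison. Pixel `(r,
#' c)` covers physical coordinates `((c-1)*pixel_size, c*pixel_size]` in x
#' and likewise for y; centers sit at `(c - 0.5) * pixel_size`.
#'
#' @param emitters Data frame with columns `x_nm`, `y_nm`, `sigma_x_nm`,
#'   `sigma_y_nm`, `amplitude`; may have zero rows.
#' @param anchors Data frame with columns `x_nm`, `y_nm` (e.g. the
#'   crossover-site channel); may be `NULL`.
#' @param pixel_size Pixel size, nm (> 0).
#' @param image_shape Image size in pixels, `c(n_rows, n_cols)` (y, x).
#' @param noise_sd Gaussian read-noise SD, intensity units.
#' @param offset Constant background offset, intensity units.
#' @param seed Integer seed.
#'
#' @return A list of class `spot_field`: `image` (matrix, rows = y),
#'   `pixel_size`, `emitters`, `anchors`, `seed`.
#' @export
gen_spot_field <- function(emitters, anchors = NULL, pixel_size = 65,
                           image_shape = c(64, 64), noise_sd = 1,
                           offset = 100, seed = 1) {
  stopifnot(pixel_size > 0, length(image_shape) == 2)
  emitters <- if (is.null(emitters)) {
    tibble(x_nm = numeric(), y_nm = numeric(), sigma_x_nm = numeric(),
           sigma_y_nm = numeric(), amplitude = numeric())
  } else as_tibble(emitters)
  ny <- image_shape[1]; nx <- image_shape[2]
  wx <- nx * pixel_size; wy <- ny * pixel_size
  if (nrow(emitters) > 0 &&
      any(emitters$x_nm < 0 | emitters$x_nm > wx |
          emitters$y_nm < 0 | emitters$y_nm > wy)) {
    stop("emitter outside image bounds", call. = FALSE)
  }
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  img <- matrix(offset, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(emitters))) {
    gx <- exp(-(xc - emitters$x_nm[i])^2 / (2 * emitters$sigma_x_nm[i]^2))
    gy <- exp(-(yc - emitters$y_nm[i])^2 / (2 * emitters$sigma_y_nm[i]^2))
    img <- img + emitters$amplitude[i] * (gy %o% gx)
  }
  withr::with_seed(seed, {
    if (noise_sd > 0) img <- img + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
  })
  structure(list(image = img, pixel_size = pixel_size, emitters = emitters,
                 anchors = if (is.null(anchors)) NULL else as_tibble(anchors),
                 seed = seed),
            class = "spot_field")
}

#' Simulate a genotyped progeny cohort for five ordered SNP markers
#'
#' Each progeny contributes one chromatid scored at five ordered markers
#' (A-E). The call at marker A is drawn uniformly from Bristol (`"B"`) /
#' Hawaiian (`"H"`); each of the four intervals then flips the parental
#' phase independently with its own probability (no crossover interference).
#' Calls are masked to missing (`NA`) at `missing_rate`.
#'
#' @param n_progeny Number of progeny (chromatids).
#' @param interval_probs Numeric length-4 vector of per-interval crossover
#'   probabilities for intervals AB, BC, CD, DE, each in `[0, 1]`.
#' @param missing_rate Fraction of calls masked to missing.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `progeny_id`, `A` .. `E` (values `"B"`,
#'   `"H"`, or `NA`), with attribute `seed`.
#' @export
#' @examples
#' gen_genotype_cohort(5, c(0.098, 0.278, 0.014, 0.181), seed = 1)
gen_genotype_cohort <- function(n_progeny,
                                interval_probs = c(0.098, 0.278, 0.014, 0.181),
                                missing_rate = 0, seed = 1) {
  stopifnot(n_progeny >= 1, length(interval_probs) == 4)
  if (any(interval_probs < 0 | interval_probs > 1)) {
    stop("interval probabilities must be in [0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    phase0 <- sample(c(0L, 1L), n_progeny, replace = TRUE)
    flips <- sapply(interval_probs,
                    function(p) as.integer(runif(n_progeny) < p))
    flips <- matrix(flips, nrow = n_progeny)
    phases <- cbind(phase0,
                    (phase0 + t(apply(flips, 1, cumsum))) %% 2L)
    calls <- matrix(c("B", "H")[phases + 1L], nrow = n_progeny)
    if (missing_rate > 0) {
      calls[matrix(runif(length(calls)) < missing_rate,
                   nrow = n_progeny)] <- NA_character_
    }
    out <- as_tibble(as.data.frame(calls, stringsAsFactors = FALSE))
    names(out) <- LETTERS[1:5]
    out <- dplyr::bind_cols(
      tibble(progeny_id = sprintf("p%04d", seq_len(n_progeny))), out)
    attr(out, "seed") <- seed
    attr(out, "truth") <- list(interval_probs = interval_probs,
                               missing_rate = missing_rate)
    out
  })
}

#' Simulate per-nucleus focus counts across gonad zones
#'
#' Draws integer focus counts per nucleus and zone from a Poisson
#' distribution (or negative binomial when `dispersion` is given), emulating
#' the zone-wise focus-count tables scored along the gonad's spatial
#' time-course.
#'
#' @param zone_means Numeric vector of per-zone mean counts (>= 0).
#' @param n_nuclei_per_zone Integer count per zone (recycled if scalar).
#' @param dispersion Optional negative-binomial size parameter (recycled);
#'   `NULL` for Poisson.
#' @param group Group label (e.g. genotype) written into the table.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `nucleus_id`, `group`, `zone`, `count`,
#'   with attribute `seed`.
#' @export
gen_zone_counts <- function(zone_means, n_nuclei_per_zone,
                            dispersion = NULL, group = "wt", seed = 1) {
  if (any(zone_means < 0)) stop("zone rates must be >= 0", call. = FALSE)
  nz <- length(zone_means)
  n_nuclei_per_zone <- rep_len(n_nuclei_per_zone, nz)
  if (!is.null(dispersion)) dispersion <- rep_len(dispersion, nz)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nz), function(z) {
      n <- n_nuclei_per_zone[z]
      counts <- if (is.null(dispersion)) {
        rpois(n, zone_means[z])
      } else {
        rnbinom(n, size = dispersion[z], mu = zone_means[z])
      }
      tibble(nucleus_id = sprintf("z%d_n%04d", z, seq_len(n)),
             group = group, zone = z, count = counts)
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "seed") <- seed
    attr(out, "truth") <- list(zone_means = zone_means)
    out
  })
}
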