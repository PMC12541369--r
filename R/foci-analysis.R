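# Difference-of-Gaussians response of a unit-amplitude Gaussian of SD s0
# (pixels) under blurs s1 < s2: peak amplitude factor in 2-D.
dog_peak_factor <- function(s0, s1, s2) {
  s0^2 / (s0^2 + s1^2) - s0^2 / (s0^2 + s2^2)
}

# Anisotropic Gaussian + offset least-squares refinement in a local window.
# (cand_r, cand_c) is the candidate maximum in local pixel coordinates; the
# fitted center is confined to its vicinity so an overlapping neighbor spot
# inside the window cannot capture the fit. Returns parameters in pixel
# units (centers in pixel coordinates where pixel c covers (c-1, c]).
fit_gaussian_window <- function(win, r0, c0, cand_r, cand_c, max_shift = 2.5) {
  ny <- nrow(win); nx <- ncol(win)
  cc <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
  rr <- matrix(rep(seq_len(ny) - 0.5, times = nx), ny, nx)
  off0 <- min(win); amp0 <- max(win) - off0
  wgt <- pmax(win - off0, 0)
  sw <- sum(wgt)
  cx0 <- cand_c - 0.5
  cy0 <- cand_r - 0.5
  sx0 <- max(0.8, sqrt(max(sum(wgt * (cc - cx0)^2) / max(sw, 1e-9), 0.25)))
  sy0 <- max(0.8, sqrt(max(sum(wgt * (rr - cy0)^2) / max(sw, 1e-9), 0.25)))

  sse <- function(par) {
    amp <- par[1]; cx <- par[2]; cy <- par[3]
    sx <- par[4]; sy <- par[5]; off <- par[6]
    if (amp <= 0 || sx < 0.25 || sy < 0.25 || sx > nx || sy > ny ||
        abs(cx - (cand_c - 0.5)) > max_shift ||
        abs(cy - (cand_r - 0.5)) > max_shift) return(1e12)
    model <- off + amp * exp(-((cc - cx)^2 / (2 * sx^2) +
                               (rr - cy)^2 / (2 * sy^2)))
    sum((win - model)^2)
  }
  opt <- stats::optim(c(amp0, cx0, cy0, sx0, sy0, off0), sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  # restart once: Nelder-Mead on 6 parameters can stall on a shrunk simplex
  opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- opt$par
  list(amplitude = p[1],
       x_px = c0 - 1 + p[2], y_px = r0 - 1 + p[3],
       sigma_x_px = p[4], sigma_y_px = p[5], offset = p[6],
       sse = opt$value)
}

#' Detect diffraction-limited spots in a 2-D image
#'
#' Band-pass spot detection followed by sub-pixel Gaussian refinement:
#' candidate maxima are local maxima of a difference-of-Gaussians (DoG)
#' response tuned to `expected_sigma`; each candidate is refined by
#' least-squares fitting of an anisotropic 2-D Gaussian plus constant offset
#' in a local window, and kept if its fitted amplitude reaches
#' `min_amplitude`. Centers are returned in nm (sub-pixel), sigmas converted
#' from pixels to nm.
#'
#' @param image Numeric matrix (rows = y) or a `spot_field` from
#'   [gen_spot_field()].
#' @param pixel_size Pixel size, nm (taken from the `spot_field` if given).
#' @param min_amplitude Minimum fitted amplitude above local offset.
#' @param expected_sigma Expected spot SD, nm; sets the DoG scales and the
#'   fitting window.
#'
#' @return A tibble of spots: `spot_id`, `x_nm`, `y_nm`, `amplitude`,
#'   `sigma_x_fit_nm`, `sigma_y_fit_nm`, `offset`. Zero rows when nothing is
#'   found.
#' @export
detect_spots <- function(image, pixel_size = NULL, min_amplitude,
                         expected_sigma = 100) {
  if (inherits(image, "spot_field")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    image <- image$image
  }
  stopifnot(is.matrix(image), !is.null(pixel_size), pixel_size > 0,
            expected_sigma > 0)
  empty <- tibble(spot_id = character(), x_nm = numeric(), y_nm = numeric(),
                  amplitude = numeric(), sigma_x_fit_nm = numeric(),
                  sigma_y_fit_nm = numeric(), offset = numeric())
  ny <- nrow(image); nx <- ncol(image)
  if (ny < 5 || nx < 5) return(empty)

  s_px <- expected_sigma / pixel_size
  s1 <- max(0.5, s_px); s2 <- 1.6 * s1
  g1 <- EBImage::gblur(image, sigma = s1, boundary = "replicate")
  g2 <- EBImage::gblur(image, sigma = s2, boundary = "replicate")
  resp <- g1 - g2
  # candidate gate: half the DoG response a spot at threshold amplitude
  # and expected width would produce
  cand_thr <- 0.5 * min_amplitude * dog_peak_factor(s_px, s1, s2)

  is_max <- matrix(FALSE, ny, nx)
  inner_r <- 2:(ny - 1); inner_c <- 2:(nx - 1)
  ctr <- resp[inner_r, inner_c]
  nb_ok <- ctr >= resp[inner_r - 1, inner_c - 1] &
    ctr >= resp[inner_r - 1, inner_c] &
    ctr >= resp[inner_r - 1, inner_c + 1] &
    ctr >= resp[inner_r, inner_c - 1] &
    ctr >= resp[inner_r, inner_c + 1] &
    ctr >= resp[inner_r + 1, inner_c - 1] &
    ctr >= resp[inner_r + 1, inner_c] &
    ctr >= resp[inner_r + 1, inner_c + 1]
  is_max[inner_r, inner_c] <- nb_ok & (ctr > cand_thr)
  cand <- which(is_max, arr.ind = TRUE)
  dimnames(cand) <- NULL
  if (nrow(cand) == 0L) return(empty)

  # merge candidates closer than 2 px, keeping the stronger response
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][d2 < 4] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  w <- max(4L, as.integer(ceiling(3.5 * s_px)))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    r1 <- max(1, r - w); r2 <- min(ny, r + w)
    c1 <- max(1, c - w); c2 <- min(nx, c + w)
    fit <- fit_gaussian_window(image[r1:r2, c1:c2], r1, c1,
                               cand_r = r - r1 + 1L, cand_c = c - c1 + 1L)
    if (fit$amplitude >= min_amplitude) {
      rows[[length(rows) + 1L]] <- tibble(
        spot_id = sprintf("spot_%03d", length(rows) + 1L),
        x_nm = fit$x_px * pixel_size,
        y_nm = fit$y_px * pixel_size,
        amplitude = fit$amplitude,
        sigma_x_fit_nm = fit$sigma_x_px * pixel_size,
        sigma_y_fit_nm = fit$sigma_y_px * pixel_size,
        offset = fit$offset)
    }
  }
  if (length(rows) == 0L) return(empty)
  dplyr::bind_rows(rows)
}

#' Classify spot shape by fitted sigma
#'
#' A single fitted spot is an *elongated singlet* when either fitted
#' Gaussian SD reaches the threshold (default 75.12 nm, inclusive) in the x
#' or y direction; otherwise it is a plain singlet.
#'
#' @param spots Data frame with columns `sigma_x_fit_nm`, `sigma_y_fit_nm`
#'   (one row per spot), or a single `Spot`-like list with those fields.
#' @param sigma_threshold Threshold, nm (inclusive).
#'
#' @return Character vector: `"singlet"` or `"elongated_singlet"`.
#' @export
#' @examples
#' classify_spot_shape(data.frame(sigma_x_fit_nm = 75.12,
#'                                sigma_y_fit_nm = 50))
classify_spot_shape <- function(spots, sigma_threshold = 75.12) {
  if (!is.data.frame(spots)) spots <- as_tibble(spots[c("sigma_x_fit_nm",
                                                        "sigma_y_fit_nm")])
  stopifnot(all(c("sigma_x_fit_nm", "sigma_y_fit_nm") %in% names(spots)),
            all(spots$sigma_x_fit_nm > 0), all(spots$sigma_y_fit_nm > 0))
  ifelse(spots$sigma_x_fit_nm >= sigma_threshold |
           spots$sigma_y_fit_nm >= sigma_threshold,
         "elongated_singlet", "singlet")
}

#' Assign spots to anchor foci within a colocalization radius
#'
#' A spot joins an anchor's site when its center lies within `radius`
#' (inclusive) of the anchor; a spot within the radius of several anchors
#' joins the nearest one, with exact distance ties resolved in favor of the
#' lower anchor index. Spots farther than the radius from every anchor are
#' not counted. Anchors with no member spots produce no site.
#'
#' @param spots Spot table with columns `x_nm`, `y_nm` (plus any others,
#'   carried through).
#' @param anchors Anchor table with columns `x_nm`, `y_nm`; row order
#'   defines the anchor index.
#' @param radius Colocalization radius, nm (> 0; default 150).
#'
#' @return The spot table restricted to assigned spots, with added columns
#'   `anchor_id` (1-based index) and `anchor_dist_nm`.
#' @export
assign_to_anchor <- function(spots, anchors, radius = 150) {
  stopifnot(radius > 0)
  spots <- as_tibble(spots); anchors <- as_tibble(anchors)
  if (nrow(spots) == 0L || nrow(anchors) == 0L) {
    out <- spots[integer(0), , drop = FALSE]
    out$anchor_id <- integer(); out$anchor_dist_nm <- numeric()
    return(out)
  }
  d <- outer(spots$x_nm, anchors$x_nm, "-")^2 +
    outer(spots$y_nm, anchors$y_nm, "-")^2
  d <- sqrt(d)
  # which.max(-d) on ties returns the first (lowest) anchor index
  nearest <- apply(d, 1, which.min)
  dist <- d[cbind(seq_len(nrow(spots)), nearest)]
  keep <- dist <= radius
  out <- spots[keep, , drop = FALSE]
  out$anchor_id <- nearest[keep]
  out$anchor_dist_nm <- dist[keep]
  out
}

#' Categorize one anchored focus site
#'
#' In `"multiplicity"` mode the category follows the member count: 1 / 2 /
#' 3 / >= 4 member spots give singlet / doublet / triplet / multi. In
#' `"shape"` mode a single member is classified by [classify_spot_shape()]
#' and any site with two or more members is a doublet.
#'
#' @param members Spot table of one site's member spots (>= 1 row).
#' @param mode `"multiplicity"` or `"shape"`.
#' @param sigma_threshold Passed to [classify_spot_shape()] in shape mode.
#'
#' @return A single category string.
#' @export
categorize_site <- function(members, mode = c("multiplicity", "shape"),
                            sigma_threshold = 75.12) {
  mode <- match.arg(mode)
  members <- as_tibble(members)
  n <- nrow(members)
  if (n == 0L) stop("empty site", call. = FALSE)
  if (mode == "multiplicity") {
    if (n == 1L) "singlet" else if (n == 2L) "doublet"
    else if (n == 3L) "triplet" else "multi"
  } else {
    if (n == 1L) classify_spot_shape(members, sigma_threshold) else "doublet"
  }
}

#' Categorize all sites in an assigned spot table
#'
#' @param assigned Output of [assign_to_anchor()] (must contain
#'   `anchor_id`).
#' @inheritParams categorize_site
#'
#' @return A tibble with one row per site: `anchor_id`, `n_members`,
#'   `category`.
#' @export
categorize_sites <- function(assigned, mode = c("multiplicity", "shape"),
                             sigma_threshold = 75.12) {
  mode <- match.arg(mode)
  assigned <- as_tibble(assigned)
  stopifnot("anchor_id" %in% names(assigned))
  ids <- sort(unique(assigned$anchor_id))
  dplyr::bind_rows(lapply(ids, function(id) {
    m <- assigned[assigned$anchor_id == id, , drop = FALSE]
    tibble(anchor_id = id, n_members = nrow(m),
           category = categorize_site(m, mode, sigma_threshold))
  }))
}

#' Distance spanned by a doublet
#'
#' Euclidean distance between the two member spots of a doublet site.
#'
#' @param members Spot table with exactly two rows (columns `x_nm`,
#'   `y_nm`).
#'
#' @return Distance in nm.
#' @export
#' @examples
#' doublet_span(data.frame(x_nm = c(0, 60), y_nm = c(0, 80)))  # 100
doublet_span <- function(members) {
  members <- as_tibble(members)
  if (nrow(members) != 2L) {
    stop("doublet_span requires a site with exactly 2 member spots",
         call. = FALSE)
  }
  sqrt(diff(members$x_nm)^2 + diff(members$y_nm)^2)
}

#' Partition normalized gonad positions into equal zones
#'
#' The gonad is treated as a spatial time-course and divided into
#' equal-width zones from the distal end; bins are half-open `[lo, hi)`
#' except the last, which is closed, so position 1 falls in the final zone.
#'
#' @param positions Normalized positions in `[0, 1]`.
#' @param n_zones Number of zones (the germline analyses use 4 or 7).
#'
#' @return Integer zone indices (1-based).
#' @export
#' @examples
#' zone_partition(c(0, 0.25, 1), n_zones = 4)  # 1 2 4
zone_partition <- function(positions, n_zones = 4) {
  stopifnot(n_zones >= 1)
  if (any(positions < 0 | positions > 1)) {
    stop("positions must lie in [0, 1]", call. = FALSE)
  }
  as.integer(pmin(floor(positions * n_zones) + 1, n_zones))
}

#' Zone-wise focus-count summary with pairwise Mann-Whitney tests
#'
#' Per zone and group, reports the number of nuclei, mean and sample SD
#' (n - 1 denominator) of the focus counts, and compares every pair of
#' groups within each zone with the two-sided Mann-Whitney test.
#'
#' @param counts Count table with columns `group`, `zone`, `count` (one row
#'   per nucleus), e.g. from [gen_zone_counts()].
#'
#' @return A list with `summary` (tibble: zone, group, `n`, `mean`, `sd`)
#'   and `pairwise` (tibble: zone, both groups, U, p), the latter `NULL`
#'   with fewer than two groups.
#' @export
zone_summary <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("group", "zone", "count") %in% names(counts)))
  if (nrow(counts) == 0L) stop("empty count table", call. = FALSE)
  summary <- dplyr::summarise(
    dplyr::group_by(counts, .data$zone, .data$group),
    n = dplyr::n(), mean = mean(.data$count), sd = sd(.data$count),
    .groups = "drop")
  groups <- unique(counts$group)
  pairwise <- NULL
  if (length(groups) >= 2L) {
    prs <- utils::combn(as.character(groups), 2, simplify = FALSE)
    rows <- list()
    for (z in sort(unique(counts$zone))) {
      for (pr in prs) {
        x <- counts$count[counts$zone == z & counts$group == pr[1]]
        y <- counts$count[counts$zone == z & counts$group == pr[2]]
        if (length(x) == 0L || length(y) == 0L) next
        mw <- mann_whitney(x, y)
        rows[[length(rows) + 1L]] <- tibble(
          zone = z, group_1 = pr[1], group_2 = pr[2],
          U = mw$U, p_value = mw$p_value)
      }
    }
    pairwise <- dplyr::bind_rows(rows)
  }
  list(summary = summary, pairwise = pairwise)
}
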