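#' Ellipse parameters
#'
#' Container for the elliptical shape models used to describe late
#' recombination foci. Axis lengths are *full* axes in nm (the convention in
#' which a 65 x 35 nm focus has semi-axes 32.5 and 17.5 nm); the orientation
#' `theta` is normalized to `[0, pi)`.
#'
#' @param cx,cy Center, nm.
#' @param full_major_axis,full_minor_axis Full axis lengths, nm. The major
#'   axis must be at least as long as the minor axis and both must be
#'   positive.
#' @param theta Orientation of the major axis, radians; any real value is
#'   accepted and normalized modulo pi.
#'
#' @return An object of class `ellipse_params`: a list with fields `cx`,
#'   `cy`, `full_major_axis`, `full_minor_axis`, `theta`, and derived
#'   semi-axes `a` (major) and `b` (minor).
#' @export
#' @examples
#' ellipse_params(full_major_axis = 65, full_minor_axis = 35)
ellipse_params <- function(cx = 0, cy = 0, full_major_axis = 65,
                           full_minor_axis = 35, theta = 0) {
  if (!is.numeric(full_major_axis) || !is.numeric(full_minor_axis) ||
      length(full_major_axis) != 1L || length(full_minor_axis) != 1L ||
      !is.finite(full_major_axis) || !is.finite(full_minor_axis)) {
    stop("invalid ellipse: axis lengths must be finite numbers", call. = FALSE)
  }
  if (full_minor_axis <= 0) {
    stop("invalid ellipse: full_minor_axis must be > 0", call. = FALSE)
  }
  if (full_major_axis < full_minor_axis) {
    stop("invalid ellipse: full_major_axis must be >= full_minor_axis",
         call. = FALSE)
  }
  theta <- theta %% pi
  structure(
    list(cx = cx, cy = cy,
         full_major_axis = full_major_axis,
         full_minor_axis = full_minor_axis,
         theta = theta,
         a = full_major_axis / 2,
         b = full_minor_axis / 2),
    class = "ellipse_params"
  )
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse_params> center (%.1f, %.1f) nm, full axes %.1f x %.1f nm, theta %.3f rad\n",
    x$cx, x$cy, x$full_major_axis, x$full_minor_axis, x$theta))
  invisible(x)
}

# Rotate points by theta and translate by (cx, cy).
ellipse_to_world <- function(params, ex, ey) {
  ct <- cos(params$theta); st <- sin(params$theta)
  list(x = params$cx + ct * ex - st * ey,
       y = params$cy + st * ex + ct * ey)
}

# Perimeter quadrature: n points at equally spaced parameter values with
# weights proportional to local speed (periodic midpoint rule in arc length),
# normalized so weights sum to 1 -> uniform line density on the perimeter.
ellipse_perimeter_quadrature <- function(params, n = 256) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  a <- params$a; b <- params$b
  speed <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  w <- speed / sum(speed)
  p <- ellipse_to_world(params, a * cos(t), b * sin(t))
  list(x = p$x, y = p$y, w = w)
}

# Interior quadrature: tensor Gauss-Legendre grid in (radius, angle) mapped
# to the ellipse; probability weights sum to 1 -> uniform area density.
ellipse_interior_quadrature <- function(params, n_r = 32, n_phi = 32) {
  gr <- pracma::gaussLegendre(n_r, 0, 1)
  gp <- pracma::gaussLegendre(n_phi, 0, 2 * pi)
  r <- rep(gr$x, times = n_phi)
  phi <- rep(gp$x, each = n_r)
  w <- rep(gr$w * gr$x, times = n_phi) * rep(gp$w, each = n_r) / pi
  p <- ellipse_to_world(params, params$a * r * cos(phi), params$b * r * sin(phi))
  list(x = p$x, y = p$y, w = w)
}

# Inverse-CDF sampler for arc-length-uniform positions on the perimeter.
# Returns parameter values t in [0, 2*pi).
sample_perimeter_param <- function(params, n, grid = 4096) {
  t <- seq(0, 2 * pi, length.out = grid + 1)
  speed <- sqrt((params$a * sin(t))^2 + (params$b * cos(t))^2)
  cs <- cumsum(c(0, (speed[-1] + speed[-length(speed)]) / 2 * diff(t)))
  cdf <- cs / cs[length(cs)]
  stats::approx(cdf, t, xout = runif(n), ties = "ordered")$y
}

# Membership test in ellipse-local frame.
inside_ellipse <- function(params, x, y) {
  ct <- cos(params$theta); st <- sin(params$theta)
  dx <- x - params$cx; dy <- y - params$cy
  ex <- ct * dx + st * dy
  ey <- -st * dx + ct * dy
  (ex / params$a)^2 + (ey / params$b)^2 <= 1
}
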