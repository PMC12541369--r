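# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: hypergeometric point probabilities from choose(),
# U-statistic null distributions from explicit enumeration, and plain grid
# quadrature for density normalization.

# Two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins, summing the probabilities of tables no more probable
# than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p for tie-free samples: full enumeration of
# the U1 null distribution, doubling the smaller tail.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(N, n1)
  u_dist <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u_dist <= U1), mean(u_dist >= U1)))
}

# Shortest distance from points to an ellipse perimeter, via a dense
# polyline.
oracle_dist_to_perimeter <- function(params, x, y, n = 2048) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  ct <- cos(params$theta); st <- sin(params$theta)
  ex <- params$a * cos(t); ey <- params$b * sin(t)
  px <- params$cx + ct * ex - st * ey
  py <- params$cy + st * ex + ct * ey
  vapply(seq_along(x), function(i) {
    sqrt(min((x[i] - px)^2 + (y[i] - py)^2))
  }, numeric(1))
}

# Small deterministic genotype cohort: n chromatids, of which `spec` rows
# get prescribed call vectors and the rest are fully parental Bristol.
fixed_cohort <- function(n, spec = list()) {
  calls <- matrix("B", nrow = n, ncol = 5)
  for (i in seq_along(spec)) calls[i, ] <- spec[[i]]
  out <- as.data.frame(calls, stringsAsFactors = FALSE)
  names(out) <- LETTERS[1:5]
  cbind(data.frame(progeny_id = sprintf("p%04d", seq_len(n)),
                   stringsAsFactors = FALSE), out)
}
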