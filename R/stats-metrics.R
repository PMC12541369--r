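#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the count in cell (1,1) follows a
#' hypergeometric distribution; the two-sided p-value is the sum of the
#' probabilities of all tables with the same margins whose point probability
#' does not exceed that of the observed table (the convention of mainstream
#' statistics packages; mid-p and doubling conventions differ and are not
#' used). The odds ratio is the sample cross-product ratio `(a*d)/(b*c)`,
#' reported as `Inf` when `b*c = 0` with `a*d > 0`. A table with an empty
#' margin carries no information: p is reported as 1 with a warning and the
#' odds ratio as `NA`.
#'
#' @param table A 2x2 matrix of non-negative counts (rows = groups, columns
#'   = outcome / not), or a length-4 vector in row-major order `(a, b, c,
#'   d)`.
#'
#' @return A list with `odds_ratio`, `p_value`, and the input `table`.
#' @export
#' @examples
#' fisher_exact(matrix(c(13, 8, 4, 11), 2, byrow = TRUE))  # p ~ 0.049
fisher_exact <- function(table) {
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (any(c(a + b, c + d, a + c, b + d) == 0)) {
    warning("degenerate 2x2 table (zero margin): p = 1, odds ratio undefined")
    return(list(odds_ratio = NA_real_, p_value = 1, table = table))
  }
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  # relative tolerance guards against ties lost to floating point
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = p, table = table)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a location difference between two independent samples.
#' For small tie-free samples (`max(n1, n2) <= 8`) the null distribution of
#' U is enumerated exactly over all assignments of the pooled ranks and the
#' two-sided p doubles the smaller tail; otherwise the normal approximation
#' with tie correction and continuity correction is used. The reported `U`
#' is `min(U1, U2)`.
#'
#' @param x,y Numeric samples (both non-empty).
#'
#' @return A list with `U`, `U1`, `U2`, `p_value`, and `method` (`"exact"`
#'   or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- anyDuplicated(pooled) > 0L

  if (max(n1, n2) <= 8 && !ties) {
    combos <- utils::combn(N, n1)
    ranksum <- colSums(matrix(r[combos], nrow = n1))
    u_dist <- ranksum - n1 * (n1 + 1) / 2
    p_le <- mean(u_dist <= U1)
    p_ge <- mean(u_dist >= U1)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tt <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U1 - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(U = min(U1, U2), U1 = U1, U2 = U2, p_value = p, method = method)
}

#' Pairwise category-frequency comparisons between groups
#'
#' For each category, builds the in-category vs rest 2x2 table for every
#' pair of groups and applies [fisher_exact()]. This is the comparison used
#' for focus-type frequencies (singlet / elongated singlet / doublet / ...)
#' between genotypes.
#'
#' @param counts Data frame with columns `group`, `category`, `n` (count of
#'   sites of that category in that group). At least two groups and two
#'   categories are required.
#'
#' @return A tibble with one row per (category, group pair): the 2x2 cell
#'   counts, odds ratio, and two-sided p.
#' @export
#' @examples
#' counts <- data.frame(
#'   group = rep(c("wt", "mut"), each = 2),
#'   category = rep(c("singlet", "doublet"), 2),
#'   n = c(129, 79, 121, 42))
#' category_comparison(counts)
category_comparison <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("group", "category", "n") %in% names(counts)))
  groups <- unique(counts$group)
  cats <- unique(counts$category)
  if (length(groups) < 2L || length(cats) < 2L) {
    stop("need >= 2 groups and >= 2 categories", call. = FALSE)
  }
  totals <- tapply(counts$n, counts$group, sum)
  if (any(totals == 0)) stop("empty group", call. = FALSE)
  cell <- function(g, cat) {
    v <- counts$n[counts$group == g & counts$category == cat]
    if (length(v) == 0) 0 else sum(v)
  }
  prs <- utils::combn(as.character(groups), 2, simplify = FALSE)
  rows <- list()
  for (cat in cats) {
    for (pr in prs) {
      a <- cell(pr[1], cat); b <- totals[[pr[1]]] - a
      c <- cell(pr[2], cat); d <- totals[[pr[2]]] - c
      ft <- fisher_exact(matrix(c(a, b, c, d), 2, byrow = TRUE))
      rows[[length(rows) + 1L]] <- tibble(
        category = cat, group_1 = pr[1], group_2 = pr[2],
        x1 = a, n1 = totals[[pr[1]]], x2 = c, n2 = totals[[pr[2]]],
        odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }
  }
  dplyr::bind_rows(rows)
}

#' Viability and male-frequency metrics per group
#'
#' Per worm, viability is the percentage of laid eggs that hatched into
#' larvae (unfertilized eggs are excluded upstream of this table) and male
#' frequency is the percentage of males among the hatched offspring. Both
#' are then summarized per group as mean and sample SD (n - 1 denominator).
#'
#' @param brood Data frame with columns `worm_id`, `group`, `eggs_laid`,
#'   `larvae`, `males`; must satisfy `males <= larvae <= eggs_laid` and
#'   `eggs_laid > 0`.
#'
#' @return A tibble per group: `n`, `viability_mean`, `viability_sd`,
#'   `male_pct_mean`, `male_pct_sd`. Worms with zero larvae contribute no
#'   male-percentage value.
#' @export
viability_metrics <- function(brood) {
  brood <- as_tibble(brood)
  stopifnot(all(c("worm_id", "group", "eggs_laid", "larvae", "males") %in%
                  names(brood)))
  if (any(brood$eggs_laid <= 0)) stop("zero brood size", call. = FALSE)
  if (any(brood$larvae > brood$eggs_laid) || any(brood$males > brood$larvae)) {
    stop("counts must satisfy males <= larvae <= eggs_laid", call. = FALSE)
  }
  brood$viability <- 100 * brood$larvae / brood$eggs_laid
  brood$male_pct <- ifelse(brood$larvae > 0,
                           100 * brood$males / brood$larvae, NA_real_)
  dplyr::summarise(
    dplyr::group_by(brood, .data$group),
    n = dplyr::n(),
    viability_mean = mean(.data$viability),
    viability_sd = sd(.data$viability),
    male_pct_mean = mean(.data$male_pct, na.rm = TRUE),
    male_pct_sd = sd(.data$male_pct, na.rm = TRUE),
    .groups = "drop")
}
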