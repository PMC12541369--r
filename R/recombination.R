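#' Ordered SNP marker map
#'
#' Describes the ordered markers used to localize crossovers. The default
#' five markers A-E span chromosome V at illustrative, synthetic coordinates
#' (the analysis depends only on marker order, never on base-pair values).
#'
#' @param marker Marker labels, in chromosomal order.
#' @param chrom Chromosome name.
#' @param pos_bp Strictly increasing coordinates, bp.
#'
#' @return A tibble of class `marker_map` with columns `marker`, `chrom`,
#'   `pos_bp`.
#' @export
#' @examples
#' marker_map()
marker_map <- function(marker = LETTERS[1:5], chrom = "V",
                       pos_bp = c(1.1e6, 5.3e6, 10.5e6, 15.8e6, 20.0e6)) {
  stopifnot(length(marker) >= 2, length(pos_bp) == length(marker))
  if (any(diff(pos_bp) <= 0)) {
    stop("marker positions must be strictly increasing", call. = FALSE)
  }
  out <- tibble(marker = as.character(marker), chrom = chrom,
                pos_bp = as.numeric(pos_bp))
  class(out) <- c("marker_map", class(out))
  out
}

interval_labels <- function(map) {
  paste0(map$marker[-nrow(map)], map$marker[-1])
}

#' Call crossovers on one chromatid from ordered marker genotypes
#'
#' Walks adjacent pairs of non-missing calls along the marker order; every
#' differing pair records one crossover. When the two markers of a
#' transition are chromosomally adjacent the crossover is assigned to that
#' marker interval; when one or more missing calls separate them it is
#' assigned to the composite interval spanning the gap and the chromatid is
#' flagged unusable for per-interval counting (it still counts toward the
#' overall recombinant fraction). Even numbers of exchanges between adjacent
#' markers are invisible at marker resolution; this is a property of the
#' assay, not corrected here.
#'
#' @param calls Character vector of per-marker calls in map order, values
#'   `"B"`, `"H"`, or `NA`; at least two non-missing calls required.
#' @param map A [marker_map()].
#' @param progeny_id Optional label carried into the profile.
#'
#' @return A list of class `co_profile`: `progeny_id`,
#'   `crossover_intervals` (character vector), `n_co`, `usable`.
#' @export
#' @examples
#' call_crossovers(c("B", "B", "H", "H", "H"), marker_map())  # one CO in BC
call_crossovers <- function(calls, map = marker_map(), progeny_id = NA) {
  calls <- as.character(calls)
  stopifnot(length(calls) == nrow(map))
  ok <- which(!is.na(calls))
  if (length(ok) < 2L) {
    stop("need at least 2 non-missing marker calls", call. = FALSE)
  }
  intervals <- character(0)
  usable <- TRUE
  for (i in seq_len(length(ok) - 1L)) {
    a <- ok[i]; b <- ok[i + 1L]
    if (calls[a] != calls[b]) {
      intervals <- c(intervals, paste0(map$marker[a], map$marker[b]))
      if (b - a > 1L) usable <- FALSE
    }
  }
  structure(list(progeny_id = progeny_id,
                 crossover_intervals = intervals,
                 n_co = length(intervals),
                 usable = usable),
            class = "co_profile")
}

# Profiles for every progeny row with >= 2 usable calls; rows failing the
# precondition are dropped with a message.
cohort_profiles <- function(cohort, map) {
  cohort <- as_tibble(cohort)
  stopifnot(all(map$marker %in% names(cohort)))
  callm <- as.matrix(cohort[, map$marker, drop = FALSE])
  scorable <- rowSums(!is.na(callm)) >= 2
  if (any(!scorable)) {
    message(sum(!scorable), " chromatid(s) with < 2 non-missing calls dropped")
  }
  ids <- if ("progeny_id" %in% names(cohort)) cohort$progeny_id else
    as.character(seq_len(nrow(cohort)))
  lapply(which(scorable), function(i) {
    call_crossovers(callm[i, ], map, progeny_id = ids[i])
  })
}

#' Cohort recombination frequencies and crossover-class counts
#'
#' Summarizes a genotyped cohort: per-interval crossover frequency (COs in
#' the interval divided by chromatids usable for per-interval counting),
#' overall recombinant fraction (chromatids with at least one observed CO
#' divided by all scored chromatids), and the tally of chromatids with 0, 1,
#' 2, and 3+ crossovers. Percentages are reported to 2 decimals.
#'
#' @param cohort Genotype table with columns `progeny_id` and one column
#'   per marker (values `"B"` / `"H"` / `NA`), e.g. from
#'   [gen_genotype_cohort()].
#' @param map A [marker_map()].
#'
#' @return A list of class `cohort_recombination`: `per_interval` (tibble:
#'   interval, `n_co`, `n_usable`, `frequency`), `overall` (tibble:
#'   `n_recombinant`, `n_scored`, `pct`), `co_classes` (tibble: `n_co`
#'   class 0/1/2/3+, `n`, `pct`), `n_scored`, `n_usable`.
#' @export
cohort_recombination <- function(cohort, map = marker_map()) {
  profiles <- cohort_profiles(cohort, map)
  if (length(profiles) == 0L) stop("empty cohort", call. = FALSE)
  n_scored <- length(profiles)
  n_co <- vapply(profiles, `[[`, numeric(1), "n_co")
  usable <- vapply(profiles, `[[`, logical(1), "usable")
  n_usable <- sum(usable)

  labels <- interval_labels(map)
  iv_all <- unlist(lapply(profiles[usable], `[[`, "crossover_intervals"))
  per_interval <- tibble(
    interval = labels,
    n_co = vapply(labels, function(l) sum(iv_all == l), numeric(1)),
    n_usable = n_usable)
  per_interval$frequency <- if (n_usable > 0) {
    per_interval$n_co / n_usable
  } else NA_real_

  n_rec <- sum(n_co >= 1)
  overall <- tibble(n_recombinant = n_rec, n_scored = n_scored,
                    pct = round(100 * n_rec / n_scored, 2))

  cls <- pmin(n_co, 3)
  co_classes <- tibble(
    n_co = c("0", "1", "2", "3+"),
    n = vapply(0:3, function(k) sum(cls == k), numeric(1)))
  co_classes$pct <- round(100 * co_classes$n / n_scored, 2)

  structure(list(per_interval = per_interval, overall = overall,
                 co_classes = co_classes, n_scored = n_scored,
                 n_usable = n_usable),
            class = "cohort_recombination")
}

#' @export
print.cohort_recombination <- function(x, ...) {
  cat(sprintf("<cohort_recombination> %d scored chromatids (%d usable per-interval)\n",
              x$n_scored, x$n_usable))
  cat(sprintf("  overall recombinant: %d/%d = %.2f%%\n",
              x$overall$n_recombinant, x$overall$n_scored, x$overall$pct))
  print(x$per_interval)
  invisible(x)
}

#' Compare recombination between two cohorts
#'
#' Two-sided Fisher's exact tests on the overall recombinant / parental 2x2
#' table and, per marker interval, on the CO / no-CO table of per-interval
#' usable chromatids. Degenerate tables (a zero margin) report p = 1 with a
#' warning.
#'
#' @param cohort_a,cohort_b Genotype tables (see [cohort_recombination()]).
#' @param map A [marker_map()].
#' @param labels Length-2 character labels for the cohorts.
#'
#' @return A list with `overall` (tibble: labels, counts, odds ratio, p)
#'   and `per_interval` (tibble: interval, per-cohort counts, odds ratio,
#'   p).
#' @export
compare_recombination <- function(cohort_a, cohort_b, map = marker_map(),
                                  labels = c("A", "B")) {
  ra <- cohort_recombination(cohort_a, map)
  rb <- cohort_recombination(cohort_b, map)
  ft <- fisher_exact(matrix(
    c(ra$overall$n_recombinant, ra$n_scored - ra$overall$n_recombinant,
      rb$overall$n_recombinant, rb$n_scored - rb$overall$n_recombinant),
    2, byrow = TRUE))
  overall <- tibble(
    group_1 = labels[1], group_2 = labels[2],
    x1 = ra$overall$n_recombinant, n1 = ra$n_scored,
    x2 = rb$overall$n_recombinant, n2 = rb$n_scored,
    odds_ratio = ft$odds_ratio, p_value = ft$p_value)

  per_interval <- dplyr::bind_rows(lapply(seq_len(nrow(ra$per_interval)),
    function(i) {
      a1 <- ra$per_interval$n_co[i]; u1 <- ra$n_usable
      a2 <- rb$per_interval$n_co[i]; u2 <- rb$n_usable
      fi <- fisher_exact(matrix(c(a1, u1 - a1, a2, u2 - a2), 2, byrow = TRUE))
      tibble(interval = ra$per_interval$interval[i],
             x1 = a1, n1 = u1, x2 = a2, n2 = u2,
             odds_ratio = fi$odds_ratio, p_value = fi$p_value)
    }))
  list(overall = overall, per_interval = per_interval)
}
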