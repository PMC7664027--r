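#' Per-area distribution of situations in dataset 4
#'
#' The Table-3-style analysis: for each programmatic area, the percentage of
#' dataset-4 facility-records (the set entering duplicate treatment) falling
#' in each situation, with removed duplicates as their own row, plus derived
#' rows `total_removed_pct` and `total_retained_pct`. Retained equals
#' `pct(G) + pct(H)`; per area the situation rows and the duplicates row sum
#' to 100. Percentages are rounded to 2 decimals for presentation; raw
#' fractions are kept in the `raw` attribute.
#'
#' @param situation_counts Area x situation count matrix from
#'   [run_cleaning_cycles()] (counts on the post-duplicate data).
#' @param dup_removed_per_area Number of duplicate records removed, attributed
#'   to each area (a removed facility-year record removes one row from every
#'   area). Scalar or named vector by area.
#' @param dataset4_n Number of facility-records in dataset 4 (scalar or named
#'   vector by area).
#' @return Tibble with a `situation` column and one percentage column per
#'   area; an area with a zero denominator is reported as `NA`, not 0.
#' @export
situation_distribution <- function(situation_counts, dup_removed_per_area,
                                   dataset4_n) {
  areas <- rownames(situation_counts)
  dup <- rep_len(dup_removed_per_area, length(areas))
  n4 <- rep_len(dataset4_n, length(areas))
  if (!is.null(names(dup_removed_per_area))) dup <- dup_removed_per_area[areas]
  if (!is.null(names(dataset4_n))) n4 <- dataset4_n[areas]
  labels <- c(situation_table()$label, "duplicates")
  raw <- matrix(NA_real_, length(labels) + 2L, length(areas),
                dimnames = list(c(labels, "total_removed_pct", "total_retained_pct"),
                                areas))
  for (j in seq_along(areas)) {
    if (n4[j] == 0) next
    cnt <- c(situation_counts[areas[j], ], duplicates = dup[j])
    pct <- 100 * cnt / n4[j]
    retained <- pct[["G"]] + pct[["H"]]
    raw[, j] <- c(pct, 100 - retained, retained)
  }
  out <- tibble::as_tibble(round(raw, 2), rownames = "situation")
  attr(out, "raw") <- raw
  out
}

#' Count records in a situation per year and area
#'
#' Builds the blocks-by-treatments count matrix for the rank tests: one row
#' per calendar year, one column per programmatic area, each cell the number
#' of area records in the selected situation for that year, counted on the
#' disaggregated datasets before situation treatment.
#'
#' @param area_datasets List of per-area datasets (with `year` and
#'   `situation` columns), e.g. `pre_treatment_areas` from
#'   [run_cleaning_cycles()].
#' @param situation Situation label to count (e.g. `"B"` or `"D"`).
#' @param years Year domain; defaults to all years present in the data.
#' @return Integer matrix, `length(years)` x number of areas, with dimnames.
#' @export
per_year_counts <- function(area_datasets, situation,
                            years = NULL) {
  all_rows <- dplyr::bind_rows(area_datasets)
  if (is.null(years)) years <- sort(unique(all_rows$year))
  codes <- names(area_datasets)
  mat <- matrix(
    0L, nrow = length(years), ncol = length(codes),
    dimnames = list(as.character(years), codes)
  )
  sel <- all_rows[all_rows$situation == situation, ]
  if (nrow(sel) > 0) {
    tab <- table(
      factor(sel$year, levels = years),
      factor(sel$area_code, levels = codes)
    )
    mat[, ] <- as.integer(tab)
  }
  mat
}

#' Friedman rank analysis of variance
#'
#' Nonparametric test for differences among k related treatments observed in
#' N blocks. Within each block the treatments are ranked ascending by value
#' (the largest count gets rank k; ties get average ranks), so the
#' most-affected treatment attains the highest mean rank. The chi-square
#' statistic uses the tie-corrected form
#' `(k-1) * sum((R_j - N(k+1)/2)^2) / (sum(r_ij^2) - N k (k+1)^2 / 4)`,
#' equal to `12N/(k(k+1)) * sum((Rbar_j - (k+1)/2)^2)` when no ties are
#' present, with k-1 degrees of freedom. The uncorrected statistic is
#' reported alongside. Degenerate input (all treatments equal in every
#' block) yields statistic 0 and p = 1.
#'
#' @param mat Numeric matrix, blocks in rows, treatments in columns.
#' @return An object of class `rank_test`: `method`, `statistic`,
#'   `statistic_uncorrected`, `df`, `p_value`, `mean_ranks`, `n_blocks`,
#'   `k`.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    domain_error("Friedman test needs at least 2 blocks and 2 treatments.")
  }
  N <- nrow(mat)
  k <- ncol(mat)
  r <- t(apply(mat, 1L, rank))
  Rj <- colSums(r)
  mean_ranks <- Rj / N
  ss_treat <- sum((Rj - N * (k + 1) / 2)^2)
  denom <- sum(r^2) - N * k * (k + 1)^2 / 4
  if (denom <= 0) {
    statistic <- 0
    p <- 1
  } else {
    statistic <- (k - 1) * ss_treat / denom
    p <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  }
  uncorrected <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  structure(
    list(
      method = "Friedman rank analysis of variance",
      statistic = statistic,
      statistic_uncorrected = uncorrected,
      df = k - 1L,
      p_value = p,
      mean_ranks = stats::setNames(mean_ranks, colnames(mat)),
      n_blocks = N,
      k = k
    ),
    class = "rank_test"
  )
}

#' Wilcoxon signed-rank test for paired counts
#'
#' Two-sided Wilcoxon signed-rank test using the normal approximation without
#' continuity correction. Zero differences are dropped; absolute differences
#' are ranked with average ranks for ties; the statistic is
#' `W = min(W+, W-)` and `Z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie
#' correction)`, so Z is never positive — matching the convention of
#' reporting the smaller rank sum. When the non-zero differences are untied,
#' the exact two-sided p-value from the signed-rank distribution is reported
#' alongside the normal approximation. If every difference is zero the test
#' is undefined and a no-variation result is returned.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @return An object of class `rank_test`: `method`, `statistic` (W),
#'   `z_value`, `p_value` (normal approximation), `p_exact` (`NA` when ties
#'   prevent it), `n_nonzero`, `no_variation`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    domain_error("Paired samples must have equal length >= 1.")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(
      list(
        method = "Wilcoxon signed-rank test (normal approximation)",
        statistic = NA_real_, z_value = NA_real_, p_value = NA_real_,
        p_exact = NA_real_, n_nonzero = 0L, no_variation = TRUE
      ),
      class = "rank_test"
    ))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else NA_real_
  p <- if (is.na(z)) NA_real_ else min(1, 2 * stats::pnorm(z))
  p_exact <- if (any(ties > 1)) {
    NA_real_
  } else {
    min(1, 2 * stats::psignrank(w, n))
  }
  structure(
    list(
      method = "Wilcoxon signed-rank test (normal approximation)",
      statistic = w,
      z_value = z,
      p_value = p,
      p_exact = p_exact,
      n_nonzero = n,
      no_variation = FALSE
    ),
    class = "rank_test"
  )
}

#' Pairwise post hoc Wilcoxon tests across areas
#'
#' Runs the Wilcoxon signed-rank test on every unordered pair of treatment
#' columns of a year-by-area count matrix (15 pairs for six areas), with a
#' direction summary per pair: "Higher in X for m years", where m is the
#' number of blocks in which X's count strictly exceeds the other area's.
#' Raw p-values are reported; an optional Bonferroni adjustment over the
#' pairs can be added (off by default).
#'
#' @param mat Count matrix from [per_year_counts()].
#' @param correct Add a Bonferroni-adjusted p-value column. Default `FALSE`.
#' @return Tibble with one row per pair: `pair`, `statistic`, `z_value`,
#'   `p_value`, `p_exact`, `direction` (and `p_adjusted` when requested).
#' @export
posthoc_pairwise <- function(mat, correct = FALSE) {
  mat <- as.matrix(mat)
  codes <- colnames(mat)
  pairs <- utils::combn(seq_len(ncol(mat)), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]
    j <- pairs[2L, p]
    res <- wilcoxon_signed_rank(mat[, j], mat[, i])
    wins_j <- sum(mat[, j] > mat[, i])
    wins_i <- sum(mat[, i] > mat[, j])
    direction <- if (res$no_variation) {
      "No variation between areas"
    } else if (wins_j >= wins_i) {
      sprintf("Higher in %s for %d years", codes[j], wins_j)
    } else {
      sprintf("Higher in %s for %d years", codes[i], wins_i)
    }
    tibble::tibble(
      pair = sprintf("%s—%s", codes[j], codes[i]),
      statistic = res$statistic,
      z_value = res$z_value,
      p_value = res$p_value,
      p_exact = res$p_exact,
      direction = direction
    )
  })
  out <- dplyr::bind_rows(rows)
  if (correct) out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, "\n")
  if (isTRUE(x$no_variation)) {
    cat("  no variation: all paired differences are zero; test undefined\n")
    return(invisible(x))
  }
  if (!is.null(x$mean_ranks)) {
    cat(sprintf("  chi-squared = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
    cat("  mean ranks:\n")
    print(round(x$mean_ranks, 2))
  } else {
    cat(sprintf("  W = %g, Z = %.4f, p = %.4g", x$statistic, x$z_value, x$p_value))
    if (!is.na(x$p_exact)) cat(sprintf(" (exact p = %.4g)", x$p_exact))
    cat("\n")
  }
  invisible(x)
}
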