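# Association between haplotype carriage and DAE status / magnitude.

#' Exact sign test
#'
#' Exact binomial tail at p = 1/2. One-sided: `P(X >= k)`; two-sided:
#' `min(1, 2 * min(P(X >= k), P(X <= k)))`. Defaults to one-sided in the
#' direction "carriers show DAE more often".
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return One-row tibble `k`, `n`, `alternative`, `p_value`.
#' @export
#' @examples
#' sign_test(5, 5)  # (1/2)^5 = 0.03125
sign_test <- function(k, n, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integer 0 <= k <= n with n >= 1", call. = FALSE)
  }
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  lower <- stats::pbinom(k, n, 0.5)                          # P(X <= k)
  p <- if (alternative == "greater") upper else min(1, 2 * min(upper, lower))
  tibble::tibble(k = as.integer(k), n = as.integer(n),
                 alternative = alternative, p_value = p)
}

#' Chi-square tests of DAE proportion by haplotype carriage
#'
#' For each haplotype, forms the 2x2 table carriers/non-carriers x
#' DAE/no-DAE from per-haplotype counts and applies Pearson's chi-square
#' (no continuity correction by default). Since each tested sample carries
#' the anchored haplotype plus one other, non-carrier counts are the column
#' totals minus the haplotype's own counts. A zero margin yields an
#' undefined-statistic row (`defined = FALSE`), not an error.
#'
#' @param counts Tibble with columns `haplotype`, `n_dae`, `n_no_dae` (e.g.
#'   the last columns of [brca2_haplotypes()]).
#' @param correct Apply Yates continuity correction. Default `FALSE`.
#' @return Tibble per haplotype: counts, expected DAE count among carriers,
#'   `statistic`, `p_value`, `defined`.
#' @export
dae_proportion_test <- function(counts, correct = FALSE) {
  stopifnot(all(c("haplotype", "n_dae", "n_no_dae") %in% names(counts)))
  tot_dae <- sum(counts$n_dae)
  tot_no <- sum(counts$n_no_dae)
  purrr::pmap_dfr(counts[c("haplotype", "n_dae", "n_no_dae")],
                  function(haplotype, n_dae, n_no_dae) {
    tab <- matrix(c(n_dae, n_no_dae,
                    tot_dae - n_dae, tot_no - n_no_dae),
                  nrow = 2, byrow = TRUE)
    defined <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (defined) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      stat <- unname(ct$statistic); p <- ct$p.value
      expected <- ct$expected[1, 1]
    } else {
      stat <- NA_real_; p <- NA_real_; expected <- NA_real_
    }
    tibble::tibble(haplotype = haplotype, n_dae = n_dae, n_no_dae = n_no_dae,
                   expected_dae = expected, statistic = stat, p_value = p,
                   defined = defined)
  })
}

#' Rank-sum test of DAE magnitude between haplotype groups
#'
#' Two-sided Wilcoxon rank-sum test comparing normalized log2 allelic
#' ratios between carriers of low- and high-expression second haplotypes.
#' Uses the exact rank-sum distribution when the combined sample size is at
#' most 20 and there are no ties, otherwise the normal approximation with
#' the tie-corrected variance (no continuity correction).
#'
#' @param data Tibble with one row per sample.
#' @param value Column of ratios (tidy-eval), default `norm_log2_ratio`.
#' @param group Column with two group labels, default `expression_class`.
#' @return One-row tibble: group labels and sizes, group means, `statistic`
#'   (rank-sum W of the first group), `p_value`, `exact`.
#' @export
ratio_by_group_test <- function(data, value = "norm_log2_ratio",
                                group = "expression_class") {
  x <- data[[value]]
  g <- as.character(data[[group]])
  labs <- sort(unique(g))
  if (length(labs) != 2) {
    stop("ratio_by_group_test needs exactly two non-empty groups",
         call. = FALSE)
  }
  x1 <- x[g == labs[1]]; x2 <- x[g == labs[2]]
  n <- length(x1) + length(x2)
  exact <- n <= 20 && !anyDuplicated(x)
  wt <- suppressWarnings(
    stats::wilcox.test(x1, x2, exact = exact, correct = FALSE)
  )
  tibble::tibble(
    group1 = labs[1], group2 = labs[2],
    n1 = length(x1), n2 = length(x2),
    mean1 = mean(x1), mean2 = mean(x2),
    statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact
  )
}

#' Table-style DAE association report
#'
#' One row per haplotype: counts, the carriage chi-square, and the
#' one-sided sign test of "all carriers show DAE" computed on that
#' haplotype's own counts. No multiplicity correction is applied by
#' default; `bonferroni = TRUE` multiplies the p-values by the number of
#' haplotypes tested.
#'
#' @param counts As for [dae_proportion_test()].
#' @param bonferroni Apply Bonferroni correction across haplotypes.
#' @return Tibble with chi-square and sign-test columns per haplotype.
#' @export
dae_association_report <- function(counts, bonferroni = FALSE) {
  chi <- dae_proportion_test(counts)
  sign_p <- purrr::map2_dbl(counts$n_dae, counts$n_dae + counts$n_no_dae,
                            ~ sign_test(.x, .y)$p_value)
  out <- dplyr::mutate(chi, sign_test_p = sign_p)
  if (bonferroni) {
    m <- nrow(out)
    out <- dplyr::mutate(
      out,
      p_value = pmin(1, .data$p_value * m),
      sign_test_p = pmin(1, .data$sign_test_p * m)
    )
    message("Bonferroni correction applied across ", m, " haplotypes")
  }
  out
}

#' Boxplot of DAE magnitude by second haplotype
#'
#' @param data Tibble with per-sample `norm_log2_ratio` and a haplotype or
#'   class column.
#' @param by Column to group by (default `"expression_class"`).
#' @return A ggplot object.
#' @export
plot_dae_by_haplotype <- function(data, by = "expression_class") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[by]],
                                     y = .data$norm_log2_ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = by, y = "normalized log2 allelic ratio") +
    ggplot2::theme_minimal()
}
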