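# qPCR delta-delta-Ct normalization and genotype / diplotype-group
# expression tests. Array-mode log intensities are assumed pre-normalized
# and pass through these tests unchanged.

#' Select the most stable housekeeping pair
#'
#' Scores every candidate pair by the stability of their per-sample Ct
#' difference: `sum(|dCt_i - median(dCt)|)` across samples, i.e. the pair
#' whose difference is most nearly constant. Ties are broken
#' lexicographically by gene id.
#'
#' @param expr Wide expression tibble (samples x genes).
#' @param candidates Character vector of candidate housekeeping genes
#'   (>= 2, complete data required).
#' @return Tibble of pairs sorted by score (best first): `hk1`, `hk2`,
#'   `score`. The selected pair is `c(out$hk1[1], out$hk2[1])`.
#' @export
select_housekeeping_pair <- function(expr, candidates) {
  ok <- candidates[candidates %in% names(expr)]
  ok <- ok[vapply(ok, function(g) !anyNA(expr[[g]]), logical(1))]
  if (length(ok) < 2) {
    stop("need at least two candidate housekeeping genes with complete data",
         call. = FALSE)
  }
  ok <- sort(ok)
  pairs <- utils::combn(ok, 2)
  score <- apply(pairs, 2, function(p) {
    d <- expr[[p[1]]] - expr[[p[2]]]
    sum(abs(d - stats::median(d)))
  })
  tibble::tibble(hk1 = pairs[1, ], hk2 = pairs[2, ], score = score) |>
    dplyr::arrange(.data$score, .data$hk1, .data$hk2)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample: `dCt = Ct_gene - mean(Ct_hk1, Ct_hk2)`; then
#' `ddCt = dCt - mean(dCt of the reference group)`; relative expression is
#' `2^(-ddCt)`.
#'
#' @param expr Wide Ct tibble (samples x genes) including a grouping column.
#' @param hk_pair Character vector of the two housekeeping genes.
#' @param reference_group Label of the reference group (its mean relative
#'   expression becomes 1).
#' @param genes Gene columns to normalize; defaults to every numeric column
#'   that is not a housekeeping gene.
#' @param group Name of the grouping column (default `"group"`).
#' @return Long tibble `sample_id`, `group`, `gene`, `ct`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`.
#' @export
ddct_relative_expression <- function(expr, hk_pair, reference_group,
                                     genes = NULL, group = "group") {
  stopifnot(length(hk_pair) == 2, all(hk_pair %in% names(expr)))
  if (!group %in% names(expr)) {
    stop("grouping column '", group, "' not found", call. = FALSE)
  }
  if (!reference_group %in% expr[[group]]) {
    stop("reference group '", reference_group, "' is empty", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- setdiff(names(expr)[vapply(expr, is.numeric, logical(1))],
                     c(hk_pair, "n_low"))
  }
  hk_mean <- (expr[[hk_pair[1]]] + expr[[hk_pair[2]]]) / 2
  long <- expr |>
    dplyr::mutate(.hk = hk_mean) |>
    dplyr::select(dplyr::all_of(c("sample_id", group, ".hk", genes))) |>
    tidyr::pivot_longer(dplyr::all_of(genes),
                        names_to = "gene", values_to = "ct") |>
    dplyr::mutate(delta_ct = .data$ct - .data$.hk)
  long |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct -
        mean(.data$delta_ct[.data[[group]] == reference_group]),
      rel_expr = 2^(-.data$delta_delta_ct)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".hk")
}

#' One-way ANOVA of expression on genotype
#'
#' Genotype (0/1/2 copies of the minor allele) is treated as a categorical
#' factor, matching the usual genotype-class comparison with rare-homozygote
#' contrasts; an additive-trend linear model p-value is reported as a
#' secondary statistic.
#'
#' @param data Tibble with one row per sample.
#' @param value Expression column name.
#' @param genotype Genotype column name (coded 0/1/2).
#' @return One-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `trend_p`, `defined`, and a list-column `means` (tibble
#'   `genotype`, `n`, `mean`).
#' @export
genotype_expression_anova <- function(data, value, genotype = "genotype") {
  y <- data[[value]]
  g <- factor(data[[genotype]])
  means <- tibble::tibble(genotype = levels(g),
                          n = as.integer(table(g)),
                          mean = as.numeric(tapply(y, g, mean)))
  if (nlevels(droplevels(g)) < 2 || length(y) < 3) {
    return(tibble::tibble(f_statistic = NA_real_, df_between = NA_integer_,
                          df_within = NA_integer_, p_value = NA_real_,
                          trend_p = NA_real_, defined = FALSE,
                          means = list(means)))
  }
  fit <- stats::lm(y ~ g)
  a <- stats::anova(fit)
  trend <- stats::lm(y ~ as.numeric(as.character(g)))
  trend_p <- stats::coef(summary(trend))[2, 4]
  tibble::tibble(
    f_statistic = a$`F value`[1],
    df_between = a$Df[1], df_within = a$Df[2],
    p_value = a$`Pr(>F)`[1],
    trend_p = trend_p,
    defined = TRUE,
    means = list(means)
  )
}

#' Two-group t-test of expression between diplotype groups
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` for the
#' classical pooled test). The difference is reported as first group minus
#' second group of `pair`. A requested group that is absent in the data is
#' a logged skip: the function returns a `defined = FALSE` row with a
#' message instead of failing, since some tissues lack e.g. the
#' two-low-haplotype group entirely.
#'
#' @param data Tibble with one row per sample.
#' @param value Expression column name.
#' @param pair Two group labels to compare, e.g. `c("HH", "HL")`.
#' @param group Grouping column name (default `"group"`).
#' @param var_equal Use the pooled-variance test.
#' @return One-row tibble: `group1`, `group2`, `n1`, `n2`, `difference`,
#'   `t_statistic`, `df`, `p_value`, `defined`.
#' @export
group_expression_ttest <- function(data, value, pair = c("HH", "HL"),
                                   group = "group", var_equal = FALSE) {
  stopifnot(length(pair) == 2)
  x1 <- data[[value]][data[[group]] == pair[1]]
  x2 <- data[[value]][data[[group]] == pair[2]]
  if (length(x1) == 0 || length(x2) == 0) {
    message("group ", pair[which(c(length(x1), length(x2)) == 0)][1],
            " absent; test skipped")
    return(tibble::tibble(group1 = pair[1], group2 = pair[2],
                          n1 = length(x1), n2 = length(x2),
                          difference = NA_real_, t_statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          defined = FALSE))
  }
  if (length(x1) + length(x2) < 4 || length(x1) < 2 || length(x2) < 2) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  tt <- stats::t.test(x1, x2, var.equal = var_equal)
  tibble::tibble(
    group1 = pair[1], group2 = pair[2],
    n1 = length(x1), n2 = length(x2),
    difference = mean(x1) - mean(x2),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    defined = TRUE
  )
}

#' Boxplot of expression by diplotype group
#'
#' @param data Tibble with one row per sample.
#' @param value Expression column name.
#' @param group Grouping column name.
#' @return A ggplot object.
#' @export
plot_expression_by_group <- function(data, value, group = "group") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                     y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "diplotype group", y = value) +
    ggplot2::theme_minimal()
}
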