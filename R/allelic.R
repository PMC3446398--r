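# Normalization of replicate allelic peak ratios and DAE calling.

#' Normalize cDNA allelic ratios against genomic DNA
#'
#' For each sample x SNP, the normalized log2 allelic ratio is the mean of
#' the log2 cDNA replicate ratios minus the mean of the log2 gDNA replicate
#' ratios (genomic DNA carries one copy of each allele, so its ratio is the
#' assay's unit). Replicates are combined as the mean of log-ratios, which
#' treats the two alleles symmetrically. The standard error is the Welch
#' combination of the two replicate variances, 0 when both assays have a
#' single replicate.
#'
#' @param measurements Long tibble of replicate measurements with columns
#'   `sample_id`, `snp_id`, `allele_a`, `allele_b`, `assay` (`cdna`/`gdna`),
#'   `replicate`, `ratio`. All ratios must be positive and every sample x SNP
#'   needs at least one replicate of each assay.
#' @return Tibble with one row per sample x SNP: `sample_id`, `snp_id`,
#'   `allele_a`, `allele_b`, `norm_log2_ratio`, `se`, `n_cdna`, `n_gdna`.
#' @export
#' @examples
#' m <- tibble::tibble(sample_id = "s1", snp_id = "rs144848",
#'                     allele_a = "G", allele_b = "T",
#'                     assay = c("cdna", "gdna"), replicate = 1L,
#'                     ratio = c(1.5, 1.25))
#' normalize_allelic_ratios(m)  # log2(1.5/1.25) = 0.263
normalize_allelic_ratios <- function(measurements) {
  bad <- which(!(measurements$ratio > 0) | !is.finite(measurements$ratio))
  if (length(bad)) {
    b <- measurements[bad[1], ]
    stop("non-positive allelic ratio for sample ", b$sample_id,
         ", ", b$assay, " replicate ", b$replicate, call. = FALSE)
  }
  out <- measurements |>
    dplyr::mutate(log2_ratio = log2(.data$ratio)) |>
    dplyr::group_by(.data$sample_id, .data$snp_id,
                    .data$allele_a, .data$allele_b, .data$assay) |>
    dplyr::summarise(m = mean(.data$log2_ratio),
                     v = stats::var(.data$log2_ratio),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assay", values_from = c("m", "v", "n"))
  for (col in c("m_cdna", "m_gdna")) {
    if (!col %in% names(out) || anyNA(out[[col]])) {
      stop("each sample x SNP needs both cdna and gdna replicates",
           call. = FALSE)
    }
  }
  out |>
    dplyr::mutate(
      norm_log2_ratio = .data$m_cdna - .data$m_gdna,
      se = sqrt(dplyr::coalesce(.data$v_cdna / .data$n_cdna, 0) +
                  dplyr::coalesce(.data$v_gdna / .data$n_gdna, 0))
    ) |>
    dplyr::select("sample_id", "snp_id", "allele_a", "allele_b",
                  "norm_log2_ratio", "se", "n_cdna", "n_gdna")
}

#' Call differential allelic expression against a fold-change threshold
#'
#' A sample shows DAE when its absolute normalized log2 ratio strictly
#' exceeds `log2(threshold_fold)` (exact equality at the boundary is not a
#' call). The direction is `allele_a` for positive ratios, `allele_b` for
#' negative. Optionally a per-sample one-sample t-test of the replicate
#' cDNA log-ratios against the gDNA mean is required as well
#' (`test = TRUE`), for assays with enough replicates to support it.
#'
#' @param normalized Output of [normalize_allelic_ratios()].
#' @param threshold_fold Fold-change threshold, must be > 1. Default 1.2
#'   (log2 = 0.263).
#' @param test Require a significant per-sample t-test in addition to
#'   threshold exceedance. Needs `measurements` to recompute replicate
#'   log-ratios. Default off.
#' @param alpha Significance level for the optional t-test.
#' @param measurements The replicate table, only needed when `test = TRUE`.
#' @return The input with columns `threshold_fold`, `is_dae`, `direction`
#'   (NA when not DAE) appended; and `p_value` when `test = TRUE`.
#' @export
call_dae <- function(normalized, threshold_fold = 1.2, test = FALSE,
                     alpha = 0.05, measurements = NULL) {
  if (!is.numeric(threshold_fold) || threshold_fold <= 1) {
    stop("threshold_fold must be > 1", call. = FALSE)
  }
  cut <- log2(threshold_fold)
  out <- normalized |>
    dplyr::mutate(
      threshold_fold = threshold_fold,
      is_dae = abs(.data$norm_log2_ratio) > cut,
      direction = dplyr::case_when(
        !.data$is_dae ~ NA_character_,
        .data$norm_log2_ratio > 0 ~ .data$allele_a,
        TRUE ~ .data$allele_b
      )
    )
  if (test) {
    if (is.null(measurements)) {
      stop("test = TRUE needs the replicate measurements", call. = FALSE)
    }
    p <- dae_replicate_pvalues(measurements)
    out <- dplyr::left_join(out, p, by = c("sample_id", "snp_id")) |>
      dplyr::mutate(
        is_dae = .data$is_dae & !is.na(.data$p_value) & .data$p_value < alpha,
        direction = dplyr::if_else(.data$is_dae, .data$direction,
                                   NA_character_)
      )
  }
  out
}

# One-sample t-test of replicate cDNA log2 ratios against the gDNA mean.
dae_replicate_pvalues <- function(measurements) {
  measurements |>
    dplyr::mutate(log2_ratio = log2(.data$ratio)) |>
    dplyr::group_by(.data$sample_id, .data$snp_id) |>
    dplyr::summarise(
      p_value = {
        cd <- .data$log2_ratio[.data$assay == "cdna"]
        gd <- mean(.data$log2_ratio[.data$assay == "gdna"])
        if (length(cd) < 2 || stats::sd(cd) == 0) NA_real_
        else stats::t.test(cd, mu = gd)$p.value
      },
      .groups = "drop"
    )
}

#' Summarize a set of DAE calls
#'
#' @param calls Output of [call_dae()]; must be non-empty.
#' @return One-row tibble: `n_tested`, `n_dae`, `n_dae_allele_a`,
#'   `n_dae_allele_b`, `fraction_dae`.
#' @export
#' @examples
#' # 29 of 45 heterozygotes over-expressing the first allele -> 64%
#' calls <- tibble::tibble(
#'   allele_a = "G", allele_b = "T",
#'   is_dae = rep(c(TRUE, FALSE), c(29, 16)),
#'   direction = rep(c("G", NA), c(29, 16)))
#' summarize_dae(calls)
summarize_dae <- function(calls) {
  if (nrow(calls) == 0) stop("no DAE calls to summarize", call. = FALSE)
  tibble::tibble(
    n_tested = nrow(calls),
    n_dae = sum(calls$is_dae),
    n_dae_allele_a = sum(calls$is_dae & calls$direction == calls$allele_a,
                         na.rm = TRUE),
    n_dae_allele_b = sum(calls$is_dae & calls$direction == calls$allele_b,
                         na.rm = TRUE),
    fraction_dae = sum(calls$is_dae) / nrow(calls)
  )
}

#' Plot normalized allelic ratios with the DAE threshold
#'
#' Dot plot of per-sample normalized log2 allelic ratios, colored by call,
#' with dashed lines at +/- log2(threshold).
#'
#' @param calls Output of [call_dae()].
#' @return A ggplot object.
#' @export
plot_dae_calls <- function(calls) {
  cut <- log2(calls$threshold_fold[1])
  calls |>
    dplyr::arrange(.data$norm_log2_ratio) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rank, y = .data$norm_log2_ratio,
                                 colour = .data$is_dae)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-cut, cut), linetype = "dashed") +
    ggplot2::labs(x = "sample (ranked)", y = "normalized log2 allelic ratio",
                  colour = "DAE") +
    ggplot2::theme_minimal()
}
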