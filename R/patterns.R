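# Built-in tag-SNP haplotype system for the BRCA2 DAE region.

#' Tag SNPs of the built-in BRCA2 haplotype system
#'
#' The seven SNPs whose alleles define the five common European haplotypes of
#' the BRCA2 differential-allelic-expression (DAE) region, in map order.
#' `rs144848` is the transcribed coding marker used for allelic quantification:
#' its G allele is carried only by haplotype 1, so samples heterozygous G/T at
#' the marker carry exactly one copy of haplotype 1.
#'
#' @return Character vector of SNP identifiers.
#' @export
brca2_tag_snps <- function() {
  c("rs1799943", "rs11571579", "rs9534174", "rs206070",
    "rs144848", "rs4942440", "rs9567576")
}

#' Marker SNP used for allelic transcript quantification
#'
#' @return Named list with `snp` (identifier), `allele_a` (the allele carried
#'   by haplotype 1, G) and `allele_b` (T).
#' @export
brca2_marker_snp <- function() {
  list(snp = "rs144848", allele_a = "G", allele_b = "T")
}

#' Built-in haplotype patterns, frequencies and observed DAE counts
#'
#' The five common haplotypes of the BRCA2 DAE region with their HapMap CEU
#' frequencies (percent), the allele carried at each of the seven tag SNPs,
#' the expression class assigned from the allelic-expression study
#' (haplotypes 2 and 5 are "low" expression, 1, 3 and 4 "high"), and the
#' published counts of rs144848-heterozygous samples with and without DAE by
#' second haplotype.
#'
#' @return A tibble with one row per haplotype: `haplotype`, `freq_pct`, one
#'   column per tag SNP, `expression_class`, `n_dae`, `n_no_dae`.
#' @export
#' @examples
#' brca2_haplotypes()
brca2_haplotypes <- function() {
  tibble::tribble(
    ~haplotype, ~freq_pct, ~rs1799943, ~rs11571579, ~rs9534174, ~rs206070,
    ~rs144848, ~rs4942440, ~rs9567576, ~expression_class, ~n_dae, ~n_no_dae,
    "hap1", 27.5, "G", "T", "A", "C", "G", "G", "T", "high", 29L, 12L,
    "hap2", 24.2, "A", "C", "G", "C", "T", "G", "G", "low",  10L,  0L,
    "hap3", 18.8, "G", "T", "A", "T", "T", "G", "T", "high",  4L,  4L,
    "hap4", 11.7, "G", "T", "G", "C", "T", "A", "T", "high", 10L,  7L,
    "hap5",  5.0, "G", "C", "G", "C", "T", "G", "G", "low",   5L,  1L
  )
}

#' Published mutation-carrier cohort size by disease status
#'
#' The association cohort: carriers censored at a first breast-cancer
#' diagnosis count as affected, the rest as unaffected. Note that
#' per-SNP genotyping tables (see [brca2_carrier_counts()]) cover the
#' subset successfully genotyped at that SNP, so their totals are smaller.
#'
#' @return A tibble with columns `status` and `n`.
#' @export
brca2_carrier_cohort <- function() {
  tibble::tibble(status = c("affected", "unaffected"),
                 n = c(1617L, 1137L))
}

#' Published carrier genotype counts for rs4942440
#'
#' Genotype counts of BRCA2 germline mutation carriers by disease status for
#' the tag SNP of the high-expression haplotype 4 (A is the minor allele).
#' Used as a worked input for [genotype_status_table()] and [trend_test()].
#'
#' @return A tibble with columns `genotype` ("GG", "AG", "AA"),
#'   `n_unaffected`, `n_affected`.
#' @export
brca2_carrier_counts <- function() {
  tibble::tibble(
    genotype     = c("GG", "AG", "AA"),
    n_unaffected = c(648L, 246L, 27L),
    n_affected   = c(817L, 271L, 24L)
  )
}

# Long (label, snp, allele, expression_class) view of a pattern table.
patterns_long <- function(patterns = brca2_haplotypes()) {
  snps <- setdiff(names(patterns),
                  c("haplotype", "freq_pct", "expression_class",
                    "n_dae", "n_no_dae"))
  patterns |>
    dplyr::select(dplyr::all_of(c("haplotype", snps, "expression_class"))) |>
    tidyr::pivot_longer(dplyr::all_of(snps),
                        names_to = "snp", values_to = "allele")
}

# SNP columns of a pattern table, in stored order.
pattern_snps <- function(patterns = brca2_haplotypes()) {
  setdiff(names(patterns),
          c("haplotype", "freq_pct", "expression_class", "n_dae", "n_no_dae"))
}

#' Read and write haplotype pattern tables
#'
#' Pattern files are TSV with columns `haplotype`, `snp`, `allele`,
#' `expression_class` (one row per haplotype x SNP), so haplotype systems
#' other than the built-in BRCA2 one can be analyzed.
#'
#' @param path File path.
#' @return `read_haplotype_patterns()` returns a wide tibble in the same shape
#'   as [brca2_haplotypes()] (without frequency and count columns);
#'   `write_haplotype_patterns()` returns `path` invisibly.
#' @export
read_haplotype_patterns <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  need <- c("haplotype", "snp", "allele", "expression_class")
  if (!all(need %in% names(long))) {
    stop("pattern file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  long |>
    tidyr::pivot_wider(id_cols = c("haplotype", "expression_class"),
                       names_from = "snp", values_from = "allele") |>
    dplyr::relocate("expression_class", .after = dplyr::last_col())
}

#' @rdname read_haplotype_patterns
#' @param patterns A wide pattern table such as [brca2_haplotypes()].
#' @export
write_haplotype_patterns <- function(patterns, path) {
  write_tsv_atomic(patterns_long(patterns), path)
  invisible(path)
}
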