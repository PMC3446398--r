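# Synthetic-data generators.
#
# Every generator draws from a substream of the master seed in the config
# (seed + a fixed offset per generator), so stages are individually
# reproducible and adding samples to one stage does not perturb another.

seed_offsets <- c(diplotypes = 11L, allelic = 23L, expression = 37L,
                  carriers = 53L)

#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohorts in one validated list.
#' Defaults emulate the built-in BRCA2 haplotype system: five haplotypes at
#' the published CEU frequencies (renormalized to sum to 1), low-expression
#' haplotypes transcribed at 0.7 relative to high ones (true cDNA allelic
#' ratio 1/0.7 = 1.43), 10% log-normal replicate measurement CV with 3
#' replicates per assay, and a carrier cohort with minor-allele frequency
#' 0.16 at the risk SNP spread over 11 studies.
#'
#' @param n_samples Number of tissue donors to simulate.
#' @param hap_freqs Named numeric vector of haplotype frequencies; must sum
#'   to 1 (within 1e-9) and name haplotypes present in `patterns`.
#' @param hap_expr_level Named positive vector: relative transcription rate
#'   of each haplotype.
#' @param meas_cv Coefficient of variation of the multiplicative (log-normal)
#'   replicate noise on peak ratios.
#' @param n_reps Replicates per assay (>= 1).
#' @param gene_effects Tibble with columns `gene`, `effect` (change in log2
#'   expression per low-expression haplotype carried), `sd` (residual SD),
#'   `housekeeping` (logical). Housekeeping genes must have effect 0.
#' @param carrier List with `n`, `log_hr` (per-allele log hazard ratio),
#'   `maf`, `baseline` (baseline hazard per year), `censor_rate` (exponential
#'   censoring rate per year), `n_studies`, and optionally `hap_log_hr`
#'   (named per-copy log-HRs by haplotype, for haplotype-level cohorts).
#' @param patterns Haplotype pattern table ([brca2_haplotypes()] by default).
#' @param seed Master integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 58,
                       hap_freqs = NULL,
                       hap_expr_level = c(hap1 = 1, hap2 = 0.7, hap3 = 1,
                                          hap4 = 1, hap5 = 0.7),
                       meas_cv = 0.10,
                       n_reps = 3,
                       gene_effects = default_gene_effects(),
                       carrier = list(),
                       patterns = brca2_haplotypes(),
                       seed = 1L) {
  if (is.null(hap_freqs)) {
    hap_freqs <- stats::setNames(patterns$freq_pct / sum(patterns$freq_pct),
                                 patterns$haplotype)
  }
  if (abs(sum(hap_freqs) - 1) > 1e-9) {
    stop("hap_freqs must sum to 1", call. = FALSE)
  }
  if (!all(names(hap_freqs) %in% patterns$haplotype)) {
    stop("hap_freqs names unknown to the pattern table", call. = FALSE)
  }
  if (any(hap_expr_level <= 0)) {
    stop("hap_expr_level entries must be positive", call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (meas_cv < 0) stop("meas_cv must be non-negative", call. = FALSE)
  stopifnot(is.data.frame(gene_effects),
            all(c("gene", "effect", "sd") %in% names(gene_effects)))
  if (!"housekeeping" %in% names(gene_effects)) gene_effects$housekeeping <- FALSE
  if (any(gene_effects$housekeeping & gene_effects$effect != 0)) {
    stop("housekeeping genes must have effect 0", call. = FALSE)
  }
  carrier <- utils::modifyList(
    list(n = 2754, log_hr = log(0.85), maf = 0.16, baseline = 0.01,
         censor_rate = 0.007, n_studies = 11, hap_log_hr = NULL),
    carrier)
  if (carrier$maf <= 0 || carrier$maf >= 1) {
    stop("carrier minor-allele frequency must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_samples = n_samples, hap_freqs = hap_freqs,
                 hap_expr_level = hap_expr_level, meas_cv = meas_cv,
                 n_reps = as.integer(n_reps), gene_effects = gene_effects,
                 carrier = carrier, patterns = patterns,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Default planted effects: SPP1 lower with low-expression haplotypes
# (HH vs HL fold 1.74, i.e. log2 effect -log2(1.74) per low copy), MUC16
# higher (high-vs-low group difference -0.125 over two copies), and the four
# usual qPCR housekeeping genes, two stable and two noisy.
default_gene_effects <- function() {
  tibble::tibble(
    gene = c("SPP1", "MUC16", "ACTB", "HPRT1", "GAPDH", "RN18S"),
    effect = c(-log2(1.74), 0.0625, 0, 0, 0, 0),
    sd = c(0.30, 0.05, 0.05, 0.05, 0.50, 0.50),
    housekeeping = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

sub_seed <- function(config, stage) {
  (config$seed + seed_offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate diplotypes and unphased tag-SNP genotypes
#'
#' Haplotypes are drawn i.i.d. from the configured frequencies (random
#' mating); the genotype at each SNP is the unphased union of the two
#' patterns' alleles, stored as `"X/Y"` strings in pattern-table allele
#' order.
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `hap_a`, `hap_b`, `group` (HH/HL/LL) and
#'   one genotype column per tag SNP.
#' @export
sim_diplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config, "diplotypes"), {
    labs <- names(config$hap_freqs)
    hap_a <- sample(labs, config$n_samples, replace = TRUE,
                    prob = config$hap_freqs)
    hap_b <- sample(labs, config$n_samples, replace = TRUE,
                    prob = config$hap_freqs)
  })
  pat <- config$patterns
  snps <- pattern_snps(pat)
  al <- as.matrix(pat[, snps])
  rownames(al) <- pat$haplotype
  geno <- purrr::map(snps, function(s) {
    paste(al[hap_a, s], al[hap_b, s], sep = "/")
  })
  names(geno) <- snps
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(config$n_samples)),
    hap_a = hap_a, hap_b = hap_b,
    group = classify_group(hap_a, hap_b, pat),
    !!!geno
  )
}

#' Simulate replicate allelic peak-ratio measurements
#'
#' Only samples heterozygous at the transcribed marker SNP (carrying one
#' allele-A and one allele-B haplotype) yield records. The true cDNA ratio
#' is the ratio of the two haplotypes' transcription levels
#' (A-haplotype over B-haplotype); the true gDNA ratio is 1. Each replicate
#' multiplies the truth by log-normal noise with the configured CV.
#'
#' @param diplotypes Output of [sim_diplotypes()].
#' @param config A [sim_config()].
#' @param marker Marker SNP description, as [brca2_marker_snp()].
#' @return Long tibble of replicate measurements in the interchange layout
#'   (`sample_id`, `snp_id`, `allele_a`, `allele_b`, `assay`, `replicate`,
#'   `ratio`).
#' @export
sim_allelic_measurements <- function(diplotypes, config,
                                     marker = brca2_marker_snp()) {
  stopifnot(inherits(config, "sim_config"))
  pat <- config$patterns
  allele_of <- stats::setNames(pat[[marker$snp]], pat$haplotype)
  a_of <- allele_of[diplotypes$hap_a]
  b_of <- allele_of[diplotypes$hap_b]
  het <- a_of != b_of
  d <- diplotypes[het, ]
  if (nrow(d) == 0) {
    return(tibble::tibble(sample_id = character(), snp_id = character(),
                          allele_a = character(), allele_b = character(),
                          assay = character(), replicate = integer(),
                          ratio = double()))
  }
  # orient so the reported ratio is marker allele_a over allele_b
  hap_on_a <- ifelse(allele_of[d$hap_a] == marker$allele_a, d$hap_a, d$hap_b)
  hap_on_b <- ifelse(allele_of[d$hap_a] == marker$allele_a, d$hap_b, d$hap_a)
  true_ratio <- config$hap_expr_level[hap_on_a] / config$hap_expr_level[hap_on_b]
  sdlog <- sqrt(log(1 + config$meas_cv^2))
  n_reps <- config$n_reps
  base <- tidyr::expand_grid(
    i = seq_len(nrow(d)),
    assay = c("cdna", "gdna"),
    replicate = seq_len(n_reps)
  )
  withr::with_seed(sub_seed(config, "allelic"), {
    noise <- if (sdlog > 0) {
      stats::rlnorm(nrow(base), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(base))
  })
  truth <- ifelse(base$assay == "cdna", true_ratio[base$i], 1)
  tibble::tibble(
    sample_id = d$sample_id[base$i],
    snp_id = marker$snp,
    allele_a = marker$allele_a,
    allele_b = marker$allele_b,
    assay = base$assay,
    replicate = as.integer(base$replicate),
    ratio = truth * noise
  )
}

#' Simulate a downstream expression table
#'
#' For each gene, measurement = intercept + effect x (number of
#' low-expression haplotypes carried) + Normal(0, sd). Housekeeping genes
#' have effect 0 by construction. In Ct mode the sign is inverted (higher
#' expression means lower Ct) and a gene-specific baseline Ct is added.
#'
#' @param diplotypes Output of [sim_diplotypes()].
#' @param config A [sim_config()].
#' @param mode `"log_intensity"` (default) or `"ct"`.
#' @param intercept Baseline measurement level per gene (single number).
#' @return Tibble `sample_id`, `group`, `n_low` plus one numeric column per
#'   gene; attribute `"genes"` lists the gene columns, `"mode"` the mode,
#'   `"housekeeping"` the housekeeping genes.
#' @export
sim_expression <- function(diplotypes, config,
                           mode = c("log_intensity", "ct"),
                           intercept = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(intercept)) intercept <- if (mode == "ct") 25 else 8
  ge <- config$gene_effects
  pat <- config$patterns
  low <- pat$haplotype[pat$expression_class == "low"]
  n_low <- (diplotypes$hap_a %in% low) + (diplotypes$hap_b %in% low)
  n <- nrow(diplotypes)
  withr::with_seed(sub_seed(config, "expression"), {
    cols <- purrr::pmap(ge, function(gene, effect, sd, housekeeping) {
      expr <- effect * n_low + stats::rnorm(n, 0, sd)
      if (mode == "ct") intercept - expr else intercept + expr
    })
  })
  names(cols) <- ge$gene
  out <- tibble::tibble(sample_id = diplotypes$sample_id,
                        group = diplotypes$group,
                        n_low = n_low, !!!cols)
  attr(out, "genes") <- ge$gene
  attr(out, "mode") <- mode
  attr(out, "housekeeping") <- ge$gene[ge$housekeeping]
  out
}

#' Simulate a mutation-carrier cohort
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at the configured
#' minor-allele frequency (SNP model) or as diplotypes from the haplotype
#' pool (haplotype model). Event times are exponential with hazard
#' `baseline * exp(linear predictor)`; censoring times are exponential with
#' rate `censor_rate`; `status` is 1 when the event precedes censoring.
#' Studies are assigned round-robin.
#'
#' @param config A [sim_config()].
#' @param model `"snp"` (additive per-allele log-HR on minor-allele count) or
#'   `"haplotype"` (per-copy log-HRs from `carrier$hap_log_hr`, zero for
#'   unlisted haplotypes).
#' @return Tibble `carrier_id`, `study`, `status`, `time`, plus `genotype`
#'   (SNP model) or `hap_a`/`hap_b` and per-haplotype dosage columns
#'   (haplotype model).
#' @export
sim_carriers <- function(config, model = c("snp", "haplotype")) {
  model <- match.arg(model)
  stopifnot(inherits(config, "sim_config"))
  cc <- config$carrier
  n <- cc$n
  withr::with_seed(sub_seed(config, "carriers"), {
    if (model == "snp") {
      g <- stats::rbinom(n, 2, cc$maf)
      eta <- cc$log_hr * g
    } else {
      labs <- names(config$hap_freqs)
      hap_a <- sample(labs, n, replace = TRUE, prob = config$hap_freqs)
      hap_b <- sample(labs, n, replace = TRUE, prob = config$hap_freqs)
      beta <- stats::setNames(rep(0, length(labs)), labs)
      if (!is.null(cc$hap_log_hr)) beta[names(cc$hap_log_hr)] <- cc$hap_log_hr
      eta <- beta[hap_a] + beta[hap_b]
    }
    t_event <- stats::rexp(n, rate = cc$baseline * exp(eta))
    t_cens <- if (cc$censor_rate > 0) {
      stats::rexp(n, rate = cc$censor_rate)
    } else rep(Inf, n)
  })
  status <- as.integer(t_event <= t_cens)
  out <- tibble::tibble(
    carrier_id = sprintf("C%05d", seq_len(n)),
    study = sprintf("study%02d", ((seq_len(n) - 1L) %% cc$n_studies) + 1L),
    status = status,
    time = pmin(t_event, t_cens)
  )
  if (model == "snp") {
    out$genotype <- g
  } else {
    out$hap_a <- hap_a
    out$hap_b <- hap_b
    for (h in names(config$hap_freqs)) {
      out[[h]] <- (hap_a == h) + (hap_b == h)
    }
  }
  out
}
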