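# Genotype tabulation, trend test, and the Cox partial-likelihood fitter
# (checked against survival:: as an independent oracle).

sim_cox_data <- function(n, beta, maf = 0.3, base = 0.08, cens = 0.05,
                         n_studies = 2, seed = 1) {
  withr::with_seed(seed, {
    g <- rbinom(n, 2, maf)
    t_ev <- rexp(n, base * exp(beta * g))
    t_c <- if (cens > 0) rexp(n, cens) else rep(Inf, n)
    tibble::tibble(
      carrier_id = paste0("c", seq_len(n)),
      study = paste0("st", ((seq_len(n) - 1) %% n_studies) + 1),
      genotype = g,
      status = as.integer(t_ev <= t_c),
      time = pmin(t_ev, t_c))
  })
}

test_that("genotype/status tabulation reproduces published percentages", {
  counts <- brca2_carrier_counts()
  carriers <- dplyr::bind_rows(
    tidyr::uncount(dplyr::transmute(counts, genotype, n = n_unaffected),
                   n) |> dplyr::mutate(status = 0L),
    tidyr::uncount(dplyr::transmute(counts, genotype, n = n_affected),
                   n) |> dplyr::mutate(status = 1L))
  tab <- genotype_status_table(carriers)
  expect_equal(tab$pct_unaffected[tab$genotype == "GG"], 70.36)
  expect_equal(tab$pct_affected[tab$genotype == "GG"], 73.47)
  expect_equal(tab$pct_affected[tab$genotype == "AA"], 2.16)
  # totals cover the subset genotyped at this SNP
  totals <- attr(tab, "totals")
  expect_equal(unname(totals["affected"]), sum(counts$n_affected))
  expect_equal(unname(totals["unaffected"]), sum(counts$n_unaffected))
  expect_equal(unname(totals["total"]),
               sum(counts$n_affected) + sum(counts$n_unaffected))
  # the full cohort bookkeeping: affected + unaffected carriers
  cohort <- brca2_carrier_cohort()
  expect_equal(sum(cohort$n), 2754)
  # single record occupies 100% of its column
  one <- genotype_status_table(tibble::tibble(genotype = 1, status = 1))
  expect_equal(one$pct_affected, 100)
  expect_error(genotype_status_table(
    tibble::tibble(genotype = NA, status = 1)), "non-missing")
})

test_that("trend statistic matches the independent implementation", {
  counts <- dplyr::mutate(brca2_carrier_counts(), genotype = 0:2)
  z <- trend_test(counts)
  oracle <- stats::prop.trend.test(counts$n_affected,
                                   counts$n_affected + counts$n_unaffected,
                                   score = 0:2)
  expect_equal(z$z^2, unname(oracle$statistic))
  expect_equal(z$p_value, oracle$p.value)
  # identical genotype distributions in both columns: Z = 0, p = 1
  flat <- tibble::tibble(genotype = 0:2, n_unaffected = c(50, 30, 20),
                         n_affected = c(50, 30, 20))
  expect_equal(trend_test(flat)$z, 0)
  expect_equal(trend_test(flat)$p_value, 1)
  # minor-allele excess among affected gives a positive Z
  up <- tibble::tibble(genotype = 0:2, n_unaffected = c(70, 25, 5),
                       n_affected = c(50, 35, 15))
  expect_gt(trend_test(up)$z, 0)
})

test_that("the Cox fitter matches survival::coxph on both tie schemes", {
  skip_if_not_installed("survival")
  d <- sim_cox_data(400, log(0.8), seed = 5)
  d$time <- round(d$time, 1) + 0.1  # force ties
  for (ties in c("breslow", "efron")) {
    fit <- cox_per_allele(d, ties = ties)
    oracle <- survival::coxph(survival::Surv(time, status) ~ genotype,
                              data = d, ties = ties)
    expect_equal(fit$fit$beta, unname(coef(oracle)), tolerance = 1e-6)
    expect_equal(fit$fit$se, unname(sqrt(diag(vcov(oracle)))),
                 tolerance = 1e-6)
    expect_equal(fit$fit$loglik, oracle$loglik[2], tolerance = 1e-6)
  }
  # 2-df genotype coding
  fit2 <- cox_per_allele(d, coding = "2df")
  oracle2 <- survival::coxph(
    survival::Surv(time, status) ~ I(genotype == 1) + I(genotype == 2),
    data = d, ties = "breslow")
  expect_equal(fit2$fit$beta, unname(coef(oracle2)), tolerance = 1e-6)
  expect_equal(fit2$lrt$statistic,
               2 * (oracle2$loglik[2] - oracle2$loglik[1]),
               tolerance = 1e-6)
  # study-stratified baseline
  fits <- cox_per_allele(d, stratify_by_study = TRUE)
  oracles <- survival::coxph(
    survival::Surv(time, status) ~ genotype + survival::strata(study),
    data = d, ties = "breslow")
  expect_equal(fits$fit$beta, unname(coef(oracles)), tolerance = 1e-6)
})

test_that("left-truncated records match a counting-process oracle", {
  skip_if_not_installed("survival")
  d <- sim_cox_data(200, log(0.7), seed = 8)
  d$entry_time <- d$time * runif(200, 0, 0.5)
  fit <- cox_per_allele(d)
  oracle <- survival::coxph(
    survival::Surv(entry_time, time, status) ~ genotype,
    data = d, ties = "breslow")
  expect_equal(fit$fit$beta, unname(coef(oracle)), tolerance = 1e-6)
})

test_that("score test at beta = 0 equals the log-rank statistic", {
  skip_if_not_installed("survival")
  d <- sim_cox_data(300, 0, maf = 0.5, seed = 9)
  d$genotype <- as.integer(d$genotype > 0)  # two groups
  derivs <- getFromNamespace("cox_stratum_derivs", "daehap")
  dd <- derivs(0, matrix(as.numeric(d$genotype), ncol = 1),
               d$time, d$status)
  score_stat <- dd$grad^2 / dd$hess[1, 1]
  lr <- survival::survdiff(survival::Surv(time, status) ~ genotype,
                           data = d)
  expect_equal(unname(score_stat), unname(lr$chisq), tolerance = 1e-6)
})

test_that("estimates behave under allele recoding and optimizer contract", {
  d <- sim_cox_data(500, log(0.85), seed = 11)
  fit <- cox_per_allele(d)
  flipped <- dplyr::mutate(d, genotype = 2L - genotype)
  fit_fl <- cox_per_allele(flipped)
  expect_equal(fit_fl$fit$beta, -fit$fit$beta, tolerance = 1e-7)
  expect_lt(max(abs(fit$fit$score)), 1e-6)  # gradient at the optimum
  td <- tidy(fit)
  expect_true(td$conf_low < td$estimate && td$estimate < td$conf_high)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_error(cox_per_allele(dplyr::mutate(d, status = 0L)), "affected")
  expect_error(cox_per_allele(dplyr::mutate(d, genotype = 1L)), "variation")
})

test_that("uncensored exponential data agree with the closed-form
           rate ratio", {
  d <- sim_cox_data(1500, log(0.7), maf = 0.5, cens = 0, seed = 13)
  d$genotype <- as.integer(d$genotype > 0)
  # administratively censor two records at their observed times; the
  # exponential closed form d/T is unchanged by that
  d$status[c(1, 2)] <- 0L
  fit <- cox_per_allele(d)
  d1 <- sum(d$genotype == 1); t1 <- sum(d$time[d$genotype == 1])
  d0 <- sum(d$genotype == 0); t0 <- sum(d$time[d$genotype == 0])
  beta_closed <- log((d1 / t1) / (d0 / t0))
  se <- sqrt(1 / d1 + 1 / d0)
  expect_lt(abs(fit$fit$beta - beta_closed), 3 * se)
})

test_that("heterogeneity test needs several studies and detects conflict", {
  expect_error(
    heterogeneity_test(sim_cox_data(100, 0, n_studies = 1, seed = 2)),
    ">= 2")
  d1 <- sim_cox_data(600, 0.8, n_studies = 1, seed = 3)
  d2 <- sim_cox_data(600, -0.8, n_studies = 1, seed = 4)
  d2$study <- "st2"; d2$carrier_id <- paste0("x", d2$carrier_id)
  het <- heterogeneity_test(dplyr::bind_rows(d1, d2))
  expect_equal(het$df, 1)
  expect_lt(het$p_value, 0.001)
  # a study without genotype variation is dropped with a message
  d3 <- dplyr::mutate(sim_cox_data(50, 0, n_studies = 1, seed = 6),
                      study = "st3", genotype = 1L)
  expect_message(het2 <- heterogeneity_test(dplyr::bind_rows(d1, d2, d3)),
                 "no df")
  expect_equal(het2$n_studies, 2)
})

test_that("haplotype dosages reduce to a plain Cox fit when phase-known", {
  skip_if_not_installed("survival")
  sc <- sim_config(carrier = list(n = 800, hap_log_hr = c(hap4 = log(0.8)),
                                  n_studies = 3),
                   seed = 15)
  cc <- sim_carriers(sc, model = "haplotype")
  fit <- haplotype_cohort_assoc(cc, haplotypes = paste0("hap", 1:5),
                                reference = c("hap2", "hap5"))
  oracle <- survival::coxph(
    survival::Surv(time, status) ~ hap1 + hap3 + hap4,
    data = cc, ties = "breslow")
  expect_equal(fit$fit$beta, unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(fit$terms, c("hap1", "hap3", "hap4"))
  # all carriers homozygous for the reference: nothing to estimate
  ref_only <- dplyr::mutate(cc, hap1 = 0, hap3 = 0, hap4 = 0,
                            hap2 = 2, hap5 = 0)
  expect_error(haplotype_cohort_assoc(ref_only,
                                      haplotypes = paste0("hap", 1:5),
                                      reference = c("hap2", "hap5")),
               "estimable|variation")
  expect_error(haplotype_cohort_assoc(cc, haplotypes = paste0("hap", 1:5),
                                      reference = "hap9"),
               "reference")
})
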