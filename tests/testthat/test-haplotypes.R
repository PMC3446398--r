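# Haplotype assignment, expression groups, LD, and EM phasing.

test_that("second-haplotype assignment round-trips every built-in pattern", {
  for (h in c("hap1", "hap2", "hap3", "hap4", "hap5")) {
    gt <- make_genotype("hap1", h)
    res <- assign_second_haplotype(gt)
    expect_equal(res$hap_b, h)
    expect_equal(res$hap_a, "hap1")
  }
  # hap1 + hap2 is one high and one low haplotype
  expect_equal(assign_second_haplotype(make_genotype("hap1", "hap2"))$group,
               "HL")
  expect_equal(assign_second_haplotype(make_genotype("hap1", "hap1"))$group,
               "HH")
})

test_that("unresolvable residuals are excluded with a warning", {
  gt <- make_genotype("hap1", "hap2")
  gt$rs206070 <- "C/A"  # allele A at rs206070 matches no pattern
  expect_warning(res <- assign_second_haplotype(gt), "unresolvable")
  expect_equal(nrow(res), 0)
  # missing tag SNP column is an error
  expect_error(assign_second_haplotype(gt[, 1:5]), "missing tag SNP")
})

test_that("expression group classification counts low haplotypes", {
  expect_equal(classify_group("hap1", "hap3"), "HH")
  expect_equal(classify_group("hap2", "hap5"), "LL")
  expect_equal(classify_group("hap4", "hap5"), "HL")
  expect_equal(classify_group(c("hap1", "hap2"), c("hap2", "hap2")),
               c("HL", "LL"))
  expect_error(classify_group("hap1", "hap9"), "unknown")
})

test_that("LD attains its textbook limits", {
  # perfect coupling: only AB and ab present
  coupled <- tibble::tibble(l1 = rep(c("A", "a"), c(30, 70)),
                            l2 = rep(c("B", "b"), c(30, 70)))
  ld <- pairwise_ld(coupled)
  expect_equal(ld$r2, 1)
  expect_equal(ld$Dprime, 1)
  # independent loci at equilibrium
  indep <- tidyr::expand_grid(l1 = rep(c("A", "a"), each = 2),
                              l2 = c("B", "b"))
  ld0 <- pairwise_ld(indep)
  expect_equal(ld0$r2, 0)
  expect_equal(ld0$D, 0)
  # monomorphic locus: undefined, not an error
  mono <- tibble::tibble(l1 = rep("A", 10), l2 = rep(c("B", "b"), 5))
  expect_false(pairwise_ld(mono)$defined)
  expect_error(pairwise_ld(tibble::tibble(l1 = c("A", "C", "G"),
                                          l2 = c("B", "b", "B"))),
               "biallelic")
})

test_that("a constructed 100-haplotype table reproduces r2 = 0.55", {
  # integer counts found by brute-force search over all 2x2 tables of 100
  # haplotypes; direct-formula oracle below
  cnt <- c(AB = 1, Ab = 37, aB = 49, ab = 13)
  haps <- tibble::tibble(
    l1 = rep(c("A", "A", "a", "a"), cnt),
    l2 = rep(c("B", "b", "B", "b"), cnt))
  nA <- cnt["AB"] + cnt["Ab"]; nB <- cnt["AB"] + cnt["aB"]
  r2_oracle <- (100 * cnt["AB"] - nA * nB)^2 /
    (nA * (100 - nA) * nB * (100 - nB))
  ld <- pairwise_ld(haps)
  expect_equal(ld$r2, unname(r2_oracle))
  expect_lt(abs(ld$r2 - 0.55), 1e-3)
})

test_that("LD is invariant under allele relabelling", {
  set.seed(5)
  haps <- tibble::tibble(l1 = sample(c("A", "a"), 80, TRUE),
                         l2 = sample(c("B", "b"), 80, TRUE, c(0.7, 0.3)))
  base <- pairwise_ld(haps)
  flipped <- dplyr::mutate(haps, l1 = dplyr::if_else(l1 == "A", "a", "A"))
  both <- dplyr::mutate(flipped, l2 = dplyr::if_else(l2 == "B", "b", "B"))
  for (v in list(flipped, both)) {
    ld <- pairwise_ld(v)
    expect_equal(ld$r2, base$r2)
    expect_equal(ld$Dprime, base$Dprime)
  }
})

test_that("phase-unambiguous cohorts reduce EM to direct counting", {
  gt <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    snp1 = c("A/A", "A/A", "G/G", "A/G"),
    snp2 = c("C/C", "C/T", "C/C", "C/C"))  # at most one het site each
  em <- em_haplotype_frequencies(gt)
  counted <- table(c("AC", "AC", "AC", "AT", "GC", "GC", "AC", "GC")) / 8
  for (h in names(counted)) {
    expect_equal(em$frequencies$freq[em$frequencies$haplotype == h],
                 unname(counted[[h]]), tolerance = 1e-6)
  }
  expect_true(em$converged)
})

test_that("a lone double heterozygote splits posterior mass evenly", {
  gt <- tibble::tibble(sample_id = "s1", snp1 = "A/G", snp2 = "C/T")
  em <- em_haplotype_frequencies(gt)
  expect_equal(nrow(em$posterior), 2)
  expect_equal(em$posterior$posterior, c(0.5, 0.5))
})

test_that("EM log-likelihood is monotone and matches a grid-search oracle", {
  set.seed(31)
  # three-haplotype toy over two SNPs
  pool <- c(AC = 0.5, AT = 0.3, GC = 0.2)
  n <- 60
  draw <- function() sample(names(pool), 1, prob = pool)
  h1 <- replicate(n, draw()); h2 <- replicate(n, draw())
  gt <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    snp1 = paste(pmin(substr(h1, 1, 1), substr(h2, 1, 1)),
                 pmax(substr(h1, 1, 1), substr(h2, 1, 1)), sep = "/"),
    snp2 = paste(pmin(substr(h1, 2, 2), substr(h2, 2, 2)),
                 pmax(substr(h1, 2, 2), substr(h2, 2, 2)), sep = "/"))
  em <- em_haplotype_frequencies(gt)
  expect_true(all(diff(em$loglik) >= -1e-9))
  expect_equal(sum(em$frequencies$freq), 1, tolerance = 1e-9)

  # brute-force likelihood over the 4-haplotype frequency simplex,
  # evaluated on genotype classes; summing f(h1)f(h2) over every per-site
  # allele assignment counts each ordered diplotype once per homozygous
  # site, hence the 2^(hom sites) divisor
  all_haps <- c("AC", "AT", "GC", "GT")
  classes <- dplyr::count(gt, snp1, snp2)
  class_prob <- function(f, s1, s2) {
    g1 <- strsplit(s1, "/")[[1]]; g2 <- strsplit(s2, "/")[[1]]
    p <- 0
    for (x1 in 1:2) for (x2 in 1:2) {
      ha <- paste0(g1[x1], g2[x2])
      hb <- paste0(g1[3 - x1], g2[3 - x2])
      p <- p + f[ha] * f[hb]
    }
    p / 2^((g1[1] == g1[2]) + (g2[1] == g2[2]))
  }
  geno_ll <- function(f) {
    names(f) <- all_haps
    sum(purrr::pmap_dbl(classes, function(snp1, snp2, n) {
      n * log(class_prob(f, snp1, snp2))
    }))
  }
  step <- 0.02
  best_ll <- -Inf; best_f <- NULL
  for (f1 in seq(0, 1, step)) for (f2 in seq(0, 1 - f1, step)) {
    for (f3 in seq(0, 1 - f1 - f2, step)) {
      f <- c(f1, f2, f3, 1 - f1 - f2 - f3)
      ll <- geno_ll(pmax(f, 1e-12))
      if (ll > best_ll) { best_ll <- ll; best_f <- f }
    }
  }
  em_ll <- em$loglik[length(em$loglik)]
  expect_gte(em_ll, best_ll - 1e-6)  # EM at least as good as the grid
  freqs <- stats::setNames(rep(0, 4), all_haps)
  freqs[em$frequencies$haplotype] <- em$frequencies$freq
  expect_true(all(abs(freqs - best_f) <= step))
})

test_that("EM recovers the five-haplotype pool within 3 SE at n = 200", {
  sc <- sim_config(n_samples = 200, seed = 17)
  d <- sim_diplotypes(sc)
  em <- em_haplotype_frequencies(d[, c("sample_id", brca2_tag_snps())])
  pat <- brca2_haplotypes()
  hap_string <- apply(as.matrix(pat[, brca2_tag_snps()]), 1, paste,
                      collapse = "")
  truth <- table(factor(c(d$hap_a, d$hap_b), levels = pat$haplotype)) / 400
  for (i in seq_along(hap_string)) {
    est <- em$frequencies$freq[em$frequencies$haplotype == hap_string[i]]
    if (length(est) == 0) est <- 0
    se <- sqrt(truth[i] * (1 - truth[i]) / 400)
    expect_lt(abs(est - truth[i]), 3 * max(se, 0.01))
  }
})
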