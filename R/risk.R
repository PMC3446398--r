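# Carrier risk modelling: genotype tabulation, Cochran-Armitage trend
# statistic, and a purpose-built Cox proportional-hazards fitter
# (Newton-Raphson on the partial likelihood, Breslow or Efron ties,
# optional stratification and left truncation). The retrospective-likelihood
# machinery used for ascertainment-corrected carrier analyses is
# deliberately not part of this package; these are plain cohort fits and
# reports are labelled accordingly.

#' Genotype-by-status counts with column percentages
#'
#' @param carriers Tibble with `genotype` (0/1/2 or labels) and `status`
#'   (1 = affected). Missing genotypes are dropped.
#' @return Tibble per genotype: `genotype`, `n_unaffected`, `pct_unaffected`,
#'   `n_affected`, `pct_affected` (column percentages, 2 decimals), plus a
#'   totals attribute `"totals"` (named vector).
#' @export
genotype_status_table <- function(carriers) {
  x <- dplyr::filter(carriers, !is.na(.data$genotype))
  if (nrow(x) == 0) stop("no non-missing genotypes", call. = FALSE)
  out <- x |>
    dplyr::count(.data$genotype, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L, names_prefix = "s")
  for (col in c("s0", "s1")) if (!col %in% names(out)) out[[col]] <- 0L
  out <- out |>
    dplyr::transmute(
      genotype = .data$genotype,
      n_unaffected = .data$s0,
      pct_unaffected = round(100 * .data$s0 / sum(.data$s0), 2),
      n_affected = .data$s1,
      pct_affected = round(100 * .data$s1 / sum(.data$s1), 2)
    )
  attr(out, "totals") <- c(unaffected = sum(out$n_unaffected),
                           affected = sum(out$n_affected),
                           total = sum(out$n_unaffected) + sum(out$n_affected))
  out
}

#' Cochran-Armitage trend test on a genotype-by-status table
#'
#' Trend statistic with scores (0, 1, 2) on minor-allele count. The signed
#' Z is positive when the minor allele is in excess among the affected.
#'
#' @param counts Tibble with `genotype` coded 0/1/2 (or a `genotype` column
#'   convertible to those scores), `n_unaffected`, `n_affected`.
#' @return One-row tibble `z`, `p_value` (two-sided).
#' @export
trend_test <- function(counts) {
  g <- counts$genotype
  scores <- if (is.numeric(g)) g else (seq_along(g) - 1)
  r <- counts$n_affected          # cases per genotype
  n <- counts$n_affected + counts$n_unaffected
  N <- sum(n); R <- sum(r)
  if (N == 0 || R == 0 || R == N) stop("degenerate table", call. = FALSE)
  num <- sum(scores * (r - n * R / N))
  p_bar <- R / N
  s2 <- p_bar * (1 - p_bar) *
    (sum(scores^2 * n) - sum(scores * n)^2 / N)
  if (s2 <= 0) stop("no genotype variation", call. = FALSE)
  z <- num / sqrt(s2)
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# ---- Cox partial likelihood ------------------------------------------------

# Log partial likelihood, gradient and Hessian for one stratum.
# X: n x p matrix; time, status, entry (may be NULL). Ties: breslow | efron.
# Without left truncation the risk sums S0/S1/S2 come from cumulative sums
# over the sample sorted by decreasing time (O(n log n)); with entry times
# the risk set is rebuilt per event time.
cox_stratum_derivs <- function(beta, X, time, status, entry = NULL,
                               ties = "breslow") {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)

  ev <- which(status == 1)
  any_ties <- anyDuplicated(time[ev]) > 0
  if (is.null(entry) && (ties == "breslow" || !any_ties)) {
    # fully vectorized Breslow path (Efron coincides without ties)
    ord <- order(time, decreasing = TRUE)
    t_s <- time[ord]
    X_s <- X[ord, , drop = FALSE]
    w_s <- w[ord]
    cw <- cumsum(w_s)
    cXw <- apply(X_s * w_s, 2, cumsum)
    if (p == 1) cXw <- matrix(cXw, ncol = 1)
    pair_i <- rep(seq_len(p), times = p)
    pair_j <- rep(seq_len(p), each = p)
    cXXw <- apply(X_s[, pair_i, drop = FALSE] * X_s[, pair_j, drop = FALSE] *
                    w_s, 2, cumsum)
    if (length(t_s) == 1) cXXw <- matrix(cXXw, nrow = 1)
    ev_t <- time[ev]
    ut <- sort(unique(ev_t))   # keep exact doubles (no character round-trip)
    gidx <- match(ev_t, ut)
    d_t <- tabulate(gidx, length(ut))
    xd <- rowsum(X[ev, , drop = FALSE], gidx)
    k <- findInterval(-ut, -t_s)  # risk-set size at each event time
    S0 <- cw[k]
    S1 <- cXw[k, , drop = FALSE]
    S2 <- cXXw[k, , drop = FALSE]
    R <- S1 / S0
    ll <- sum(eta[ev]) - sum(d_t * log(S0))
    grad <- colSums(xd) - colSums(d_t * R)
    hess <- matrix(colSums(d_t * S2 / S0), p, p) -
      crossprod(R * sqrt(d_t))
    return(list(loglik = ll, grad = grad, hess = hess))
  }

  risk_sums <- NULL
  if (is.null(entry)) {
    ord <- order(time, decreasing = TRUE)
    t_s <- time[ord]
    X_s <- X[ord, , drop = FALSE]
    w_s <- w[ord]
    cw <- cumsum(w_s)
    cXw <- apply(X_s * w_s, 2, cumsum)
    if (p == 1) cXw <- matrix(cXw, ncol = 1)
    pair_i <- rep(seq_len(p), times = p)
    pair_j <- rep(seq_len(p), each = p)
    cXXw <- apply(X_s[, pair_i, drop = FALSE] * X_s[, pair_j, drop = FALSE] *
                    w_s, 2, cumsum)
    if (length(t_s) == 1) cXXw <- matrix(cXXw, nrow = 1)
    risk_sums <- function(t) {
      k <- findInterval(-t, -t_s)  # count of time >= t
      list(S0 = cw[k], S1 = cXw[k, ],
           S2 = matrix(cXXw[k, ], p, p))
    }
  } else {
    risk_sums <- function(t) {
      r <- which(time >= t & entry < t)
      wr <- w[r]
      Xr <- X[r, , drop = FALSE]
      list(S0 = sum(wr), S1 = drop(crossprod(Xr, wr)),
           S2 = crossprod(Xr * wr, Xr))
    }
  }

  ev_groups <- split(which(status == 1), time[status == 1])
  for (g in ev_groups) {
    t <- time[g[1]]
    d <- length(g)
    rs <- risk_sums(t)
    S0 <- rs$S0; S1 <- rs$S1; S2 <- rs$S2
    if (!is.finite(S0) || S0 <= 0) next
    xd <- colSums(X[g, , drop = FALSE])
    if (ties == "breslow" || d == 1) {
      ll <- ll + sum(eta[g]) - d * log(S0)
      grad <- grad + xd - d * S1 / S0
      hess <- hess + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {  # efron
      wd <- w[g]
      Xd <- X[g, , drop = FALSE]
      S0d <- sum(wd)
      S1d <- drop(crossprod(Xd, wd))
      S2d <- crossprod(Xd * wd, Xd)
      for (l in seq_len(d) - 1) {
        S0l <- S0 - (l / d) * S0d
        S1l <- S1 - (l / d) * S1d
        S2l <- S2 - (l / d) * S2d
        ll <- ll - log(S0l)
        grad <- grad - S1l / S0l
        hess <- hess + S2l / S0l - tcrossprod(S1l / S0l)
      }
      ll <- ll + sum(eta[g])
      grad <- grad + xd
    }
  }
  list(loglik = ll, grad = grad, hess = hess)
}

# Newton-Raphson Cox fit over strata (shared beta, stratum-specific
# baselines). Returns beta, se, loglik, score at optimum, iteration count.
cox_fit <- function(X, time, status, strata = NULL, entry = NULL,
                    ties = c("breslow", "efron"),
                    tol = 1e-8, max_iter = 50) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(status) == 0) stop("no events in the data", call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("a covariate has no variation", call. = FALSE)
  }
  strata <- if (is.null(strata)) rep(1L, nrow(X)) else as.integer(factor(strata))
  idx <- split(seq_len(nrow(X)), strata)
  derivs <- function(beta) {
    parts <- purrr::map(idx, function(i) {
      cox_stratum_derivs(beta, X[i, , drop = FALSE], time[i], status[i],
                         if (is.null(entry)) NULL else entry[i], ties)
    })
    list(loglik = sum(purrr::map_dbl(parts, "loglik")),
         grad = Reduce(`+`, purrr::map(parts, "grad")),
         hess = Reduce(`+`, purrr::map(parts, "hess")))
  }
  beta <- numeric(p)
  converged <- FALSE
  flagged <- FALSE
  d <- derivs(beta)
  loglik0 <- d$loglik
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(d$hess, d$grad), error = function(e) NULL)
    if (is.null(step)) { flagged <- TRUE; break }
    # halve the step until the likelihood does not decrease
    for (h in 0:8) {
      cand <- beta + step / 2^h
      dc <- derivs(cand)
      if (is.finite(dc$loglik) && dc$loglik >= d$loglik - 1e-12) break
    }
    beta <- cand; d <- dc
    if (max(abs(d$grad)) < tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(d$grad)) >= 1e-4) flagged <- TRUE
  vcov <- tryCatch(solve(d$hess), error = function(e) {
    flagged <<- TRUE
    matrix(NA_real_, p, p)
  })
  if (flagged && !converged) {
    warning("Cox fit did not converge cleanly (monotone likelihood or ",
            "singular information); estimate flagged", call. = FALSE)
  }
  list(beta = unname(beta), se = unname(sqrt(diag(vcov))), vcov = vcov,
       loglik = d$loglik, loglik_null = loglik0, score = unname(d$grad),
       iterations = iter, converged = converged, flagged = flagged)
}

#' Per-allele and genotype Cox models for carrier cohorts
#'
#' Fits the Cox proportional-hazards model by Newton-Raphson on the partial
#' likelihood, starting from beta = 0, with Breslow tie handling by default
#' (Efron optional), optional baseline stratification by study, and support
#' for left-truncated records via an `entry_time` column. `coding =
#' "additive"` fits the per-allele (multiplicative) model on minor-allele
#' count; `coding = "2df"` fits separate log-HRs for heterozygotes and
#' rare homozygotes and adds a 2-df likelihood-ratio test.
#'
#' @param carriers Tibble with `genotype` (0/1/2), `status` (1 = affected),
#'   `time` (> 0), optionally `study` and `entry_time`.
#' @param coding `"additive"` or `"2df"`.
#' @param stratify_by_study Stratify the baseline hazard by `study`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `"carrier_cox"` with [tidy()]/[glance()] methods:
#'   estimates on the log scale, Wald 95% CIs as `exp(beta +/- 1.96 se)`,
#'   and for 2df coding a likelihood-ratio test.
#' @export
cox_per_allele <- function(carriers, coding = c("additive", "2df"),
                           stratify_by_study = FALSE,
                           ties = c("breslow", "efron")) {
  coding <- match.arg(coding)
  ties <- match.arg(ties)
  x <- dplyr::filter(carriers, !is.na(.data$genotype))
  if (sum(x$status == 1) == 0 || sum(x$status == 0) == 0) {
    stop("need both affected and unaffected carriers", call. = FALSE)
  }
  X <- if (coding == "additive") {
    matrix(as.numeric(x$genotype), ncol = 1,
           dimnames = list(NULL, "per_allele"))
  } else {
    cbind(het = as.numeric(x$genotype == 1),
          hom = as.numeric(x$genotype == 2))
  }
  strata <- if (stratify_by_study) x$study else NULL
  entry <- if ("entry_time" %in% names(x)) x$entry_time else NULL
  fit <- cox_fit(X, x$time, x$status, strata = strata, entry = entry,
                 ties = ties)
  lrt <- NULL
  if (coding == "2df") {
    stat <- 2 * (fit$loglik - fit$loglik_null)
    lrt <- tibble::tibble(statistic = stat, df = 2L,
                          p_value = stats::pchisq(stat, 2, lower.tail = FALSE))
  }
  structure(list(fit = fit, coding = coding, terms = colnames(X),
                 n = nrow(x), n_event = sum(x$status == 1),
                 stratified = stratify_by_study, ties = ties, lrt = lrt),
            class = "carrier_cox")
}

#' @export
print.carrier_cox <- function(x, ...) {
  cat("Cohort Cox model (", x$coding, " coding, ", x$ties, " ties",
      if (x$stratified) ", study-stratified" else "", "); ",
      x$n, " carriers, ", x$n_event, " events\n", sep = "")
  print(tidy.carrier_cox(x), ...)
  if (!is.null(x$lrt)) {
    cat(sprintf("2-df LRT: chi2 = %.3f, p = %.4g\n",
                x$lrt$statistic, x$lrt$p_value))
  }
  invisible(x)
}

#' Tidy methods for carrier Cox fits
#'
#' `tidy()` gives one row per model term with hazard ratio, Wald 95% CI and
#' p-value; `glance()` the fit-level summary.
#'
#' @param x A `"carrier_cox"` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy carrier_cox
#' @export
tidy.carrier_cox <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    term = x$terms,
    estimate = exp(f$beta),
    log_hr = f$beta,
    std_error = f$se,
    conf_low = exp(f$beta - 1.96 * f$se),
    conf_high = exp(f$beta + 1.96 * f$se),
    p_value = 2 * stats::pnorm(-abs(f$beta / f$se))
  )
}

#' @rdname tidy.carrier_cox
#' @method glance carrier_cox
#' @export
glance.carrier_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, logLik = x$fit$loglik,
                 logLik_null = x$fit$loglik_null,
                 iterations = x$fit$iterations,
                 converged = x$fit$converged, flagged = x$fit$flagged)
}

#' Forest-style plot of carrier hazard ratios
#'
#' @param object A `"carrier_cox"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carrier_cox
#' @export
autoplot.carrier_cox <- function(object, ...) {
  td <- tidy.carrier_cox(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Likelihood-ratio test of between-study heterogeneity
#'
#' Compares study-specific per-allele log-HRs against a shared log-HR, both
#' with study-stratified baselines: the full model is the sum of separate
#' per-study fits, the reduced one the shared stratified fit. Studies
#' without genotype variation or without events contribute no degree of
#' freedom (logged).
#'
#' @param carriers Tibble as for [cox_per_allele()], with a `study` column
#'   covering at least two studies with events.
#' @return One-row tibble `statistic`, `df`, `p_value`, `n_studies`.
#' @export
heterogeneity_test <- function(carriers) {
  x <- dplyr::filter(carriers, !is.na(.data$genotype))
  usable <- x |>
    dplyr::group_by(.data$study) |>
    dplyr::filter(sum(.data$status) > 0, sum(.data$status == 0) > 0,
                  dplyr::n_distinct(.data$genotype) > 1) |>
    dplyr::ungroup()
  studies <- unique(usable$study)
  dropped <- setdiff(unique(x$study), studies)
  if (length(dropped)) {
    message("studies contributing no df: ", paste(dropped, collapse = ", "))
  }
  if (length(studies) < 2) {
    stop("heterogeneity test needs >= 2 informative studies", call. = FALSE)
  }
  shared <- cox_per_allele(usable, stratify_by_study = TRUE)
  ll_full <- sum(purrr::map_dbl(studies, function(s) {
    cox_per_allele(dplyr::filter(usable, .data$study == s))$fit$loglik
  }))
  stat <- 2 * (ll_full - shared$fit$loglik)
  df <- length(studies) - 1L
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n_studies = length(studies))
}

#' Haplotype-level cohort association
#'
#' Per-copy hazard ratios of each non-reference haplotype versus the
#' reference class, from posterior-weighted haplotype dosages entered
#' additively in the Cox model. With phase-known input the dosages are
#' integers and the fit equals a plain Cox fit on counted haplotypes. This
#' is a standard cohort analysis: it does not adjust for the non-random
#' ascertainment of carriers or for familial relationships.
#'
#' @param carriers Tibble with `status`, `time`, optionally `study` /
#'   `entry_time`, and either per-haplotype dosage columns (named by
#'   haplotype) or `hap_a`/`hap_b` label columns, or a posterior tibble
#'   joined as `posterior` (columns `sample_id`/`carrier_id`, `hap_a`,
#'   `hap_b`, `posterior`) from [em_haplotype_frequencies()].
#' @param haplotypes Character vector of all haplotype labels in the system.
#' @param reference Reference haplotype label(s), excluded from the
#'   covariates (e.g. the low-expression haplotypes).
#' @param stratify_by_study,ties Passed to the Cox fitter.
#' @return A `"carrier_cox"` object with one term per non-reference
#'   haplotype.
#' @export
haplotype_cohort_assoc <- function(carriers, haplotypes,
                                   reference,
                                   stratify_by_study = FALSE,
                                   ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (!all(reference %in% haplotypes)) {
    stop("reference haplotype(s) not in the haplotype set", call. = FALSE)
  }
  x <- carriers
  if (!all(haplotypes %in% names(x))) {
    if (!all(c("hap_a", "hap_b") %in% names(x))) {
      stop("need per-haplotype dosage columns or hap_a/hap_b labels",
           call. = FALSE)
    }
    for (h in haplotypes) {
      x[[h]] <- (x$hap_a == h) + (x$hap_b == h)
    }
  }
  covs <- setdiff(haplotypes, reference)
  present <- vapply(covs, function(h) any(x[[h]] > 0), logical(1))
  if (!any(x[[reference[1]]] > 0) &&
      !any(vapply(reference, function(h) any(x[[h]] > 0), logical(1)))) {
    stop("reference haplotype absent from the cohort", call. = FALSE)
  }
  covs <- covs[present]
  if (length(covs) == 0 ||
      all(vapply(covs, function(h) stats::sd(x[[h]]) == 0, logical(1)))) {
    stop("no estimable non-reference haplotype covariates", call. = FALSE)
  }
  X <- as.matrix(x[, covs, drop = FALSE])
  strata <- if (stratify_by_study) x$study else NULL
  entry <- if ("entry_time" %in% names(x)) x$entry_time else NULL
  fit <- cox_fit(X, x$time, x$status, strata = strata, entry = entry,
                 ties = ties)
  structure(list(fit = fit, coding = "haplotype", terms = covs,
                 n = nrow(x), n_event = sum(x$status == 1),
                 stratified = stratify_by_study, ties = ties, lrt = NULL,
                 reference = reference),
            class = "carrier_cox")
}
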