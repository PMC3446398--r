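# Tag-SNP haplotype assignment, diplotype expression groups, pairwise LD,
# and EM haplotype-frequency estimation for unphased cohorts.

#' Classify a diplotype into an expression group
#'
#' Counts the low-expression haplotypes in the pair: 0 -> "HH", 1 -> "HL",
#' 2 -> "LL". Vectorized over pairs.
#'
#' @param hap_a,hap_b Haplotype labels.
#' @param patterns Pattern table with `haplotype` and `expression_class`.
#' @return Character vector of group labels.
#' @export
#' @examples
#' classify_group("hap1", "hap3")  # both high -> "HH"
#' classify_group("hap2", "hap5")  # both low -> "LL"
classify_group <- function(hap_a, hap_b, patterns = brca2_haplotypes()) {
  cls <- stats::setNames(patterns$expression_class, patterns$haplotype)
  unknown <- setdiff(c(hap_a, hap_b), names(cls))
  if (length(unknown)) {
    stop("unknown haplotype label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n_low <- (cls[hap_a] == "low") + (cls[hap_b] == "low")
  unname(c("HH", "HL", "LL")[n_low + 1L])
}

#' Resolve the second haplotype of marker-heterozygous samples
#'
#' Samples heterozygous at the transcribed marker SNP are known to carry the
#' anchored haplotype (the only pattern with the marker's A allele), so the
#' second haplotype is obtained by subtracting the anchored pattern's allele
#' from each unphased genotype and matching the residual allele vector
#' against the pattern table. Samples whose residual matches no pattern are
#' excluded with a warning rather than imputed; a residual matching more
#' than one pattern raises an error listing the candidates.
#'
#' @param genotypes Tibble with `sample_id` and one `"X/Y"` genotype column
#'   per tag SNP.
#' @param patterns Pattern table ([brca2_haplotypes()] by default).
#' @param anchor Label of the anchored haplotype (default `"hap1"`).
#' @return Tibble `sample_id`, `hap_a` (anchor), `hap_b`, `group`, with
#'   unresolved samples dropped.
#' @export
assign_second_haplotype <- function(genotypes, patterns = brca2_haplotypes(),
                                    anchor = "hap1") {
  snps <- intersect(pattern_snps(patterns), names(genotypes))
  if (length(snps) != length(pattern_snps(patterns))) {
    stop("genotype table is missing tag SNP columns: ",
         paste(setdiff(pattern_snps(patterns), names(genotypes)),
               collapse = ", "), call. = FALSE)
  }
  pat <- as.matrix(patterns[, snps])
  rownames(pat) <- patterns$haplotype
  if (!anchor %in% rownames(pat)) {
    stop("anchor haplotype ", anchor, " not in pattern table", call. = FALSE)
  }
  resolve_one <- function(row) {
    residual <- character(length(snps))
    for (j in seq_along(snps)) {
      g <- sort(strsplit(row[[snps[j]]], "/")[[1]])
      a <- pat[anchor, j]
      if (!a %in% g) return(NA_character_)  # anchor allele absent
      # remove one copy of the anchor allele
      g <- g[-match(a, g)]
      if (length(g) != 1) return(NA_character_)
      residual[j] <- g
    }
    hits <- rownames(pat)[apply(pat, 1, function(p) all(p == residual))]
    if (length(hits) == 0) return(NA_character_)
    if (length(hits) > 1) {
      stop("ambiguous residual haplotype; candidates: ",
           paste(hits, collapse = ", "), call. = FALSE)
    }
    hits
  }
  hap_b <- vapply(seq_len(nrow(genotypes)),
                  function(i) resolve_one(genotypes[i, ]), character(1))
  unresolved <- genotypes$sample_id[is.na(hap_b)]
  if (length(unresolved)) {
    warning("excluded ", length(unresolved),
            " sample(s) with unresolvable second haplotype: ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(hap_b)
  hb <- hap_b[keep]
  tibble::tibble(
    sample_id = genotypes$sample_id[keep],
    hap_a = anchor,
    hap_b = hb,
    group = classify_group(rep(anchor, length(hb)), hb, patterns)
  )
}

#' Pairwise linkage disequilibrium between two biallelic loci
#'
#' Standard two-locus measures from a sample of phased haplotypes:
#' `D = p_AB - p_A p_B`, `D' = D / Dmax` (with the usual Dmax for the sign
#' of D), `r2 = D^2 / (p_A p_a p_B p_b)`. A monomorphic locus yields NA
#' measures with `defined = FALSE` rather than an error.
#'
#' @param haplotypes Tibble (or data frame) whose first two columns hold the
#'   alleles of each phased haplotype at the two loci (one row per
#'   chromosome).
#' @return One-row tibble: `locus_a`, `locus_b`, `D`, `Dprime`, `r2`,
#'   `defined`.
#' @export
pairwise_ld <- function(haplotypes) {
  stopifnot(ncol(haplotypes) >= 2, nrow(haplotypes) >= 1)
  a <- as.character(haplotypes[[1]])
  b <- as.character(haplotypes[[2]])
  ua <- sort(unique(a)); ub <- sort(unique(b))
  if (length(ua) > 2 || length(ub) > 2) {
    stop("pairwise_ld needs biallelic loci", call. = FALSE)
  }
  out <- tibble::tibble(locus_a = names(haplotypes)[1],
                        locus_b = names(haplotypes)[2],
                        D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                        defined = FALSE)
  if (length(ua) < 2 || length(ub) < 2) return(out)
  pA <- mean(a == ua[1]); pB <- mean(b == ub[1])
  pAB <- mean(a == ua[1] & b == ub[1])
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  out$D <- D
  out$Dprime <- if (dmax > 0) abs(D) / dmax else NA_real_
  out$r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  out$defined <- TRUE
  out
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard expectation-maximization over diplotype compatibility classes:
#' each sample's unphased multi-SNP genotype is expanded into every
#' consistent ordered pair of haplotypes; the E step weights each pair by
#' its current probability (`p_h1 p_h2`, doubled for heterozygous pairs);
#' the M step re-estimates frequencies from expected counts. Initial
#' frequencies are uniform over the compatible haplotypes; iteration stops
#' when the largest frequency change falls below `tol` or after `max_iter`
#' iterations. The observed-data log-likelihood is non-decreasing.
#'
#' @param genotypes Tibble with `sample_id` plus one `"X/Y"` column per SNP
#'   (unphased; biallelic).
#' @param snps SNP columns to phase; defaults to every column except
#'   `sample_id`.
#' @param tol Convergence tolerance on the max frequency change.
#' @param max_iter Iteration cap.
#' @return Object of class `"hap_em"`: list with `frequencies` (tibble
#'   `haplotype`, `freq` where `haplotype` is the joined allele string),
#'   `posterior` (tibble `sample_id`, `hap_a`, `hap_b`, `posterior`),
#'   `loglik` (trace), `iterations`, `converged`. Has [tidy()] and
#'   [glance()] methods.
#' @export
em_haplotype_frequencies <- function(genotypes, snps = NULL,
                                     tol = 1e-8, max_iter = 500) {
  if (is.null(snps)) snps <- setdiff(names(genotypes), "sample_id")
  stopifnot(nrow(genotypes) >= 1, length(snps) >= 1)
  # expand each sample into compatible unordered haplotype pairs
  expansions <- purrr::map(seq_len(nrow(genotypes)), function(i) {
    gl <- purrr::map(snps, function(s) {
      sort(strsplit(as.character(genotypes[[s]][i]), "/")[[1]])
    })
    if (any(lengths(gl) != 2)) {
      stop("genotypes must be unphased diploid 'X/Y' strings", call. = FALSE)
    }
    het <- which(vapply(gl, function(g) g[1] != g[2], logical(1)))
    h1 <- vapply(gl, `[`, character(1), 1)
    h2 <- vapply(gl, `[`, character(1), 2)
    if (length(het) <= 1) {
      pairs <- matrix(c(paste(h1, collapse = ""),
                        paste(h2, collapse = "")), ncol = 2)
    } else {
      # fix the first het site's phase; enumerate the rest
      flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)),
                                         length(het) - 1)))
      pairs <- t(apply(flips, 1, function(fl) {
        a <- h1; b <- h2
        sw <- het[-1][fl]
        tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
        c(paste(a, collapse = ""), paste(b, collapse = ""))
      }))
    }
    tibble::tibble(sample = i, hap_a = pairs[, 1], hap_b = pairs[, 2])
  })
  exp_tbl <- dplyr::bind_rows(expansions)
  haps <- sort(unique(c(exp_tbl$hap_a, exp_tbl$hap_b)))
  freq <- stats::setNames(rep(1 / length(haps), length(haps)), haps)
  n <- nrow(genotypes)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    w <- freq[exp_tbl$hap_a] * freq[exp_tbl$hap_b] *
      ifelse(exp_tbl$hap_a == exp_tbl$hap_b, 1, 2)
    tot <- tapply(w, exp_tbl$sample, sum)
    loglik <- c(loglik, sum(log(tot)))
    post <- w / tot[as.character(exp_tbl$sample)]
    cnt <- stats::setNames(rep(0, length(haps)), haps)
    add_a <- tapply(post, exp_tbl$hap_a, sum)
    add_b <- tapply(post, exp_tbl$hap_b, sum)
    cnt[names(add_a)] <- cnt[names(add_a)] + add_a
    cnt[names(add_b)] <- cnt[names(add_b)] + add_b
    new_freq <- cnt / (2 * n)
    delta <- max(abs(new_freq - freq))
    freq <- new_freq
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  w <- freq[exp_tbl$hap_a] * freq[exp_tbl$hap_b] *
    ifelse(exp_tbl$hap_a == exp_tbl$hap_b, 1, 2)
  tot <- tapply(w, exp_tbl$sample, sum)
  post <- w / tot[as.character(exp_tbl$sample)]
  structure(list(
    frequencies = tibble::tibble(haplotype = haps, freq = unname(freq)),
    posterior = tibble::tibble(
      sample_id = genotypes$sample_id[exp_tbl$sample],
      hap_a = exp_tbl$hap_a, hap_b = exp_tbl$hap_b,
      posterior = as.numeric(post)),
    loglik = loglik, iterations = iter, converged = converged,
    snps = snps),
    class = "hap_em")
}

#' @export
print.hap_em <- function(x, ...) {
  cat("EM haplotype frequencies over", length(x$snps), "SNPs;",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(dplyr::arrange(x$frequencies, dplyr::desc(.data$freq)), ...)
  invisible(x)
}

#' Tidy methods for EM haplotype fits
#'
#' `tidy()` returns the estimated haplotype frequencies; `glance()` the fit
#' summary (final log-likelihood, iterations, convergence).
#'
#' @param x A `"hap_em"` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hap_em
#' @export
tidy.hap_em <- function(x, ...) {
  dplyr::arrange(x$frequencies, dplyr::desc(.data$freq))
}

#' @rdname tidy.hap_em
#' @method glance hap_em
#' @export
glance.hap_em <- function(x, ...) {
  tibble::tibble(logLik = x$loglik[length(x$loglik)],
                 iterations = x$iterations, converged = x$converged,
                 n_haplotypes = nrow(x$frequencies))
}
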