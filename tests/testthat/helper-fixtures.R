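# Fixtures built in code: replicate-measurement tables, toy PWMs, and the
# planted regulatory-screen cohort.

make_measurement <- function(cdna, gdna, sample_id = "s1",
                             snp_id = "rs144848",
                             allele_a = "G", allele_b = "T") {
  tibble::tibble(
    sample_id = sample_id, snp_id = snp_id,
    allele_a = allele_a, allele_b = allele_b,
    assay = rep(c("cdna", "gdna"), c(length(cdna), length(gdna))),
    replicate = c(seq_along(cdna), seq_along(gdna)),
    ratio = c(cdna, gdna)
  )
}

# genotype row formed by the unphased union of two built-in haplotypes
make_genotype <- function(hap_x, hap_y, sample_id = "s1",
                          patterns = brca2_haplotypes()) {
  snps <- setdiff(names(patterns),
                  c("haplotype", "freq_pct", "expression_class",
                    "n_dae", "n_no_dae"))
  ax <- patterns[patterns$haplotype == hap_x, snps]
  ay <- patterns[patterns$haplotype == hap_y, snps]
  g <- purrr::map2(as.character(ax), as.character(ay),
                   ~ paste(.x, .y, sep = "/"))
  names(g) <- snps
  tibble::tibble(sample_id = sample_id, !!!g)
}

# near-deterministic PWM with the given consensus (count 20 on the
# consensus base per position)
consensus_pwm <- function(consensus, id = "toy", uniform_at = integer(0)) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  counts <- matrix(0, L, 4, dimnames = list(NULL, bases))
  cs <- strsplit(consensus, "")[[1]]
  for (i in seq_len(L)) counts[i, cs[i]] <- 20
  for (i in uniform_at) counts[i, ] <- 5
  pwm(counts, id = id, factor_name = paste0("TF_", id))
}

# independent brute-force MATCH scorer: plain loops, no shared code paths
oracle_match <- function(seq, freq, info, core_start, core_len) {
  bases <- c("A", "C", "G", "T")
  revcomp_chr <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  L <- nrow(freq)
  core <- core_start:(core_start + core_len - 1)
  best <- -Inf; best_css <- NA
  for (s in c(seq, revcomp_chr(seq))) {
    for (from in seq_len(nchar(seq) - L + 1)) {
      # score_at over all positions, offset via from
      mss <- {
        cur <- mn <- mx <- 0
        for (i in seq_len(L)) {
          b <- substr(s, from + i - 1, from + i - 1)
          fv <- if (b %in% bases) freq[i, b] else min(freq[i, ])
          cur <- cur + info[i] * fv
          mn <- mn + info[i] * min(freq[i, ])
          mx <- mx + info[i] * max(freq[i, ])
        }
        if (mx > mn) (cur - mn) / (mx - mn) else 1
      }
      css <- {
        cur <- mn <- mx <- 0
        for (i in core) {
          b <- substr(s, from + i - 1, from + i - 1)
          fv <- if (b %in% bases) freq[i, b] else min(freq[i, ])
          cur <- cur + info[i] * fv
          mn <- mn + info[i] * min(freq[i, ])
          mx <- mx + info[i] * max(freq[i, ])
        }
        if (mx > mn) (cur - mn) / (mx - mn) else 1
      }
      if (mss > best + 1e-12) { best <- mss; best_css <- css }
    }
  }
  c(mss = unname(best), css = unname(best_css))
}

# Planted regulatory screen: 26 SNPs of which exactly 4 satisfy all four
# selection criteria against the two-matrix library below.
build_tfbs_fixture <- function() {
  trun <- function(n) strrep("T", n)
  place <- function(motif, at, width = 41) {
    # motif embedded in a T-run window of the given width
    paste0(trun(at - 1), motif, trun(width - (at - 1) - nchar(motif)))
  }
  pwm_main <- consensus_pwm("ACGTACGT", id = "M1")
  pwm_soft <- consensus_pwm("ACGTACGA", id = "M2", uniform_at = 5)
  contexts <- list()
  add <- function(snp_id, seq, pos, allele_a = "T", allele_b = "G") {
    contexts[[length(contexts) + 1]] <<- tibble::tibble(
      snp_id = snp_id, seq = seq, offset = 21L,
      allele_a = allele_a, allele_b = allele_b,
      chrom = "13", pos = pos)
  }
  # 4 true candidates: inside BED, motif over the SNP (motif position 4,
  # in the core), allele T matches the consensus, G breaks it
  for (i in 1:4) add(sprintf("cand%02d", i), place("ACGTACGT", 18), 1500 + i)
  # 10 outside any regulatory interval (never scored)
  for (i in 1:10) add(sprintf("nobed%02d", i), place("ACGTACGT", 18), 500 + i)
  # 6 inside BED with no motif anywhere
  for (i in 1:6) add(sprintf("nomotif%02d", i), trun(41), 1510 + i)
  # 3 inside BED, motif present but not overlapping the SNP
  for (i in 1:3) add(sprintf("noover%02d", i), place("ACGTACGT", 5), 1520 + i,
                     allele_a = "A", allele_b = "G")
  # 3 inside BED, the soft matrix spans the SNP at its indifferent
  # position 5, so both alleles score identically
  for (i in 1:3) add(sprintf("nodiff%02d", i), place("ACGTACGA", 17), 1530 + i,
                     allele_a = "A", allele_b = "G")
  contexts <- dplyr::bind_rows(contexts)
  regulatory <- tibble::tibble(chrom = "13", start0 = 1000L, end = 2000L,
                               name = "reg1")
  list(contexts = contexts, regulatory = regulatory,
       pwms = list(M1 = pwm_main, M2 = pwm_soft))
}

# small TRANSFAC flat file written to a temp path
write_transfac_fixture <- function(path, scale = 1) {
  rows1 <- c("5 0 0 0", "0 5 0 0", "1 1 1 2")
  rows2 <- c("0 0 8 0", "8 0 0 0", "0 0 0 8", "2 2 2 2")
  scale_row <- function(r) {
    paste(as.numeric(strsplit(r, " ")[[1]]) * scale, collapse = "  ")
  }
  lines <- c(
    "ID  TOY1", "NA  factor one", "P0      A      C      G      T",
    paste0(sprintf("%02d  ", seq_along(rows1)),
           vapply(rows1, scale_row, character(1))),
    "//",
    "ID  TOY2", "NA  factor two", "P0      A      C      G      T",
    paste0(sprintf("%02d  ", seq_along(rows2)),
           vapply(rows2, scale_row, character(1))),
    "//")
  writeLines(lines, path)
  path
}
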