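# End-to-end pipeline over a config file, and the command-line dispatcher.

#' Run the full synthetic pipeline from a config file
#'
#' Stages: simulate (diplotypes, allelic measurements, expression table,
#' carrier cohort) -> DAE calling -> second-haplotype assignment ->
#' DAE association report -> expression tests -> risk models. Every stage's
#' report is written as TSV into `out_dir` (atomically) and returned.
#'
#' @param config Path to an INI-style config file (see
#'   [read_run_config()]), or a config list. Recognized sections/keys:
#'   `[simulate]` `n_samples`, `seed`, `meas_cv`, `n_reps`, `carrier_n`,
#'   `carrier_log_hr`, `carrier_maf`, `n_studies`; `[dae]`
#'   `threshold_fold`; `[risk]` `stratify_by_study`.
#' @param out_dir Output directory (created if missing).
#' @param seed Overrides the config seed when non-NULL.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  sim <- cfg$simulate %||% list()
  carrier <- list()
  for (k in c("n", "log_hr", "maf", "n_studies")) {
    v <- sim[[paste0("carrier_", k)]] %||% sim[[k]]
    if (!is.null(v)) carrier[[k]] <- v
  }
  sc <- sim_config(
    n_samples = sim$n_samples %||% 58,
    meas_cv = sim$meas_cv %||% 0.10,
    n_reps = sim$n_reps %||% 3,
    carrier = carrier,
    seed = as.integer(seed %||% sim$seed %||% 1)
  )
  threshold <- (cfg$dae$threshold_fold) %||% 1.2
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  dip <- sim_diplotypes(sc)
  meas <- sim_allelic_measurements(dip, sc)
  calls <- call_dae(normalize_allelic_ratios(meas), threshold_fold = threshold)
  geno_cols <- c("sample_id", pattern_snps(sc$patterns))
  assigned <- assign_second_haplotype(dip[, geno_cols], sc$patterns)
  counts <- assigned |>
    dplyr::inner_join(calls, by = "sample_id") |>
    dplyr::count(.data$hap_b, .data$is_dae) |>
    tidyr::pivot_wider(names_from = "is_dae", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename(haplotype = "hap_b")
  for (col in c("TRUE", "FALSE")) if (!col %in% names(counts)) counts[[col]] <- 0L
  counts <- dplyr::transmute(counts, haplotype = .data$haplotype,
                             n_dae = .data$`TRUE`, n_no_dae = .data$`FALSE`)
  dae_report <- dae_association_report(counts)

  expr <- sim_expression(dip, sc, mode = "ct")
  hk <- select_housekeeping_pair(expr, attr(expr, "housekeeping"))
  hk_pair <- c(hk$hk1[1], hk$hk2[1])
  rel <- ddct_relative_expression(expr, hk_pair,
                                  reference_group = "HH",
                                  genes = setdiff(attr(expr, "genes"),
                                                  attr(expr, "housekeeping")))
  expr_tests <- purrr::map_dfr(
    setdiff(attr(expr, "genes"), attr(expr, "housekeeping")),
    function(g) {
      d <- dplyr::filter(rel, .data$gene == g)
      dplyr::mutate(group_expression_ttest(d, "delta_delta_ct",
                                           pair = c("HH", "HL")),
                    gene = g, .before = 1)
    })

  carriers <- sim_carriers(sc)
  risk_fit <- cox_per_allele(
    carriers, stratify_by_study = isTRUE(cfg$risk$stratify_by_study))
  risk_tab <- genotype_status_table(carriers)

  results <- list(
    diplotypes = dip, measurements = meas, dae_calls = calls,
    dae_report = dae_report, expression_tests = expr_tests,
    genotype_table = risk_tab, risk = tidy(risk_fit)
  )
  paths <- c(diplotypes = "diplotypes.tsv", measurements = "measurements.tsv",
             dae_calls = "dae_calls.tsv", dae_report = "dae_report.tsv",
             expression_tests = "expression_tests.tsv",
             genotype_table = "genotype_table.tsv", risk = "risk.tsv")
  for (nm in names(paths)) {
    write_tsv_atomic(results[[nm]], file.path(out_dir, paths[[nm]]))
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line dispatcher
#'
#' Subcommands: `simulate`, `dae-call`, `assign-haplotypes`, `dae-assoc`,
#' `expr-assoc`, `tfbs-screen`, `risk`, `ld`, `phase-em`, `pipeline`.
#' Global flags: `--seed <int>`, `--version`. Logs go to stderr; exit
#' status 0 on success, 1 on a data/model error, 2 on a usage error. The
#' status is returned (invisibly) rather than calling `quit()`, so the
#' wrapper script decides the process exit.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` in the wrapper).
#' @return Integer exit status, invisibly.
#' @export
daehap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) {
      message("usage: daehap <subcommand> [options]")
      return(invisible(2L))
    }
    if (args[1] == "--version") {
      cat(as.character(utils::packageVersion("daehap")), "\n")
      return(invisible(0L))
    }
    sub <- args[1]
    opts <- parse_cli_flags(args[-1])
    seed <- as.integer(opts$seed %||% 1)
    out <- opts$out %||% "."
    switch(
      sub,
      "simulate" = {
        sc <- sim_config(n_samples = as.integer(opts$`n-samples` %||% 58),
                         seed = seed)
        dip <- sim_diplotypes(sc)
        if (!dir.exists(out)) dir.create(out, recursive = TRUE)
        write_tsv_atomic(dip, file.path(out, "diplotypes.tsv"))
        write_tsv_atomic(sim_allelic_measurements(dip, sc),
                         file.path(out, "measurements.tsv"))
        write_tsv_atomic(sim_carriers(sc), file.path(out, "carriers.tsv"))
        0L
      },
      "dae-call" = {
        thr <- as.numeric(opts$threshold %||% 1.2)
        calls <- call_dae(normalize_allelic_ratios(
          read_allelic_measurements(req_opt(opts, "input"))),
          threshold_fold = thr)
        write_tsv_atomic(calls, opts$output %||% "dae_calls.tsv")
        0L
      },
      "assign-haplotypes" = {
        gt <- read_genotypes(req_opt(opts, "input"),
                             format = opts$format %||% "tsv")
        write_tsv_atomic(assign_second_haplotype(gt),
                         opts$output %||% "haplotypes.tsv")
        0L
      },
      "dae-assoc" = {
        counts <- readr::read_tsv(req_opt(opts, "input"),
                                  show_col_types = FALSE)
        write_tsv_atomic(dae_association_report(counts),
                         opts$output %||% "dae_assoc.tsv")
        0L
      },
      "expr-assoc" = {
        expr <- read_expression(req_opt(opts, "input"))
        genes <- setdiff(attr(expr, "genes"), c("n_low"))
        res <- purrr::map_dfr(genes, function(g) {
          dplyr::mutate(group_expression_ttest(expr, g), gene = g,
                        .before = 1)
        })
        write_tsv_atomic(res, opts$output %||% "expr_assoc.tsv")
        0L
      },
      "tfbs-screen" = {
        ctx <- read_snp_contexts(req_opt(opts, "fasta"),
                                 req_opt(opts, "annotation"))
        pwms <- read_transfac(req_opt(opts, "matrices"))
        bed <- read_regulatory_bed(req_opt(opts, "bed"))
        rep <- candidate_filter(ctx, bed, pwms,
                                min_mss = as.numeric(opts$`min-mss` %||% 0.9),
                                min_core = as.numeric(opts$`min-core` %||% 0.9))
        write_tsv_atomic(rep, opts$output %||% "tfbs_candidates.tsv")
        0L
      },
      "risk" = {
        carriers <- read_carriers(req_opt(opts, "input"))
        coding <- if ((opts$model %||% "per-allele") == "2df") "2df"
                  else "additive"
        fit <- cox_per_allele(carriers, coding = coding)
        write_tsv_atomic(tidy(fit), opts$output %||% "risk.tsv")
        0L
      },
      "ld" = {
        haps <- readr::read_tsv(req_opt(opts, "input"),
                                show_col_types = FALSE)
        write_tsv_atomic(pairwise_ld(haps), opts$output %||% "ld.tsv")
        0L
      },
      "phase-em" = {
        gt <- read_genotypes(req_opt(opts, "input"),
                             format = opts$format %||% "tsv")
        em <- em_haplotype_frequencies(gt)
        write_tsv_atomic(tidy(em), opts$output %||% "hap_freqs.tsv")
        0L
      },
      "pipeline" = {
        run_pipeline(req_opt(opts, "config"), out_dir = out,
                     seed = if (!is.null(opts$seed)) seed)
        0L
      },
      {
        message("unknown subcommand: ", sub)
        2L
      }
    )
  },
  usage_error = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!grepl("^--", a)) {
      stop(structure(class = c("usage_error", "error", "condition"),
                     list(message = paste("unexpected argument:", a),
                          call = NULL)))
    }
    key <- sub("^--", "", a)
    if (i < length(args) && !grepl("^--", args[i + 1])) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}

req_opt <- function(opts, key) {
  v <- opts[[key]]
  if (is.null(v) || isTRUE(v)) {
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = paste0("missing required --", key),
                        call = NULL)))
  }
  v
}
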