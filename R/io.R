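# Readers and writers for the package's interchange formats.
#
# TSV with self-describing headers is the primary interchange; a minimal VCF
# dialect (unphased GT of biallelic sites) is accepted for genotypes. All
# writers go through an atomic write-to-temp + rename so a failure never
# leaves a partial output file.

write_tsv_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  readr::write_tsv(x, tmp)
  if (!file.rename(tmp, path)) {
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read unphased tag-SNP genotypes
#'
#' @param path File path.
#' @param format `"tsv"` (columns `sample_id` plus one column per SNP holding
#'   `"A/G"`-style unphased genotype strings; `"./."` or `NA` for missing) or
#'   `"vcf"` (minimal dialect: biallelic sites, unphased `GT` field; alleles
#'   are mapped through REF/ALT to nucleotides).
#' @param patterns Optional pattern table; when given, alleles seen in the
#'   file are checked against the alleles the patterns use and a mismatch is
#'   an error naming the SNP.
#' @return Tibble with `sample_id` and one character column per SNP.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), patterns = NULL) {
  format <- match.arg(format)
  gt <- if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
  if (!is.null(patterns)) check_genotype_alleles(gt, patterns)
  gt
}

read_genotypes_tsv <- function(path) {
  gt <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!"sample_id" %in% names(gt)) {
    stop("genotype TSV must have a sample_id column", call. = FALSE)
  }
  dplyr::mutate(gt, dplyr::across(-"sample_id",
                                  ~ dplyr::if_else(.x %in% c("./.", "."), NA_character_, .x)))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  alleles <- purrr::map2(fix$REF, fix$ALT, ~ c(.x, strsplit(.y, ",")[[1]]))
  decode <- function(codes, al) {
    unname(purrr::map_chr(codes, function(g) {
      if (is.na(g) || g %in% c("./.", ".")) return(NA_character_)
      idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
      paste(al[idx], collapse = "/")
    }))
  }
  cols <- purrr::map(seq_len(nrow(fix)), ~ decode(gt_raw[.x, ], alleles[[.x]]))
  names(cols) <- fix$ID
  tibble::tibble(sample_id = colnames(gt_raw), !!!cols)
}

check_genotype_alleles <- function(gt, patterns) {
  long <- patterns_long(patterns)
  for (s in intersect(pattern_snps(patterns), names(gt))) {
    seen <- unique(unlist(strsplit(stats::na.omit(gt[[s]]), "/")))
    known <- unique(long$allele[long$snp == s])
    bad <- setdiff(seen, known)
    if (length(bad)) {
      stop("genotype file carries allele(s) ", paste(bad, collapse = ","),
           " at ", s, " not present in the pattern definitions", call. = FALSE)
    }
  }
  invisible(gt)
}

#' @rdname read_genotypes
#' @param genotypes Genotype tibble as returned by `read_genotypes()`.
#' @export
write_genotypes <- function(genotypes, path) {
  out <- dplyr::mutate(genotypes,
                       dplyr::across(-"sample_id",
                                     ~ dplyr::if_else(is.na(.x), "./.", .x)))
  write_tsv_atomic(out, path)
  invisible(path)
}

#' Read and write replicate allelic measurements
#'
#' Long TSV with columns `sample_id`, `snp_id`, `allele_a`, `allele_b`,
#' `assay` (`cdna` or `gdna`), `replicate`, `ratio` (A-peak over B-peak).
#'
#' @param path File path.
#' @return A tibble of replicate measurements.
#' @export
read_allelic_measurements <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(ratio = "d", replicate = "i",
                                               .default = "c"))
  need <- c("sample_id", "snp_id", "allele_a", "allele_b",
            "assay", "replicate", "ratio")
  if (!all(need %in% names(m))) {
    stop("allelic measurement TSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  m
}

#' @rdname read_allelic_measurements
#' @param measurements Tibble of replicate measurements.
#' @export
write_allelic_measurements <- function(measurements, path) {
  write_tsv_atomic(measurements, path)
  invisible(path)
}

#' Read a carrier cohort table
#'
#' TSV with columns `carrier_id`, `study`, `genotype` (0/1/2 minor-allele
#' count, empty for missing), `status` (`affected`/`unaffected` or 1/0),
#' `time` (years), and optionally `entry_time` for left-truncated records.
#'
#' @param path File path.
#' @return Tibble of carrier records with integer `genotype`, integer
#'   `status` (1 = affected) and numeric `time`.
#' @export
read_carriers <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  need <- c("carrier_id", "study", "genotype", "status", "time")
  if (!all(need %in% names(x))) {
    stop("carrier TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::mutate(
    x,
    genotype = as.integer(.data$genotype),
    status = dplyr::case_when(
      .data$status %in% c("affected", "1") ~ 1L,
      .data$status %in% c("unaffected", "0") ~ 0L,
      TRUE ~ NA_integer_
    ),
    time = as.numeric(.data$time)
  )
  if ("entry_time" %in% names(x)) x$entry_time <- as.numeric(x$entry_time)
  if (any(is.na(x$status))) stop("unrecognized status values", call. = FALSE)
  if (any(x$time <= 0, na.rm = TRUE)) {
    stop("carrier follow-up times must be positive", call. = FALSE)
  }
  x
}

#' Read an expression table
#'
#' Wide TSV: `sample_id` column plus one numeric column per gene; any further
#' annotation columns (e.g. `group`, genotype columns) are carried through.
#'
#' @param path File path.
#' @param genes Optional character vector naming which columns are genes;
#'   by default every numeric column other than `sample_id` is treated as one.
#' @return Tibble with attribute `"genes"` listing the gene columns.
#' @export
read_expression <- function(path, genes = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(x)) {
    stop("expression TSV must have a sample_id column", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- names(x)[vapply(x, is.numeric, logical(1))]
  }
  attr(x, "genes") <- genes
  x
}

#' Read SNP sequence contexts from FASTA plus an annotation TSV
#'
#' The FASTA holds one window per SNP, named by `snp_id`; the TSV gives, per
#' SNP, the 1-based `offset` of the variant base inside the window, the two
#' `allele_a`/`allele_b` nucleotides, and optionally `chrom` and `pos`
#' (1-based genomic coordinate) for the regulatory-interval filter.
#'
#' @param fasta Path to the FASTA of window sequences.
#' @param annotation Path to the TSV of per-SNP annotations.
#' @return Tibble with columns `snp_id`, `seq`, `offset`, `allele_a`,
#'   `allele_b` and any annotation columns.
#' @export
read_snp_contexts <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- readr::read_tsv(annotation, show_col_types = FALSE)
  need <- c("snp_id", "offset", "allele_a", "allele_b")
  if (!all(need %in% names(ann))) {
    stop("context annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  seq_tbl <- tibble::tibble(snp_id = names(seqs),
                            seq = unname(toupper(as.character(seqs))))
  out <- dplyr::inner_join(ann, seq_tbl, by = "snp_id")
  if (nrow(out) < nrow(ann)) {
    stop("FASTA is missing sequence for some annotated SNPs", call. = FALSE)
  }
  dplyr::relocate(out, "snp_id", "seq", "offset", "allele_a", "allele_b")
}

#' Read regulatory feature intervals from BED
#'
#' BED uses 0-based half-open coordinates; the returned tibble keeps them as
#' `start0` (0-based inclusive) and `end` (exclusive), so a 1-based SNP
#' position `p` lies inside an interval iff `start0 < p <= end`.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start0`, `end`, `name`.
#' @export
read_regulatory_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) {
                   stop("malformed BED file ", path, ": ", conditionMessage(e),
                        call. = FALSE)
                 })
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start0 = BiocGenerics::start(gr) - 1L,  # back to BED convention
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  )
}

#' Read a flat key-value configuration file
#'
#' INI dialect: `[section]` headers, `key = value` lines, `#` comments.
#' Values are coerced to numeric where possible; comma-separated values
#' become vectors; `name:value` pairs in a comma list become named vectors.
#'
#' @param path Config file path.
#' @return Named list of sections, each a named list of values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    cfg[[section]][[key]] <- parse_config_value(val)
  }
  cfg
}

parse_config_value <- function(val) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  if (all(grepl(":", parts, fixed = TRUE))) {
    kv <- strsplit(parts, ":", fixed = TRUE)
    out <- vapply(kv, function(x) trimws(x[2]), character(1))
    names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
    num <- suppressWarnings(as.numeric(out))
    if (!anyNA(num)) out <- stats::setNames(num, names(out))
    return(out)
  }
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  if (length(parts) == 1 && parts %in% c("true", "false")) {
    return(parts == "true")
  }
  parts
}
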