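# MATCH-style position-weight-matrix scanning of SNP-centred sequence
# windows, and the four-criteria candidate SNP filter.
#
# Scoring: per position i, information content
#   I(i) = sum_b f(i,b) * ln(4 f(i,b)),
# current score of a placement Current = sum_i I(i) * f(i, base_i), and the
# matrix similarity score mss = (Current - Min) / (Max - Min), where Min/Max
# substitute the per-position worst/best base. The core similarity score css
# is the same quantity restricted to the core block: the 5 consecutive
# positions with the largest total information (leftmost on ties). Both
# scores lie in [0, 1]; a non-ACGT base contributes the position's Min value.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts (or frequencies) are normalized row-wise, then a pseudocount of
#' `pseudocount` per row (split evenly across the four bases) is added and
#' the row renormalized; scores are therefore invariant to rescaling all
#' counts by a constant. The information vector and core block are
#' precomputed.
#'
#' @param counts L x 4 numeric matrix, columns A, C, G, T (rows = motif
#'   positions).
#' @param id Matrix identifier.
#' @param factor_name Name of the transcription factor.
#' @param pseudocount Total pseudocount per row (default 0.01).
#' @return Object of class `"pwm"`: list with `id`, `factor`, `freq`,
#'   `info`, `core_start`, `core_len`.
#' @export
pwm <- function(counts, id = "pwm", factor_name = id, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) stop("PWM needs 4 columns (A,C,G,T)", call. = FALSE)
  if (any(counts < 0) || any(rowSums(counts) <= 0)) {
    stop("PWM rows must have non-negative counts with positive sums",
         call. = FALSE)
  }
  colnames(counts) <- BASES
  p <- counts / rowSums(counts)
  f <- (p + pseudocount / 4) / (1 + pseudocount)
  info <- rowSums(f * log(4 * f))
  L <- nrow(f)
  core_len <- min(5L, L)
  if (L > core_len) {
    sums <- vapply(seq_len(L - core_len + 1),
                   function(s) sum(info[s:(s + core_len - 1)]), numeric(1))
    core_start <- which.max(sums)  # leftmost maximum
  } else {
    core_start <- 1L
  }
  structure(list(id = id, factor = factor_name, freq = f, info = info,
                 core_start = as.integer(core_start),
                 core_len = as.integer(core_len)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(", x$factor, "),", nrow(x$freq), "positions, core at",
      x$core_start, "-", x$core_start + x$core_len - 1, "\n")
  invisible(x)
}

#' Per-position information content of a PWM
#'
#' `I(i) = sum_b f(i,b) ln(4 f(i,b))`; 0 for a uniform position, approaching
#' `ln 4` for a fully conserved one.
#'
#' @param x A [pwm()].
#' @return Numeric vector of length L.
#' @export
information_vector <- function(x) {
  stopifnot(inherits(x, "pwm"))
  x$info
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
}

# Weighted score of one placement; non-ACGT bases take the minimum value.
placement_scores <- function(bases, x) {
  w <- x$info
  f <- x$freq
  vals <- numeric(length(bases))
  mins <- apply(f, 1, min)
  for (i in seq_along(bases)) {
    vals[i] <- if (bases[i] %in% BASES) f[i, bases[i]] else mins[i]
  }
  core <- x$core_start:(x$core_start + x$core_len - 1)
  maxs <- apply(f, 1, max)
  mss_den <- sum(w * maxs) - sum(w * mins)
  css_den <- sum(w[core] * maxs[core]) - sum(w[core] * mins[core])
  c(
    mss = if (mss_den > 0) (sum(w * vals) - sum(w * mins)) / mss_den else 1,
    css = if (css_den > 0) {
      (sum(w[core] * vals[core]) - sum(w[core] * mins[core])) / css_den
    } else 1
  )
}

#' Scan a window with a PWM on both strands
#'
#' Enumerates every placement of the matrix on the forward and reverse
#' strand of the window and scores each. Spans are reported in forward
#' coordinates of the window (1-based, inclusive).
#'
#' @param seq Window sequence (A/C/G/T/N).
#' @param x A [pwm()].
#' @return Tibble with one row per placement: `start`, `end`, `strand`,
#'   `mss`, `css`.
#' @export
scan_pwm <- function(seq, x) {
  stopifnot(inherits(x, "pwm"))
  seq <- toupper(seq)
  L <- nrow(x$freq)
  W <- nchar(seq)
  if (W < L) stop("window shorter than the matrix", call. = FALSE)
  fwd <- strsplit(seq, "")[[1]]
  rev <- strsplit(revcomp(seq), "")[[1]]
  rows <- purrr::map(seq_len(W - L + 1), function(s) {
    sc_f <- placement_scores(fwd[s:(s + L - 1)], x)
    sc_r <- placement_scores(rev[s:(s + L - 1)], x)
    tibble::tibble(
      start = c(s, W - (s + L - 1) + 1L),
      end = c(s + L - 1L, W - s + 1L),
      strand = c("+", "-"),
      mss = c(sc_f[["mss"]], sc_r[["mss"]]),
      css = c(sc_f[["css"]], sc_r[["css"]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Best matrix/core similarity of a PWM in a window
#'
#' Returns the placement with maximal matrix similarity over all offsets
#' and both strands; ties are resolved toward the smaller offset, then the
#' forward strand.
#'
#' @param seq Window sequence.
#' @param x A [pwm()].
#' @return One-row tibble: `mss`, `css`, `start`, `end`, `strand`.
#' @export
match_similarity <- function(seq, x) {
  hits <- scan_pwm(seq, x)
  best <- hits |>
    dplyr::arrange(dplyr::desc(.data$mss), .data$start,
                   dplyr::desc(.data$strand == "+")) |>
    dplyr::slice(1)
  dplyr::select(best, "mss", "css", "start", "end", "strand")
}

substitute_allele <- function(seq, offset, allele) {
  paste0(substr(seq, 1, offset - 1), allele,
         substr(seq, offset + 1, nchar(seq)))
}

#' Allele-differential transcription-factor binding hits
#'
#' Scores both allele versions of a SNP-centred window against a matrix
#' library. A matrix yields a hit when (a) at least one allele has a
#' placement passing both score cutoffs whose span covers the SNP offset,
#' and (b) the alleles differ: either in pass/fail status
#' (`"presence_absence"`) or in matrix similarity by more than `delta`
#' (`"score_shift"`). Per-allele scores are the best-mss placement among
#' those overlapping the SNP.
#'
#' @param context One-row tibble (or list) with `snp_id`, `seq`, `offset`
#'   (1-based position of the SNP in the window), `allele_a`, `allele_b`.
#' @param pwms List of [pwm()] objects (non-empty).
#' @param min_mss,min_core Score cutoffs (default 0.9 each).
#' @param delta Minimal mss difference counting as a score shift; the
#'   default 0 means any difference.
#' @return Tibble of hits: `snp_id`, `pwm_id`, `factor`, per-allele
#'   `mss_a`, `css_a`, `mss_b`, `css_b`, `pass_a`, `pass_b`, `start`,
#'   `end`, `strand`, `type`.
#' @export
allele_differential_hits <- function(context, pwms, min_mss = 0.9,
                                     min_core = 0.9, delta = 0) {
  if (length(pwms) == 0) stop("empty matrix library", call. = FALSE)
  ctx <- as.list(context)
  rows <- purrr::map(pwms, function(x) {
    best <- purrr::map(c(a = ctx$allele_a, b = ctx$allele_b), function(al) {
      win <- substitute_allele(ctx$seq, ctx$offset, al)
      sc <- scan_pwm(win, x) |>
        dplyr::filter(.data$start <= ctx$offset, .data$end >= ctx$offset) |>
        dplyr::arrange(dplyr::desc(.data$mss), .data$start,
                       dplyr::desc(.data$strand == "+"))
      if (nrow(sc) == 0) NULL else sc[1, ]
    })
    if (is.null(best$a) || is.null(best$b)) return(NULL)
    pass_a <- best$a$mss >= min_mss && best$a$css >= min_core
    pass_b <- best$b$mss >= min_mss && best$b$css >= min_core
    if (!pass_a && !pass_b) return(NULL)
    differs <- (pass_a != pass_b) || abs(best$a$mss - best$b$mss) > delta
    if (!differs) return(NULL)
    tibble::tibble(
      snp_id = ctx$snp_id, pwm_id = x$id, factor = x$factor,
      mss_a = best$a$mss, css_a = best$a$css,
      mss_b = best$b$mss, css_b = best$b$css,
      pass_a = pass_a, pass_b = pass_b,
      start = if (pass_a) best$a$start else best$b$start,
      end = if (pass_a) best$a$end else best$b$end,
      strand = if (pass_a) best$a$strand else best$b$strand,
      type = if (pass_a != pass_b) "presence_absence" else "score_shift"
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Four-criteria candidate SNP filter
#'
#' Applies, in order: (1) the SNP lies inside a regulatory feature interval
#' (BED, 0-based half-open: a 1-based position `p` is inside iff
#' `start0 < p <= end`); (2) some matrix passes both score cutoffs somewhere
#' in either allele's window; (3) some passing placement overlaps the SNP;
#' (4) the alleles differ in presence/absence of binding or in score.
#' SNPs failing criterion 1 are never scored.
#'
#' @param contexts Tibble of SNP contexts with `snp_id`, `seq`, `offset`,
#'   `allele_a`, `allele_b`, `chrom`, `pos` (1-based).
#' @param regulatory Regulatory intervals from [read_regulatory_bed()].
#' @param pwms Matrix library (list of [pwm()]).
#' @param min_mss,min_core,delta As in [allele_differential_hits()].
#' @return Tibble per SNP: `snp_id`, `candidate`, `eliminated_at` (`NA`,
#'   `"regulatory_element"`, `"tf_binding"`, `"snp_overlap"` or
#'   `"allele_difference"`), `n_hits`.
#' @export
candidate_filter <- function(contexts, regulatory, pwms,
                             min_mss = 0.9, min_core = 0.9, delta = 0) {
  purrr::map_dfr(seq_len(nrow(contexts)), function(i) {
    ctx <- contexts[i, ]
    inside <- any(regulatory$chrom == ctx$chrom &
                    regulatory$start0 < ctx$pos & ctx$pos <= regulatory$end)
    if (!inside) {
      return(tibble::tibble(snp_id = ctx$snp_id, candidate = FALSE,
                            eliminated_at = "regulatory_element",
                            n_hits = 0L))
    }
    scans <- purrr::map(pwms, function(x) {
      dplyr::bind_rows(
        scan_pwm(substitute_allele(ctx$seq, ctx$offset, ctx$allele_a), x),
        scan_pwm(substitute_allele(ctx$seq, ctx$offset, ctx$allele_b), x)
      ) |>
        dplyr::filter(.data$mss >= min_mss, .data$css >= min_core)
    })
    passing <- dplyr::bind_rows(scans)
    if (nrow(passing) == 0) {
      return(tibble::tibble(snp_id = ctx$snp_id, candidate = FALSE,
                            eliminated_at = "tf_binding", n_hits = 0L))
    }
    overl <- dplyr::filter(passing, .data$start <= ctx$offset,
                           .data$end >= ctx$offset)
    if (nrow(overl) == 0) {
      return(tibble::tibble(snp_id = ctx$snp_id, candidate = FALSE,
                            eliminated_at = "snp_overlap", n_hits = 0L))
    }
    hits <- allele_differential_hits(ctx, pwms, min_mss, min_core, delta)
    tibble::tibble(
      snp_id = ctx$snp_id,
      candidate = nrow(hits) > 0,
      eliminated_at = if (nrow(hits) > 0) NA_character_
                      else "allele_difference",
      n_hits = nrow(hits)
    )
  })
}

#' Read TRANSFAC flat-file matrices
#'
#' Parses the classic TRANSFAC matrix dialect: `ID` (or `AC`) line, `NA`
#' factor-name line, a `P0` header naming the base column order, numbered
#' count rows (four counts, optional consensus letter), blocks terminated
#' by `//`.
#'
#' @param path Matrix flat file.
#' @param pseudocount Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
read_transfac <- function(path, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  pwms <- list()
  id <- fac <- NULL
  order <- BASES
  rows <- list()
  flush <- function() {
    if (length(rows) == 0) return()
    counts <- do.call(rbind, rows)
    colnames(counts) <- order
    counts <- counts[, BASES, drop = FALSE]
    if (is.null(id)) id <- paste0("pwm", length(pwms) + 1)
    pwms[[id]] <<- pwm(counts, id = id,
                       factor_name = if (is.null(fac)) id else fac,
                       pseudocount = pseudocount)
  }
  for (ln_i in seq_along(lines)) {
    ln <- trimws(lines[ln_i])
    if (ln == "" || grepl("^XX", ln)) next
    if (grepl("^//", ln)) {
      flush(); id <- fac <- NULL; rows <- list(); order <- BASES
    } else if (grepl("^(ID|AC)\\s", ln)) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (is.null(id)) id <- tok[2]
    } else if (grepl("^NA\\s", ln)) {
      fac <- sub("^NA\\s+", "", ln)
    } else if (grepl("^P0", ln)) {
      tok <- strsplit(ln, "\\s+")[[1]][-1]
      if (length(tok) != 4 || !setequal(tok, BASES)) {
        stop("bad P0 header at line ", ln_i, call. = FALSE)
      }
      order <- tok
    } else if (grepl("^[0-9]+\\s", ln)) {
      tok <- strsplit(ln, "\\s+")[[1]][-1]
      vals <- suppressWarnings(as.numeric(tok))
      vals <- vals[!is.na(vals)]
      if (length(vals) != 4) {
        stop("matrix row with ", length(vals), " counts (expected 4) at line ",
             ln_i, call. = FALSE)
      }
      rows[[length(rows) + 1]] <- vals
    }
  }
  flush()
  pwms
}
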