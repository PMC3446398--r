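# PWM information content, MATCH-style scoring, and the candidate filter.

test_that("information content hits its analytic limits", {
  x <- pwm(matrix(c(1, 1, 1, 1,
                    4, 0, 0, 0,
                    2, 2, 0, 0), ncol = 4, byrow = TRUE), id = "toy")
  info <- information_vector(x)
  expect_equal(info[1], 0)                       # uniform row
  expect_lt(info[2], log(4)); expect_gt(info[2], 1.3)  # near-conserved
  # hand-computed value for every row, straight from the formula
  f <- x$freq
  oracle <- rowSums(f * log(4 * f))
  expect_equal(info, oracle)
  # vanishing pseudocount: a conserved position approaches ln 4
  sharp <- pwm(matrix(c(1, 0, 0, 0), ncol = 4), id = "sharp",
               pseudocount = 1e-9)
  expect_equal(information_vector(sharp)[1], log(4), tolerance = 1e-6)
})

test_that("consensus scores 1 and the worst-base window scores 0", {
  x <- pwm(matrix(c(8, 1, 1, 0,
                    0, 9, 1, 0,
                    1, 0, 0, 9), ncol = 4, byrow = TRUE), id = "toy")
  consensus <- "ACT"
  worst <- paste(c("A", "C", "G", "T")[apply(x$freq, 1, which.min)],
                 collapse = "")
  expect_equal(match_similarity(consensus, x)$mss, 1)
  expect_equal(match_similarity(consensus, x)$css, 1)
  # embed the worst bases in a window of more worst bases
  sc <- scan_pwm(worst, x)
  expect_equal(min(sc$mss), 0)
  expect_error(scan_pwm("AC", x), "shorter")
})

test_that("best placement equals exhaustive enumeration on random windows", {
  set.seed(61)
  x <- pwm(matrix(c(5, 0, 0, 0,
                    0, 5, 0, 0,
                    1, 1, 1, 2), ncol = 4, byrow = TRUE), id = "toy")
  for (i in 1:15) {
    win <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    got <- match_similarity(win, x)
    oracle <- oracle_match(win, x$freq, x$info, x$core_start, x$core_len)
    expect_equal(got$mss, unname(oracle["mss"]))
  }
})

test_that("scores respect strand symmetry and count rescaling", {
  x <- pwm(matrix(c(6, 1, 2, 1,
                    0, 8, 0, 2,
                    3, 3, 3, 1,
                    0, 0, 10, 0), ncol = 4, byrow = TRUE), id = "toy")
  set.seed(13)
  for (i in 1:10) {
    win <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(win, "")[[1]]), collapse = ""))
    expect_equal(match_similarity(rc, x)$mss, match_similarity(win, x)$mss)
  }
  x10 <- pwm(10 * matrix(c(6, 1, 2, 1,
                           0, 8, 0, 2,
                           3, 3, 3, 1,
                           0, 0, 10, 0), ncol = 4, byrow = TRUE), id = "x10")
  expect_equal(x10$freq, x$freq)
  expect_equal(match_similarity("ACGTACGTACGT", x10)$mss,
               match_similarity("ACGTACGTACGT", x)$mss)
})

test_that("non-ACGT bases take the per-position minimum", {
  x <- pwm(matrix(c(9, 0, 0, 0,
                    0, 9, 0, 0), ncol = 4, byrow = TRUE), id = "toy")
  with_n <- scan_pwm("NC", x)
  worst <- scan_pwm("TC", x)  # T is a worst base for position 1
  expect_equal(with_n$mss[with_n$strand == "+"],
               worst$mss[worst$strand == "+"])
})

test_that("core block is the most informative 5-mer, leftmost on ties", {
  counts <- matrix(1, 8, 4)
  counts[3:7, 1] <- 50  # positions 3..7 strongly conserved
  x <- pwm(counts, id = "core")
  expect_equal(x$core_start, 3L)
  flat <- pwm(matrix(5, 6, 4), id = "flat")
  expect_equal(flat$core_start, 1L)  # all-tie: leftmost window
  short <- pwm(matrix(c(4, 0, 0, 0, 0, 4, 0, 0, 0, 0, 4, 0), ncol = 4,
                      byrow = TRUE), id = "short")
  expect_equal(short$core_len, 3L)   # shorter matrices use all positions
})

test_that("allele-differential hits require overlap and a real difference", {
  fix <- build_tfbs_fixture()
  # planted candidate: T allele matches the consensus, G breaks the core
  cand <- fix$contexts[fix$contexts$snp_id == "cand01", ]
  hits <- allele_differential_hits(cand, fix$pwms)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$type, "presence_absence")
  expect_true(hits$pass_a); expect_false(hits$pass_b)
  expect_true(hits$start <= cand$offset && hits$end >= cand$offset)
  # motif away from the SNP: no hit despite a passing placement elsewhere
  noover <- fix$contexts[fix$contexts$snp_id == "noover01", ]
  expect_equal(nrow(allele_differential_hits(noover, fix$pwms)), 0)
  # indifferent matrix position: both alleles pass identically, no hit
  nodiff <- fix$contexts[fix$contexts$snp_id == "nodiff01", ]
  expect_equal(nrow(allele_differential_hits(nodiff, fix$pwms)), 0)
  expect_error(allele_differential_hits(cand, list()), "empty")
})

test_that("raising cutoffs never increases the number of hits", {
  fix <- build_tfbs_fixture()
  ctx <- fix$contexts[fix$contexts$snp_id == "cand01", ]
  n_prev <- Inf
  for (cut in c(0.5, 0.7, 0.9, 0.99)) {
    n <- nrow(allele_differential_hits(ctx, fix$pwms, min_mss = cut,
                                       min_core = cut))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("the four-criteria filter keeps exactly the planted candidates", {
  fix <- build_tfbs_fixture()
  res <- candidate_filter(fix$contexts, fix$regulatory, fix$pwms)
  expect_equal(nrow(res), 26)
  expect_setequal(res$snp_id[res$candidate], paste0("cand0", 1:4))
  elim <- stats::setNames(res$eliminated_at, res$snp_id)
  expect_true(all(elim[paste0("nobed", sprintf("%02d", 1:10))] ==
                    "regulatory_element"))
  expect_true(all(elim[paste0("nomotif", sprintf("%02d", 1:6))] ==
                    "tf_binding"))
  expect_true(all(elim[paste0("noover", sprintf("%02d", 1:3))] ==
                    "snp_overlap"))
  expect_true(all(elim[paste0("nodiff", sprintf("%02d", 1:3))] ==
                    "allele_difference"))
})

test_that("interval membership uses the half-open BED convention", {
  fix <- build_tfbs_fixture()
  ctx <- fix$contexts[fix$contexts$snp_id == "cand01", ]
  bed <- tibble::tibble(chrom = "13", start0 = 100L, end = 110L,
                        name = "r")
  for (p in c(100L, 111L)) {  # abutting and just past the end
    res <- candidate_filter(dplyr::mutate(ctx, pos = !!p), bed, fix$pwms)
    expect_equal(res$eliminated_at, "regulatory_element")
  }
  for (p in c(101L, 110L)) {  # first and last covered base
    res <- candidate_filter(dplyr::mutate(ctx, pos = !!p), bed, fix$pwms)
    expect_true(res$candidate)
  }
})

test_that("TRANSFAC matrices parse, regularize and rescale cleanly", {
  path <- withr::local_tempfile(fileext = ".dat")
  write_transfac_fixture(path)
  pwms <- read_transfac(path)
  expect_equal(names(pwms), c("TOY1", "TOY2"))
  expect_equal(pwms$TOY1$factor, "factor one")
  expect_equal(nrow(pwms$TOY1$freq), 3)
  expect_equal(unname(rowSums(pwms$TOY1$freq)), rep(1, 3))
  expect_true(all(is.finite(information_vector(pwms$TOY2))))
  # a rescaled file scores identically downstream
  path10 <- withr::local_tempfile(fileext = ".dat")
  write_transfac_fixture(path10, scale = 10)
  pwms10 <- read_transfac(path10)
  win <- "GATGACCTGA"
  expect_equal(match_similarity(win, pwms10$TOY2),
               match_similarity(win, pwms$TOY2))
  # malformed count row: parse error naming the line
  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("ID  BAD", "P0  A C G T", "01  1 2 3", "//"), bad)
  expect_error(read_transfac(bad), "line 3")
})
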