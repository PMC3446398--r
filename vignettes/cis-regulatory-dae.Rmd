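---
title: "Models and methods: allelic expression, expression haplotypes and carrier risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: allelic expression, expression haplotypes and carrier risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daehap)
```

`daehap` chains five analyses that together ask whether common
cis-regulatory haplotypes of a gene shift its allelic output, its
downstream expression programme, and — in germline mutation carriers —
disease risk. This vignette records the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Differential allelic expression

The assay measures, per sample, replicate allelic peak ratios (allele A
over allele B) in cDNA and in genomic DNA at a transcribed marker SNP.
Genomic DNA carries one copy of each allele, so its ratio calibrates the
assay; the normalized statistic is

$$\widehat{\log_2 R} \;=\; \overline{\log_2 r^{\mathrm{cDNA}}} \;-\;
\overline{\log_2 r^{\mathrm{gDNA}}},$$

with a Welch-combined standard error over replicates. Replicates are
averaged on the log scale, not as a log of mean ratios, so the two alleles
are treated symmetrically and inverting every ratio exactly negates the
statistic (a tested invariant).

A sample is called DAE when $|\widehat{\log_2 R}|$ *strictly* exceeds
$\log_2(\text{threshold})$, with threshold fold 1.2 by default
($\log_2 = 0.263$). The strict boundary is a deliberate choice: exact
equality is measure-zero in real data and a strict rule is reproducible.
Because the per-sample significance procedure behind a threshold call is a
design point on which reasonable assays differ, the caller also offers a
gated mode (`test = TRUE`) that additionally requires a one-sample t-test
of the replicate cDNA log-ratios against the gDNA mean at
$\alpha = 0.05$; the pure threshold rule is the default.

## Haplotypes and expression groups

The built-in system (`brca2_haplotypes()`) has five haplotypes over seven
tag SNPs; haplotypes 2 and 5 are classed "low expression", 1, 3 and 4
"high". Only haplotype 1 carries the marker's G allele, which yields the
anchoring trick: a marker heterozygote carries haplotype 1 plus exactly one
other, recovered by subtracting the anchored alleles from the unphased
genotypes and matching the residual vector against the table. Residuals
matching no pattern are excluded with a warning, never imputed — in a real
cohort a handful of samples are lost this way, and silent imputation would
bias the DAE-by-haplotype counts. The pattern table is loaded from a TSV,
so other haplotype systems can be analyzed unchanged.

Cohorts without the anchoring guarantee go through a standard EM
haplotype-frequency estimator over diplotype compatibility classes:
uniform initial frequencies over the compatible haplotypes, convergence
when the largest frequency change drops below $10^{-8}$ or after 500
iterations. The observed-data log-likelihood is non-decreasing (tested),
and with phase-unambiguous data one M step equals direct counting.
Pairwise LD is computed from phased haplotype samples as
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$, $r^2 = D^2/(p_A p_a p_B p_b)$;
monomorphic loci return an undefined flag rather than an error.

## Association statistics

Three test families mirror the study designs the pipeline serves. The
exact sign test uses binomial tails at $p = 1/2$; it defaults to the
one-sided direction "carriers show DAE more often", because that is the
hypothesis the carriage analysis poses, and both sidedness options are
exposed. Carriage chi-squares are Pearson without continuity correction
(correction switchable); the 2×2 table per haplotype contrasts its
carriers against all other tested samples, which is exact in the anchored
design where each sample contributes one non-anchor haplotype. DAE
magnitude between low- and high-haplotype carriers uses the Wilcoxon
rank-sum test: exact for combined $n \le 20$ without ties, otherwise the
tie-corrected normal approximation without continuity correction. No
multiplicity correction is applied across haplotypes by default; a
Bonferroni switch logs its use.

For expression panels, qPCR Ct values are normalized by the
delta-delta-Ct method: $\Delta C_t$ against the mean of two housekeeping
genes, $\Delta\Delta C_t$ against a reference diplotype group, relative
expression $2^{-\Delta\Delta C_t}$. The housekeeping pair is chosen as the
candidate pair whose per-sample Ct difference is most stable
(`sum(|dCt - median dCt|)`, lexicographic tie-break), which matches the
practice of picking the two genes with the most similar Ct distributions.
The pipeline is invariant to per-sample plate offsets by construction
(tested). Genotype–expression correlation uses one-way ANOVA with
genotype as a factor (an additive-trend linear model p-value is reported
alongside); group comparisons use Welch's t-test by default, with the
pooled variant available because published analyses often report the
classical Student form. An absent group (e.g. no two-low-haplotype
individuals in a tissue) is a logged skip, not an error.

## Regulatory screen

Matrices are parsed from TRANSFAC flat files. Rows are normalized to
frequencies and a pseudocount of 0.01 per row, split across the four
bases, is added before renormalization — applied on the frequency scale so
that scores are invariant to rescaling all counts, with zero-count cells
made finite. Information content is
$I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))$; the core block is the 5 consecutive
positions maximizing $\sum I(i)$, leftmost on ties. A placement scores
$\mathrm{mss} = (\mathrm{Cur}-\mathrm{Min})/(\mathrm{Max}-\mathrm{Min})$
with per-position best/worst bases defining Max/Min, and
$\mathrm{css}$ identically over the core. Both strands are always
scanned; ties go to the smaller offset, then the forward strand; non-ACGT
bases contribute the position's minimum.

The candidate filter applies four criteria in order: the SNP lies inside a
regulatory interval (BED, 0-based half-open, conversion centralized); some
matrix passes both 0.9 cutoffs somewhere in either allele's window; a
passing placement covers the SNP; and the alleles differ, either in
pass/fail status or in matrix score by more than a configurable `delta`
(default 0, i.e. any difference). The flat 0.9/0.9 cutoffs are the
screen's operating point; profile-specific cutoff tables from the original
matrix curation are proprietary and not reproduced. SNP windows default to
20 bp of flank on each side of the variant base (41 bp total) and are
configurable, since "40 bp of surrounding sequence" can be read as either
a total width or a per-side flank.

## Carrier risk models

Risk in mutation carriers is estimated with a Cox proportional-hazards
fitter written for this package: Newton–Raphson from $\beta = 0$ on the
partial likelihood, convergence at $|U(\beta)| < 10^{-8}$ or 50
iterations with step-halving, Breslow tie handling by default and Efron
as an option, optional baseline stratification by study, and left
truncation via an entry-age column (risk sets are rebuilt per event time
in that case; otherwise cumulative sums over the time-sorted sample give
an $O(n \log n)$ evaluation). Wald 95% CIs are
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. Codings: additive per-allele,
2-df heterozygote/homozygote with a likelihood-ratio test, and
per-haplotype-copy dosages (posterior-weighted where phase is uncertain)
against a named reference class. Between-study heterogeneity is the
likelihood-ratio comparison of study-specific versus shared log-HRs, both
with study-stratified baselines; studies without events or genotype
variation contribute no degree of freedom and are logged. A
Cochran–Armitage trend test on the genotype-by-status counts is provided
as a companion statistic to the model-based trend p-value — the two are
asymptotically related but not identical, and on published count tables
the count-based p is reported as such.

These are **plain cohort analyses**. Carrier studies are typically
ascertained through affected families, and the field's
retrospective-likelihood machinery with kinship adjustment corrects for
that; reimplementing it is out of scope here, and every risk report from
this package should be read with that caveat, exactly as applies to any
standard cohort treatment of such data.

## The synthetic-data generator

The generator exists so each stage is testable against known truth. Its
defaults are the package's reference conditions: five haplotypes at the
built-in frequencies renormalized to sum to one; low-expression
haplotypes transcribed at 0.7 relative to high ones, giving a true cDNA
allelic ratio of 1/0.7 ≈ 1.43 in marker heterozygotes carrying one low
haplotype; multiplicative log-normal replicate noise with a 10%
coefficient of variation (the assay's CV is not published; 10% is a
realistic sequencing peak-ratio figure and is configurable) and 3
replicates per assay; gene effects linear in the number of low-expression
haplotypes with Gaussian residuals — defaults plant a 1.74-fold
high-vs-heterozygous-group change in SPP1 and a −0.125 high-vs-low group
difference in MUC16, with two stable (SD 0.05) and two noisy (SD 0.5)
housekeeping genes; and a carrier cohort of 2,754 under Hardy–Weinberg at
minor-allele frequency 0.16 (the frequency implied by the bundled
genotype table), exponential event times at baseline hazard 0.01/year,
exponential censoring at 0.007/year (so about 59% of carriers are
affected, matching the bundled cohort's composition), and 11 studies
assigned round-robin. A single master seed spawns fixed per-generator
substreams, so stages are individually reproducible.

What the generator does *not* emulate: population structure or departures
from random mating, pedigree relationships and non-random ascertainment
of carriers, age-specific incidence (event times are exponential),
microarray probe-level noise, and mutation phase. Passing tests therefore
demonstrate that the estimators recover what they model — not that the
modelled structure exhausts real data. Test and acceptance problem sizes
follow the regimes each check needs: n = 10,000 for frequency
convergence (3 binomial SE), n = 20,000 for hazard-ratio recovery
(3 SE of the planted log-HR), 500 replicates for type-I calibration of
the trend, ANOVA, t- and heterogeneity tests, and a few hundred samples
elsewhere.

## Numerical and degenerate-input conventions

Thresholds are strict inequalities at the DAE boundary and inclusive
(`>=`) at the screen's score cutoffs. Zero-margin contingency tables,
monomorphic loci, single-genotype-class ANOVA and absent diplotype groups
return flagged rows (`defined = FALSE`) or logged skips rather than
errors; genuinely contradictory inputs (non-positive ratios, thresholds
at or below 1, frequencies not summing to one, reference haplotypes
absent from a cohort) fail fast with named errors. All writers are
atomic (write-to-temp then rename), so interrupted runs leave no partial
outputs. EM ties are broken by the uniform start; Cox monotone-likelihood
or singular-information fits are returned flagged with a warning rather
than silently.
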