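---
title: "Methods: ZW dosage compensation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ZW dosage compensation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`zwdc` implements the computational core of a ZW dosage-compensation (DC)
study: sex inference from expressed-SNP allelic balance, stratum-wise
chromatin-enrichment statistics on binned coverage, DC-onset testing in
embryos, aging variability statistics, and sex-specific survival analysis,
together with a seeded generator that simulates every input. This vignette
documents the models, the defaults and why they were chosen, and the
numerical decisions a user should know before trusting the output.

## Coordinate model

A genome is described by a `zw_layout`: chromosome names and lengths, the
identity of the Z, and the 1-based PAR boundary (default 46,043,529 on the
Z). `classify_position()` labels any position `AUTOSOME`, `PAR`
(`pos <= boundary`) or `ZDIFF`. The boundary base itself is assigned to the
PAR: the strict inequalities in the originating rule (`< boundary` vs
`> boundary`) leave that single base unassigned, and we resolve the
ambiguity toward the PAR and document it rather than dropping the base.

Evolutionary strata are a separate classifier (`zw_strata`,
`stratum_label()`): S1 46,085,001–48,385,001; S0 48,665,001–53,365,001,
53,585,001–54,575,001 and 54,715,001–61,855,001; S2 63,345,001–64,075,001
(1-based inclusive). Z(diff) positions outside these intervals are treated
as `ZDIFF_OUTSIDE` in enrichment summaries. The two classifiers are kept
separate deliberately: the SNP-based sex inference needs the PAR/Z(diff)
split, while stratum summaries need the interval labels, and the small gaps
between strata belong to Z(diff) by the boundary rule but to no stratum.

Internally all bins and windows are 0-based half-open (BED convention);
VCF/GFF-style inputs are 1-based inclusive and converted at the I/O layer
only. `make_bins()` truncates the final bin of each chromosome (the
convention of fixed-width binning tools); `make_equal_windows()` instead
gives the last of the `n` windows the remainder, because "equally sized
windows" plots expect exactly `n` windows.

## The synthetic study

`sim_config()` fixes the conditions every end-to-end test runs under.

* **Genome**: 21 chromosomes; the Z (chr6) is 65.8 Mb with the boundary and
  strata above; 20 autosomes of 82 Mb give a ~1.7 Gb genome in which
  Z(diff) is ~1.2% of the sequence, matching the karyotype and genome scale
  of the brine-shrimp system the defaults emulate. The Z(diff) genome
  fraction matters quantitatively: CPM normalization forces each library to
  sum to 10^6, so a female-specific enrichment of Z(diff) necessarily
  depresses female CPM everywhere else by `log2(1 + f * (E[fold] - 1))`,
  with `f` the Z(diff) read share. At `f ~ 0.012` this composition shift is
  ~0.02 log2 units — visible in the PAR/autosome medians (~ -0.02) but small
  against the stratum signals. A toy genome with Z(diff) at 10-20% of the
  sequence would shift every median by ~0.3 and misrepresent the biology.
* **Genes**: 5956 autosomal, 330 PAR and 102 Z(diff) expressed genes (the
  per-region gene counts of the emulated study), placed uniformly without
  overlap, 1–5 exons each, true expression log-normal (`meanlog = log 30`,
  `sdlog = 1`, TPM scale) so roughly two thirds pass the TPM ≥ 10
  expressed cutoff.
* **Counts**: negative binomial throughout, `Var = mu + phi * mu^2` with a
  shared dispersion `phi = 0.1` — the simplest overdispersed model
  consistent with CPM and median-of-ratios normalization (between-replicate
  CV ~32% at high coverage, a realistic figure for CUT&Tag bins and
  low-input RNA-seq).
* **SNPs**: heterozygous population SNPs at 2 per exon-kb plus
  homozygous-alternate reference-divergence SNPs at 0.5 per exon-kb; depth
  NB with mean 40. Hemizygosity is modelled as *leakage*, not as a hard
  zero: at a female Z(diff) het site the silent allele receives
  `Binomial(depth, 0.005)` reads, so the `AB == 0` monoallelic rule is
  stress-tested against sequencing error. 5% of records carry failing
  mapping quality (< 20) as filter decoys.
* **Coverage**: per-bin NB counts around a smooth deterministic baseline
  (~50 expected reads per 10-kb bin, i.e. ~8-12 M reads per library),
  promoter peaks (x4 over `TSS ± 500` of expressed genes, both sexes), and
  for females only a per-stratum multiplier `2^Delta` on Z(diff) bins with
  `Delta` = 1.280 (S0), 1.169 (S1), 0.435 (S2) and 0.8 outside the strata.
  Library sizes vary x0.5–2 between individuals; CPM cancels this exactly.
* **Embryos**: female Z(diff) gene means are multiplied by a dose deficit of
  0.65 at the early (blastula-like) stage and 1.0 at the late stage. The
  early value is a free default — the emulated observation is qualitative
  ("significantly lower expression") — chosen to give a clear but not
  trivial shift (~ -0.6 log2) at n = 3 embryos per sex.
* **Aging**: every signal carries global log-normal noise (sdlog 0.1); old
  females additionally receive an independent per-gene, per-individual
  log-normal factor with sdlog 0.6 on Z(diff) genes only. Both factors are
  mean-preserving (`meanlog = -sdlog^2 / 2`), so mean-level comparisons stay
  null while the coefficient of variation rises — exactly the pattern the
  aging analysis is meant to detect.
* **Survival**: Weibull lifetimes with shape 3 and scale set so the mean is
  45 d (females) and 60 d (males); a lifespan study is 3 replicate cultures
  of 50 individuals per sex.

Everything is seeded and byte-reproducible; per-individual draws derive
sub-seeds from the configuration seed. The `scale` parameter shrinks
lengths, stratum coordinates and gene counts proportionally for fast unit
tests; rate-based expectations are scale-free.

What the generator does **not** emulate: read-level artefacts (mapping
bias, duplicates), W-homologous decoy reads (available as an option, off by
default), peak shape beyond promoter windows, correlated dispersion across
genes, and batch effects. Passing tests therefore demonstrate that the
statistics recover the generator's structure, not that they are robust to
every artefact of real libraries.

## Sex inference

`filter_variants()` keeps exonic records with `MQM > 20`, `MQMR > 20` and
depth `AO + RO > 10`. The per-allele reading of the depth rule
(`AO > 10 AND RO > 10`) would discard every monoallelic site — the very
signal the method needs — so total depth is the default and
`depth_mode = "both"`/`"either"` are provided for auditing. Allelic balance
is recomputed from counts as `min(AO, RO) / (AO + RO)`, which makes
"`AB == 0` iff monoallelic observation" exact and genotype-free; records
with `AO + RO == 0` are `NA` and removed before counting.

`call_sex()` formalizes what a by-eye comparison against known-sex controls
does: female iff `frac_mono(ZDIFF) - frac_mono(PAR) >= 0.3` *and* the
one-sided rank-sum test of `AB(ZDIFF) < AB(PAR)` has `p < 0.05`; fewer than
20 usable SNPs in either region yields `UNCERTAIN`. The effect-size gate
keeps large-sample noise from producing significant-but-tiny differences;
the test keeps small samples honest. At default generator settings the
male monoallelic fraction is ~0.16 in both regions (the reference-divergence
share times the leakage-free probability), far below the 0.3 gate.

## Enrichment statistics

Tracks are CPM-normalized per sample (`sum = 10^6`), averaged within sex,
and compared as per-bin `log2((F + pc) / (M + pc))`; bins are assigned to
strata/regions by midpoint (bins may straddle a boundary; the midpoint rule
is the deterministic tie-break). Medians are reported per group
(S0/S1/S2/ZDIFF_OUTSIDE/PAR/AUTOSOME).

**Pseudocount.** `bin_log2fc()` defaults to `pc = 1` in track units, the
familiar browser-tool default. That default is only innocuous when typical
bin values are well above 1. A 10-kb binning of a ~1.7 Gb genome spreads
10^6 CPM over ~170,000 bins (mean ~6 CPM per bin), where a pseudocount of 1
shrinks a 2.4-fold change by ~0.15 log2 units — larger than the effect
differences between strata. The stratum-recovery analyses in this package
therefore pass `pc = 1e6 / (mean library size)`: a pseudocount of **one
mapped read** expressed in CPM units (~0.08 here), the prior-count idea
used by count-based DE tools. It guards `log 0` identically while staying
small relative to any bin that carries reads. Users comparing tracks at
coarser bin density (or small genomes) can keep `pc = 1`.

`window_summary()` reports quartiles of 10-kb bin values in 14 equal
windows along the Z (the last window absorbs the remainder).
`gene_signal()` averages CPM over `[TSS - 1 kb, TES]`, strand-aware and
clipped at chromosome edges. `metaprofile()` rescales gene bodies to 5 kb
between TSS and TES with 1 kb unscaled flanks at 50-bp resolution, reverses
minus-strand genes, takes per-grid-cell coverage means weighted by base
overlap, and summarizes each gene group by the median (robust to the heavy
right tail of coverage); genes shorter than one grid cell are skipped with
a warning. Replicates are averaged per sex before ratio formation by
default; per-replicate analysis is available by simply mapping over tracks.

## Expression statistics

`size_factors()` is the median-of-ratios estimator (features positive in
every sample; factors rescaled to geometric mean 1); `group_log2fc()` is a
naive pseudocounted ratio of normalized group means. This deliberately
emulates only the normalization of a shrinkage-based DE fit: no dispersion
estimation, no Wald tests. The downstream statistics here operate on
log2FC *distributions* across many genes (region shifts, Manhattan ranks),
which the naive estimate reproduces; per-gene inference is out of scope and
a fidelity limit worth stating.

`dc_onset()` filters to genes with mean raw count > 100 across the samples
of the comparison (the averaging set is the comparison, not a per-time-point
subset), computes female/male log2FC, and tests each region's values
against zero with the one-sided signed-rank test. A signed-rank test
*between* two independent gene groups is ill-defined (it is a one-sample /
paired test), so the one-sample-versus-zero mode is the default and a
between-region rank-sum mode is provided; neither is asserted to be the
emulated study's exact choice. The per-region p-values are
Bonferroni-adjusted over the regions tested (three), matching the package's
multiplicity handling elsewhere; raw p-values are reported alongside.

`bin_de_scan()` excludes bins below a mean normalized count (independent
filtering analogue), tests the rest with the two-sided rank-sum test on
normalized counts (robust and assumption-light at n = 6 vs 6; at that size
the exact two-sided p has a floor of 2/924, so ties at the minimum adjusted
p are expected), applies Benjamini–Hochberg over tested bins and returns a
Manhattan-ready table.

`cv_compare()` computes the per-gene CV (n − 1 standard deviation over the
mean — the denominator the CV definition leaves open) within each age
group and compares young vs old distributions per region with two-sided
rank-sum tests, Bonferroni-corrected for the full six-comparison family
(two sexes × three regions) even when one call covers a single sex, so
p-values are comparable across calls. Constant signals produce all-zero
CVs and the degenerate-tie branch returns p = 1 rather than erroring.

`age_decline_correlation()` drops genes with zero mean expression in more
than half of the time points, computes per-gene Pearson correlations of
mean expression with age, and compares chromosome classes with the
two-sided rank-sum test *without* continuity correction (the convention of
the emulated analysis), Bonferroni-adjusted.

## Rank tests and survival

`rank_sum_test()` / `signed_rank_test()` use midranks for ties, exact
enumeration when the (combined) sample size is ≤ 12 without ties, and
otherwise the normal approximation with tie-corrected variance and an
optional 0.5 continuity correction; a degenerate null (zero variance, e.g.
all observations tied) returns p = 1. The 12-observation switch point is
where enumeration is trivially cheap; at the boundary the two branches
agree to ~0.01 one-sided (~0.02 two-sided). Two-sided p-values are
`min(1, 2 * min(p_less, p_greater))`.

`km_estimate()` is the product-limit estimator with Greenwood variance and
log-scale confidence intervals; censoring at an event time counts the
individual as at risk through that time (right-continuous convention).
`restricted_mean_survival()` integrates the step function; with complete
follow-up it equals the sample mean. `stratified_logrank()` sums
hypergeometric observed-minus-expected terms and variances over event times
within strata (multi-death times use the standard multi-death variance);
a stratum containing a single group is skipped with a warning; replicate
cultures within a stratum are pooled before estimation.

## Problem sizes used in validation

The validation suite and `scripts/acceptance.R` run the generator at full
scale for the enrichment recovery (3 + 3 replicates, ~170,000 10-kb bins;
the S2 stratum contributes 73 bins, so its recovered median carries a
standard error of ~0.06 log2 units — the dominant uncertainty in that
comparison), 40 + 100 individuals for sex-call recovery, 50 seeds for the
DC-onset frequency, 100 seeds for the survival power check, and 10,000 null
replicates for the type-I calibration of both rank tests. These sizes were
chosen so each check's Monte-Carlo error is small against its tolerance
while the whole suite runs in minutes on one CPU.

## Known limitations

* The DE emulation has no dispersion shrinkage; per-gene significance from
  `group_log2fc()` alone would be anticonservative and is not offered.
* CPM composition coupling means the PAR/autosome log2FC medians sit at
  ~ -0.02, not exactly 0, whenever Z(diff) is genuinely enriched; this is a
  property of the normalization, not an implementation artefact.
* The AB definition folds to `[0, 0.5]` (minor-allele fraction). Analyses
  that plot reference-allele fractions up to 1 are related by reflection
  but not identical; the folded definition is the one that makes the
  monoallelic rule exact.
* The sex caller assumes expressed heterozygosity is abundant enough
  (≥ 20 usable SNPs per region); very low-input libraries will return
  `UNCERTAIN` rather than a guess.
* FreeBayes invocation, alignment, quantification and peak calling are out
  of scope; the package consumes their tabular outputs.
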