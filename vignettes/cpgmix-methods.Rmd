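---
title: "cpgmix: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpgmix: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgmix)
```

# Scope

`cpgmix` implements, end to end, the analysis chain of a candidate-gene
methylation study of adolescent psychopathology: methylation
quantification from targeted bisulfite amplicon sequencing, unsupervised
discovery of severity profiles from bivariate CBCL T-scores with
constrained Gaussian mixtures, and cluster-characterization statistics.
Because raw data of this kind are typically not deposited, the package is
driven by a seeded synthetic-data generator whose defaults encode the
reference study conditions; every stage can therefore be validated against
exact ground truth.

# The synthetic cohort generator

`generateCohort()` draws, per subject, a latent component from the mixing
weights and then, conditional on the component:

* internalizing and externalizing **T-scores** from independent normals
  (T-scores: population mean 50, SD 10). The default two components are a
  lower-severity component (weight 0.51; means 51.0 / 47.1; SDs
  6.91 / 6.51) and a higher-severity component (weight 0.49; means
  63.7 / 58.9; SDs 5.97 / 7.10);
* binary **risk indicators** as Bernoulli draws: stressful life events at
  0.37 / 0.48 per component, perinatal risk at 0.46 / 0.66. The
  component-level prevalences are taken as the generating truth; the
  cohort-level descriptive figures quoted alongside them in the source
  material (0.42 / 0.44) are slightly below the mixture-implied marginals
  and cannot hold simultaneously, so the component-level values win;
* **demographics**: age, SES as normals and sex as Bernoulli, with
  per-component parameters matching the reported cluster descriptives;
* one **methylation percentage per CpG** (54 CpGs across six amplicons of
  BDNF intron 1, FKBP5 intron 7, the IGF2 DMR and three OXTR regions)
  from a normal with the per-component mean/SD, truncated by clipping to
  [0, 100]. Clipping (rather than rejection sampling) was chosen because
  only means and SDs are available as targets and most CpGs sit far from
  the bounds; for low-methylation CpGs (means < 1%) it produces a small
  point mass at 0, which mirrors the floor effects real percent data show.

The generator emulates the *marginal, per-variable* structure of such a
cohort. It deliberately does **not** model CpG–CpG correlation within an
amplicon, age or sex effects on methylation, genotype effects, or
cell-type composition of saliva. Passing tests therefore demonstrate that
the pipeline recovers what it is pointed at under the stated conditions —
not that real saliva methylation behaves this way.

On the OXTR region labels: published annotations of the three OXTR
amplicons are mutually inconsistent (the same labels appear with swapped
coordinates and CpG counts in different places). `ampliconRegions()` keys
regions by coordinates and CpG-count consistency: exon 3 carries 15 CpGs
(`OXTR_E3`), intron 1 carries 13 (`OXTR_I1`), and the promoter carries 9
of which 7 are analyzed (`OXTR_PR`). `qcSample()` accepts an explicit
CpG-inclusion mask because which two promoter CpGs were dropped is not
recorded anywhere; the generator simply simulates the 7 analyzed sites.

# The bisulfite read simulator

`simulateBisulfitePairs()` models one template molecule per read pair.
Each CpG cytosine is drawn methylated with its site probability and then
stays C; unmethylated CpG cytosines and all non-CpG cytosines convert
C→T independently with probability `conversionEff`. Only the converted
original-top strand is simulated — amplicon bisulfite PCR is
strand-specific, and a single strand keeps the C/T asymmetry of calling
unambiguous: mate 1 reads the template 5' end, mate 2 is the reverse
complement of the 3' end, and at the default read length (the amplicon
length) the mates overlap the whole amplicon. Sequencing error is uniform
substitution at `errorRate` per base; base qualities are constant
Phred 40, since no quality-dependent step exists downstream. The per-pair
truth record keeps every drawn CpG state, which is what makes the
exactness tests possible (with `errorRate = 0`, `conversionEff = 1` the
caller must reproduce the realized per-molecule proportions exactly — a
property the test suite checks).

Amplicon reference sequences are synthetic: random sequences with exactly
the declared number of CG dinucleotides at recorded positions (verified
against an independent substring scan in the tests), with genomic
coordinates carried as metadata only.

# Alignment and methylation calling

Each mate is aligned to **every** reference with an affine-gap local
(Smith–Waterman/Gotoh) aligner implemented in C++; a gap of length $L$
costs `gapOpen` + $L$·`gapExtend`. The bisulfite rule scores read T
opposite reference C as a match (conversion), while reference C vs read C
also matches (methylation); the rule is asymmetric and applies only in
that orientation. Defaults — match +2, mismatch −3, gap open −5, gap
extend −2 — are conventional local-alignment values; no scoring scheme is
prescribed by the study design, and the tests verify the implementation
against a brute-force dynamic-programming oracle rather than any
particular parameter choice.

A pair is retained only when both mates' best alignments hit the same
reference (*coherent pairs*), with equal-score ties broken toward the
lowest reference index for determinism. A retention floor of
0.6·readLen·match filters degenerate short local hits that would
otherwise let junk reads form coherent pairs; 0.6 is low enough that a
read with ~25% scattered mismatches still maps, high enough that a
repeat-matching fragment does not.

At each CpG cytosine the four base frequencies are tallied. Overlapping
mates of one pair contribute **once** per reference position (mate 1 wins
on disagreement) so a single molecule is never counted twice. Methylation
per site is `100·C/(C+T)`; A/G observations are excluded from the
denominator (they indicate error or misalignment, not conversion state)
but stay visible in the counts. A site with `C+T = 0` is reported `NA`,
never 0 — collapsing "no information" to "unmethylated" would bias
low-coverage sites. Conversion efficiency is `100·T/(C+T)` pooled over
non-CpG cytosines. QC fails a sample×amplicon profile if any analyzed CpG
is under 100x coverage or conversion is not **strictly** above 99%.

# The mixture model

For T-score matrix $X \in \mathbb{R}^{n\times 2}$, `fitMixture()`
maximizes the likelihood of
$$ f(x) = \sum_{k=1}^{K} \pi_k \, \mathcal{N}(x \mid \mu_k, \Sigma_k) $$
by EM under three diagonal covariance families:

| family | $\Sigma_k$ | variance parameters |
| --- | --- | --- |
| EII | $\lambda I$ | 1 |
| VII | $\lambda_k I$ | $K$ |
| EEI | $\mathrm{diag}(\lambda_1..\lambda_d)$ | $d$ |

Free parameters $m = (K-1) + Kd + \{1, K, d\}$, and models are compared
with the model-based-clustering BIC convention
$\mathrm{BIC} = 2\,\ell - m\ln n$ (larger better). Ties in
`selectModel()` break toward smaller $m$, then smaller $K$.

Numerical choices: k-means seeding with 10 restarts under a derived seed
(deterministic given the user seed), relative log-likelihood tolerance
1e-8, at most 500 iterations, and a variance floor of 1e-6 (squared
T-score units) to avert component collapse; a restart whose component
weight vanishes is discarded. K-means seeding is a deliberate departure
from the agglomerative model-based initialization some mixture software
uses: with only two well-separated dimensions it reaches the same optima
(the tests cross-check the reached optimum and the likelihood arithmetic
against an independent mixture implementation) and is simpler to seed
reproducibly.

One genuinely open modeling point deserves a note: for a two-component
solution on these data the spherical equal-volume model (EII, $m=6$) and
the shared-diagonal model (EEI, $m=7$) are near-equivalent, and the
reference description of the best model is ambiguous between them — the
printed BIC/log-likelihood arithmetic matches $m=6$ (EII) while the
model is elsewhere *named* EEI. The package takes no side: both families
are first-class, `selectModel()` ranks them empirically, and the
acceptance script fits EEI for the recovery study while the BIC worked
example uses EII's parameter count, mirroring each published number in
its own convention.

`mapAssign()` orders components by ascending internalizing mean, so for
$K=2$ the labels LOW / HIGH are stable regardless of EM's internal
component order.

# Cohort statistics

* **Cleaning and imputation** (`cleanAndImpute`): subjects with strictly
  more than 50% missing non-identifier cells are removed; each remaining
  missing value is replaced by a uniform draw from the variable's observed
  values (random hot-deck), preserving the empirical support and spread.
* **t-tests** (`twoSampleT`, `summaryT`): Welch is the default variant —
  re-deriving published table rows from rounded group summaries matches
  Welch for some rows and pooled for others, so both variants are exposed
  and the report records which was used. Cohen's d always uses the pooled
  SD. `summaryT` applies identical formulas to printed summaries, which
  is how published rows are re-checked without raw data (the suite
  verifies the two routes agree to 1e-10 on moment-matched samples).
* **2×2 χ²** (`chiSq2x2`): Yates continuity correction on by default —
  the published perinatal-risk statistic is reproduced only with the
  correction — while the phi coefficient $\sqrt{\chi^2/N}$ always uses
  the uncorrected statistic, which is what reproduces the published
  effect size.
* **Bonferroni** (`bonferroniAdjust`, `characterize`): the default family
  is the 54 methylation comparisons; demographics and clinical scales are
  reported with raw p (a `"all"` family option exists). The published
  analysis is ambiguous on the family definition — several of its
  "significant" raw p-values would not survive a 54-test correction — so
  the report always carries both raw and adjusted columns.
* **Sign convention**: continuous statistics are reported HIGH − LOW.
  Published table signs are internally inconsistent, so the package fixes
  one convention and documents it.
* **Shapiro–Wilk** (`shapiroWilk`): wraps the standard Royston
  approximation, with explicit degenerate-input errors.

The type-I calibration test simulates cohorts in which both components
share every methylation distribution and checks that the raw-p rejection
rate of the 54 CpG t-tests sits within binomial error of the nominal 5%.

# Pipeline and reproducibility

`runPipeline()` executes simulate → call → clean/impute → cluster →
characterize. Read-level simulation and calling run for a configurable
subset of subjects (default 2) as a measurement-model validation; the
cohort-level statistics use the generator's per-subject methylation
table directly, since simulating ~200 subjects × 6 amplicons of reads
adds cost but no statistical information once the caller's exactness is
established. Every output file is declared in `manifest.json` with an MD5
digest, and a rerun with the same configuration is bit-identical — a
property the test suite asserts.

Problem sizes used by the shipped tests and acceptance script (the
package's own choices for a thorough-but-quick default run): recovery
studies use 50 replicate cohorts of n = 200; the conversion-efficiency
check uses 5000 pairs on a 146-bp amplicon; oracle alignment checks use
instances up to 50 bp; the calibration study uses 50 × 54 null tests.

# Limitations

* The aligner is a full $O(nm)$ panel aligner for short amplicon panels —
  no indexing or seeding, and unsuitable for genome-scale bisulfite data.
* No SNP-aware calling, UMI/duplicate handling, PCR-bias or chimera
  simulation; error is uniform substitution only.
* The generator's independence assumptions (across CpGs and between
  methylation and risk factors, given the component) make the null
  calibration clean but understate real-data correlation.
* Mixture fits assume diagonal covariance within components; correlated
  T-score components would call for richer families not implemented here.
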