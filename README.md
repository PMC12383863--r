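# cpgmix

Targeted bisulfite amplicon methylation calling and model-based clustering
of adolescent psychopathology profiles.

## What problem does this solve?

Candidate-gene methylation studies of adolescent psychopathology typically
combine three analysis layers that are rarely available as one tested
pipeline:

1. **Methylation quantification** from targeted bisulfite amplicon
   sequencing: paired-end reads are locally aligned to a panel of amplicon
   references with a bisulfite-aware Smith–Waterman scoring (read T
   opposite reference C counts as a match), only pairs whose two mates
   coherently hit the same reference are retained, and at each CpG
   cytosine the four base frequencies are tallied. Per-CpG methylation is
   `100·C/(C+T)`; bisulfite conversion efficiency is `100·T/(C+T)` pooled
   over non-CpG cytosines; samples need ≥ 100x coverage at every analyzed
   CpG and strictly > 99% conversion to pass QC.
2. **Unsupervised profile discovery**: bivariate CBCL internalizing /
   externalizing T-scores are clustered with constrained-covariance
   Gaussian finite mixture models fitted by EM — families EII (spherical,
   equal volume), VII (spherical, varying volume) and EEI (shared diagonal)
   — compared by the model-based-clustering BIC convention
   `BIC = 2·logL − m·ln n` (larger is better).
3. **Cluster characterization**: Yates-corrected 2×2 χ² with the phi
   coefficient for binary risk factors (stressful life events, perinatal
   complications, sex), Welch or pooled t-tests with Cohen's d for
   continuous traits and all 54 candidate-gene CpG methylation
   percentages, Bonferroni-corrected within a configurable family, after
   >50%-missing subject removal and random hot-deck imputation.

Because cohort data of this kind are not publicly deposited, the package
also ships a first-class **synthetic-data generator**: seeded cohorts
drawn from a two-component T-score mixture with per-component risk
prevalences and per-CpG methylation distributions, plus a bisulfite read
simulator (conversion efficiency, sequencing error, constant Phred 40
qualities) with exact per-molecule ground truth, so every stage can be
validated against known truth.

## Worked example

```r
library(cpgmix)

co  <- generateCohort(defaultCohortSpec(n = 200), seed = 1)
X   <- as.matrix(co$table[, c("internalizing", "externalizing")])
sel <- selectModel(X, KRange = 1:4, seed = 1)
head(sel$ranking, 3)
#>   family K    loglik m       bic
#> 1    EII 2 -1446.504 6 -2924.798
#> 2    EEI 2 -1446.197 7 -2929.481
#> 3    VII 2 -1446.269 7 -2929.627

asg <- mapAssign(sel$best, X)
table(asg$labels)
#>  LOW HIGH
#>   92  108

rep <- characterize(co$table, asg)
rep[rep$variable %in% c("internalizing", "perinatal_risk", "BDNF_CpG5"),
    c("variable", "kind", "statistic", "p_raw", "p_bonferroni", "effect")]
#>          variable     kind statistic    p_raw p_bonferroni effect
#> 3  perinatal_risk chi2_2x2     8.759 3.08e-03     3.08e-03  0.219
#> 6   internalizing  welch_t    12.092 4.17e-25     4.17e-25  1.734
#> 12      BDNF_CpG5  welch_t    -0.701 4.84e-01     1.00e+00 -0.100
```

The BIC ranking selects the two-component spherical equal-volume model
(EII, `m = 6` free parameters); MAP assignment splits this simulated
cohort into 92 lower-severity (LOW) and 108 higher-severity (HIGH)
subjects. In the characterization table, continuous statistics are signed
HIGH − LOW: the HIGH cluster scores ~12 Welch-t units higher on
internalizing problems and carries significantly more perinatal risk
(χ² = 8.76, phi = 0.22), while this particular draw shows no BDNF CpG5
difference after Bonferroni correction across the 54 methylation tests.

A full run — read simulation, methylation calling with QC, cleaning and
imputation, model selection, characterization, plus a digest manifest that
makes reruns bit-reproducible — is one call:

```r
res <- runPipeline(pipelineConfig(seed = 42), "run1")
```

## Package tour

| Module | Key functions |
| --- | --- |
| Synthetic data | `makeAmpliconReference`, `simulateBisulfitePairs`, `generateCohort`, `injectMissingness`, `writeFastqPair` |
| Methylation calling | `bisulfiteScoring`, `bisulfiteAlignPair`, `tallyCpgBases`, `methylationPercentages`, `conversionEfficiency`, `qcSample`, `callSampleMethylation` |
| Mixture clustering | `fitMixture`, `nFreeParams`, `bicMclust`, `selectModel`, `mapAssign` |
| Cohort statistics | `cleanAndImpute`, `twoSampleT`, `summaryT`, `chiSq2x2`, `bonferroniAdjust`, `shapiroWilk`, `characterize` |
| Orchestration | `pipelineConfig`, `runPipeline` |

See `vignettes/cpgmix-methods.Rmd` for the full statistical and numerical
account of the methods.
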