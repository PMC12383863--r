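#' Target amplicon regions of the candidate genes
#'
#' The six bisulfite-PCR target regions across BDNF (intron 1), FKBP5
#' (intron 7), IGF2 (the imprinted differentially methylated region) and
#' OXTR (exon 3, intron 1, promoter), with hg19 coordinates (1-based,
#' inclusive) and the number of CpG sites analyzed in each. Region labels
#' are keyed to coordinates by CpG-count consistency: the exon-3 region
#' carries 15 CpGs (OXTR_E3), intron 1 carries 13 (OXTR_I1), and the
#' promoter region carries 9 CpGs of which 7 are analyzed (OXTR_PR);
#' published annotations of these OXTR labels are mutually inconsistent, so
#' coordinates plus CpG counts are authoritative here.
#'
#' @return data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `length`, `n_cpg`.
#' @examples
#' ampliconRegions()
#' @export
ampliconRegions <- function() {
  r <- data.frame(
    name  = c("BDNF", "FKBP5", "IGF2", "OXTR_E3", "OXTR_I1", "OXTR_PR"),
    chrom = c("chr11", "chr6", "chr11", "chr3", "chr3", "chr3"),
    start = c(27723077, 35558405, 2169373, 8809340, 8810654, 8811488),
    end   = c(27723244, 35558550, 2169658, 8809530, 8810919, 8811837),
    n_cpg = c(11L, 3L, 5L, 15L, 13L, 7L),
    stringsAsFactors = FALSE
  )
  r$length <- r$end - r$start + 1L
  r[, c("name", "chrom", "start", "end", "length", "n_cpg")]
}

#' Per-cluster per-CpG methylation parameters
#'
#' Mean and standard deviation of the methylation percentage at each of the
#' 54 analyzed CpG sites, for the lower-severity (LOW) and higher-severity
#' (HIGH) psychopathology clusters of the reference cohort. These are the
#' generating parameters of [defaultCohortSpec()].
#'
#' @return data.frame with columns `amplicon`, `cpg`, `variable`,
#'   `mean_low`, `sd_low`, `mean_high`, `sd_high` (all percentages).
#' @examples
#' head(clusterMethylationParams())
#' @export
clusterMethylationParams <- function() {
  # columns: mean_low sd_low mean_high sd_high, CpGs in genomic order
  v <- c(
    # BDNF, 11 CpGs
    1.71, 0.51, 1.65, 0.44,   0.40, 0.32, 0.41, 0.18,
    0.40, 0.20, 0.42, 0.17,   0.33, 0.14, 0.28, 0.17,
    0.54, 0.25, 0.46, 0.16,   0.47, 0.17, 0.46, 0.21,
    0.53, 0.41, 0.46, 0.18,   0.79, 0.36, 0.77, 0.25,
    0.63, 0.27, 0.65, 0.27,   0.83, 0.29, 0.83, 0.29,
    0.59, 0.19, 0.51, 0.15,
    # FKBP5, 3 CpGs
    72.38, 4.66, 72.32, 5.59, 92.87, 3.81, 92.76, 3.95,
    90.22, 4.59, 89.89, 5.03,
    # IGF2 DMR, 5 CpGs
    49.58, 5.73, 48.95, 5.04, 39.05, 3.86, 37.65, 5.29,
    40.42, 4.60, 39.47, 4.67, 34.61, 4.92, 33.48, 5.16,
    0.08, 0.05, 0.08, 0.05,
    # OXTR exon 3, 15 CpGs
    7.94, 3.38, 7.93, 3.10,   6.56, 3.01, 6.44, 2.87,
    4.65, 2.59, 4.70, 2.14,   4.48, 2.83, 4.56, 2.42,
    2.01, 1.42, 1.98, 1.19,   8.30, 3.72, 8.49, 3.98,
    5.86, 3.12, 5.93, 2.96,   2.95, 1.93, 3.12, 1.89,
    5.24, 3.02, 5.40, 2.85,   5.80, 3.16, 5.81, 2.92,
    5.67, 3.51, 5.84, 3.34,   3.04, 2.24, 3.09, 2.01,
    4.82, 3.43, 5.10, 3.15,   3.02, 2.09, 2.93, 1.98,
    4.26, 2.51, 3.40, 2.33,
    # OXTR intron 1, 13 CpGs
    1.76, 0.73, 1.69, 0.81,   2.76, 0.94, 2.73, 1.10,
    7.36, 2.04, 7.15, 2.09,   2.92, 1.71, 2.75, 1.06,
    36.33, 4.87, 35.89, 4.97, 38.70, 5.60, 38.29, 5.58,
    62.71, 4.91, 61.45, 5.17, 43.77, 4.57, 43.25, 5.24,
    23.43, 5.00, 23.32, 4.79, 8.55, 2.58, 7.97, 2.25,
    10.92, 2.99, 10.44, 3.00, 12.37, 3.97, 11.77, 3.15,
    13.40, 3.45, 13.03, 3.26,
    # OXTR promoter, 7 analyzed CpGs
    91.63, 2.29, 91.05, 2.20, 78.71, 4.09, 78.39, 4.68,
    79.64, 4.13, 78.87, 3.94, 64.66, 5.94, 63.93, 4.64,
    85.13, 2.81, 84.34, 2.65, 47.53, 5.07, 46.42, 4.96,
    71.09, 4.92, 70.19, 3.78
  )
  m <- matrix(v, ncol = 4L, byrow = TRUE)
  regions <- ampliconRegions()
  amp <- rep(regions$name, regions$n_cpg)
  cpg <- unlist(lapply(regions$n_cpg, seq_len))
  data.frame(
    amplicon = amp, cpg = cpg,
    variable = paste0(amp, "_CpG", cpg),
    mean_low = m[, 1], sd_low = m[, 2],
    mean_high = m[, 3], sd_high = m[, 4],
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort-generation specification
#'
#' Bundles and validates every parameter of the synthetic cohort generator:
#' component weights of the two-component bivariate T-score mixture,
#' per-component (internalizing, externalizing) means and SDs, binary risk
#' prevalences, demographic parameters, and the per-component per-CpG
#' methylation means and SDs.
#'
#' @param n number of subjects.
#' @param mixing per-component weights, positive, summing to 1.
#' @param means K x 2 matrix of (internalizing, externalizing) T-score means.
#' @param sds K x 2 matrix of corresponding SDs (> 0).
#' @param slePrevalence per-component probability of at least one stressful
#'   life event.
#' @param perinatalPrevalence per-component probability of at least one
#'   pre-/perinatal risk factor.
#' @param ageMean,ageSd per-component age parameters, years.
#' @param maleProb per-component probability of male sex.
#' @param sesMean,sesSd per-component socioeconomic-status parameters.
#' @param methylation data.frame as [clusterMethylationParams()] (columns
#'   `variable`, `mean_low`, `sd_low`, `mean_high`, `sd_high`), or NULL for
#'   no methylation variables.
#' @return validated list of class `"CohortSpec"`.
#' @seealso [defaultCohortSpec()], [generateCohort()]
#' @export
cohortSpec <- function(n, mixing, means, sds,
                       slePrevalence = rep(0, length(mixing)),
                       perinatalPrevalence = rep(0, length(mixing)),
                       ageMean = rep(14.45, length(mixing)),
                       ageSd = rep(2.16, length(mixing)),
                       maleProb = rep(0.76, length(mixing)),
                       sesMean = rep(48.95, length(mixing)),
                       sesSd = rep(19.39, length(mixing)),
                       methylation = NULL) {
  K <- length(mixing)
  stopifnot(n >= 0, K >= 1)
  if (any(mixing < 0) || any(mixing > 1) || abs(sum(mixing) - 1) > 1e-8)
    stop("mixing weights must lie in [0,1] and sum to 1")
  means <- rbind(means); sds <- rbind(sds)
  if (nrow(means) != K || nrow(sds) != K || ncol(means) != 2L ||
      ncol(sds) != 2L)
    stop("means and sds must be K x 2")
  if (any(sds <= 0)) stop("T-score SDs must be positive")
  for (p in list(slePrevalence, perinatalPrevalence, maleProb))
    if (length(p) != K || any(p < 0) || any(p > 1))
      stop("prevalences and maleProb must be length-K probabilities")
  if (any(ageSd <= 0) || any(sesSd <= 0))
    stop("demographic SDs must be positive")
  if (!is.null(methylation)) {
    need <- c("variable", "mean_low", "sd_low", "mean_high", "sd_high")
    if (!all(need %in% names(methylation)))
      stop("methylation table lacks required columns")
    mm <- as.matrix(methylation[, c("mean_low", "mean_high")])
    if (any(mm < 0) || any(mm > 100))
      stop("methylation means must lie in [0, 100]")
    if (any(methylation$sd_low <= 0) || any(methylation$sd_high <= 0))
      stop("methylation SDs must be positive")
  }
  structure(list(
    n = as.integer(n), mixing = mixing, means = means, sds = sds,
    slePrevalence = slePrevalence,
    perinatalPrevalence = perinatalPrevalence,
    ageMean = ageMean, ageSd = ageSd, maleProb = maleProb,
    sesMean = sesMean, sesSd = sesSd, methylation = methylation
  ), class = "CohortSpec")
}

#' Default cohort specification: the reference study conditions
#'
#' Two components of 200 subjects: a LOW-severity component (weight 0.51,
#' internalizing/externalizing means 51.0/47.1, SDs 6.91/6.51) and a
#' HIGH-severity component (weight 0.49, means 63.7/58.9, SDs 5.97/7.10);
#' stressful-life-event prevalences 0.37/0.48 and perinatal-risk
#' prevalences 0.46/0.66 per component; per-component demographics (age
#' 14.5 +/- 2.02 vs 14.4 +/- 2.31 years, male fraction 76/102 vs 77/98, SES
#' 50.8 +/- 20.3 vs 47.0 +/- 18.3); and the 54 per-CpG methylation
#' parameters of [clusterMethylationParams()]. Component-level prevalences
#' are taken as the generating truth (the marginal prevalences they imply
#' are slightly above the cohort-level descriptive figures, which cannot
#' both hold exactly).
#'
#' @param n cohort size (default 200).
#' @return a `"CohortSpec"` list, see [cohortSpec()].
#' @examples
#' spec <- defaultCohortSpec()
#' spec$mixing
#' @export
defaultCohortSpec <- function(n = 200L) {
  cohortSpec(
    n = n,
    mixing = c(0.51, 0.49),
    means = rbind(c(51.0, 47.1), c(63.7, 58.9)),
    sds = rbind(c(6.91, 6.51), c(5.97, 7.10)),
    slePrevalence = c(0.37, 0.48),
    perinatalPrevalence = c(0.46, 0.66),
    ageMean = c(14.5, 14.4), ageSd = c(2.02, 2.31),
    maleProb = c(76 / 102, 77 / 98),
    sesMean = c(50.8, 47.0), sesSd = c(20.3, 18.3),
    methylation = clusterMethylationParams()
  )
}
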