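#' AmpliconReference: one bisulfite-PCR target region
#'
#' Holds the reference sequence of a single amplicon together with the
#' 0-based offsets of the C of every CG dinucleotide and the (1-based,
#' inclusive) genomic coordinates the region mirrors. Sequences produced by
#' [makeAmpliconReference()] are synthetic stand-ins for the real genomic
#' sequence; the coordinates are metadata only.
#'
#' @slot name short region label (e.g. `"BDNF"`).
#' @slot chrom chromosome label, metadata only.
#' @slot start,end 1-based inclusive genomic coordinates, metadata only.
#' @slot sequence uppercase A/C/G/T string.
#' @slot cpgPositions strictly increasing integer vector of 0-based offsets
#'   of the cytosine of each CpG.
#'
#' @seealso [makeAmpliconReference()], [cpgPositions()], [refSequence()]
#' @export
setClass("AmpliconReference",
  representation(
    name = "character",
    chrom = "character",
    start = "numeric",
    end = "numeric",
    sequence = "character",
    cpgPositions = "integer"
  )
)

setValidity("AmpliconReference", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
    msg <- c(msg, "'sequence' must be a single non-empty string")
  else {
    if (grepl("[^ACGT]", object@sequence))
      msg <- c(msg, "'sequence' must contain only A/C/G/T")
    p <- object@cpgPositions
    if (length(p) && (any(p < 0L) || any(p + 2L > nchar(object@sequence))))
      msg <- c(msg, "'cpgPositions' out of range")
    else if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, "'cpgPositions' must be strictly increasing")
    else if (length(p)) {
      dinucs <- substring(object@sequence, p + 1L, p + 2L)
      if (!all(dinucs == "CG"))
        msg <- c(msg, "every cpgPosition must point at a CG dinucleotide")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ReadPairSet: simulated bisulfite paired-end reads with ground truth
#'
#' Mate 1 is drawn from the bisulfite-converted original-top strand of the
#' amplicon; mate 2 is the reverse complement of the 3' end of the same
#' converted template. The truth slot records, per template molecule, the
#' drawn methylation state of every CpG, so callers can be validated
#' exactly.
#'
#' @slot mate1,mate2 character vectors of read sequences (equal length).
#' @slot qual1,qual2 Phred+33 quality strings, same lengths as the reads.
#' @slot reference name of the source [AmpliconReference-class].
#' @slot truth data.frame with one row per pair: `pair`, `start1`, `start2`
#'   (0-based template offsets) and one logical `cpg<i>` column per CpG
#'   (TRUE = methylated, i.e. the template kept its C).
#'
#' @seealso [simulateBisulfitePairs()], [writeFastqPair()]
#' @export
setClass("ReadPairSet",
  representation(
    mate1 = "character",
    mate2 = "character",
    qual1 = "character",
    qual2 = "character",
    reference = "character",
    truth = "data.frame"
  )
)

setValidity("ReadPairSet", function(object) {
  n <- length(object@mate1)
  if (length(object@mate2) != n || length(object@qual1) != n ||
      length(object@qual2) != n)
    return("mate and quality vectors must have equal length")
  if (n && (any(!nzchar(object@mate1)) || any(!nzchar(object@mate2))))
    return("mate sequences must be non-empty")
  if (n && (any(nchar(object@qual1) != nchar(object@mate1)) ||
            any(nchar(object@qual2) != nchar(object@mate2))))
    return("quality strings must match read lengths")
  if (nrow(object@truth) != n)
    return("truth table must have one row per pair")
  TRUE
})

#' MethylationProfile: per-CpG calls for one sample x amplicon
#'
#' Per CpG site, the counts of A/C/G/T observed at the cytosine position of
#' the CpG across all retained mates, the coverage (their sum), and the
#' methylation percentage 100*C/(C+T) (NA when C+T = 0). The amplicon-level
#' bisulfite conversion efficiency is 100*T/(C+T) pooled over non-CpG
#' cytosines.
#'
#' @slot sample sample identifier.
#' @slot amplicon amplicon name.
#' @slot counts integer matrix, one row per CpG, columns A/C/G/T.
#' @slot methPct numeric vector of methylation percentages (NA if undefined).
#' @slot conversion conversion efficiency percentage (NA if not computable).
#' @slot qc list with elements `pass` (logical), `reasons` (character).
#'
#' @seealso [callSampleMethylation()], [qcSample()], [methPct()], [coverage()]
#' @export
setClass("MethylationProfile",
  representation(
    sample = "character",
    amplicon = "character",
    counts = "matrix",
    methPct = "numeric",
    conversion = "numeric",
    qc = "list"
  )
)

setValidity("MethylationProfile", function(object) {
  cn <- colnames(object@counts)
  if (!identical(cn, c("A", "C", "G", "T")))
    return("counts must have columns A, C, G, T")
  if (any(object@counts < 0))
    return("counts must be non-negative")
  if (length(object@methPct) != nrow(object@counts))
    return("methPct length must equal number of CpG sites")
  ok <- is.na(object@methPct) |
    (object@methPct >= 0 & object@methPct <= 100)
  if (!all(ok))
    return("methylation percentages must lie in [0, 100] or be NA")
  if (!is.na(object@conversion) &&
      (object@conversion < 0 || object@conversion > 100))
    return("conversion efficiency must lie in [0, 100]")
  TRUE
})

#' MixtureModel: fitted constrained-covariance Gaussian mixture
#'
#' A K-component bivariate Gaussian mixture with one of three diagonal
#' covariance parameterizations: EII (spherical, equal volume: one shared
#' scalar variance), VII (spherical, varying volume: one scalar per
#' component), EEI (diagonal, equal volume and shape: one shared variance
#' per dimension). The `bic` slot follows the model-based-clustering
#' convention 2*loglik - m*log(n), larger is better.
#'
#' @slot family `"EII"`, `"VII"` or `"EEI"`.
#' @slot K number of components.
#' @slot weights mixing proportions, length K, positive, summing to 1.
#' @slot means K x d matrix of component means.
#' @slot variances EII: length-1 numeric; VII: length-K; EEI: length-d.
#' @slot loglik maximized log-likelihood.
#' @slot m number of free parameters, see [nFreeParams()].
#' @slot n sample size used in the fit.
#' @slot bic 2*loglik - m*log(n), see [bicMclust()].
#'
#' @seealso [fitMixture()], [selectModel()], [mapAssign()]
#' @export
setClass("MixtureModel",
  representation(
    family = "character",
    K = "integer",
    weights = "numeric",
    means = "matrix",
    variances = "numeric",
    loglik = "numeric",
    m = "integer",
    n = "integer",
    bic = "numeric"
  )
)

setValidity("MixtureModel", function(object) {
  msg <- character()
  if (!object@family %in% c("EII", "VII", "EEI"))
    msg <- c(msg, "family must be one of EII, VII, EEI")
  K <- object@K
  d <- ncol(object@means)
  if (length(object@weights) != K || nrow(object@means) != K)
    msg <- c(msg, "weights/means dimensions must match K")
  if (any(object@weights <= 0) || abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must be positive and sum to 1")
  if (any(object@variances <= 0))
    msg <- c(msg, "variances must be positive")
  nvar <- switch(object@family, EII = 1L, VII = K, EEI = d)
  if (!is.null(nvar) && length(object@variances) != nvar)
    msg <- c(msg, "variance vector length inconsistent with family")
  if (object@family %in% c("EII", "VII", "EEI") &&
      object@m != nFreeParams(object@family, K, d))
    msg <- c(msg, "free-parameter count inconsistent with family/K/d")
  if (abs(object@bic - (2 * object@loglik - object@m * log(object@n))) >
      1e-6 * max(1, abs(object@bic)))
    msg <- c(msg, "bic inconsistent with loglik, m, n")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmpliconReference", function(object) {
  cat(sprintf("AmpliconReference '%s' (%s:%s-%s)\n", object@name,
              object@chrom, format(object@start, scientific = FALSE),
              format(object@end, scientific = FALSE)))
  cat(sprintf("  %d bp, %d CpG sites\n", nchar(object@sequence),
              length(object@cpgPositions)))
})

setMethod("show", "ReadPairSet", function(object) {
  cat(sprintf("ReadPairSet: %d pairs from '%s'\n", length(object@mate1),
              object@reference))
  if (length(object@mate1))
    cat(sprintf("  read length %d bp (mate 1)\n", nchar(object@mate1[1])))
})

setMethod("show", "MethylationProfile", function(object) {
  cat(sprintf("MethylationProfile: sample '%s', amplicon '%s'\n",
              object@sample, object@amplicon))
  cov <- rowSums(object@counts)
  cat(sprintf("  %d CpGs; coverage %s; conversion %s%%; QC %s\n",
              nrow(object@counts),
              if (length(cov)) paste0(min(cov), "-", max(cov)) else "NA",
              ifelse(is.na(object@conversion), "NA",
                     sprintf("%.2f", object@conversion)),
              if (isTRUE(object@qc$pass)) "pass" else "FAIL"))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel %s, K = %d (n = %d)\n", object@family,
              object@K, object@n))
  cat(sprintf("  loglik %.3f, m = %d, BIC %.3f\n", object@loglik,
              object@m, object@bic))
  cat("  weights:", sprintf("%.3f", object@weights), "\n")
})
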