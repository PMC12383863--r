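#' Accessors for cpgmix S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `cpgPositions()` returns the 0-based CpG cytosine offsets of an amplicon,
#' `refSequence()` its sequence, `methPct()` the per-CpG methylation
#' percentages of a profile, `coverage()` its per-CpG coverage (sum of the
#' four base counts), `baseCounts()` the A/C/G/T count matrix,
#' `conversionPct()` the amplicon-level conversion efficiency, and
#' `bicValue()` / `logLik()`-style accessors the fit summaries of a
#' [MixtureModel-class].
#'
#' @param x an object of the documented class.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' @rdname accessors
#' @export
setMethod("cpgPositions", "AmpliconReference", function(x) x@cpgPositions)

#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname accessors
#' @export
setMethod("refSequence", "AmpliconReference", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("methPct", function(x) standardGeneric("methPct"))

#' @rdname accessors
#' @export
setMethod("methPct", "MethylationProfile", function(x) x@methPct)

#' @rdname accessors
#' @export
setGeneric("baseCounts", function(x) standardGeneric("baseCounts"))

#' @rdname accessors
#' @export
setMethod("baseCounts", "MethylationProfile", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setMethod("coverage", "MethylationProfile", function(x) rowSums(x@counts))

#' @rdname accessors
#' @export
setGeneric("conversionPct", function(x) standardGeneric("conversionPct"))

#' @rdname accessors
#' @export
setMethod("conversionPct", "MethylationProfile", function(x) x@conversion)

#' @rdname accessors
#' @export
setGeneric("qcStatus", function(x) standardGeneric("qcStatus"))

#' @rdname accessors
#' @export
setMethod("qcStatus", "MethylationProfile", function(x) x@qc)

#' @rdname accessors
#' @export
setGeneric("bicValue", function(x) standardGeneric("bicValue"))

#' @rdname accessors
#' @export
setMethod("bicValue", "MixtureModel", function(x) x@bic)

#' @rdname accessors
#' @export
setGeneric("logLikValue", function(x) standardGeneric("logLikValue"))

#' @rdname accessors
#' @export
setMethod("logLikValue", "MixtureModel", function(x) x@loglik)

#' @rdname accessors
#' @export
setGeneric("mixWeights", function(x) standardGeneric("mixWeights"))

#' @rdname accessors
#' @export
setMethod("mixWeights", "MixtureModel", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("componentMeans", function(x) standardGeneric("componentMeans"))

#' @rdname accessors
#' @export
setMethod("componentMeans", "MixtureModel", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("componentVariances",
           function(x) standardGeneric("componentVariances"))

#' @rdname accessors
#' @export
setMethod("componentVariances", "MixtureModel", function(x) x@variances)
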