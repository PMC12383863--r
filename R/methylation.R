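# Per-pair base collection honouring the overlap rule: each reference
# position contributes once per pair, mate 1 winning on positions both
# mates cover, so one template molecule is never double-counted.
pairBasesAt <- function(aln) {
  p1 <- aln$aln1$ref_pos; b1 <- strsplit(aln$aln1$read_bases, "")[[1]]
  p2 <- aln$aln2$ref_pos; b2 <- strsplit(aln$aln2$read_bases, "")[[1]]
  keep2 <- !(p2 %in% p1)
  list(pos = c(p1, p2[keep2]), base = c(b1, b2[keep2]))
}

tallyBasesAt <- function(alignments, positions) {
  counts <- matrix(0L, nrow = length(positions), ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (!length(positions)) return(counts)
  for (aln in alignments) {
    pb <- pairBasesAt(aln)
    hit <- match(pb$pos, positions)
    ok <- !is.na(hit) & pb$base %in% colnames(counts)
    if (any(ok)) {
      idx <- cbind(hit[ok], match(pb$base[ok], colnames(counts)))
      for (r in seq_len(nrow(idx)))
        counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
    }
  }
  counts
}

#' Tally the four base frequencies at each CpG site
#'
#' For every CpG cytosine position of the reference, counts the read base
#' aligned to it across all retained pair alignments. Overlapping mates of
#' a pair contribute once per position (mate 1 wins on disagreement);
#' positions under deletions are skipped.
#'
#' @param alignments list of `"PairAlignment"` objects targeting `ref`
#'   (e.g. `alignPairSet(...)$alignments`).
#' @param ref the [AmpliconReference-class] they target.
#' @return integer matrix, one row per CpG site, columns A/C/G/T; row sums
#'   are the per-site coverage.
#' @export
tallyCpgBases <- function(alignments, ref) {
  stopifnot(is(ref, "AmpliconReference"))
  for (a in alignments)
    if (!identical(a$reference, ref@name))
      stop("all alignments must target the given reference")
  tallyBasesAt(alignments, cpgPositions(ref))
}

#' Methylation percentages from per-CpG base counts
#'
#' Per site, methylation percent is `100 * C / (C + T)`: A/G observations
#' are excluded from the denominator (they reflect sequencing error or
#' misalignment, not conversion state) but remain visible in the counts.
#' Sites with `C + T = 0` are undefined and reported as NA, never as 0.
#'
#' @param counts base-count matrix from [tallyCpgBases()].
#' @return numeric vector of percentages (NA where undefined).
#' @examples
#' m <- matrix(c(0L, 3L, 0L, 7L), 1, dimnames = list(NULL, c("A","C","G","T")))
#' methylationPercentages(m)  # 30
#' @export
methylationPercentages <- function(counts) {
  stopifnot(identical(colnames(counts), c("A", "C", "G", "T")))
  denom <- counts[, "C"] + counts[, "T"]
  ifelse(denom > 0, 100 * counts[, "C"] / denom, NA_real_)
}

#' Bisulfite conversion efficiency from non-CpG cytosines
#'
#' Pooled over every non-CpG cytosine position of the reference:
#' `100 * T / (C + T)`. Complete conversion reads every such cytosine as T,
#' so values near 100 indicate successful bisulfite treatment.
#'
#' @param alignments retained `"PairAlignment"` list targeting `ref`.
#' @param ref the [AmpliconReference-class].
#' @return conversion efficiency as a percentage.
#' @export
conversionEfficiency <- function(alignments, ref) {
  stopifnot(is(ref, "AmpliconReference"))
  chars <- strsplit(refSequence(ref), "")[[1]]
  pos <- setdiff(which(chars == "C") - 1L, cpgPositions(ref))
  if (!length(pos))
    stop("not computable: reference has no non-CpG cytosine")
  counts <- tallyBasesAt(alignments, pos)
  ct <- sum(counts[, "C"]) + sum(counts[, "T"])
  if (ct == 0)
    stop("not computable: no coverage at non-CpG cytosines")
  100 * sum(counts[, "T"]) / ct
}

#' QC a methylation profile on coverage and conversion
#'
#' A sample x amplicon profile fails if any analyzed CpG has coverage below
#' `minCoverage` (default 100x) or if the conversion efficiency is not
#' strictly greater than `minConversion` (default 99%). Reasons enumerate
#' the failing sites.
#'
#' @param profile a [MethylationProfile-class].
#' @param minCoverage minimum per-CpG coverage (default 100).
#' @param minConversion conversion threshold in percent; pass requires a
#'   strictly greater value (default 99).
#' @param cpgMask optional logical vector selecting the CpGs that count as
#'   analyzed (default: all).
#' @return list with `pass` (logical) and `reasons` (character vector).
#' @export
qcSample <- function(profile, minCoverage = 100, minConversion = 99,
                     cpgMask = NULL) {
  stopifnot(is(profile, "MethylationProfile"))
  cov <- rowSums(profile@counts)
  if (is.null(cpgMask)) cpgMask <- rep(TRUE, length(cov))
  reasons <- character(0)
  low <- which(cpgMask & cov < minCoverage)
  if (length(low))
    reasons <- c(reasons, sprintf("coverage %dx < %dx at CpG %d",
                                  cov[low], as.integer(minCoverage), low))
  if (is.na(profile@conversion)) {
    reasons <- c(reasons, "conversion efficiency not computable")
  } else if (profile@conversion <= minConversion) {
    reasons <- c(reasons,
                 sprintf("conversion %.3f%% <= %.3f%%", profile@conversion,
                         minConversion))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Call per-CpG methylation for one sample's read pairs
#'
#' Runs the full quantification for one sample: coherent-pair alignment
#' against the reference panel, per-CpG base tallying, C/(C+T) methylation
#' percentages, conversion efficiency from non-CpG cytosines, and QC. One
#' profile is produced per reference that received at least one retained
#' pair.
#'
#' @param rps a [ReadPairSet-class].
#' @param refs list of [AmpliconReference-class] objects.
#' @param sample sample identifier recorded in the profiles.
#' @param scoring a [bisulfiteScoring()] object.
#' @param minCoverage,minConversion QC thresholds, see [qcSample()].
#' @return named list of [MethylationProfile-class] objects (one per
#'   reference with retained pairs), with attribute `"rejected"` carrying
#'   the rejection log.
#' @export
callSampleMethylation <- function(rps, refs, sample = "sample1",
                                  scoring = bisulfiteScoring(),
                                  minCoverage = 100, minConversion = 99) {
  res <- alignPairSet(rps, refs, scoring)
  byRef <- split(res$alignments,
                 vapply(res$alignments, function(a) a$reference, ""))
  profiles <- lapply(names(byRef), function(nm) {
    ref <- refs[[match(nm, vapply(refs, function(r) r@name, ""))]]
    counts <- tallyCpgBases(byRef[[nm]], ref)
    conv <- tryCatch(conversionEfficiency(byRef[[nm]], ref),
                     error = function(e) NA_real_)
    prof <- new("MethylationProfile", sample = sample, amplicon = nm,
                counts = counts,
                methPct = methylationPercentages(counts),
                conversion = conv,
                qc = list(pass = NA, reasons = character(0)))
    prof@qc <- qcSample(prof, minCoverage, minConversion)
    prof
  })
  names(profiles) <- names(byRef)
  attr(profiles, "rejected") <- res$rejected
  profiles
}

#' Flatten methylation profiles to a per-CpG table
#'
#' @param profiles list of [MethylationProfile-class] objects.
#' @param refs optional list of [AmpliconReference-class] used to attach
#'   genomic positions of the CpG cytosines (1-based).
#' @return data.frame with columns sample, amplicon, cpg_index,
#'   genomic_pos, A, C, G, T, coverage, meth_pct, qc_pass.
#' @export
methylationTable <- function(profiles, refs = NULL) {
  refNames <- if (!is.null(refs))
    vapply(refs, function(r) r@name, "") else character(0)
  rows <- lapply(profiles, function(p) {
    n <- nrow(p@counts)
    gpos <- rep(NA_real_, n)
    if (!is.null(refs)) {
      ref <- refs[[match(p@amplicon, refNames)]]
      gpos <- ref@start + cpgPositions(ref)
    }
    data.frame(sample = p@sample, amplicon = p@amplicon,
               cpg_index = seq_len(n), genomic_pos = gpos,
               A = p@counts[, "A"], C = p@counts[, "C"],
               G = p@counts[, "G"], T = p@counts[, "T"],
               coverage = rowSums(p@counts), meth_pct = p@methPct,
               qc_pass = isTRUE(p@qc$pass), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
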