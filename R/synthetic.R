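#' Generate a synthetic amplicon reference sequence
#'
#' Builds a random A/C/G/T sequence containing exactly `nCpg` CG
#' dinucleotides at recorded positions and no others, at approximately the
#' requested GC fraction. CpG cytosine positions are drawn uniformly among
#' all placements with pairwise spacing of at least 2 bp. The result is a
#' synthetic stand-in for a real target region: genomic coordinates are
#' attached as metadata only.
#'
#' @param length sequence length in bp.
#' @param nCpg number of CpG sites; requires `length >= 2 * nCpg`.
#' @param gcFrac target GC fraction in `[0, 1]`.
#' @param seed integer seed; output is deterministic given the seed.
#' @param name,chrom,start,end metadata labels; `end` defaults to
#'   `start + length - 1` (1-based inclusive).
#' @return an [AmpliconReference-class] object.
#' @examples
#' ref <- makeAmpliconReference(168, 11, seed = 1, name = "BDNF")
#' length(cpgPositions(ref))
#' @export
makeAmpliconReference <- function(length, nCpg, gcFrac = 0.5, seed = 1L,
                                  name = "amplicon", chrom = "chrUn",
                                  start = 1L, end = start + length - 1L) {
  if (nCpg < 0 || length < 2 * nCpg)
    stop("invalid parameters: need length >= 2 * nCpg and nCpg >= 0")
  if (gcFrac < 0 || gcFrac > 1) stop("invalid parameters: gcFrac in [0,1]")
  withr::with_seed(as.integer(seed), {
    bases <- c("A", "C", "G", "T")
    probs <- c((1 - gcFrac) / 2, gcFrac / 2, gcFrac / 2, (1 - gcFrac) / 2)
    chars <- sample(bases, length, replace = TRUE, prob = probs)
    pos <- integer(0)
    if (nCpg > 0) {
      # spacing >= 2: sample strictly increasing q, map p_i = q_i + (i - 1)
      q <- sort(sample.int(length - nCpg, nCpg)) - 1L
      pos <- q + seq_len(nCpg) - 1L
      chars[pos + 1L] <- "C"
      chars[pos + 2L] <- "G"
    }
    # break any incidental CG: its G can be replaced without creating a new CG
    isC <- chars == "C"
    isG <- chars == "G"
    cg <- which(isC[-length] & isG[-1]) - 1L   # 0-based
    stray <- setdiff(cg, pos)
    if (length(stray))
      chars[stray + 2L] <- sample(c("A", "T"), length(stray), replace = TRUE)
    new("AmpliconReference", name = name, chrom = chrom,
        start = as.numeric(start), end = as.numeric(end),
        sequence = paste(chars, collapse = ""),
        cpgPositions = as.integer(pos))
  })
}

# reverse complement of a plain base string; hot path, so no S4 round-trip
revcompChar <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Simulate bisulfite-converted paired-end amplicon reads
#'
#' Emulates PCR amplification of bisulfite-treated DNA followed by
#' sequencing. Per template molecule, each CpG cytosine is drawn methylated
#' with probability `meth[i]` (and then stays C); unmethylated CpG
#' cytosines and every non-CpG cytosine are converted C->T with probability
#' `conversionEff`. Only the converted original-top strand is simulated:
#' mate 1 reads the first `readLen` bases of the converted template, mate 2
#' is the reverse complement of its last `readLen` bases, so mates overlap
#' the whole amplicon at the default read length. Uniform substitution
#' errors are applied at `errorRate` per sequenced base; base qualities are
#' constant Phred 40.
#'
#' @param ref an [AmpliconReference-class].
#' @param meth per-CpG methylation probabilities, length
#'   `length(cpgPositions(ref))`.
#' @param conversionEff bisulfite conversion probability per unmethylated
#'   cytosine, in `[0, 1]`.
#' @param errorRate per-base substitution error probability, in `[0, 1]`.
#' @param nPairs number of read pairs.
#' @param readLen read length in bp; defaults to the amplicon length and
#'   may not exceed it.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [ReadPairSet-class] whose `truth` table records each
#'   molecule's drawn CpG methylation states.
#' @examples
#' ref <- makeAmpliconReference(60, 3, seed = 2)
#' rps <- simulateBisulfitePairs(ref, meth = c(1, 0, 0.5), nPairs = 5,
#'                               seed = 3)
#' rps
#' @export
simulateBisulfitePairs <- function(ref, meth, conversionEff = 1,
                                   errorRate = 0, nPairs = 100L,
                                   readLen = NULL, seed = 1L) {
  stopifnot(is(ref, "AmpliconReference"))
  pos <- cpgPositions(ref)
  if (length(meth) != length(pos))
    stop("meth must have one probability per CpG site")
  if (any(meth < 0 | meth > 1) || conversionEff < 0 || conversionEff > 1 ||
      errorRate < 0 || errorRate > 1)
    stop("probabilities must lie in [0, 1]")
  L <- nchar(refSequence(ref))
  if (is.null(readLen)) readLen <- L
  if (readLen > L) stop("invalid parameters: readLen exceeds amplicon length")
  if (readLen < 1L) stop("invalid parameters: readLen must be >= 1")
  nPairs <- as.integer(nPairs)

  withr::with_seed(as.integer(seed), {
    chars <- strsplit(refSequence(ref), "")[[1]]
    tmpl <- matrix(chars, nrow = nPairs, ncol = L, byrow = TRUE)
    k <- length(pos)
    state <- matrix(FALSE, nrow = nPairs, ncol = k)
    if (nPairs > 0 && k > 0) {
      state <- matrix(runif(nPairs * k), nPairs, k) <
        matrix(meth, nPairs, k, byrow = TRUE)
      conv <- matrix(runif(nPairs * k), nPairs, k) < conversionEff
      for (j in seq_len(k))
        tmpl[!state[, j] & conv[, j], pos[j] + 1L] <- "T"
    }
    nonCpgC <- setdiff(which(chars == "C") - 1L, pos)
    if (nPairs > 0) for (p in nonCpgC) {
      conv <- runif(nPairs) < conversionEff
      tmpl[conv, p + 1L] <- "T"
    }

    start2 <- L - readLen
    m1 <- tmpl[, seq_len(readLen), drop = FALSE]
    m2 <- tmpl[, start2 + seq_len(readLen), drop = FALSE]
    # reverse complement mate 2
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    m2 <- matrix(comp[m2], nrow = nPairs)[, rev(seq_len(readLen)),
                                          drop = FALSE]
    addErrors <- function(m) {
      if (errorRate <= 0 || !length(m)) return(m)
      idx <- which(runif(length(m)) < errorRate)
      if (length(idx)) {
        bases <- c("A", "C", "G", "T")
        shift <- sample.int(3L, length(idx), replace = TRUE)
        m[idx] <- bases[(match(m[idx], bases) - 1L + shift) %% 4L + 1L]
      }
      m
    }
    m1 <- addErrors(m1); m2 <- addErrors(m2)
    collapse <- function(m)
      if (nrow(m)) apply(m, 1L, paste, collapse = "") else character(0)
    qual <- strrep(rawToChar(as.raw(40L + 33L)), readLen)
    truth <- data.frame(pair = seq_len(nPairs),
                        start1 = rep(0L, nPairs),
                        start2 = rep(as.integer(start2), nPairs))
    if (k > 0)
      for (j in seq_len(k)) truth[[paste0("cpg", j)]] <- state[, j]
    new("ReadPairSet",
        mate1 = collapse(m1), mate2 = collapse(m2),
        qual1 = rep(qual, nPairs), qual2 = rep(qual, nPairs),
        reference = ref@name, truth = truth)
  })
}

#' Generate a synthetic cohort from a mixture specification
#'
#' Draws component labels from the mixing weights, then per component:
#' bivariate (internalizing, externalizing) T-scores from independent
#' normals, Bernoulli stressful-life-event and perinatal-risk indicators at
#' the component prevalences, demographics (age, sex, SES), and one
#' methylation percentage per CpG from a normal truncated by clipping to
#' `[0, 100]`. The true component labels are returned separately.
#'
#' @param spec a `"CohortSpec"`, see [cohortSpec()] / [defaultCohortSpec()].
#' @param seed integer seed; the table is deterministic given the seed.
#' @return list with `table` (data.frame, one row per subject) and `labels`
#'   (integer true component per subject; component 1 is the first row of
#'   `spec$means`).
#' @examples
#' cohort <- generateCohort(defaultCohortSpec(n = 20), seed = 1)
#' table(cohort$labels)
#' @export
generateCohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n
  withr::with_seed(as.integer(seed), {
    K <- length(spec$mixing)
    lab <- if (n > 0)
      sample.int(K, n, replace = TRUE, prob = spec$mixing) else integer(0)
    tab <- data.frame(
      subject = sprintf("S%04d", seq_len(n)),
      age = rnorm(n, spec$ageMean[lab], spec$ageSd[lab]),
      sex = ifelse(runif(n) < spec$maleProb[lab], "M", "F"),
      ses = rnorm(n, spec$sesMean[lab], spec$sesSd[lab]),
      internalizing = rnorm(n, spec$means[lab, 1], spec$sds[lab, 1]),
      externalizing = rnorm(n, spec$means[lab, 2], spec$sds[lab, 2]),
      sle = as.integer(runif(n) < spec$slePrevalence[lab]),
      perinatal_risk = as.integer(runif(n) < spec$perinatalPrevalence[lab]),
      stringsAsFactors = FALSE
    )
    if (n == 0) tab$sex <- character(0)
    if (!is.null(spec$methylation)) {
      mp <- spec$methylation
      for (i in seq_len(nrow(mp))) {
        mu <- c(mp$mean_low[i], mp$mean_high[i])[lab]
        sg <- c(mp$sd_low[i], mp$sd_high[i])[lab]
        tab[[mp$variable[i]]] <- pmin(100, pmax(0, rnorm(n, mu, sg)))
      }
    }
    list(table = tab, labels = lab)
  })
}

#' Mask cohort cells at random to emulate missing data
#'
#' Each non-identifier cell is set to NA independently with probability
#' `rate`, for exercising the cleaning and imputation stage downstream.
#'
#' @param table cohort data.frame; the `subject` column is never masked.
#' @param rate per-cell missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @param exclude column names never masked (default `"subject"`).
#' @return the table with NAs injected.
#' @export
injectMissingness <- function(table, rate, seed = 1L, exclude = "subject") {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  cols <- setdiff(names(table), exclude)
  withr::with_seed(as.integer(seed), {
    for (cl in cols) {
      mask <- runif(nrow(table)) < rate
      table[[cl]][mask] <- NA
    }
  })
  table
}

#' Write and read amplicon references and simulated reads
#'
#' `writeAmpliconReference()` emits a FASTA file plus a JSON sidecar
#' carrying the 0-based CpG positions and genomic metadata;
#' `readAmpliconReference()` restores the object. `writeFastqPair()` writes
#' the two mates of a [ReadPairSet-class] as Phred+33 FASTQ files (and the
#' truth table as JSON when `truthPath` is given); `readFastqPair()` reads
#' two FASTQ files back into a [ReadPairSet-class] with an empty truth
#' table unless `truthPath` is supplied.
#'
#' @param ref an [AmpliconReference-class].
#' @param fastaPath,jsonPath FASTA and JSON sidecar paths.
#' @param rps a [ReadPairSet-class].
#' @param prefix output prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written.
#' @param truthPath optional JSON path for the ground-truth table.
#' @return `writeAmpliconReference()` and `writeFastqPair()` return the
#'   written paths invisibly; the readers return the restored object.
#' @name amplicon-io
NULL

#' @rdname amplicon-io
#' @export
writeAmpliconReference <- function(ref, fastaPath, jsonPath) {
  seqs <- Biostrings::DNAStringSet(setNames(refSequence(ref), ref@name))
  Biostrings::writeXStringSet(seqs, fastaPath)
  jsonlite::write_json(
    list(name = ref@name, chrom = ref@chrom, start = ref@start,
         end = ref@end, cpg_positions = cpgPositions(ref)),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(fastaPath, jsonPath))
}

#' @rdname amplicon-io
#' @export
readAmpliconReference <- function(fastaPath, jsonPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  new("AmpliconReference", name = meta$name, chrom = meta$chrom,
      start = meta$start, end = meta$end,
      sequence = as.character(seqs[[1]]),
      cpgPositions = as.integer(meta$cpg_positions))
}

#' @rdname amplicon-io
#' @export
writeFastqPair <- function(rps, prefix, truthPath = NULL) {
  stopifnot(is(rps, "ReadPairSet"))
  ids <- sprintf("%s_pair%05d", rps@reference, seq_along(rps@mate1))
  # the quality metadata column is serialized in the FASTQ itself, so the
  # "metadata columns dropped" warning is expected, not a data loss
  wrt <- function(seqs, quals, path) suppressWarnings({
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(x, path)
  })
  p1 <- paste0(prefix, "_R1.fastq"); p2 <- paste0(prefix, "_R2.fastq")
  wrt(rps@mate1, rps@qual1, p1)
  wrt(rps@mate2, rps@qual2, p2)
  out <- c(p1, p2)
  if (!is.null(truthPath)) {
    jsonlite::write_json(rps@truth, truthPath, digits = NA)
    out <- c(out, truthPath)
  }
  invisible(out)
}

#' @rdname amplicon-io
#' @export
readFastqPair <- function(prefix, reference = "unknown", truthPath = NULL) {
  rd <- function(path) {
    # qualities travel in the FASTQ records; the dropped-metadata warning
    # from the internal StringSet conversion carries no information here
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)))
  }
  r1 <- rd(paste0(prefix, "_R1.fastq"))
  r2 <- rd(paste0(prefix, "_R2.fastq"))
  truth <- if (!is.null(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE)
  else data.frame(pair = seq_along(r1$seq))
  new("ReadPairSet", mate1 = unname(r1$seq), mate2 = unname(r2$seq),
      qual1 = unname(r1$qual), qual2 = unname(r2$qual),
      reference = reference, truth = truth)
}
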