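#' Bisulfite-aware alignment scoring parameters
#'
#' Affine-gap local-alignment scoring with the bisulfite rule: a read T
#' opposite a reference C scores as a match, because bisulfite conversion
#' reads unmethylated cytosines as thymines on the sequenced strand
#' (reference C vs read C remains an ordinary match). A gap of length L
#' costs `gapOpen + L * gapExtend`. `minScoreFrac` sets the retention
#' threshold: a mate is kept only if its best local score reaches
#' `minScoreFrac * readLen * match`, which suppresses spurious short local
#' hits that would otherwise form coherent pairs by chance.
#'
#' @param match positive match score (default 2).
#' @param mismatch mismatch penalty, `<= 0` (default -3).
#' @param gapOpen gap-opening penalty, `<= 0` (default -5).
#' @param gapExtend gap-extension penalty, with
#'   `gapOpen <= gapExtend <= 0` (default -2).
#' @param bisulfite apply the read-T/reference-C match rule (default TRUE).
#' @param minScoreFrac retention threshold as a fraction of the maximum
#'   attainable score (default 0.6).
#' @return a validated list of class `"BisulfiteScoring"`.
#' @export
bisulfiteScoring <- function(match = 2L, mismatch = -3L, gapOpen = -5L,
                             gapExtend = -2L, bisulfite = TRUE,
                             minScoreFrac = 0.6) {
  if (match <= 0) stop("match score must be positive")
  if (mismatch > 0 || gapOpen > 0 || gapExtend > 0)
    stop("penalties must be <= 0")
  if (gapOpen > gapExtend)
    stop("require gapOpen <= gapExtend <= 0 (opening costs more)")
  if (minScoreFrac < 0 || minScoreFrac > 1)
    stop("minScoreFrac must lie in [0, 1]")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend),
                 bisulfite = isTRUE(bisulfite),
                 minScoreFrac = minScoreFrac),
            class = "BisulfiteScoring")
}

#' Local alignment of a single read against one reference
#'
#' Affine-gap Smith-Waterman with optional bisulfite-aware scoring.
#' Intervals are 0-based half-open on both sequences.
#'
#' @param read read sequence (A/C/G/T string), in reference orientation.
#' @param ref an [AmpliconReference-class] or plain sequence string.
#' @param scoring a [bisulfiteScoring()] object.
#' @return list with `score`, `read_start`, `read_end`, `ref_start`,
#'   `ref_end`, `cigar`, `ref_pos` (0-based reference positions of aligned
#'   columns) and `read_bases` (the read base at each of those positions).
#' @export
alignReadToRef <- function(read, ref, scoring = bisulfiteScoring()) {
  seqc <- if (is(ref, "AmpliconReference")) refSequence(ref) else ref
  stopifnot(nzchar(read), nzchar(seqc))
  .sw_align_cpp(read, seqc, scoring$match, scoring$mismatch,
                scoring$gapOpen, scoring$gapExtend, scoring$bisulfite)
}

#' Align a read pair to a panel of references with coherent-pair retention
#'
#' Each mate is independently locally aligned against every reference
#' (mate 2 is reverse-complemented first, since it reads the opposite
#' orientation of the converted strand). A pair is retained only if both
#' mates' best alignments hit the same reference; ties between references
#' with equal best score are broken toward the lowest reference index.
#' Mates must also reach the minimum retention score; otherwise the pair is
#' rejected with a reason code.
#'
#' @param mate1,mate2 read sequences as sequenced.
#' @param refs list of [AmpliconReference-class] objects.
#' @param scoring a [bisulfiteScoring()] object.
#' @return on retention, a list of class `"PairAlignment"` with `reference`
#'   (name), `refIndex`, and per-mate alignments `aln1`, `aln2` (mate 2
#'   reported in reference coordinates); on rejection, a list of class
#'   `"PairRejection"` with `reason` one of `"discordant"`,
#'   `"low_score"`.
#' @export
bisulfiteAlignPair <- function(mate1, mate2, refs,
                               scoring = bisulfiteScoring()) {
  stopifnot(length(refs) >= 1)
  m2rc <- revcompChar(mate2)
  alnBest <- function(read) {
    best <- NULL; bestIdx <- NA_integer_
    for (i in seq_along(refs)) {
      a <- alignReadToRef(read, refs[[i]], scoring)
      if (is.null(best) || a$score > best$score) { best <- a; bestIdx <- i }
    }
    list(aln = best, idx = bestIdx)
  }
  b1 <- alnBest(mate1)
  b2 <- alnBest(m2rc)
  if (b1$idx != b2$idx)
    return(structure(list(reason = "discordant",
                          idx1 = b1$idx, idx2 = b2$idx),
                     class = "PairRejection"))
  minScore <- function(read)
    scoring$minScoreFrac * nchar(read) * scoring$match
  if (b1$aln$score < minScore(mate1) || b2$aln$score < minScore(mate2))
    return(structure(list(reason = "low_score",
                          score1 = b1$aln$score, score2 = b2$aln$score),
                     class = "PairRejection"))
  structure(list(reference = refs[[b1$idx]]@name, refIndex = b1$idx,
                 aln1 = b1$aln, aln2 = b2$aln),
            class = "PairAlignment")
}

#' Align every pair of a read set, keeping retained alignments
#'
#' Convenience wrapper over [bisulfiteAlignPair()] for a whole
#' [ReadPairSet-class]; returns retained `"PairAlignment"` objects plus a
#' rejection log.
#'
#' @param rps a [ReadPairSet-class].
#' @param refs list of [AmpliconReference-class] objects.
#' @param scoring a [bisulfiteScoring()] object.
#' @return list with `alignments` (list of `"PairAlignment"`), `rejected`
#'   (data.frame: pair index, reason).
#' @export
alignPairSet <- function(rps, refs, scoring = bisulfiteScoring()) {
  stopifnot(is(rps, "ReadPairSet"))
  alns <- vector("list", length(rps@mate1))
  rej <- list()
  kept <- logical(length(alns))
  for (i in seq_along(alns)) {
    r <- bisulfiteAlignPair(rps@mate1[i], rps@mate2[i], refs, scoring)
    if (inherits(r, "PairAlignment")) {
      alns[[i]] <- r; kept[i] <- TRUE
    } else {
      rej[[length(rej) + 1L]] <- data.frame(pair = i, reason = r$reason)
    }
  }
  list(alignments = alns[kept],
       keptPairs = which(kept),
       rejected = if (length(rej)) do.call(rbind, rej)
                  else data.frame(pair = integer(0), reason = character(0)))
}
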