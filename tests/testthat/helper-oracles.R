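# Independent brute-force oracles used across the suite. They deliberately
# share no code with the package implementation.

# Score-only affine-gap local alignment by direct dynamic programming over
# three matrices; a gap of length L costs open + L * ext. Bisulfite rule:
# read T opposite reference C scores as a match.
oracleSwScore <- function(read, ref, match = 2, mismatch = -3,
                          open = -5, ext = -2, bisulfite = TRUE) {
  r <- strsplit(read, "")[[1]]; s <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(s)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] + open + ext, E[i + 1, j] + ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] + open + ext, F[i, j + 1] + ext)
    sc <- if (r[i] == s[j] || (bisulfite && s[j] == "C" && r[i] == "T"))
      match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + sc,
                           E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# Linear scan for CG dinucleotides, 0-based positions of the C.
oracleCgScan <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits - 1L)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Raw sample of length n with exactly the requested mean and SD.
momentMatched <- function(n, mean, sd, seed = 1) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    as.numeric(mean + sd * scale(z))
  })
}

# T-score-only cohort spec under the reference study conditions
tscoreSpec <- function(n = 200) {
  cohortSpec(n = n, mixing = c(0.51, 0.49),
             means = rbind(c(51.0, 47.1), c(63.7, 58.9)),
             sds = rbind(c(6.91, 6.51), c(5.97, 7.10)))
}
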