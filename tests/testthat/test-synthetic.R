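test_that("generated references carry exactly the requested CpGs", {
  ref <- makeAmpliconReference(168, 11, seed = 1, name = "BDNF")
  expect_length(cpgPositions(ref), 11)
  expect_identical(oracleCgScan(refSequence(ref)), cpgPositions(ref))

  # property over random parameters: the recorded positions are exactly
  # the CG dinucleotides an independent scan finds
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(30:300, 1)
      k <- sample(0:floor(n / 3), 1)
      gc <- runif(1, 0.2, 0.8)
      r <- makeAmpliconReference(n, k, gcFrac = gc, seed = i)
      expect_identical(oracleCgScan(refSequence(r)), cpgPositions(r))
      expect_length(cpgPositions(r), k)
    }
  })
  expect_identical(cpgPositions(makeAmpliconReference(50, 0, seed = 3)),
                   integer(0))
  expect_error(makeAmpliconReference(10, 8, seed = 1), "invalid")
  # determinism
  expect_identical(refSequence(makeAmpliconReference(80, 5, seed = 7)),
                   refSequence(makeAmpliconReference(80, 5, seed = 7)))
})

test_that("bisulfite read simulation follows the conversion model", {
  ref <- makeAmpliconReference(80, 4, seed = 5, name = "A")
  chars <- strsplit(refSequence(ref), "")[[1]]
  pos <- cpgPositions(ref)

  # fully methylated, perfect conversion, no errors: CpG C stays C,
  # every non-CpG C reads T on mate 1
  rps <- simulateBisulfitePairs(ref, meth = rep(1, 4), conversionEff = 1,
                                errorRate = 0, nPairs = 5, seed = 1)
  m1 <- strsplit(rps@mate1[1], "")[[1]]
  expect_true(all(m1[pos + 1] == "C"))
  nonCpgC <- setdiff(which(chars == "C") - 1L, pos)
  expect_true(all(m1[nonCpgC + 1] == "T"))

  # fully unmethylated: every original C reads T
  rps0 <- simulateBisulfitePairs(ref, meth = rep(0, 4), conversionEff = 1,
                                 errorRate = 0, nPairs = 5, seed = 1)
  m1 <- strsplit(rps0@mate1[1], "")[[1]]
  expect_true(all(m1[which(chars == "C")] == "T"))

  # mate 2 is the reverse complement of the converted template end
  rc <- strsplit(rps0@mate2[1], "")[[1]]
  expect_identical(paste(rev(chartr("ACGT", "TGCA", rc)), collapse = ""),
                   rps0@mate1[1])

  expect_error(simulateBisulfitePairs(ref, rep(0.5, 4), readLen = 81),
               "invalid")
  expect_error(simulateBisulfitePairs(ref, rep(0.5, 3)), "per CpG")
})

test_that("drawn methylation fractions follow the binomial oracle", {
  ref <- makeAmpliconReference(60, 1, seed = 11)
  n <- 5000
  rps <- simulateBisulfitePairs(ref, meth = 0.40, conversionEff = 1,
                                errorRate = 0, nPairs = n, seed = 2)
  frac <- mean(rps@truth$cpg1)
  tol <- 3 * sqrt(0.40 * 0.60 / n)
  expect_lt(abs(frac - 0.40), tol)
  # and the C fraction read at the CpG equals the drawn fraction
  at <- cpgPositions(ref) + 1
  baseAt <- substring(rps@mate1, at, at)
  expect_equal(mean(baseAt == "C"), frac)
})

test_that("identical seeds give byte-identical FASTQ", {
  ref <- makeAmpliconReference(70, 3, seed = 4)
  d <- withr::local_tempdir()
  for (run in 1:2) {
    rps <- simulateBisulfitePairs(ref, rep(0.5, 3), errorRate = 0.01,
                                  nPairs = 25, seed = 99)
    writeFastqPair(rps, file.path(d, paste0("run", run)))
  }
  for (mate in c("_R1.fastq", "_R2.fastq"))
    expect_identical(readLines(file.path(d, paste0("run1", mate))),
                     readLines(file.path(d, paste0("run2", mate))))
  # and the round trip restores the reads
  back <- readFastqPair(file.path(d, "run1"), reference = ref@name)
  rps <- simulateBisulfitePairs(ref, rep(0.5, 3), errorRate = 0.01,
                                nPairs = 25, seed = 99)
  expect_identical(back@mate1, rps@mate1)
  expect_identical(back@mate2, rps@mate2)
})

test_that("reference FASTA/JSON round trip preserves the object", {
  ref <- makeAmpliconReference(90, 6, seed = 8, name = "IGF2",
                               chrom = "chr11", start = 2169373)
  d <- withr::local_tempdir()
  writeAmpliconReference(ref, file.path(d, "r.fasta"), file.path(d, "r.json"))
  back <- readAmpliconReference(file.path(d, "r.fasta"),
                                file.path(d, "r.json"))
  expect_identical(refSequence(back), refSequence(ref))
  expect_identical(cpgPositions(back), cpgPositions(ref))
  expect_identical(back@chrom, "chr11")
})

test_that("cohort generation matches its generating parameters", {
  spec <- defaultCohortSpec(n = 2000)
  ch <- generateCohort(spec, seed = 31)
  tab <- ch$table; lab <- ch$labels
  expect_equal(nrow(tab), 2000)
  # component-wise T-score means within 3 SE of the generating means
  for (k in 1:2) {
    nk <- sum(lab == k)
    for (j in 1:2) {
      v <- tab[lab == k, c("internalizing", "externalizing")[j]]
      expect_lt(abs(mean(v) - spec$means[k, j]),
                3 * spec$sds[k, j] / sqrt(nk))
    }
    # risk prevalences within 3 binomial SDs
    p <- spec$perinatalPrevalence[k]
    expect_lt(abs(mean(tab$perinatal_risk[lab == k]) - p),
              3 * sqrt(p * (1 - p) / nk))
  }
  # methylation stays in [0, 100]
  mvars <- grep("_CpG", names(tab), value = TRUE)
  expect_length(mvars, 54)
  expect_true(all(as.matrix(tab[, mvars]) >= 0))
  expect_true(all(as.matrix(tab[, mvars]) <= 100))
  # empty cohort
  empty <- generateCohort(defaultCohortSpec(n = 0), seed = 1)
  expect_equal(nrow(empty$table), 0)
})

test_that("missingness injection hits the requested rate", {
  ch <- generateCohort(defaultCohortSpec(n = 300), seed = 5)
  expect_identical(injectMissingness(ch$table, 0, seed = 1), ch$table)
  out <- injectMissingness(ch$table, 0.1, seed = 2)
  cells <- prod(dim(out[, setdiff(names(out), "subject")]))
  frac <- sum(is.na(out)) / cells
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / cells))
  expect_false(anyNA(out$subject))
  expect_error(injectMissingness(ch$table, 1), "rate")
})
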