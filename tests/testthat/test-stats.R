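test_that("cleaning removes >50%-missing subjects and imputes the rest", {
  ch <- generateCohort(defaultCohortSpec(n = 205), seed = 61)
  tab <- injectMissingness(ch$table, 0.05, seed = 62)
  # force 5 subjects over the threshold
  cols <- setdiff(names(tab), "subject")
  over <- withr::with_seed(66, {
    idx <- sample(nrow(tab), 5)
    for (i in idx)
      tab[i, sample(cols, ceiling(0.6 * length(cols)))] <- NA
    idx
  })
  # (a sixth subject exactly at 50% must be kept: threshold is strict)
  res <- cleanAndImpute(tab, maxMissing = 0.5, seed = 63)
  expect_equal(nrow(res$table), 205 - nrow(res$removed))
  expect_true(all(tab$subject[over] %in% res$removed$subject))
  expect_false(anyNA(res$table))

  # every imputed value is a member of the variable's observed support
  kept <- tab[!(tab$subject %in% res$removed$subject), ]
  for (cl in cols) {
    miss <- is.na(kept[[cl]])
    if (!any(miss)) next
    expect_true(all(res$table[[cl]][miss] %in% kept[[cl]][!miss]),
                info = cl)
  }
  # no missing data: output identical to input
  clean <- generateCohort(defaultCohortSpec(n = 20), seed = 64)$table
  expect_identical(cleanAndImpute(clean, seed = 65)$table, clean)
})

test_that("t statistics reproduce the published group summaries", {
  # Externalizing T-scores, Welch from summaries
  tw <- summaryT(102, 47.1, 6.51, 98, 58.9, 7.10, "welch")
  expect_equal(abs(tw$statistic), 12.24, tolerance = 0.001)
  # IGF2 CpG2 methylation, pooled
  tp <- summaryT(102, 39.05, 3.86, 98, 37.65, 5.29, "pooled")
  expect_equal(abs(tp$statistic), 2.14, tolerance = 0.002)
  expect_lt(abs(abs(tp$effect) - 0.30), 0.005)  # Cohen's d
  expect_equal(summaryT(30, 5, 1, 30, 5, 1)$statistic, 0)
})

test_that("summary-based and raw-sample t-tests agree on matched moments", {
  for (variant in c("welch", "pooled")) {
    x <- momentMatched(102, 47.1, 6.51, seed = 71)
    y <- momentMatched(98, 58.9, 7.10, seed = 72)
    a <- twoSampleT(x, y, variant)
    b <- summaryT(102, 47.1, 6.51, 98, 58.9, 7.10, variant)
    for (f in c("statistic", "df", "p_raw", "effect"))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-10, info = variant)
  }
  # identical samples
  z <- momentMatched(20, 10, 2, seed = 73)
  r <- twoSampleT(z, z)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)
})

test_that("Welch df never exceeds the pooled df", {
  withr::with_seed(74, {
    for (i in 1:25) {
      x <- rnorm(sample(5:50, 1), sd = runif(1, 0.5, 3))
      y <- rnorm(sample(5:50, 1), sd = runif(1, 0.5, 3))
      expect_lte(twoSampleT(x, y, "welch")$df,
                 length(x) + length(y) - 2 + 1e-9)
    }
  })
})

test_that("2x2 chi-square with Yates reproduces the perinatal-risk result", {
  # HIGH cluster 65/33 with risk present/absent, LOW cluster 47/55
  res <- chiSq2x2(65, 33, 47, 55, yates = TRUE)
  expect_lt(abs(res$statistic - 7.51), 0.005)
  expect_lt(abs(res$p_raw - 0.006), 0.0005)
  expect_lt(abs(res$effect - 0.20), 0.005)  # phi, uncorrected
  # equal proportions give 0
  expect_equal(chiSq2x2(20, 30, 40, 60, yates = FALSE)$statistic, 0)
  expect_error(chiSq2x2(0, 0, 5, 5), "degenerate")
})

test_that("Yates correction never increases the chi-square statistic", {
  withr::with_seed(75, {
    for (i in 1:1000) {
      cnt <- sample(1:50, 4, replace = TRUE)
      y <- chiSq2x2(cnt[1], cnt[2], cnt[3], cnt[4], yates = TRUE)
      u <- chiSq2x2(cnt[1], cnt[2], cnt[3], cnt[4], yates = FALSE)
      expect_lte(y$statistic, u$statistic + 1e-12)
    }
  })
})

test_that("Bonferroni adjustment caps at 1 and preserves order", {
  adj <- bonferroniAdjust(c(0.01, 0.5, 0.002), m = 5)
  expect_equal(adj$adjusted, c(0.05, 1, 0.01))
  expect_identical(adj$significant, c(FALSE, FALSE, TRUE))
  expect_equal(bonferroniAdjust(0.5, m = 3)$adjusted, 1)
  # monotone transform of the input (ties allowed where capping hits 1)
  p <- withr::with_seed(76, runif(20))
  adj <- bonferroniAdjust(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("Shapiro-Wilk wrapper matches reference values", {
  # near-perfect normality on exact standard-normal quantiles
  q <- qnorm(ppoints(50))
  expect_gt(shapiroWilk(q)$W, 0.99)
  expect_lte(shapiroWilk(q)$W, 1)
  # frozen reference values (independent implementation, Royston approx.)
  expect_equal(shapiroWilk((1:20)^1.5)$W, 0.938639, tolerance = 1e-3)
  expect_equal(shapiroWilk(c(148, 154, 158, 160, 161, 162, 166, 170, 182,
                             195, 236))$W, 0.788815, tolerance = 1e-3)
  expect_error(shapiroWilk(rep(1, 10)), "degenerate")
})

test_that("cluster characterization mirrors the study's report layout", {
  ch <- generateCohort(defaultCohortSpec(n = 300), seed = 81)
  labels <- factor(ifelse(ch$labels == 1, "LOW", "HIGH"),
                   levels = c("LOW", "HIGH"))
  rep <- characterize(ch$table, labels, bonferroniFamily = "all")
  # 3 categorical + 4 demographic/clinical + 54 methylation variables
  expect_equal(nrow(rep), 61)
  expect_true(all(c("p_raw", "p_bonferroni", "significant") %in% names(rep)))
  expect_true(all(rep$p_bonferroni >= rep$p_raw, na.rm = TRUE))
  # the clinical separation survives Bonferroni across all comparisons
  clin <- rep[rep$variable %in% c("internalizing", "externalizing"), ]
  expect_true(all(clin$significant))
  # continuous statistics are signed HIGH - LOW
  expect_gt(rep$statistic[rep$variable == "internalizing"], 0)
  szs <- attr(rep, "clusterSizes")
  expect_equal(sum(szs), 300)
})

test_that("type-I error is calibrated under a null methylation simulation", {
  # both components share every methylation distribution; only the
  # T-scores differ, so CpG t-tests are null
  mp <- clusterMethylationParams()
  mp$mean_high <- mp$mean_low
  mp$sd_high <- mp$sd_low
  spec <- cohortSpec(n = 120, mixing = c(0.5, 0.5),
                     means = rbind(c(51, 47), c(64, 59)),
                     sds = rbind(c(7, 6.5), c(6, 7.1)),
                     methylation = mp)
  praw <- c()
  for (r in 1:25) {
    ch <- generateCohort(spec, seed = 500 + r)
    labels <- factor(ifelse(ch$labels == 1, "LOW", "HIGH"),
                     levels = c("LOW", "HIGH"))
    rep <- characterize(ch$table, labels)
    praw <- c(praw, rep$p_raw[grepl("_CpG", rep$variable)])
  }
  rate <- mean(praw < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(praw)))
})
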