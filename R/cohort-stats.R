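.testResult <- function(kind, statistic, df, pRaw, effect,
                        summaries = list()) {
  out <- data.frame(kind = kind, statistic = statistic, df = df,
                    p_raw = pRaw, p_bonferroni = NA_real_,
                    effect = effect, stringsAsFactors = FALSE)
  for (nm in names(summaries)) out[[nm]] <- summaries[[nm]]
  class(out) <- c("TestResult", "data.frame")
  out
}

#' Remove high-missingness subjects and impute the rest
#'
#' Subjects with strictly more than `maxMissing` of their non-identifier
#' cells missing are dropped; every remaining missing cell is replaced by a
#' value drawn uniformly from the observed values of the same variable
#' (random hot-deck imputation), which preserves each variable's empirical
#' support and spread.
#'
#' @param table cohort data.frame.
#' @param maxMissing missing-fraction removal threshold (default 0.5).
#' @param seed integer seed; imputation is deterministic given the seed.
#' @param exclude identifier columns ignored by both steps
#'   (default `"subject"`).
#' @return list with `table` (cleaned and imputed), `removed` (data.frame:
#'   subject, frac_missing), `nImputed` (cells imputed).
#' @export
cleanAndImpute <- function(table, maxMissing = 0.5, seed = 1L,
                           exclude = "subject") {
  stopifnot(nrow(table) > 0)
  cols <- setdiff(names(table), exclude)
  frac <- rowMeans(is.na(table[, cols, drop = FALSE]))
  drop <- frac > maxMissing
  removed <- data.frame(
    subject = if ("subject" %in% names(table))
      table$subject[drop] else which(drop),
    frac_missing = frac[drop], stringsAsFactors = FALSE)
  table <- table[!drop, , drop = FALSE]
  nImputed <- 0L
  withr::with_seed(as.integer(seed), {
    for (cl in cols) {
      miss <- is.na(table[[cl]])
      if (!any(miss)) next
      obs <- table[[cl]][!miss]
      if (!length(obs))
        stop("not imputable: variable '", cl, "' has no observed values")
      table[[cl]][miss] <- sample(obs, sum(miss), replace = TRUE)
      nImputed <- nImputed + sum(miss)
    }
  })
  rownames(table) <- NULL
  list(table = table, removed = removed, nImputed = nImputed)
}

.tFromSummaries <- function(n1, mean1, sd1, n2, mean2, sd2,
                            variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (variant == "welch") {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    se <- sp * sqrt(1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tstat <- (mean1 - mean2) / se
  list(statistic = tstat, df = df,
       p = 2 * pt(-abs(tstat), df),
       d = (mean1 - mean2) / sp)
}

#' Two-sample t-test with Cohen's d
#'
#' Welch (default) or pooled-variance two-sided t-test via [stats::t.test()],
#' augmented with Cohen's d, which always uses the pooled SD regardless of
#' the test variant. When both groups have zero variance and equal means
#' the statistic is 0 with p = 1; zero variance with unequal means is an
#' error.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param variant `"welch"` or `"pooled"`.
#' @return one-row `TestResult` data.frame with kind, statistic, df, raw p,
#'   effect (Cohen's d) and group summaries.
#' @export
twoSampleT <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 values per group")
  kind <- if (variant == "welch") "welch_t" else "pooled_t"
  summ <- list(n1 = length(x), mean1 = mean(x), sd1 = sd(x),
               n2 = length(y), mean2 = mean(y), sd2 = sd(y))
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(.testResult(kind, 0, length(x) + length(y) - 2, 1, 0, summ))
    stop("degenerate: zero variance in both groups with unequal means")
  }
  tt <- t.test(x, y, var.equal = variant == "pooled")
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  .testResult(kind, unname(tt$statistic), unname(tt$parameter),
              tt$p.value, (mean(x) - mean(y)) / sp, summ)
}

#' Two-sample t-test from printed group summaries
#'
#' Identical formulas to [twoSampleT()] applied to summary statistics
#' (n, mean, SD per group), so published table rows can be re-derived
#' without raw data.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 group summaries (`n >= 2`, `sd > 0`).
#' @param variant `"welch"` or `"pooled"`.
#' @return one-row `TestResult` data.frame, as [twoSampleT()].
#' @examples
#' summaryT(102, 47.1, 6.51, 98, 58.9, 7.10, "welch")  # |t| = 12.24
#' @export
summaryT <- function(n1, mean1, sd1, n2, mean2, sd2,
                     variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  r <- .tFromSummaries(n1, mean1, sd1, n2, mean2, sd2, variant)
  .testResult(if (variant == "welch") "welch_t" else "pooled_t",
              r$statistic, r$df, r$p, r$d,
              list(n1 = n1, mean1 = mean1, sd1 = sd1,
                   n2 = n2, mean2 = mean2, sd2 = sd2))
}

#' 2x2 chi-square test with phi coefficient
#'
#' Pearson chi-square on the 2x2 table `rbind(c(a, b), c(c, d))`, with the
#' Yates continuity correction by default. The phi effect size is always
#' computed from the uncorrected statistic, `sqrt(chi2 / N)`.
#'
#' @param a,b counts of the first group (e.g. risk present / absent).
#' @param c,d counts of the second group.
#' @param yates apply the continuity correction (default TRUE).
#' @return one-row `TestResult` data.frame (kind `"chi2_2x2"`, df 1, effect
#'   = phi) with the four counts as summaries.
#' @examples
#' chiSq2x2(47, 55, 65, 33)  # Yates chi2 = 7.51, phi = 0.20
#' @export
chiSq2x2 <- function(a, b, c, d, yates = TRUE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- rbind(c(a, b), c(c, d))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate: 2x2 table has a zero margin")
  res <- suppressWarnings(chisq.test(m, correct = yates))
  unc <- suppressWarnings(chisq.test(m, correct = FALSE))
  phi <- sqrt(unname(unc$statistic) / sum(m))
  .testResult("chi2_2x2", unname(res$statistic), 1, res$p.value, phi,
              list(a = a, b = b, c = c, d = d))
}

#' Bonferroni correction over a family of comparisons
#'
#' Adjusted p is `min(1, m * p)`. The family size `m` defaults to the
#' number of p-values but can be set explicitly when the tested family is
#' larger than the vector at hand.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param m family size (default `length(p)`).
#' @param alpha significance level applied to the adjusted values.
#' @return list with `adjusted` (numeric) and `significant` (logical).
#' @export
bonferroniAdjust <- function(p, m = length(p), alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  adj <- pmin(1, m * p)
  list(adjusted = adj, significant = !is.na(adj) & adj < alpha)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] (Royston's algorithm) with an
#' explicit degenerate-input error, returning the W statistic and
#' approximate p-value.
#'
#' @param x numeric sample, `3 <= n <= 5000`.
#' @return list with `W` and `p`.
#' @export
shapiroWilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("sample size must be in [3, 5000]")
  if (length(unique(x)) == 1L)
    stop("degenerate: constant input")
  res <- shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Characterize clusters with a table of group comparisons
#'
#' Produces the full cluster-characterization report: Yates chi-square for
#' the categorical variables (sex, stressful life events, perinatal risk),
#' t-tests for age, SES, the clinical T-scores and every methylation
#' variable, with Bonferroni correction applied within the configured
#' family (default: the methylation comparisons form one family; the few
#' demographic/clinical tests are reported with raw p). Continuous
#' statistics are signed HIGH minus LOW.
#'
#' @param table cohort data.frame (post [cleanAndImpute()]).
#' @param labels a `"ClusterAssignment"` from [mapAssign()], or a factor
#'   with levels `LOW`/`HIGH`, one per row of `table`.
#' @param variant t-test variant, `"welch"` (default) or `"pooled"`.
#' @param alpha significance level (default 0.05).
#' @param methylationVars names of the methylation columns; default: every
#'   column whose name contains `"_CpG"`.
#' @param bonferroniFamily `"methylation"` (default: the methylation tests
#'   form one Bonferroni family, others are uncorrected) or `"all"` (every
#'   comparison in one family).
#' @return data.frame of class `"ClusterReport"`, one row per variable:
#'   variable, test kind, group summaries, statistic (HIGH - LOW), df,
#'   p_raw, p_bonferroni, effect, significant. Cluster sizes are attached
#'   as attribute `"clusterSizes"`; per-test failures yield NA rows.
#' @export
characterize <- function(table, labels, variant = c("welch", "pooled"),
                         alpha = 0.05, methylationVars = NULL,
                         bonferroniFamily = c("methylation", "all")) {
  variant <- match.arg(variant)
  bonferroniFamily <- match.arg(bonferroniFamily)
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  labels <- factor(labels, levels = c("LOW", "HIGH"))
  stopifnot(length(labels) == nrow(table), !anyNA(labels))
  if (is.null(methylationVars))
    methylationVars <- grep("_CpG", names(table), value = TRUE)
  catVars <- intersect(c("sex", "sle", "perinatal_risk"), names(table))
  contVars <- c(intersect(c("age", "ses", "internalizing", "externalizing"),
                          names(table)), methylationVars)

  low <- labels == "LOW"; high <- labels == "HIGH"
  oneRow <- function(variable, res, extra) {
    cbind(data.frame(variable = variable, stringsAsFactors = FALSE),
          extra, res[, c("kind", "statistic", "df", "p_raw", "effect")])
  }
  rows <- list()
  for (v in catVars) {
    x <- table[[v]]
    present <- if (v == "sex") x == "M" else x == 1 | x == TRUE
    res <- tryCatch(
      chiSq2x2(sum(present[high]), sum(!present[high]),
               sum(present[low]), sum(!present[low])),
      error = function(e) NULL)
    extra <- data.frame(
      n_low = sum(low), stat_low = sum(present[low]),
      spread_low = NA_real_,
      n_high = sum(high), stat_high = sum(present[high]),
      spread_high = NA_real_)
    rows[[v]] <- if (is.null(res))
      oneRow(v, .testResult("chi2_2x2", NA, NA, NA, NA), extra)
    else oneRow(v, res, extra)
  }
  for (v in contVars) {
    xh <- table[[v]][high]; xl <- table[[v]][low]
    res <- tryCatch(twoSampleT(xh, xl, variant), error = function(e) NULL)
    extra <- data.frame(
      n_low = sum(low), stat_low = mean(xl, na.rm = TRUE),
      spread_low = sd(xl, na.rm = TRUE),
      n_high = sum(high), stat_high = mean(xh, na.rm = TRUE),
      spread_high = sd(xh, na.rm = TRUE))
    rows[[v]] <- if (is.null(res))
      oneRow(v, .testResult(paste0(variant, "_t"), NA, NA, NA, NA), extra)
    else oneRow(v, res, extra)
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  isMeth <- report$variable %in% methylationVars
  m <- if (bonferroniFamily == "all") nrow(report) else length(methylationVars)
  report$p_bonferroni <- report$p_raw
  fam <- if (bonferroniFamily == "all") rep(TRUE, nrow(report)) else isMeth
  report$p_bonferroni[fam] <- pmin(1, m * report$p_raw[fam])
  report$significant <- !is.na(report$p_bonferroni) &
    report$p_bonferroni < alpha
  attr(report, "clusterSizes") <- c(LOW = sum(low), HIGH = sum(high))
  attr(report, "variant") <- variant
  class(report) <- c("ClusterReport", "data.frame")
  report
}
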