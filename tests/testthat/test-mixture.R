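test_that("free-parameter counts and BIC follow the convention", {
  expect_equal(nFreeParams("EII", 2, 2), 6L)
  expect_equal(nFreeParams("EEI", 2, 2), 7L)
  expect_equal(nFreeParams("VII", 2, 2), 7L)
  expect_equal(nFreeParams("EII", 1, 2), 3L)
  expect_error(nFreeParams("VVV", 2, 2), "invalid")
  expect_equal(bicMclust(0, 0, 1), 0)
  expect_equal(bicMclust(-1427.85, 7, 200), 2 * (-1427.85) - 7 * log(200))
})

test_that("K = 1 fit recovers the closed-form MLE", {
  X <- withr::with_seed(1, cbind(rnorm(100, 5, 2), rnorm(100, -3, 0.5)))
  fit <- fitMixture(X, K = 1, family = "EII", seed = 2)
  expect_equal(unname(componentMeans(fit)[1, ]), colMeans(X))
  # EII variance = mean of the per-dimension MLE (1/n) variances
  vml <- mean(apply(X, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(componentVariances(fit), vml, tolerance = 1e-8)
  expect_equal(mixWeights(fit), 1)
})

test_that("EM log-likelihood is non-decreasing within tolerance", {
  X <- withr::with_seed(3, rbind(cbind(rnorm(80, 0), rnorm(80, 0)),
                                 cbind(rnorm(80, 4), rnorm(80, 5))))
  for (fam in c("EII", "VII", "EEI")) {
    init <- withr::with_seed(4, sample(1:2, 160, replace = TRUE))
    run <- cpgmix:::.emRun(X, 2L, fam, init, tol = 1e-8, maxIter = 500,
                           varFloor = 1e-6)
    expect_true(all(diff(run$llTrace) >= -1e-8 * (abs(run$loglik) + 1)),
                info = fam)
  }
})

test_that("the bic slot always equals bicMclust(loglik, m, n)", {
  X <- withr::with_seed(5, cbind(rnorm(120), rnorm(120)))
  for (fam in c("EII", "VII", "EEI")) for (K in 1:3) {
    fit <- fitMixture(X, K, fam, seed = 6)
    expect_identical(bicValue(fit),
                     bicMclust(logLikValue(fit), fit@m, fit@n))
  }
})

test_that("EII is nested in VII and EEI at convergence", {
  co <- generateCohort(tscoreSpec(200), seed = 7)
  X <- as.matrix(co$table[, c("internalizing", "externalizing")])
  ll <- sapply(c("EII", "VII", "EEI"), function(f)
    logLikValue(fitMixture(X, 2, f, seed = 8)))
  expect_gte(ll[["VII"]], ll[["EII"]] - 1e-6)
  expect_gte(ll[["EEI"]], ll[["EII"]] - 1e-6)
})

test_that("parameters of the generating mixture are recovered", {
  # moderate replicate count here; the full recovery study runs in the
  # acceptance suite
  errW <- replicate(20, NA_real_)
  for (r in 1:20) {
    co <- generateCohort(tscoreSpec(200), seed = 100 + r)
    X <- as.matrix(co$table[, c("internalizing", "externalizing")])
    fit <- fitMixture(X, 2, "EII", seed = r)
    ord <- order(componentMeans(fit)[, 1])
    errW[r] <- mixWeights(fit)[ord[1]] - 0.51
  }
  expect_lt(mean(abs(errW)), 0.05)
})

test_that("model likelihood agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  co <- generateCohort(tscoreSpec(200), seed = 9)
  X <- as.matrix(co$table[, c("internalizing", "externalizing")])
  mc <- mclust::Mclust(X, G = 2, modelNames = "EII", verbose = FALSE)
  # evaluating our likelihood at mclust's fitted parameters reproduces
  # mclust's log-likelihood
  lp <- cpgmix:::.componentLogLik(
    X, "EII", mc$parameters$pro, t(mc$parameters$mean),
    mc$parameters$variance$sigmasq)
  # (mclust reports the log-likelihood of its last E-step, half an EM
  # iteration behind the returned parameters, so agreement is near-exact
  # rather than to machine precision)
  expect_lt(abs(sum(cpgmix:::.logSumExpRows(lp)) - mc$loglik), 0.05)
  # and our EM reaches at least mclust's optimum on these data
  fit <- fitMixture(X, 2, "EII", seed = 10)
  expect_gte(logLikValue(fit), mc$loglik - 1e-6)
  expect_lt(abs(logLikValue(fit) - mc$loglik), 0.1)
})

test_that("BIC model selection prefers the right structure", {
  # single tight Gaussian cloud: K = 1 beats K = 2
  X1 <- withr::with_seed(11, cbind(rnorm(150, 50, 2), rnorm(150, 50, 2)))
  sel1 <- selectModel(X1, KRange = 1:2, families = "EII", seed = 12)
  expect_equal(sel1$best@K, 1L)
  # ranking covers the whole grid
  co <- generateCohort(tscoreSpec(200), seed = 13)
  X <- as.matrix(co$table[, c("internalizing", "externalizing")])
  sel <- selectModel(X, KRange = 1:3, seed = 14)
  expect_equal(nrow(sel$ranking), 9)
  expect_true(!is.unsorted(rev(sel$ranking$bic)))
})

test_that("MAP assignment orders clusters by internalizing severity", {
  co <- generateCohort(tscoreSpec(300), seed = 15)
  X <- as.matrix(co$table[, c("internalizing", "externalizing")])
  fit <- fitMixture(X, 2, "EII", seed = 16)
  asg <- mapAssign(fit, X)
  expect_setequal(levels(asg$labels), c("LOW", "HIGH"))
  expect_lt(mean(X[asg$labels == "LOW", 1]),
            mean(X[asg$labels == "HIGH", 1]))
  # responsibilities are a proper posterior
  expect_equal(rowSums(asg$responsibilities), rep(1, 300),
               tolerance = 1e-12)
  # a point at a well-separated component mean is assigned with near
  # certainty
  Xs <- rbind(c(0, 0), c(100, 100))
  fs <- fitMixture(rbind(withr::with_seed(17, cbind(rnorm(50), rnorm(50))),
                         withr::with_seed(18, cbind(rnorm(50, 100),
                                                    rnorm(50, 100)))),
                   2, "EII", seed = 19)
  a2 <- mapAssign(fs, Xs)
  expect_gt(a2$responsibilities[1, 1], 0.99)
  expect_gt(a2$responsibilities[2, 2], 0.99)
})
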