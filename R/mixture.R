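#' Free-parameter count of a constrained Gaussian mixture
#'
#' Mixing weights contribute K - 1, means K * d, and the covariance
#' structure 1 (EII, one shared spherical variance), K (VII, one spherical
#' variance per component) or d (EEI, one shared diagonal).
#'
#' @param family `"EII"`, `"VII"` or `"EEI"`.
#' @param K number of components (>= 1).
#' @param d data dimension (>= 1).
#' @return integer free-parameter count.
#' @examples
#' nFreeParams("EII", 2, 2)  # 6
#' @export
nFreeParams <- function(family, K, d) {
  stopifnot(K >= 1, d >= 1)
  nvar <- switch(family, EII = 1L, VII = as.integer(K), EEI = as.integer(d))
  if (is.null(nvar))
    stop("invalid parameters: unknown family '", family,
         "' (supported: EII, VII, EEI)")
  as.integer((K - 1L) + K * d + nvar)
}

#' BIC in the model-based-clustering convention
#'
#' `2 * loglik - m * log(n)`; larger values indicate better models (note
#' the sign: this is the negative of the textbook definition).
#'
#' @param loglik maximized log-likelihood.
#' @param m number of free parameters.
#' @param n sample size.
#' @return the BIC value.
#' @examples
#' bicMclust(-1427.85, 6, 200)
#' @export
bicMclust <- function(loglik, m, n) {
  stopifnot(n >= 1, m >= 0)
  2 * loglik - m * log(n)
}

# per-component log density under a diagonal Gaussian; X n x d,
# mu length d, v length d
.logDensDiag <- function(X, mu, v) {
  d <- ncol(X)
  cst <- -0.5 * sum(log(2 * pi * v))
  q <- sweep(X, 2L, mu)
  cst - 0.5 * as.vector(q^2 %*% (1 / v))
}

.varianceVectors <- function(family, variances, K, d) {
  switch(family,
         EII = matrix(variances, K, d),
         VII = matrix(variances, K, d),
         EEI = matrix(variances, K, d, byrow = TRUE))
}

# n x K matrix of log(pi_k) + log N(x | mu_k, Sigma_k)
.componentLogLik <- function(X, family, weights, means, variances) {
  K <- length(weights); d <- ncol(X)
  vv <- .varianceVectors(family, variances, K, d)
  lp <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    lp[, k] <- log(weights[k]) + .logDensDiag(X, means[k, ], vv[k, ])
  lp
}

.logSumExpRows <- function(lp) {
  mx <- apply(lp, 1L, max)
  mx + log(rowSums(exp(lp - mx)))
}

# one EM run from hard initial labels; returns NULL on degeneracy
.emRun <- function(X, K, family, init, tol, maxIter, varFloor) {
  n <- nrow(X); d <- ncol(X)
  R <- matrix(0, n, K)
  R[cbind(seq_len(n), init)] <- 1
  ll <- -Inf
  llTrace <- numeric(0)
  weights <- NULL; means <- NULL; variances <- NULL
  for (iter in seq_len(maxIter)) {
    nk <- colSums(R)
    if (any(nk < 1e-8)) return(NULL)
    weights <- nk / n
    means <- (t(R) %*% X) / nk
    resid2 <- matrix(0, n, K)
    for (k in seq_len(K))
      resid2[, k] <- rowSums(sweep(X, 2L, means[k, ])^2)
    variances <- switch(family,
      EII = max(sum(R * resid2) / (n * d), varFloor),
      VII = pmax(colSums(R * resid2) / (d * nk), varFloor),
      EEI = {
        v <- numeric(d)
        for (j in seq_len(d)) {
          sq <- outer(X[, j], means[, j], "-")^2
          v[j] <- sum(R * sq) / n
        }
        pmax(v, varFloor)
      })
    lp <- .componentLogLik(X, family, weights, means, variances)
    lse <- .logSumExpRows(lp)
    llNew <- sum(lse)
    llTrace <- c(llTrace, llNew)
    R <- exp(lp - lse)
    if (is.finite(ll) && abs(llNew - ll) <= tol * (abs(llNew) + 1)) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  list(weights = weights, means = means, variances = variances,
       loglik = ll, llTrace = llTrace)
}

#' Fit a constrained-covariance Gaussian mixture by EM
#'
#' Maximum-likelihood EM for a K-component Gaussian mixture under one of
#' three diagonal covariance parameterizations: EII (spherical, one shared
#' variance), VII (spherical, per-component variance), EEI (shared diagonal
#' variance vector). Initialization is k-means seeding; the best of
#' `nRestarts` runs by log-likelihood is returned. Restarts whose
#' components degenerate (vanishing weight) are discarded; all variances
#' are floored at `varFloor`.
#'
#' @param X numeric n x d matrix (rows = subjects; here d = 2 T-scores).
#' @param K number of components, `K < n`.
#' @param family `"EII"`, `"VII"` or `"EEI"`.
#' @param seed integer seed controlling initialization; fits are
#'   deterministic given the seed.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations per restart (default 500).
#' @param nRestarts number of k-means-seeded restarts (default 10).
#' @param varFloor lower bound on every variance parameter (default 1e-6).
#' @return a [MixtureModel-class].
#' @examples
#' X <- cbind(c(rnorm(50), rnorm(50, 6)), c(rnorm(50), rnorm(50, 6)))
#' fitMixture(X, K = 2, family = "EII", seed = 1)
#' @export
fitMixture <- function(X, K, family = c("EII", "VII", "EEI"), seed = 1L,
                       tol = 1e-8, maxIter = 500L, nRestarts = 10L,
                       varFloor = 1e-6) {
  family <- match.arg(family)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (n <= K) stop("need more observations than components")
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRestarts)) {
      init <- if (K == 1L) rep(1L, n)
              else tryCatch(kmeans(X, centers = K, nstart = 1L)$cluster,
                            error = function(e) NULL)
      if (is.null(init)) next
      fit <- .emRun(X, K, family, init, tol, maxIter, varFloor)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
    }
  })
  if (is.null(best))
    stop("all EM restarts degenerated; no mixture could be fitted")
  m <- nFreeParams(family, K, d)
  new("MixtureModel", family = family, K = as.integer(K),
      weights = as.numeric(best$weights),
      means = unname(best$means),
      variances = as.numeric(best$variances),
      loglik = best$loglik, m = m, n = as.integer(n),
      bic = bicMclust(best$loglik, m, n))
}

#' Fit a grid of mixtures and select the best by BIC
#'
#' Fits every (family, K) combination and returns the model maximizing the
#' BIC (larger better), together with the full ranking. Ties are broken
#' toward fewer free parameters, then fewer components. Combinations whose
#' fit fails are dropped from the ranking.
#'
#' @param X numeric n x d matrix.
#' @param KRange component counts to try (default 1:5).
#' @param families families to try (default all three).
#' @param seed base seed, offset per combination for independence.
#' @param ... passed on to [fitMixture()].
#' @return list with `best` (a [MixtureModel-class]) and `ranking`
#'   (data.frame: family, K, loglik, m, bic, ordered best first).
#' @export
selectModel <- function(X, KRange = 1:5,
                        families = c("EII", "VII", "EEI"), seed = 1L,
                        ...) {
  fits <- list(); rows <- list()
  for (fam in families) for (K in KRange) {
    fit <- tryCatch(fitMixture(X, K, fam, seed = seed, ...),
                    error = function(e) NULL)
    if (is.null(fit)) next
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, K = K, loglik = fit@loglik, m = fit@m, bic = fit@bic)
  }
  if (!length(fits)) stop("all mixture fits failed")
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$bic, ranking$m, ranking$K)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(best = fits[[ord[1]]], ranking = ranking)
}

#' Maximum-a-posteriori cluster assignment
#'
#' Computes posterior responsibilities under a fitted model and assigns
#' each subject to the component with the highest responsibility.
#' Components are re-ordered by ascending mean of the first column
#' (internalizing T-score), so for K = 2 component 1 is the lower-severity
#' "LOW" cluster and component 2 the "HIGH" cluster.
#'
#' @param model a [MixtureModel-class].
#' @param X data matrix compatible with the fit (n x d).
#' @return list of class `"ClusterAssignment"`: `labels` (factor, levels
#'   `LOW`/`HIGH` for K = 2, else `C1..CK` in ascending order of the first
#'   mean), `map` (integer component in the re-ordered numbering),
#'   `responsibilities` (n x K matrix, columns re-ordered; rows sum to 1),
#'   `order` (the permutation applied to the fitted components).
#' @export
mapAssign <- function(model, X) {
  stopifnot(is(model, "MixtureModel"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@means))
    stop("data dimension incompatible with the fitted model")
  lp <- .componentLogLik(X, model@family, model@weights, model@means,
                         model@variances)
  R <- exp(lp - .logSumExpRows(lp))
  ord <- order(model@means[, 1])
  R <- R[, ord, drop = FALSE]
  map <- max.col(R, ties.method = "first")
  lev <- if (model@K == 2L) c("LOW", "HIGH") else paste0("C", seq_len(model@K))
  colnames(R) <- lev
  structure(list(labels = factor(lev[map], levels = lev),
                 map = map, responsibilities = R, order = ord),
            class = "ClusterAssignment")
}
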