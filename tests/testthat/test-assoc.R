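## Association tests: worked statistics, degrees of freedom, degeneracies,
## and agreement with an independent maximum-likelihood oracle.

fake_pred <- function(P_final, P_actual, folds = NULL,
                      trait = "continuous") {
  structure(list(P_actual = P_actual, P_final = P_final,
                 folds = if (is.null(folds))
                   rep_len(1:5, length(P_actual)) else folds,
                 trait = trait),
            class = "cv_prediction")
}

## Direct numerical maximisation of the Bernoulli log-likelihood, independent
## of glm's IRLS path.
loglik_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  nll <- function(b) {
    eta <- as.vector(X1 %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, ncol(X1)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  -opt$value
}

test_that("pooled correlation t statistic matches its closed form", {
  ## r = 0.5, N = 100 -> t = 0.5*sqrt(98/0.75) = 5.71548
  set.seed(1)
  a <- rnorm(100)
  b <- rnorm(100)
  b <- 0.5 * scale(a)[, 1] + sqrt(0.75) * scale(resid(lm(b ~ a)))[, 1]
  pr <- fake_pred(b, a)
  res <- assoc_continuous(pr, method = "pooled")
  r <- cor(a, b)
  expect_equal(unname(res$statistic), r * sqrt(98 / (1 - r^2)),
               tolerance = 1e-10)
  expect_equal(r, 0.5, tolerance = 1e-10)
  expect_equal(unname(res$statistic), 5.7154761, tolerance = 1e-6)
  ## uncorrelated pair: t = 0, p = 1
  b0 <- scale(resid(lm(rnorm(100) ~ a)))[, 1]
  res0 <- assoc_continuous(fake_pred(b0, a), method = "pooled")
  expect_equal(unname(res0$statistic), 0, tolerance = 1e-10)
  expect_equal(res0$p.value, 1, tolerance = 1e-10)
})

test_that("constant predictions give p = 1 with a warning", {
  pr <- fake_pred(rep(1, 50), rnorm(50))
  expect_warning(res <- assoc_continuous(pr), "constant")
  expect_equal(res$p.value, 1)
})

test_that("fold-stratified statistic equals its by-hand Stouffer form", {
  set.seed(2)
  y <- rnorm(100)
  p <- rnorm(100)
  folds <- rep(1:5, each = 20)
  res <- assoc_continuous(fake_pred(p, y, folds), method = "stratified")
  zs <- sapply(1:5, function(k)
    atanh(cor(p[folds == k], y[folds == k])) * sqrt(20 - 3))
  expect_equal(unname(res$statistic), sum(zs) / sqrt(5), tolerance = 1e-12)
})

test_that("case-control LRT has g+1 df and matches the likelihood oracle", {
  set.seed(3)
  n <- 40
  G <- matrix(sample(0:2, n * 2, TRUE), n, 2)
  y <- rbinom(n, 1, 0.5)
  pred <- fake_pred(runif(n), y, trait = "binary")
  res <- assoc_casecontrol(G, pred, y)
  expect_equal(unname(res$parameter), 3)  # g + 1 = 2 + 1
  X <- cbind(G, pred$P_final)
  ll_full <- loglik_oracle(X, y)
  ll_null <- sum(y) * log(mean(y)) + (n - sum(y)) * log(1 - mean(y))
  expect_equal(unname(res$statistic), 2 * (ll_full - ll_null),
               tolerance = 1e-4)
  ## df tracks the SNP count
  G3 <- matrix(sample(0:2, n * 3, TRUE), n, 3)
  expect_equal(unname(assoc_casecontrol(G3, pred, y)$parameter), 4)
  ## all-constant regressors: statistic 0, p 1
  res0 <- assoc_casecontrol(matrix(1, n, 2), fake_pred(rep(0.5, n), y), y)
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p.value, 1)
})

test_that("Steiger Z reproduces the Meng-Rosenthal-Rubin worked example", {
  expect_equal(steiger_z(0.3, 0.5, 0.4, 103), 2.0585, tolerance = 1e-4)
  ## equal correlations: Z = 0
  expect_equal(steiger_z(0.4, 0.4, 0.3, 50), 0)
  ## antisymmetry under swapping the two correlations
  expect_equal(steiger_z(0.5, 0.3, 0.4, 103),
               -steiger_z(0.3, 0.5, 0.4, 103), tolerance = 1e-12)
  ## degenerate correlation errors
  expect_error(steiger_z(1, 0.5, 0.2, 50), "degenerate")
})

test_that("covariate-adjusted continuous test wires Steiger Z correctly", {
  set.seed(4)
  n <- 103
  y <- rnorm(n)
  pc <- 0.4 * y + rnorm(n)   # covariate-only prediction
  pa <- 0.6 * y + 0.3 * pc + rnorm(n)  # SNPs improve the prediction
  res <- assoc_adjusted_continuous(fake_pred(pa, y), fake_pred(pc, y))
  z_hand <- steiger_z(cor(y, pc), cor(y, pa), cor(pc, pa), n)
  expect_equal(unname(res$statistic), z_hand, tolerance = 1e-12)
  expect_gt(unname(res$statistic), 0)  # genetics improved prediction
  expect_equal(res$p.value, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
})

test_that("adjusted case-control LRT uses g+1 df and detects no-signal", {
  set.seed(5)
  n <- 80
  G <- matrix(sample(0:2, n * 5, TRUE), n, 5)
  cov <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, 0.5)
  pa <- fake_pred(runif(n), y, trait = "binary")
  pc <- fake_pred(runif(n), y, trait = "binary")
  res <- assoc_adjusted_casecontrol(G, cov, pa, pc, y)
  expect_equal(unname(res$parameter), 6)  # g + 1 = 5 + 1
  ## constant SNPs and identical predictions: statistic exactly 0
  res0 <- assoc_adjusted_casecontrol(matrix(2, n, 3), cov, pa, pa, y)
  expect_equal(unname(res0$statistic), 0)
})

test_that("interaction F statistic matches the SSE closed form", {
  ## SSE0=110, SSE1=100, N=106, V1=5 -> F = 10, p = pf(10, 1, 100, lower=F)
  fs <- genestack:::fstat_from_sse(110, 100, 106, 5)
  expect_equal(fs$F, 10, tolerance = 1e-12)
  expect_equal(fs$df, c(1, 100))
  expect_equal(pf(fs$F, 1, 100, lower.tail = FALSE), 0.00207287,
               tolerance = 1e-4)
})

test_that("interaction tests handle nesting, degeneracy and df", {
  set.seed(6)
  n <- 120
  G <- matrix(sample(0:2, n * 4, TRUE), n, 4)
  y <- rnorm(n) + 0.3 * G[, 1]
  pl <- rnorm(n)
  ## P_ensemble identical to P_linear: F = 0 (continuous), LRT = 0 (binary)
  resc <- interaction_continuous(G, pl, pl, y)
  expect_equal(unname(resc$statistic), 0)
  expect_equal(resc$p.value, 1)
  yb <- rbinom(n, 1, 0.5)
  resb <- interaction_casecontrol(G, pl, pl, yb)
  expect_equal(unname(resb$statistic), 0)
  expect_equal(resb$p.value, 1)
  ## df is always 1 for the case-control interaction LRT, any g
  pe <- rnorm(n)
  expect_equal(unname(interaction_casecontrol(G, pl, pe, yb)$parameter), 1)
  expect_equal(unname(interaction_casecontrol(G[, 1:2], pl, pe,
                                              yb)$parameter), 1)
  ## continuous df2 = N - V1 - 1 with V1 = g + 2
  resf <- interaction_continuous(G, pl, pe, y)
  expect_equal(unname(resf$parameter), c(1, n - (4 + 2) - 1))
  ## the F statistic agrees with explicit lm() fits
  sse1 <- sum(resid(lm(y ~ G + pl + pe))^2)
  sse0 <- sum(resid(lm(y ~ G + pl))^2)
  expect_equal(unname(resf$statistic),
               (sse0 - sse1) * (n - 6 - 1) / sse1, tolerance = 1e-10)
})

test_that("interaction case-control LRT matches the likelihood oracle", {
  set.seed(7)
  n <- 40
  G <- matrix(sample(0:2, n * 2, TRUE), n, 2)
  y <- rbinom(n, 1, 0.5)
  pl <- runif(n)
  pe <- runif(n)
  res <- interaction_casecontrol(G, pl, pe, y)
  ll1 <- loglik_oracle(cbind(G, pl, pe), y)
  ll0 <- loglik_oracle(cbind(G, pl), y)
  expect_equal(unname(res$statistic), 2 * (ll1 - ll0), tolerance = 1e-4)
})
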