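## Comparison tests: Fisher, Simes, GATES, VEGAS, regression gene tests.

test_that("per-SNP statistics behave at the limits", {
  set.seed(1)
  n <- 500
  G <- cbind(a = sample(0:2, n, TRUE), mono = rep(1L, n),
             b = sample(0:2, n, TRUE))
  y <- rbinom(n, 1, 0.5)
  s <- snp_pvalues(G, y, "binary")
  expect_equal(s$p[2], 1)
  expect_equal(s$chi2[2], 0)
  expect_true(s$monomorphic[2])
  ## perfectly associated binary SNP
  G2 <- cbind(x = ifelse(y == 1, 2L, 0L))
  s2 <- snp_pvalues(G2, y, "binary")
  expect_lt(s2$p[1], 1e-10)
  ## continuous: chi2 and p are mutually consistent
  yq <- rnorm(n)
  sq <- snp_pvalues(G[, c(1, 3)], yq, "continuous")
  expect_equal(pchisq(sq$chi2, 1, lower.tail = FALSE), sq$p,
               tolerance = 1e-10)
  expect_error(snp_pvalues(G, rep(1, n), "binary"), "constant")
})

test_that("null per-SNP p-values are approximately uniform", {
  set.seed(2)
  n <- 2000
  reps <- 50
  ps <- replicate(reps, {
    G <- matrix(sample(0:2, n * 3, TRUE, prob = c(0.49, 0.42, 0.09)), n, 3)
    y <- rbinom(n, 1, 0.5)
    snp_pvalues(G, y, "binary")$p
  })
  ks <- suppressWarnings(ks.test(as.vector(ps), "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Fisher combination reproduces its worked example", {
  ## T = -2(ln .01 + ln .04 + ln .5) = 17.03439, p = pchisq tail with 6 df
  res <- fisher_combination(c(0.01, 0.04, 0.5))
  expect_equal(unname(res$statistic), 17.0343864, tolerance = 1e-6)
  expect_equal(unname(res$parameter), 6)
  expect_equal(res$p.value, pchisq(17.0343864, 6, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(res$p.value, 0.00915770, tolerance = 1e-4)
  ## all p = 1: T = 0, p = 1
  res1 <- fisher_combination(rep(1, 4))
  expect_equal(unname(res1$statistic), 0)
  expect_equal(res1$p.value, 1)
})

test_that("Simes reproduces its worked examples", {
  ## min(3*.01/1, 3*.04/2, 3*.05/3) = 0.03
  expect_equal(simes_test(c(0.01, 0.04, 0.05))$p.value, 0.03,
               tolerance = 1e-12)
  expect_equal(simes_test(0.2)$p.value, 0.2)          # m = 1
  expect_equal(simes_test(rep(0.37, 5))$p.value, 0.37) # equal p
  ## order invariance
  expect_equal(simes_test(c(0.5, 0.01, 0.04))$p.value,
               simes_test(c(0.01, 0.04, 0.5))$p.value)
})

test_that("GATES reduces to Simes under independence and collapses under
           perfect LD", {
  set.seed(3)
  for (m in c(1, 3, 6)) {
    p <- runif(m)
    s <- structure(list(p = p, chi2 = qchisq(p, 1, lower.tail = FALSE),
                        R = diag(m), m = m, n = 100,
                        monomorphic = rep(FALSE, m)),
                   class = "snp_stats")
    expect_equal(gates_test(s)$p.value, simes_test(p)$p.value,
                 tolerance = 1e-12)
  }
  ## all SNPs perfectly correlated: m_e = 1, P_G = min p
  m <- 4
  p <- runif(m)
  s <- structure(list(p = p, chi2 = qchisq(p, 1, lower.tail = FALSE),
                      R = matrix(1, m, m), m = m, n = 100,
                      monomorphic = rep(FALSE, m)),
                 class = "snp_stats")
  res <- gates_test(s)
  expect_equal(unname(res$estimate["m_e"]), 1, tolerance = 1e-10)
  expect_equal(res$p.value, min(p), tolerance = 1e-10)
})

test_that("VEGAS matches analytic nulls under independence", {
  set.seed(4)
  n <- 400
  m <- 3
  G <- matrix(sample(0:2, n * m, TRUE, prob = c(0.49, 0.42, 0.09)), n, m)
  y <- rbinom(n, 1, 0.5)
  s <- snp_pvalues(G, y, "binary")
  s$R <- diag(m)  # exact independence limit
  nsim <- 1e5
  ## sum mode: chi-square(m) tail
  res_sum <- vegas_test(s, "sum", n_sim = nsim, seed = 5)
  p_exact <- pchisq(sum(s$chi2), m, lower.tail = FALSE)
  se <- sqrt(p_exact * (1 - p_exact) / nsim)
  expect_lt(abs(res_sum$p.value - p_exact), 3 * se + 2 / nsim)
  ## max mode: 1 - (1 - p_min)^m
  res_max <- vegas_test(s, "max", n_sim = nsim, seed = 6)
  p_max <- 1 - (1 - min(s$p))^m
  se2 <- sqrt(p_max * (1 - p_max) / nsim)
  expect_lt(abs(res_max$p.value - p_max), 3 * se2 + 2 / nsim)
  ## m = 1: both modes match the single-SNP p-value
  s1 <- snp_pvalues(G[, 1, drop = FALSE], y, "binary")
  res1 <- vegas_test(s1, "sum", n_sim = nsim, seed = 7)
  se3 <- sqrt(s1$p * (1 - s1$p) / nsim)
  expect_lt(abs(res1$p.value - s1$p), 3 * se3 + 2 / nsim)
})

test_that("regression gene test matches oracles and handles degeneracies", {
  set.seed(8)
  n <- 40
  G <- matrix(sample(0:2, n * 2, TRUE), n, 2)
  y <- rbinom(n, 1, 0.5)
  res <- regression_gene_test(G, y, "binary")
  expect_equal(unname(res$parameter), 2)  # df = g
  ## independent likelihood-maximisation oracle
  X1 <- cbind(1, G)
  nll <- function(b) {
    eta <- as.vector(X1 %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  ll_full <- -optim(rep(0, 3), nll, method = "BFGS",
                    control = list(reltol = 1e-12))$value
  ll_null <- sum(y) * log(mean(y)) + (n - sum(y)) * log(1 - mean(y))
  expect_equal(unname(res$statistic), 2 * (ll_full - ll_null),
               tolerance = 1e-4)
  ## continuous trait: overall F test agrees with summary.lm
  yq <- rnorm(n)
  resq <- regression_gene_test(G, yq, "continuous")
  fs <- summary(lm(yq ~ G))$fstatistic
  expect_equal(unname(resq$statistic), unname(fs[1]), tolerance = 1e-10)
  ## all SNPs constant: p = 1
  res0 <- regression_gene_test(matrix(1, n, 3), y, "binary")
  expect_equal(res0$p.value, 1)
})
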