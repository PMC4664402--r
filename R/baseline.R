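## Classical gene-based comparison tests operating on per-SNP statistics.

#' Per-SNP single-marker statistics
#'
#' Computes a 1-df chi-square statistic and p-value per SNP: for binary
#' traits the Armitage trend chi-square `N * cor(g, y)^2`; for continuous
#' traits the correlation t test, with the chi-square taken as
#' `qchisq(1 - p, 1)` so statistic and p-value are mutually consistent.
#' Monomorphic SNPs get `p = 1`, `chi2 = 0` and are flagged. Also returns the
#' SNP dosage correlation matrix used by GATES and VEGAS.
#'
#' @param G dosage matrix (samples x SNPs).
#' @param y phenotype (0/1 or continuous).
#' @param trait `"binary"` or `"continuous"`.
#' @return an object of class `snp_stats` with fields `p`, `chi2`, `R`, `m`,
#'   `monomorphic`.
#' @export
snp_pvalues <- function(G, y, trait = c("binary", "continuous")) {
  trait <- match.arg(trait)
  G <- as.matrix(G)
  if (ncol(G) < 1) stop("need at least one SNP")
  if (stats::sd(y) == 0) stop("phenotype is constant")
  n <- nrow(G)
  m <- ncol(G)
  p <- numeric(m)
  chi2 <- numeric(m)
  mono <- logical(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    if (stats::sd(g) == 0) {
      p[j] <- 1; chi2[j] <- 0; mono[j] <- TRUE
      next
    }
    r <- stats::cor(g, y)
    if (trait == "binary") {
      chi2[j] <- n * r^2
      p[j] <- stats::pchisq(chi2[j], 1, lower.tail = FALSE)
    } else {
      t <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
      p[j] <- 2 * stats::pt(-abs(t), n - 2)
      chi2[j] <- stats::qchisq(p[j], 1, lower.tail = FALSE)
    }
  }
  R <- suppressWarnings(stats::cor(G))
  R[is.na(R)] <- 0
  diag(R) <- 1
  structure(list(p = p, chi2 = chi2, R = R, m = m, n = n,
                 monomorphic = mono),
            class = "snp_stats")
}

#' @export
print.snp_stats <- function(x, ...) {
  cat("Per-SNP statistics for", x$m, "SNPs (n =", x$n, ")\n")
  print(data.frame(chi2 = round(x$chi2, 3), p = signif(x$p, 4),
                   monomorphic = x$monomorphic))
  invisible(x)
}

as_snp_p <- function(s) {
  if (inherits(s, "snp_stats")) s$p else as.numeric(s)
}

#' Fisher combination test
#'
#' `T = -2 * sum(log p_j)` referred to a chi-square distribution with `2m`
#' degrees of freedom. Valid only when the per-SNP tests are independent;
#' under LD the test is anti-conservative.
#'
#' @param s an [snp_pvalues()] result or a vector of p-values.
#' @return a `gene_assoc` (htest) object.
#' @export
fisher_combination <- function(s) {
  p <- as_snp_p(s)
  note <- NULL
  if (any(p <= 0)) {
    p <- pmax(p, .Machine$double.xmin)
    note <- "zero p-values clipped"
  }
  m <- length(p)
  T <- -2 * sum(log(p))
  assoc_result(c(T = T), c(df = 2 * m),
               stats::pchisq(T, 2 * m, lower.tail = FALSE),
               "Fisher combination test", NA_integer_, note = note)
}

#' Simes test
#'
#' `P_S = min_j ( m * p_(j) / j )` over the ascending-ordered p-values.
#'
#' @inheritParams fisher_combination
#' @return a `gene_assoc` (htest) object with the Simes p-value.
#' @export
simes_test <- function(s) {
  p <- sort(as_snp_p(s))
  m <- length(p)
  ps <- min(m * p / seq_len(m))
  assoc_result(c(P_S = ps), NULL, min(1, ps), "Simes test", NA_integer_)
}

## Approximate correlation between two single-SNP p-values from the dosage
## correlation r (sixth-degree polynomial of Li et al. 2011, Am J Hum Genet
## 88:283-293); exact limits |r| = 1 -> 1 enforced so perfect LD collapses to
## one effective test.
pvalue_correlation <- function(r) {
  out <- 0.2982 * r^6 - 0.0127 * r^5 + 0.0588 * r^4 + 0.0099 * r^3 +
    0.6281 * r^2 - 0.0009 * r
  out[abs(r) >= 1 - 1e-12] <- 1
  out
}

## Effective number of independent p-values among a set of SNPs:
## m_e = M - sum_{lambda_i > 1} (lambda_i - 1).
effective_tests <- function(rho) {
  if (nrow(rho) == 1) return(1)
  lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  nrow(rho) - sum(pmax(0, lam - 1))
}

#' GATES gene-based test
#'
#' Extended Simes procedure: `P_G = min_j ( m_e * p_(j) / m_e(j) )` where
#' `m_e` is the effective number of independent p-values among all m SNPs and
#' `m_e(j)` the effective number among the j most significant SNPs, both
#' computed from the eigenvalues of the p-value correlation matrix (derived
#' from the dosage correlations via a published polynomial approximation).
#' With an identity correlation matrix GATES reduces exactly to Simes.
#'
#' @param s an [snp_pvalues()] result (the dosage correlation matrix is
#'   required).
#' @return a `gene_assoc` (htest) object with the GATES p-value.
#' @export
gates_test <- function(s) {
  stopifnot(inherits(s, "snp_stats"))
  ord <- order(s$p)
  p <- s$p[ord]
  rho <- pvalue_correlation(s$R[ord, ord, drop = FALSE])
  diag(rho) <- 1
  m <- s$m
  me_all <- effective_tests(rho)
  me_j <- vapply(seq_len(m), function(j)
    effective_tests(rho[seq_len(j), seq_len(j), drop = FALSE]), numeric(1))
  pg <- min(me_all * p / me_j)
  assoc_result(c(P_G = pg), NULL, min(1, pg), "GATES (extended Simes) test",
               s$n, estimate = c(m_e = me_all))
}

## Nearest-PSD repair by eigenvalue clamping, rescaled to unit diagonal.
repair_psd <- function(R) {
  ev <- eigen(R, symmetric = TRUE)
  if (all(ev$values > 1e-10)) return(list(R = R, repaired = FALSE))
  val <- pmax(ev$values, 1e-8)
  R2 <- ev$vectors %*% diag(val) %*% t(ev$vectors)
  d <- sqrt(diag(R2))
  list(R = R2 / outer(d, d), repaired = TRUE)
}

#' VEGAS gene-based test
#'
#' Sum (VEGAS-Sum) or maximum (VEGAS-Max) of the per-SNP 1-df chi-square
#' statistics, with the null distribution simulated from multivariate
#' standard normal vectors whose correlations equal the SNP dosage
#' correlations. The empirical p-value uses the `(r + 1) / (n_sim + 1)`
#' continuity correction.
#'
#' @param s an [snp_pvalues()] result.
#' @param mode `"sum"` or `"max"`.
#' @param n_sim number of null simulations (>= 100).
#' @param seed optional integer seed.
#' @return a `gene_assoc` (htest) object.
#' @export
vegas_test <- function(s, mode = c("sum", "max"), n_sim = 1e4, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "snp_stats"))
  if (n_sim < 100) stop("n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  rep <- repair_psd(s$R)
  L <- chol(rep$R)
  obs <- if (mode == "sum") sum(s$chi2) else max(s$chi2)
  Z <- matrix(stats::rnorm(n_sim * s$m), n_sim, s$m) %*% L
  null_stat <- if (mode == "sum") rowSums(Z^2) else
    apply(Z^2, 1, max)
  p <- (sum(null_stat >= obs) + 1) / (n_sim + 1)
  assoc_result(stats::setNames(obs, paste0("vegas_", mode)), NULL, p,
               sprintf("VEGAS-%s test (%d simulations)",
                       if (mode == "sum") "Sum" else "Max", n_sim),
               s$n,
               note = if (rep$repaired) "correlation matrix repaired to PSD")
}

#' Regression gene-based test
#'
#' The all-SNP regression comparison test: for binary traits, a logistic
#' likelihood-ratio test of all g SNPs against the intercept-only model
#' (chi-square, g df); for continuous traits, the overall F test of the
#' all-SNP linear model.
#'
#' @param G dosage matrix.
#' @param y phenotype.
#' @param trait `"binary"` or `"continuous"`.
#' @return a `gene_assoc` (htest) object.
#' @export
regression_gene_test <- function(G, y, trait = c("binary", "continuous")) {
  trait <- match.arg(trait)
  G <- as.matrix(G)
  keep <- apply(G, 2, stats::sd) > 0
  if (!any(keep))
    return(assoc_result(c(chisq = 0), c(df = ncol(G)), 1,
                        "regression gene test (degenerate)", length(y),
                        note = "all SNPs constant"))
  Gk <- G[, keep, drop = FALSE]
  if (trait == "binary") {
    res <- logistic_lrt(Gk, NULL, y, df = ncol(Gk),
                        "logistic regression gene test", length(y))
    return(res)
  }
  fit <- stats::lm(y ~ Gk)
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  assoc_result(c(F = unname(fs[1])), c(df1 = unname(fs[2]),
                                       df2 = unname(fs[3])),
               unname(p), "linear regression gene test (overall F)",
               length(y))
}
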