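#' SNP panel description
#'
#' Describes a panel of biallelic SNPs by minor-allele frequency, a partition
#' into LD blocks, and a target pairwise allelic correlation within each block.
#' Genotypes drawn from a panel are in Hardy-Weinberg equilibrium at each SNP;
#' within a block, haplotypes are drawn from a Gaussian copula whose latent
#' correlation is calibrated numerically so that the correlation between the
#' allele indicators of any two SNPs equals `r_within` for that block.
#' SNPs in different blocks are independent.
#'
#' @param mafs numeric vector of minor-allele frequencies, each in (0, 0.5].
#' @param blocks partition of the SNPs into LD blocks: a list of integer
#'   vectors covering `seq_along(mafs)` exactly once. `NULL` (default) puts
#'   every SNP in its own block (linkage equilibrium).
#' @param r_within target allelic correlation within each block; scalar or one
#'   value per block, each in `[0, 1)`.
#' @return an object of class `snp_panel`.
#' @export
snp_panel <- function(mafs, blocks = NULL, r_within = 0) {
  mafs <- as.numeric(mafs)
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  m <- length(mafs)
  if (is.null(blocks)) blocks <- as.list(seq_len(m))
  idx <- sort(unlist(blocks))
  if (!identical(idx, seq_len(m)))
    stop("blocks must partition 1..", m, " exactly once")
  r_within <- rep_len(as.numeric(r_within), length(blocks))
  if (any(r_within < 0 | r_within >= 1)) stop("r_within must lie in [0, 1)")
  structure(list(mafs = mafs, blocks = blocks, r_within = r_within),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel:", length(x$mafs), "SNPs in", length(x$blocks), "LD block(s)\n")
  cat("  MAF range: [", min(x$mafs), ",", max(x$mafs), "]\n")
  cat("  r within blocks:", paste(unique(x$r_within), collapse = ", "), "\n")
  invisible(x)
}

## Bivariate standard normal CDF P(Z1 < a, Z2 < b) with correlation rho,
## by one-dimensional quadrature; accurate to ~1e-10, ample for calibration.
pbvnorm <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((b - rho * z) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

## Latent Gaussian correlation giving allelic (indicator) correlation r for
## allele frequencies p1, p2. The indicator correlation at latent rho is
## (P11(rho) - p1 p2) / sqrt(p1 q1 p2 q2); solve for rho by root finding.
ld_latent_rho <- function(p1, p2, r) {
  if (r == 0) return(0)
  sd12 <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  alle_r <- function(rho)
    (pbvnorm(stats::qnorm(p1), stats::qnorm(p2), rho) - p1 * p2) / sd12
  r_max <- alle_r(0.9999)
  if (r > r_max + 1e-9)
    stop(sprintf(
      "target allelic correlation %.3f infeasible for MAFs (%.3f, %.3f); Gaussian-copula bound is %.3f",
      r, p1, p2, r_max))
  stats::uniroot(function(rho) alle_r(rho) - r,
                 interval = c(0, 0.9999), tol = 1e-9)$root
}

## Draw n haplotypes (rows) for one block: latent MVN thresholded at the
## allele-frequency quantile; allele coded 1 = minor.
sim_block_haplotypes <- function(n, mafs, r) {
  k <- length(mafs)
  if (r == 0 || k == 1) {
    H <- matrix(stats::rbinom(n * k, 1L, rep(mafs, each = n)), n, k)
    return(H)
  }
  rho <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    rho[i, j] <- rho[j, i] <- ld_latent_rho(mafs[i], mafs[j], r)
  diag(rho) <- 1
  L <- tryCatch(chol(rho), error = function(e) {
    ev <- eigen(rho, symmetric = TRUE)
    val <- pmax(ev$values, 1e-8)
    chol(ev$vectors %*% diag(val) %*% t(ev$vectors))
  })
  Z <- matrix(stats::rnorm(n * k), n, k) %*% L
  H <- matrix(0L, n, k)
  for (j in seq_len(k)) H[, j] <- as.integer(Z[, j] < stats::qnorm(mafs[j]))
  H
}

#' Simulate Hardy-Weinberg genotypes with block LD
#'
#' Draws two haplotypes per individual from the panel's Gaussian copula and
#' returns minor-allele dosages (0/1/2). Each SNP is in HWE at its MAF; the
#' allelic correlation between SNPs in the same block targets that block's
#' `r_within`; SNPs in different blocks are independent.
#'
#' @param panel an [snp_panel()].
#' @param n number of individuals (rows).
#' @param seed optional integer seed.
#' @return integer matrix `n` x `m` of dosages with column names `snp1..snpm`.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- length(panel$mafs)
  G <- matrix(0L, n, m)
  for (b in seq_along(panel$blocks)) {
    idx <- panel$blocks[[b]]
    mafs <- panel$mafs[idx]
    H1 <- sim_block_haplotypes(n, mafs, panel$r_within[b])
    H2 <- sim_block_haplotypes(n, mafs, panel$r_within[b])
    G[, idx] <- H1 + H2
  }
  colnames(G) <- paste0("snp", seq_len(m))
  G
}

#' Disease penetrance model
#'
#' Penetrance is `baseline * prod(GRR_l(x_l))` over the causal loci, where the
#' genotype relative risk for dosage x is `1 + effect*x` (additive) or
#' `effect^x` (multiplicative), and the baseline is calibrated so that the
#' expected population disease fraction equals `prevalence` under HWE at the
#' causal-locus MAFs (causal loci assumed in different LD blocks, hence
#' independent).
#'
#' @param kind `"null"`, `"additive"` or `"multiplicative"`.
#' @param effect per-allele effect: additive GRR increment (default 0.14) or
#'   multiplicative GRR factor (default 1.14); ignored for `"null"`.
#' @param prevalence population disease probability, default 0.1.
#' @param causal integer indices of the disease-susceptibility loci (empty for
#'   the null model).
#' @return an object of class `disease_model`.
#' @export
disease_model <- function(kind = c("null", "additive", "multiplicative"),
                          effect = NULL, prevalence = 0.1,
                          causal = integer(0)) {
  kind <- match.arg(kind)
  if (is.null(effect)) effect <- switch(kind, null = 0, additive = 0.14,
                                        multiplicative = 1.14)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (kind == "null" && length(causal))
    stop("null model must have no causal loci")
  structure(list(kind = kind, effect = effect, prevalence = prevalence,
                 causal = as.integer(causal)),
            class = "disease_model")
}

## Per-locus genotype relative risk for dosages 0,1,2.
grr_vector <- function(model) {
  switch(model$kind,
         null = c(1, 1, 1),
         additive = 1 + model$effect * (0:2),
         multiplicative = model$effect^(0:2))
}

## Baseline penetrance so that E[penetrance] = prevalence under HWE.
calibrate_baseline <- function(model, mafs) {
  grr <- grr_vector(model)
  e_grr <- 1
  for (l in model$causal) {
    p <- mafs[l]
    gf <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    e_grr <- e_grr * sum(gf * grr)
  }
  b <- model$prevalence / e_grr
  if (b * max(grr)^length(model$causal) > 1)
    stop("penetrance exceeds 1; model infeasible at prevalence ",
         model$prevalence)
  b
}

## Penetrance for each row of a dosage matrix.
penetrance <- function(G, model, baseline) {
  pen <- rep(baseline, nrow(G))
  grr <- grr_vector(model)
  for (l in model$causal) pen <- pen * grr[G[, l] + 1L]
  pen
}

#' Simulate a case-control study from a population
#'
#' Simulates `population_size` individuals with genotypes from `panel`,
#' assigns disease status by the penetrance model, and samples the requested
#' numbers of cases and controls without replacement.
#'
#' @param panel an [snp_panel()].
#' @param model a [disease_model()].
#' @param population_size simulated population size.
#' @param n_cases,n_controls numbers sampled from the affected/unaffected.
#' @param seed optional integer seed.
#' @return list with `genotypes` (dosage matrix, cases first), `status`
#'   (1 = case, 0 = control) and `baseline` (calibrated baseline penetrance).
#' @export
simulate_case_control <- function(panel, model, population_size = 1e5,
                                  n_cases = 1500, n_controls = 1500,
                                  seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"), inherits(model, "disease_model"))
  if (!is.null(seed)) set.seed(seed)
  baseline <- calibrate_baseline(model, panel$mafs)
  G <- simulate_genotypes(panel, population_size)
  pen <- penetrance(G, model, baseline)
  d <- stats::rbinom(population_size, 1L, pen)
  cases <- which(d == 1L)
  controls <- which(d == 0L)
  if (length(cases) < n_cases)
    stop(sprintf("population produced %d cases; %d requested",
                 length(cases), n_cases))
  if (length(controls) < n_controls)
    stop(sprintf("population produced %d controls; %d requested",
                 length(controls), n_controls))
  sel <- c(sample(cases, n_cases), sample(controls, n_controls))
  list(genotypes = G[sel, , drop = FALSE],
       status = rep(c(1L, 0L), c(n_cases, n_controls)),
       baseline = baseline)
}

#' Quantitative trait model with product and ratio terms
#'
#' The phenotype is a standard normal draw plus a sum of deterministic terms
#' evaluated on minor-allele dosages s (coded 0, 1, 2): product terms
#' `coef * s_a * s_b * ...` (main effects are one-SNP products) and ratio
#' terms `coef * (1 + s_a) / (1 + s_b)`. An empty model gives a pure N(0,1)
#' phenotype.
#'
#' @param terms list of product terms, each `list(coef = , snps = )`.
#' @param ratio_terms list of ratio terms, each
#'   `list(coef = , num = , den = )`.
#' @return an object of class `quant_trait_model`.
#' @export
quant_trait_model <- function(terms = list(), ratio_terms = list()) {
  for (t in terms)
    stopifnot(is.numeric(t$coef), length(t$snps) >= 1)
  for (t in ratio_terms)
    stopifnot(is.numeric(t$coef), length(t$num) == 1, length(t$den) == 1)
  structure(list(terms = terms, ratio_terms = ratio_terms),
            class = "quant_trait_model")
}

## Deterministic (noise-free) part of the trait for each sample.
trait_signal <- function(G, model) {
  n <- nrow(G)
  mu <- numeric(n)
  for (t in model$terms) {
    if (any(t$snps > ncol(G))) stop("SNP index out of range in trait term")
    contrib <- rep(t$coef, n)
    for (s in t$snps) contrib <- contrib * G[, s]
    mu <- mu + contrib
  }
  for (t in model$ratio_terms) {
    if (max(t$num, t$den) > ncol(G)) stop("SNP index out of range in ratio term")
    mu <- mu + t$coef * (1 + G[, t$num]) / (1 + G[, t$den])
  }
  mu
}

#' Simulate a quantitative trait
#'
#' @param G dosage matrix (samples x SNPs).
#' @param model a [quant_trait_model()].
#' @param seed optional integer seed.
#' @return numeric phenotype vector of length `nrow(G)`.
#' @export
simulate_quantitative <- function(G, model, seed = NULL) {
  stopifnot(inherits(model, "quant_trait_model"))
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(nrow(G)) + trait_signal(G, model)
}
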