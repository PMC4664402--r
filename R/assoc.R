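## Association tests built on cross-validated phenotype predictions.
## All tests return objects of class c("gene_assoc", "htest") so base R's
## htest print method applies.

assoc_result <- function(statistic, df, p.value, method, n,
                         estimate = NULL, note = NULL) {
  stat_name <- names(statistic)
  if (is.null(stat_name)) names(statistic) <- "statistic"
  if (!is.null(df)) {
    if (is.null(names(df)))
      names(df) <- if (length(df) == 2) c("df1", "df2") else "df"
  }
  structure(list(statistic = statistic, parameter = df,
                 p.value = unname(p.value), method = method,
                 estimate = estimate, n = n, note = note,
                 data.name = "cross-validated predictions"),
            class = c("gene_assoc", "htest"))
}

#' Joint association test for a quantitative trait
#'
#' Tests the joint association of the SNP set with a continuous phenotype via
#' the Pearson correlation between the cross-validated ensemble prediction
#' `P_final` and the observed phenotype `P_actual`.
#'
#' The default `"pooled"` form is the textbook statistic
#' `t = r * sqrt((N - 2)/(1 - r^2))` on `N - 2` df, computed across all
#' samples. Its calibration depends on how the predictions were made: under
#' classic k-fold training (`scheme = "kfold"` in [cv_ensemble()]) samples
#' in different folds mutually train each other's models, which inflates the
#' null variance of r by up to a factor of 2 and makes the test
#' anti-conservative — a property of any pooled statistic on reciprocally
#' cross-validated predictions, not of the ensemble specifically. With
#' `scheme = "rotational"` no two samples ever train each other's models and
#' the pooled t reference is calibrated. A warning is issued when the pooled
#' form is applied to `"kfold"` predictions. The `"stratified"` alternative
#' combines per-fold Fisher z statistics by Stouffer's method
#' (`Z = sum(atanh(r_k) * sqrt(n_k - 3)) / sqrt(K)`); it removes fold-mean
#' artifacts but the fold-level statistics remain mutually coupled under
#' `"kfold"` training, so it too is only fully calibrated with
#' `"rotational"` predictions.
#'
#' @param pred a [cv_ensemble()] result (continuous trait).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param method `"pooled"` (default) or `"stratified"`; see Details.
#' @return a `gene_assoc` (htest) object.
#' @export
assoc_continuous <- function(pred,
                             alternative = c("two.sided", "greater", "less"),
                             method = c("pooled", "stratified")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(inherits(pred, "cv_prediction"))
  n <- length(pred$P_actual)
  if (n < 4) stop("need at least 4 samples")
  if (stats::sd(pred$P_final) == 0 || stats::sd(pred$P_actual) == 0) {
    warning("constant prediction or phenotype; returning p = 1")
    return(assoc_result(c(t = 0), c(df = n - 2), 1,
                        "ensemble correlation test (degenerate)", n,
                        estimate = c(cor = 0), note = "constant input"))
  }
  r <- stats::cor(pred$P_final, pred$P_actual)
  if (method == "pooled") {
    if (identical(pred$scheme, "kfold"))
      warning("pooled correlation test on reciprocal k-fold predictions is ",
              "anti-conservative; use cv_ensemble(scheme = \"rotational\")")
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(t), n - 2),
                greater = stats::pt(t, n - 2, lower.tail = FALSE),
                less = stats::pt(t, n - 2))
    return(assoc_result(c(t = t), c(df = n - 2), p,
                        "ensemble correlation test (pooled)", n,
                        estimate = c(cor = r)))
  }
  ks <- sort(unique(pred$folds))
  z <- 0
  used <- 0
  for (k in ks) {
    idx <- pred$folds == k
    nk <- sum(idx)
    if (nk < 4) next
    pf <- pred$P_final[idx]
    pa <- pred$P_actual[idx]
    if (stats::sd(pf) == 0 || stats::sd(pa) == 0) next
    rk <- stats::cor(pf, pa)
    rk <- max(-1 + 1e-12, min(1 - 1e-12, rk))
    z <- z + atanh(rk) * sqrt(nk - 3)
    used <- used + 1
  }
  if (used == 0) {
    warning("no usable folds; returning p = 1")
    return(assoc_result(c(Z = 0), NULL, 1,
                        "ensemble correlation test (degenerate)", n,
                        estimate = c(cor = r), note = "constant folds"))
  }
  Z <- z / sqrt(used)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(Z)),
              greater = stats::pnorm(Z, lower.tail = FALSE),
              less = stats::pnorm(Z))
  assoc_result(c(Z = Z), NULL, p,
               "ensemble correlation test (fold-stratified)", n,
               estimate = c(cor = r))
}

## Log-likelihood of a fitted glm (binomial), from the deviance.
glm_loglik <- function(fit) -fit$deviance / 2

## Logistic fit with a flag when glm fails to converge or separates; in that
## case the linear predictor is restabilised with a tiny ridge penalty via
## repeated IRLS on an augmented design.
safe_logistic <- function(X, y) {
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial(),
                                     control = list(maxit = 100)))
  flagged <- !fit$converged || any(abs(stats::coef(fit)) > 30, na.rm = TRUE)
  if (flagged) {
    ## tiny-ridge refit: augment with 2 pseudo-observations per column
    Xm <- stats::model.matrix(~ ., data = data.frame(X))[, -1, drop = FALSE]
    lambda <- 1e-4
    k <- ncol(Xm)
    Xa <- rbind(Xm, diag(sqrt(lambda), k), -diag(sqrt(lambda), k))
    ya <- c(y, rep(0.5, 2 * k))
    w <- c(rep(1, length(y)), rep(1, 2 * k))
    rfit <- suppressWarnings(stats::glm.fit(cbind(1, Xa), ya, weights = w,
                                            family = stats::binomial()))
    eta <- cbind(1, Xm) %*% rfit$coefficients
    mu <- stats::plogis(eta)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    return(list(loglik = ll, flagged = TRUE))
  }
  list(loglik = glm_loglik(fit), flagged = FALSE)
}

## Likelihood-ratio chi-square between two regressor sets for a 0/1 outcome.
logistic_lrt <- function(X_full, X_null, y, df, method, n) {
  full <- safe_logistic(X_full, y)
  ll0 <- if (is.null(X_null)) {
    p0 <- mean(y)
    sum(y * log(p0) + (1 - y) * log(1 - p0))
  } else safe_logistic(X_null, y)$loglik
  stat <- max(0, 2 * (full$loglik - ll0))
  note <- if (full$flagged) "ridge-stabilised fit" else NULL
  assoc_result(c(chisq = stat), c(df = df),
               stats::pchisq(stat, df, lower.tail = FALSE),
               method, n, note = note)
}

#' Joint association test for case-control data
#'
#' Logistic regression of disease status on all g SNP dosages plus the
#' cross-validated ensemble prediction `P_final`, compared to an
#' intercept-only model by a likelihood-ratio test: `2(lik_full - lik_null)`
#' referred to a chi-square distribution with `g + 1` degrees of freedom.
#'
#' @param G dosage matrix (samples x SNPs).
#' @param pred a [cv_ensemble()] result (binary trait).
#' @param y 0/1 disease status.
#' @return a `gene_assoc` (htest) object.
#' @export
assoc_casecontrol <- function(G, pred, y) {
  stopifnot(inherits(pred, "cv_prediction"))
  G <- as.matrix(G)
  if (length(unique(y)) < 2) stop("both classes must be present")
  g <- ncol(G)
  X <- cbind(G, P_final = pred$P_final)
  if (all(apply(X, 2, stats::sd) == 0))
    return(assoc_result(c(chisq = 0), c(df = g + 1), 1,
                        "ensemble logistic LRT (degenerate)", length(y),
                        note = "constant regressors"))
  logistic_lrt(X, NULL, y, df = g + 1,
               "ensemble logistic LRT (case-control)", length(y))
}

#' Steiger Z statistic for dependent correlations
#'
#' Compares two correlations `r13` and `r12` that share variable 1 (here: the
#' observed phenotype correlated with two competing predictions), using
#' Fisher-transformed correlations and the Meng-Rosenthal-Rubin form:
#' `Z = (Z13 - Z12) * sqrt(N - 3) / sqrt(2 h (1 - r23))` with
#' `rm2 = (r12^2 + r13^2)/2`, `f = (1 - r23) / (2 - 2 rm2)` (capped at 1) and
#' `h = (1 - f * rm2) / (1 - rm2)`.
#'
#' @param r12,r13 correlations of the shared variable with each prediction.
#' @param r23 correlation between the two predictions.
#' @param n sample size (>= 4).
#' @return the Z statistic (positive when `r13 > r12`).
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (n < 4) stop("need n >= 4")
  if (any(abs(c(r12, r13)) >= 1))
    stop("degenerate correlation (|r| = 1); Fisher transform undefined")
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rm2 <- (r12^2 + r13^2) / 2
  if (rm2 >= 1) stop("rm2 must be < 1")
  f <- min(1, (1 - r23) / (2 - 2 * rm2))
  h <- (1 - f * rm2) / (1 - rm2)
  (z13 - z12) * sqrt(n - 3) / sqrt(2 * h * (1 - r23))
}

#' Covariate-adjusted association test for a quantitative trait
#'
#' Tests whether adding the SNPs to the covariates improves phenotype
#' prediction, by comparing (Steiger Z test for dependent correlations)
#' `cor(P_actual, P_final_all)` against `cor(P_actual, P_final_covariates)`,
#' where the two predictions come from ensembles trained with and without the
#' SNP variables. Positive Z means the genetic variables improve prediction.
#'
#' @param pred_all `cv_prediction` from SNPs + covariates.
#' @param pred_cov `cv_prediction` from covariates only.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `gene_assoc` (htest) object.
#' @export
assoc_adjusted_continuous <- function(pred_all, pred_cov,
                                      alternative = c("two.sided", "greater",
                                                      "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(pred_all, "cv_prediction"),
            inherits(pred_cov, "cv_prediction"))
  y <- pred_all$P_actual
  n <- length(y)
  r12 <- stats::cor(y, pred_cov$P_final)
  r13 <- stats::cor(y, pred_all$P_final)
  r23 <- stats::cor(pred_cov$P_final, pred_all$P_final)
  z <- steiger_z(r12, r13, r23, n)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  assoc_result(c(Z = z), NULL, p,
               "covariate-adjusted Steiger Z test (quantitative trait)", n,
               estimate = c(r_covariates = r12, r_all = r13, r_between = r23))
}

#' Covariate-adjusted association test for case-control data
#'
#' Logistic LRT of the full model (covariates + SNPs + `P_final_all` +
#' `P_final_covariates`) against the reduced model (covariates +
#' `P_final_covariates`), with `g + 1` degrees of freedom.
#'
#' @param G dosage matrix with g SNPs.
#' @param covariates covariate matrix.
#' @param pred_all,pred_cov `cv_prediction` objects from SNPs + covariates
#'   and covariates only.
#' @param y 0/1 disease status.
#' @return a `gene_assoc` (htest) object.
#' @export
assoc_adjusted_casecontrol <- function(G, covariates, pred_all, pred_cov, y) {
  G <- as.matrix(G)
  covariates <- as.matrix(covariates)
  if (length(unique(y)) < 2) stop("both classes must be present")
  g <- ncol(G)
  X_full <- cbind(covariates, G, P_all = pred_all$P_final,
                  P_cov = pred_cov$P_final)
  X_null <- cbind(covariates, P_cov = pred_cov$P_final)
  if (all(apply(G, 2, stats::sd) == 0) &&
      isTRUE(all.equal(pred_all$P_final, pred_cov$P_final)))
    return(assoc_result(c(chisq = 0), c(df = g + 1), 1,
                        "adjusted ensemble logistic LRT (degenerate)",
                        length(y), note = "no genetic signal available"))
  logistic_lrt(X_full, X_null, y, df = g + 1,
               "covariate-adjusted ensemble logistic LRT (case-control)",
               length(y))
}

## F statistic from nested OLS sums of squared errors; the added term has a
## single numerator degree of freedom.
fstat_from_sse <- function(sse0, sse1, n, v_model1) {
  df2 <- n - v_model1 - 1
  list(F = (sse0 - sse1) * df2 / sse1, df = c(1, df2))
}

## OLS SSE with collinear columns dropped; returns the effective number of
## explanatory variables actually fitted.
ols_sse <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  list(sse = sum(fit$residuals^2), v = fit$rank - 1,
       dropped = ncol(X) - (fit$rank - 1))
}

#' Multi-marker interaction test for a quantitative trait
#'
#' Tests for interaction effects among the SNPs by asking whether the
#' cross-validated ensemble prediction `P_ensemble` explains phenotype
#' variation beyond the SNPs and the cross-validated all-SNP linear
#' prediction `P_linear`. Model 1 regresses the phenotype on SNPs +
#' `P_linear` + `P_ensemble`; Model 0 omits `P_ensemble`. The statistic is
#' `F = (SSE0 - SSE1)(N - V1 - 1)/SSE1` with `(1, N - V1 - 1)` degrees of
#' freedom, `V1` the number of explanatory variables in Model 1.
#'
#' @param G dosage matrix.
#' @param p_linear,p_ensemble cross-validated predictions ([cv_linear()] and
#'   [cv_ensemble()] results, or plain numeric vectors).
#' @param y observed phenotype.
#' @return a `gene_assoc` (htest) object.
#' @export
interaction_continuous <- function(G, p_linear, p_ensemble, y) {
  G <- as.matrix(G)
  pl <- if (inherits(p_linear, "cv_prediction")) p_linear$P_final else p_linear
  pe <- if (inherits(p_ensemble, "cv_prediction")) p_ensemble$P_final
        else p_ensemble
  n <- length(y)
  X1 <- cbind(G, P_linear = pl, P_ensemble = pe)
  X0 <- cbind(G, P_linear = pl)
  m1 <- ols_sse(X1, y)
  m0 <- ols_sse(X0, y)
  if (n <= m1$v + 1) stop("need N > V_Model1 + 1")
  note <- if (m1$dropped > 0)
    sprintf("%d collinear column(s) dropped", m1$dropped) else NULL
  if (m1$sse == 0)
    return(assoc_result(c(F = Inf), c(df1 = 1, df2 = n - m1$v - 1), 0,
                        "ensemble interaction F test (perfect fit)", n,
                        note = "SSE of full model is zero"))
  fs <- fstat_from_sse(m0$sse, m1$sse, n, m1$v)
  f <- max(0, fs$F)
  assoc_result(c(F = f), c(df1 = fs$df[1], df2 = fs$df[2]),
               stats::pf(f, fs$df[1], fs$df[2], lower.tail = FALSE),
               "ensemble interaction F test (quantitative trait)", n,
               note = note)
}

#' Multi-marker interaction test for case-control data
#'
#' Logistic likelihood-ratio test of (SNPs + `P_linear` + `P_ensemble`)
#' against (SNPs + `P_linear`), with 1 degree of freedom regardless of the
#' number of SNPs.
#'
#' @inheritParams interaction_continuous
#' @param y 0/1 disease status.
#' @return a `gene_assoc` (htest) object.
#' @export
interaction_casecontrol <- function(G, p_linear, p_ensemble, y) {
  G <- as.matrix(G)
  pl <- if (inherits(p_linear, "cv_prediction")) p_linear$P_final else p_linear
  pe <- if (inherits(p_ensemble, "cv_prediction")) p_ensemble$P_final
        else p_ensemble
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (isTRUE(all.equal(pl, pe)))
    return(assoc_result(c(chisq = 0), c(df = 1), 1,
                        "ensemble interaction LRT (degenerate)", length(y),
                        note = "P_ensemble identical to P_linear"))
  logistic_lrt(cbind(G, P_linear = pl, P_ensemble = pe),
               cbind(G, P_linear = pl), y, df = 1,
               "ensemble interaction LRT (case-control)", length(y))
}

#' One-shot gene-based ensemble test
#'
#' Convenience wrapper running cross-validated prediction and the matching
#' test in one call. `mode = "assoc"` gives the joint association test,
#' `"adjusted"` the covariate-adjusted test (requires `covariates`), and
#' `"interaction"` the interaction test.
#'
#' @param G dosage matrix.
#' @param y phenotype (numeric or 0/1).
#' @param trait `"continuous"` or `"binary"`.
#' @param mode `"assoc"`, `"adjusted"` or `"interaction"`.
#' @param covariates optional covariate matrix.
#' @param control an [ensemble_control()].
#' @param seed optional integer seed.
#' @return a `gene_assoc` (htest) object.
#' @export
gene_ensemble_test <- function(G, y, trait = c("continuous", "binary"),
                               mode = c("assoc", "adjusted", "interaction"),
                               covariates = NULL,
                               control = ensemble_control(), seed = NULL) {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  G <- as.matrix(G)
  ## all prediction-based tests use rotational cross-fitting: reciprocal
  ## k-fold predictions are mutually coupled with the phenotype, which
  ## distorts every pooled statistic built on them (see cv_ensemble)
  if (mode == "assoc") {
    pred <- cv_ensemble(G, y, covariates, trait = trait, control = control,
                        scheme = "rotational")
    return(if (trait == "continuous") assoc_continuous(pred)
           else assoc_casecontrol(G, pred, y))
  }
  if (mode == "adjusted") {
    if (is.null(covariates)) stop("mode 'adjusted' requires covariates")
    folds <- make_folds(y, control$k, control$stratify, trait == "binary")
    pred_all <- cv_ensemble(G, y, covariates, trait = trait,
                            control = control, folds = folds,
                            scheme = "rotational")
    pred_cov <- cv_ensemble(NULL, y, covariates, trait = trait,
                            control = control, folds = folds,
                            scheme = "rotational")
    return(if (trait == "continuous")
      assoc_adjusted_continuous(pred_all, pred_cov)
      else assoc_adjusted_casecontrol(G, covariates, pred_all, pred_cov, y))
  }
  ## one shared fold partition and non-reciprocal (rotational) training for
  ## both predictors: any mutual-training pair couples P_ensemble with the
  ## phenotype and inflates the 1-df added-variable comparison
  folds <- make_folds(y, control$k, control$stratify, trait == "binary")
  p_lin <- cv_linear(G, y, covariates, trait = trait, k = control$k,
                     folds = folds, scheme = "rotational")
  p_ens <- cv_ensemble(G, y, covariates, trait = trait, control = control,
                       folds = folds, scheme = "rotational")
  if (trait == "continuous") interaction_continuous(G, p_lin, p_ens, y)
  else interaction_casecontrol(G, p_lin, p_ens, y)
}
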