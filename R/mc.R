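## Monte-Carlo estimation of Type-I error and power.

#' Method registry for the Monte-Carlo engine
#'
#' Returns a function `f(data, control)` mapping one simulated dataset (as
#' produced by [sim_dataset()]) to a `gene_assoc` result. Registered names:
#' `"ensemble"` (the ensemble association test), `"interaction"` (the
#' ensemble interaction test), `"regression"`, `"fisher"`, `"simes"`,
#' `"gates"`, `"vegas-sum"`, `"vegas-max"`.
#'
#' @param name method name, or a function `(data, control) -> gene_assoc`
#'   which is returned unchanged.
#' @return a function `(data, control)`.
#' @export
mc_method <- function(name) {
  if (is.function(name)) return(name)
  switch(name,
    ensemble = function(data, control) {
      if (data$trait_type == "continuous") {
        ## rotational cross-fitting keeps the pooled correlation t calibrated
        pred <- cv_ensemble(data$genotypes, data$phenotype,
                            trait = "continuous", control = control,
                            scheme = "rotational")
        assoc_continuous(pred)
      } else {
        pred <- cv_ensemble(data$genotypes, data$phenotype,
                            trait = "binary", control = control,
                            scheme = "rotational")
        assoc_casecontrol(data$genotypes, pred, data$phenotype)
      }
    },
    interaction = function(data, control) {
      ## one shared partition + non-reciprocal training for BOTH predictors:
      ## any mutual-training pair couples P_ensemble with the phenotype and
      ## inflates the 1-df added-variable test
      folds <- make_folds(data$phenotype, control$k, control$stratify,
                          data$trait_type == "binary")
      pl <- cv_linear(data$genotypes, data$phenotype,
                      trait = data$trait_type, k = control$k, folds = folds,
                      scheme = "rotational")
      pe <- cv_ensemble(data$genotypes, data$phenotype,
                        trait = data$trait_type, control = control,
                        folds = folds, scheme = "rotational")
      if (data$trait_type == "continuous")
        interaction_continuous(data$genotypes, pl, pe, data$phenotype)
      else interaction_casecontrol(data$genotypes, pl, pe, data$phenotype)
    },
    regression = function(data, control)
      regression_gene_test(data$genotypes, data$phenotype, data$trait_type),
    fisher = function(data, control)
      fisher_combination(snp_pvalues(data$genotypes, data$phenotype,
                                     data$trait_type)),
    simes = function(data, control)
      simes_test(snp_pvalues(data$genotypes, data$phenotype,
                             data$trait_type)),
    gates = function(data, control)
      gates_test(snp_pvalues(data$genotypes, data$phenotype,
                             data$trait_type)),
    `vegas-sum` = function(data, control)
      vegas_test(snp_pvalues(data$genotypes, data$phenotype,
                             data$trait_type), "sum"),
    `vegas-max` = function(data, control)
      vegas_test(snp_pvalues(data$genotypes, data$phenotype,
                             data$trait_type), "max"),
    stop("unknown method '", name, "'; registered: ensemble, interaction, ",
         "regression, fisher, simes, gates, vegas-sum, vegas-max")
  )
}

mc_estimate_obj <- function(k, reps_ok, reps, alpha, scenario, method, seed,
                            failures) {
  ci <- stats::binom.test(k, reps_ok)$conf.int
  structure(list(rate = 100 * k / reps_ok,
                 ci_low = 100 * ci[1], ci_high = 100 * ci[2],
                 rejections = k, reps = reps_ok, reps_requested = reps,
                 failures = failures, alpha = alpha,
                 scenario = scenario, method = method, seed = seed),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("%s | %s\n", x$scenario, x$method))
  cat(sprintf("  rejection rate at alpha = %g: %.2f%% [%.2f-%.2f] (%d/%d reps)\n",
              x$alpha, x$rate, x$ci_low, x$ci_high, x$rejections, x$reps))
  if (x$failures > 0)
    cat(sprintf("  %d replicate(s) failed and were excluded\n", x$failures))
  invisible(x)
}

## Derive one sub-seed per replicate from the master seed so that results do
## not depend on how replicates are scheduled.
derive_seeds <- function(seed, reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Monte-Carlo rejection rates for several methods on shared datasets
#'
#' Simulates `reps` independent replicate datasets from `scenario` and
#' applies every method in `methods` to each dataset (mirroring how a
#' simulation study computes several test columns from the same data).
#' Rejection is `p < alpha`, or `statistic >= threshold` when an empirical
#' threshold is supplied for a method.
#'
#' @param scenario a `sim_scenario`.
#' @param methods character vector of registry names (see [mc_method()]) or
#'   a named list of method functions.
#' @param reps number of replicate datasets.
#' @param alpha significance level, default 0.05.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param control an [ensemble_control()] passed to ensemble-based methods.
#' @param thresholds optional named numeric vector of empirical rejection
#'   thresholds (statistic scale) per method.
#' @param workers number of worker processes (forked via
#'   [parallel::mclapply()]); per-replicate seeds are derived once from the
#'   master seed, so the estimate is identical for any worker count.
#' @return a named list of `mc_estimate` objects, one per method.
#' @export
mc_estimate_rates <- function(scenario, methods, reps = 500, alpha = 0.05,
                              seed = 1, control = ensemble_control(),
                              thresholds = NULL, workers = 1) {
  stopifnot(inherits(scenario, "sim_scenario"), reps >= 1)
  if (is.character(methods)) {
    fns <- lapply(methods, mc_method)
    names(fns) <- methods
  } else {
    fns <- methods
    if (is.null(names(fns))) stop("methods list must be named")
  }
  seeds <- derive_seeds(seed, reps)
  one_rep <- function(i) {
    data <- sim_dataset(scenario, seeds[i])
    vapply(names(fns), function(mname) {
      res <- tryCatch(fns[[mname]](data, control), error = function(e) NULL)
      if (is.null(res)) return(NA)
      if (!is.null(thresholds) && mname %in% names(thresholds))
        unname(res$statistic[1]) >= thresholds[[mname]]
      else res$p.value < alpha
    }, logical(1))
  }
  rows <- if (workers > 1)
    parallel::mclapply(seq_len(reps), one_rep, mc.cores = workers)
  else lapply(seq_len(reps), one_rep)
  rej <- do.call(rbind, rows)
  colnames(rej) <- names(fns)
  out <- lapply(names(fns), function(mname) {
    ok <- !is.na(rej[, mname])
    failures <- sum(!ok)
    if (failures > 0.05 * reps)
      stop(sprintf("method '%s' failed on %d/%d replicates", mname,
                   failures, reps))
    mc_estimate_obj(sum(rej[ok, mname]), sum(ok), reps, alpha,
                    scenario$name, mname, seed, failures)
  })
  names(out) <- names(fns)
  out
}

#' Monte-Carlo rejection rate for a single method
#'
#' @inheritParams mc_estimate_rates
#' @param method a registry name or method function.
#' @param threshold optional empirical rejection threshold (statistic scale).
#' @return an `mc_estimate`.
#' @export
mc_estimate_rate <- function(scenario, method, reps = 500, alpha = 0.05,
                             seed = 1, control = ensemble_control(),
                             threshold = NULL, workers = 1) {
  mname <- if (is.character(method)) method else "custom"
  ths <- if (!is.null(threshold)) stats::setNames(threshold, mname)
  mc_estimate_rates(scenario, stats::setNames(list(mc_method(method)), mname),
                    reps = reps, alpha = alpha, seed = seed,
                    control = control, thresholds = ths,
                    workers = workers)[[1]]
}

#' Empirical rejection threshold from the null distribution
#'
#' Simulates the null distribution of a test statistic and returns its
#' empirical `(1 - alpha)` quantile, for use as an empirically calibrated
#' rejection threshold in [mc_estimate_rate()].
#'
#' @inheritParams mc_estimate_rate
#' @param scenario a null `sim_scenario`.
#' @return the threshold (numeric), with the simulated statistics attached as
#'   attribute `"stats"`.
#' @export
empirical_threshold <- function(scenario, method, reps = 1000, alpha = 0.05,
                                seed = 1, control = ensemble_control()) {
  stopifnot(reps >= 1)
  if (reps < 20 / alpha)
    warning(sprintf(
      "only %d null replicates for alpha = %g; threshold resolution is ~%.3g",
      reps, alpha, 1 / reps))
  fn <- mc_method(method)
  seeds <- derive_seeds(seed, reps)
  stats_ <- vapply(seq_len(reps), function(i) {
    data <- sim_dataset(scenario, seeds[i])
    unname(fn(data, control)$statistic[1])
  }, numeric(1))
  th <- unname(stats::quantile(stats_, 1 - alpha, type = 7))
  attr(th, "stats") <- stats_
  th
}

#' Observed-vs-theoretical chi-square quantile pairs
#'
#' Pairs the sorted empirical statistics with chi-square quantiles at
#' plotting positions `(i - 0.5) / n`, for QQ assessment of a test
#' statistic's null distribution.
#'
#' @param stats numeric vector of observed statistics.
#' @param df chi-square reference degrees of freedom.
#' @return data.frame with columns `theoretical` and `empirical`.
#' @export
qq_data <- function(stats, df) {
  stopifnot(length(stats) >= 1, df >= 1)
  n <- length(stats)
  data.frame(theoretical = stats::qchisq(((seq_len(n)) - 0.5) / n, df),
             empirical = sort(stats))
}

#' Slope of the empirical-vs-theoretical quantile line
#'
#' @param qq a [qq_data()] result.
#' @return least-squares slope of empirical on theoretical quantiles.
#' @export
qq_slope <- function(qq) {
  unname(stats::coef(stats::lm(empirical ~ theoretical, data = qq))[2])
}
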