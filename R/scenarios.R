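#' Simulation scenarios
#'
#' A scenario bundles a genotype panel recipe, a trait model and a sampling
#' design so that the Monte-Carlo engine can draw independent replicate
#' datasets from it. Two kinds exist: case-control scenarios (population
#' simulation with a penetrance model, then case/control sampling) and
#' quantitative scenarios (a fixed cohort with a normal-plus-signal trait).
#'
#' For case-control scenarios the per-SNP MAFs are redrawn uniformly from
#' `maf_range` for every replicate dataset (the study design fixes only the
#' range); quantitative scenarios use a fixed MAF for all SNPs.
#'
#' @param gene_size number of leading SNPs handed to the association test.
#' @param ld LD regime: `"le"` (linkage equilibrium), `"moderate"`
#'   (r = 0.5/0.4 alternating across blocks of 5) or `"strong"` (r = 0.9/0.8).
#' @param model_kind `"null"`, `"additive"` or `"multiplicative"`.
#' @param n_dsl number of disease-susceptibility loci; they sit at the first
#'   SNP of each successive block (positions 1, 6, 11, ...). Ignored for the
#'   null model.
#' @param population_size,n_cases,n_controls sampling design.
#' @param maf_range range for per-replicate uniform MAF draws.
#' @return an object of class `sim_scenario`.
#' @export
cc_scenario <- function(gene_size = 3,
                        ld = c("le", "moderate", "strong"),
                        model_kind = c("null", "additive", "multiplicative"),
                        n_dsl = NULL,
                        population_size = 1e5, n_cases = 1500,
                        n_controls = 1500, maf_range = c(0.1, 0.5)) {
  ld <- match.arg(ld)
  model_kind <- match.arg(model_kind)
  if (is.null(n_dsl))
    n_dsl <- if (model_kind == "null") 0L else max(1L, gene_size %/% 5L)
  structure(list(
    type = "case_control", trait_type = "binary",
    gene_size = as.integer(gene_size), ld = ld, model_kind = model_kind,
    n_dsl = as.integer(n_dsl), population_size = population_size,
    n_cases = n_cases, n_controls = n_controls, maf_range = maf_range,
    name = sprintf("cc-%s-%s-%dsnp", model_kind, ld, gene_size)),
    class = "sim_scenario")
}

#' @rdname cc_scenario
#' @param n_snps number of SNPs in the gene (all in linkage equilibrium).
#' @param trait_model a [quant_trait_model()]; `quant_trait_model()` (empty)
#'   is the null.
#' @param n cohort size.
#' @param maf fixed per-SNP minor-allele frequency (default 0.3). The
#'   presets override this per row: three-way-and-higher product traits use
#'   MAF 0.15, where dosage products are nearly pure epistasis (negligible
#'   marginal per-SNP signal), while pairwise-product and ratio traits keep
#'   MAF 0.3, where their terms carry the strong marginal components that
#'   make every test powerful. At common MAFs a triple product induces
#'   strong main effects; at rare MAFs its interaction variance vanishes.
#' @export
qt_scenario <- function(n_snps = 5, trait_model = quant_trait_model(),
                        n = 3000, maf = 0.3) {
  structure(list(
    type = "quantitative", trait_type = "continuous",
    gene_size = as.integer(n_snps), n = n, maf = maf,
    trait_model = trait_model,
    name = sprintf("qt-%dsnp", n_snps)),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario:", x$name, "\n")
  if (x$type == "case_control") {
    cat(sprintf("  %d SNPs (%s LD), %s model, %d DSL\n",
                x$gene_size, x$ld, x$model_kind, x$n_dsl))
    cat(sprintf("  %d cases / %d controls from population of %g\n",
                x$n_cases, x$n_controls, x$population_size))
  } else {
    cat(sprintf("  %d SNPs (LE, MAF %.2f), n = %d, %d product / %d ratio terms\n",
                x$gene_size, x$maf, x$n,
                length(x$trait_model$terms), length(x$trait_model$ratio_terms)))
  }
  invisible(x)
}

## Block layout used for the case-control LD regimes: blocks of 5 SNPs,
## within-block allelic r alternating (0.9, 0.8), (0.5, 0.4) or 0.
ld_blocks <- function(gene_size, ld) {
  if (ld == "le")
    return(list(blocks = NULL, r = 0))
  starts <- seq(1L, gene_size, by = 5L)
  blocks <- lapply(starts, function(s) s:min(s + 4L, gene_size))
  base <- switch(ld, strong = c(0.9, 0.8), moderate = c(0.5, 0.4))
  r <- rep_len(base, length(blocks))
  list(blocks = blocks, r = r)
}

#' Draw one replicate dataset from a scenario
#'
#' @param scenario a `sim_scenario`.
#' @param seed integer seed for this replicate.
#' @return list with `genotypes` (n x gene_size dosage matrix), `phenotype`
#'   (numeric or 0/1), and `trait_type`.
#' @export
sim_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (scenario$type == "case_control") {
    lb <- ld_blocks(scenario$gene_size, scenario$ld)
    mafs <- if (is.null(lb$blocks)) {
      stats::runif(scenario$gene_size,
                   scenario$maf_range[1], scenario$maf_range[2])
    } else {
      ## SNPs in strong LD share their allele frequency: one MAF per block
      ## (arbitrary per-SNP MAFs in a high-LD block are infeasible — the
      ## allelic correlation is bounded well below the target)
      m <- numeric(scenario$gene_size)
      for (b in lb$blocks)
        m[b] <- stats::runif(1, scenario$maf_range[1],
                             scenario$maf_range[2])
      m
    }
    panel <- snp_panel(mafs, blocks = lb$blocks, r_within = lb$r)
    causal <- if (scenario$n_dsl > 0)
      seq(1L, by = 5L, length.out = scenario$n_dsl) else integer(0)
    model <- disease_model(scenario$model_kind, prevalence = 0.1,
                           causal = causal)
    cc <- simulate_case_control(panel, model, scenario$population_size,
                                scenario$n_cases, scenario$n_controls)
    list(genotypes = cc$genotypes, phenotype = cc$status,
         trait_type = "binary")
  } else {
    panel <- snp_panel(rep(scenario$maf, scenario$gene_size))
    G <- simulate_genotypes(panel, scenario$n)
    y <- simulate_quantitative(G, scenario$trait_model)
    list(genotypes = G, phenotype = y, trait_type = "continuous")
  }
}

## Product-term shorthand for registry entries.
pt <- function(coef, ...) list(coef = coef, snps = c(...))

scenario_registry <- function() {
  ## Per-row MAFs: rows whose signal is a pure high-order product sit at
  ## MAF 0.15 (pure-epistasis regime); rows driven by pairwise products or
  ## ratio terms keep MAF 0.3 (their marginal components are the signal).
  t4 <- list(
    "T4-null-5"  = function() qt_scenario(5),
    "T4-null-10" = function() qt_scenario(10),
    "T4-0.2-product4" = function() qt_scenario(10, quant_trait_model(
      list(pt(0.20, 1, 2, 9, 10))), maf = 0.15),
    "T4-mixed-0.12-0.18" = function() qt_scenario(5, quant_trait_model(
      list(pt(0.002, 1), pt(0.002, 2), pt(0.12, 1, 2), pt(0.18, 3, 4)))),
    "T4-0.25-product" = function() qt_scenario(5, quant_trait_model(
      list(pt(0.25, 1, 2, 3))), maf = 0.15),
    "T4-0.3-product" = function() qt_scenario(5, quant_trait_model(
      list(pt(0.30, 1, 2, 3))), maf = 0.15),
    "T4-0.35-product" = function() qt_scenario(5, quant_trait_model(
      list(pt(0.35, 2, 3, 4))), maf = 0.15),
    "T4-0.65-product6" = function() qt_scenario(10, quant_trait_model(
      list(pt(0.65, 1, 2, 3, 8, 9, 10))), maf = 0.15),
    "T4-ratio" = function() qt_scenario(5, quant_trait_model(
      list(pt(0.002, 1), pt(0.002, 2), pt(0.3, 4, 5)),
      ratio_terms = list(list(coef = 0.2, num = 1, den = 2)))),
    "T4-last" = function() qt_scenario(5, quant_trait_model(
      list(pt(0.002, 1), pt(0.002, 2), pt(0.3, 1, 2), pt(0.2, 3, 4))))
  )
  cc <- list()
  for (tab in c("T1", "T2", "T3")) {
    ld <- switch(tab, T1 = "le", T2 = "moderate", T3 = "strong")
    for (g in c(3L, 10L, 30L)) {
      cc[[sprintf("%s-null-%d", tab, g)]] <-
        local({ ld0 <- ld; g0 <- g
          function() cc_scenario(g0, ld0, "null") })
      for (mk in c("additive", "multiplicative")) {
        nd <- c(`3` = 1L, `10` = 2L, `30` = 6L)[[as.character(g)]]
        cc[[sprintf("%s-%s-%d", tab, mk, g)]] <-
          local({ ld0 <- ld; g0 <- g; mk0 <- mk; nd0 <- nd
            function() cc_scenario(g0, ld0, mk0, nd0) })
      }
    }
  }
  ## Table 5 applies the interaction test to the Table 4 generative models.
  t5 <- t4
  names(t5) <- sub("^T4", "T5", names(t4))
  rows <- c("null-5", "null-10", "0.2-product4", "mixed-0.12-0.18",
            "0.25-product", "0.3-product", "0.35-product", "0.65-product6",
            "ratio", "last")
  aliases <- c(t4 = "T4", t5 = "T5")
  reg <- c(t4, cc, t5)
  for (tb in aliases)
    for (i in seq_along(rows))
      reg[[sprintf("%s-row%d", tb, i)]] <- reg[[sprintf("%s-%s", tb, rows[i])]]
  reg[["T5-last"]] <- reg[["T5-row10"]]
  reg
}

#' Look up a predefined simulation scenario
#'
#' Presets cover every row of the package's simulation study: `T1-*`/`T2-*`/
#' `T3-*` case-control rows (LE / moderate / strong LD; null, additive and
#' multiplicative models; gene sizes 3, 10, 30), and `T4-*`/`T5-*`
#' quantitative rows (nulls and epistatic trait models at n = 3000, MAF 0.3).
#' Row aliases `T4-row1` ... `T4-row10` (and `T5-*`) are also accepted.
#'
#' @param name preset name, e.g. `"T4-0.3-product"` or `"T1-null-30"`.
#' @return a `sim_scenario`.
#' @export
scenario_preset <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(sort(names(reg)), collapse = ", "))
  reg[[name]]()
}
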