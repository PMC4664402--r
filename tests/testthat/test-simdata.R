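## Genotype and phenotype simulator: HWE, LD targeting, penetrance
## calibration, trait-term evaluation, presets.

test_that("genotypes are in HWE at their MAF", {
  n <- 1e5
  for (maf in c(0.5, 0.3)) {
    G <- simulate_genotypes(snp_panel(maf), n, seed = 11)
    freq <- tabulate(G[, 1] + 1L, 3) / n
    expect_hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    se <- sqrt(expect_hwe * (1 - expect_hwe) / n)
    expect_true(all(abs(freq - expect_hwe) < 4 * se))
  }
})

test_that("within-block allelic correlation hits its target", {
  n <- 1e5
  ## independent SNPs: dosage correlation ~ 0
  G0 <- simulate_genotypes(snp_panel(c(0.3, 0.3)), n, seed = 12)
  expect_lt(abs(cor(G0[, 1], G0[, 2])), 3 / sqrt(n))
  ## strong LD at equal MAFs
  p <- snp_panel(c(0.3, 0.3), blocks = list(1:2), r_within = 0.9)
  G <- simulate_genotypes(p, n, seed = 13)
  expect_lt(abs(cor(G[, 1], G[, 2]) - 0.9), 0.03)
  ## mixed (feasible) MAFs, moderate LD
  p2 <- snp_panel(c(0.2, 0.3, 0.25), blocks = list(1:3), r_within = 0.5)
  G2 <- simulate_genotypes(p2, n, seed = 14)
  cc <- cor(G2)
  expect_true(all(abs(cc[upper.tri(cc)] - 0.5) < 0.05))
})

test_that("infeasible LD targets are reported", {
  p <- snp_panel(c(0.05 + 1e-9, 0.5), blocks = list(1:2), r_within = 0.9)
  expect_error(simulate_genotypes(p, 100, seed = 1), "infeasible")
})

test_that("penetrance model calibrates to prevalence and closed-form GRR", {
  mafs <- c(0.3, 0.2, 0.2)
  ## multiplicative: penetrance ratio x=2 vs x=0 is effect^2
  m <- disease_model("multiplicative", causal = 1L)
  b <- genestack:::calibrate_baseline(m, mafs)
  expect_equal((b * 1.14^2) / b, 1.2996, tolerance = 1e-12)
  ## additive with zero effect: flat penetrance
  m0 <- disease_model("additive", effect = 0, causal = 1L)
  b0 <- genestack:::calibrate_baseline(m0, mafs)
  pen <- genestack:::penetrance(rbind(c(0, 0, 0), c(2, 0, 0)), m0, b0)
  expect_equal(pen[1], pen[2])
  expect_equal(b0, 0.1)
  ## null model: population prevalence ~ 0.1
  cc <- simulate_case_control(snp_panel(mafs), disease_model("null"),
                              population_size = 5e4, n_cases = 100,
                              n_controls = 100, seed = 21)
  expect_equal(cc$baseline, 0.1)
})

test_that("population prevalence matches 0.1 under effect models", {
  set.seed(31)
  for (kind in c("additive", "multiplicative")) {
    panel <- snp_panel(runif(3, 0.1, 0.5))
    model <- disease_model(kind, causal = 1L)
    b <- genestack:::calibrate_baseline(model, panel$mafs)
    N <- 5e4
    G <- simulate_genotypes(panel, N)
    pen <- genestack:::penetrance(G, model, b)
    d <- rbinom(N, 1, pen)
    se <- sqrt(0.1 * 0.9 / N)
    expect_lt(abs(mean(d) - 0.1), 4 * se)
  }
})

test_that("case-control sampling errors name the shortfall", {
  expect_error(
    simulate_case_control(snp_panel(0.3), disease_model("null"),
                          population_size = 100, n_cases = 90,
                          n_controls = 5, seed = 1),
    "cases")
})

test_that("quantitative trait terms evaluate exactly", {
  ## product term with all dosages 2: 0.3 * 2^3 = 2.4
  G <- matrix(2L, 4, 5)
  m <- quant_trait_model(list(list(coef = 0.3, snps = 1:3)))
  expect_equal(genestack:::trait_signal(G, m), rep(2.4, 4))
  ## ratio term (1+2)/(1+0) * 0.2 = 0.6
  G2 <- cbind(s1 = c(2L, 2L), s2 = c(0L, 0L))
  m2 <- quant_trait_model(ratio_terms = list(list(coef = 0.2, num = 1,
                                                  den = 2)))
  expect_equal(genestack:::trait_signal(G2, m2), c(0.6, 0.6))
  ## empty model: standard normal phenotype
  G3 <- matrix(0L, 1e5, 1)
  y <- simulate_quantitative(G3, quant_trait_model(), seed = 41)
  expect_lt(abs(mean(y)), 3 / sqrt(1e5))
  expect_lt(abs(var(y) - 1), 3 * sqrt(2 / 1e5))
  ## out-of-range index errors
  expect_error(simulate_quantitative(G2, quant_trait_model(
    list(list(coef = 1, snps = 7)))), "out of range")
})

test_that("scenario presets are parameterized as documented", {
  sc <- scenario_preset("T4-0.3-product")
  expect_equal(sc$gene_size, 5L)
  expect_equal(sc$n, 3000)
  expect_equal(sc$trait_model$terms[[1]]$coef, 0.3)
  expect_equal(sc$trait_model$terms[[1]]$snps, 1:3)
  sc2 <- scenario_preset("T1-null-30")
  expect_equal(sc2$gene_size, 30L)
  expect_equal(sc2$ld, "le")
  expect_equal(sc2$model_kind, "null")
  expect_equal(sc2$n_cases, 1500)
  expect_equal(sc2$population_size, 1e5)
  expect_error(scenario_preset("X"), "unknown scenario")
  ## row aliases resolve to the same generative model
  expect_equal(scenario_preset("T4-row6")$trait_model,
               scenario_preset("T4-0.3-product")$trait_model)
})

test_that("simulation is deterministic given the seed", {
  p <- snp_panel(c(0.2, 0.4), blocks = list(1:2), r_within = 0.5)
  expect_identical(simulate_genotypes(p, 500, seed = 7),
                   simulate_genotypes(p, 500, seed = 7))
  d1 <- sim_dataset(scenario_preset("T4-null-5"), seed = 99)
  d2 <- sim_dataset(scenario_preset("T4-null-5"), seed = 99)
  expect_identical(d1, d2)
  cc1 <- simulate_case_control(p, disease_model("null"), 5000, 50, 50,
                               seed = 3)
  cc2 <- simulate_case_control(p, disease_model("null"), 5000, 50, 50,
                               seed = 3)
  expect_identical(cc1, cc2)
})
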