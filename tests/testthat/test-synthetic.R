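test_that("simulate_genotypes reproduces MAF, LD and determinism", {
  snp_map <- data.frame(snp = c("a", "b", "c", "d"), chrom = "chr1",
                        pos = c(1e6, 1.01e6, 2e6, 3e6),
                        maf = c(0.5, 0.5, 0.5, 0.2),
                        block = c(1, 1, NA, NA),
                        block_r = c(0.8, 0.8, 0, 0))
  cfg <- sim_config(n_samples = 5000, snp_map = snp_map,
                    gene_map = data.frame(gene = "G", chrom = "chr1",
                                          tss = 1e6, tes = 1.02e6,
                                          h2_cis = 0.1),
                    cis_effects = data.frame(gene = "G", snp = "a",
                                             effect = 1),
                    probe_map = data.frame(probe = "cg1", chrom = "chr2",
                                           pos = 1e6),
                    seed = 11)
  g <- simulate_genotypes(cfg)
  D <- g$dosages
  expect_true(all(D %in% 0:2))
  ## maf = 0.5 recovers allele frequency 0.5 +/- 0.02
  expect_equal(mean(D[, "a"]) / 2, 0.5, tolerance = 0.02 / 0.5)
  expect_lt(abs(mean(D[, "d"]) / 2 - 0.2), 0.02)
  ## within-block dosage correlation matches the generator's own
  ## latent-Gaussian construction (independent Monte-Carlo oracle)
  oracle <- withr::with_seed(99, {
    sh <- rnorm(2e5)
    z1 <- sqrt(0.8) * sh + sqrt(0.2) * rnorm(2e5)
    z2 <- sqrt(0.8) * sh + sqrt(0.2) * rnorm(2e5)
    cut_d <- function(z) (z > qnorm(0.25)) + (z > qnorm(0.75))
    cor(cut_d(z1), cut_d(z2))
  })
  expect_equal(cor(D[, "a"], D[, "b"]), oracle, tolerance = 0.05 / oracle)
  ## across blocks ~ 0
  expect_lt(abs(cor(D[, "a"], D[, "c"])), 0.05)
  ## same seed -> bit-identical
  expect_identical(D, simulate_genotypes(cfg)$dosages)
})

test_that("simulate_expression realizes the requested cis architecture", {
  ## null case: h2 = 0 gives R^2 compatible with noise
  cfg0 <- world_single_gene(n = 1000, h2 = 0, seed = 3)
  co0 <- simulate_cohort(cfg0)
  fit0 <- summary(lm(co0$expression[, "G1"] ~ co0$dosages))
  expect_gt(pf(fit0$fstatistic[1], fit0$fstatistic[2], fit0$fstatistic[3],
               lower.tail = FALSE), 0.01)
  ## single causal SNP, h2 = 0.04, n = 4000: direct OLS oracle on the
  ## true SNP recovers R^2 = 0.04 +/- 0.01
  cfg <- world_single_gene(n = 4000, h2 = 0.04, seed = 4)
  co <- simulate_cohort(cfg)
  r2 <- summary(lm(co$expression[, "G1"] ~ co$dosages[, "s3"]))$r.squared
  expect_equal(r2, 0.04, tolerance = 0.01 / 0.04)
  ## total variance ~ 1
  expect_equal(var(co$expression[, "G1"]), 1, tolerance = 0.1)
})

test_that("cohort covariate effects separate group means by construction", {
  cfg <- world_single_gene(n = 2000, h2 = 0.1, seed = 5)
  cfg$covariate_effects <- list(
    expression = data.frame(covariate = "cohort", gene = "G1",
                            effect = 1))
  co <- simulate_cohort(cfg)
  mu <- tapply(co$expression[, "G1"], co$covariates$cohort, mean)
  expect_equal(unname(diff(mu)), 1, tolerance = 0.15)
})

test_that("simulate_methylation injects trans effects and stays on budget", {
  cfg <- world_single_gene(n = 3000, h2 = 0.3, phi = 0.7, seed = 6)
  co <- simulate_cohort(cfg)
  ## effect present with the right sign and magnitude (OLS oracle)
  b <- coef(lm(co$methylation[, "cg01"] ~ scale(co$expression[, "G1"])))[2]
  expect_equal(unname(b), 0.7, tolerance = 0.1)
  ## null probes have unit variance and no association
  p <- summary(lm(co$methylation[, "cg02"] ~ co$expression[, "G1"]))
  expect_gt(p$coefficients[2, 4], 0.001)
  cfg_bad <- cfg
  cfg_bad$trans_map$phi <- 5
  expect_error(
    simulate_methylation(list(latent = co$expression), co$dosages,
                         cfg_bad),
    "variance budget")
})

test_that("a cis trans_map pair is rejected at config time", {
  expect_error(
    sim_config(
      n_samples = 100,
      snp_map = data.frame(snp = "s1", chrom = "chr1", pos = 1.01e6,
                           maf = 0.3),
      gene_map = data.frame(gene = "G1", chrom = "chr1", tss = 1.00e6,
                            tes = 1.05e6, h2_cis = 0.1),
      cis_effects = data.frame(gene = "G1", snp = "s1", effect = 1),
      trans_map = data.frame(gene = "G1", probe = "cg1", phi = 1),
      probe_map = data.frame(probe = "cg1", chrom = "chr1", pos = 6e6)),
    "trans criterion")
})

test_that("the generator is deterministic and carries truth separately", {
  cfg <- world_shared_pair(n = 300, seed = 7)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$dosages, c2$dosages)
  expect_identical(c1$methylation, c2$methylation)
  expect_identical(c1$truth$genetic_value, c2$truth$genetic_value)
  expect_true(all(c("trans_map", "cis_effects", "genetic_value") %in%
                    names(c1$truth)))
})

test_that("shared-eQTL scenario produces correlated true instruments", {
  cfg <- world_shared_pair(n = 2000, share = 0.8, seed = 8)
  co <- simulate_cohort(cfg)
  r <- cor(co$truth$genetic_value[, "GA"], co$truth$genetic_value[, "GB"])
  expect_gt(r, 0.5)
  expect_equal(r, 0.8, tolerance = 0.1)
  ## both genes marginally associated with the target before conditioning
  p <- vapply(c("GA", "GB"), function(g)
    summary(lm(co$methylation[, "cg01"] ~
                 co$truth$genetic_value[, g]))$coefficients[2, 4],
    numeric(1))
  expect_true(all(p < 1e-6))
})

test_that("cell-composition confounding disappears when the latent is partialled out", {
  cfg <- world_cell_conf(n = 3000, seed = 9)
  co <- simulate_cohort(cfg)
  ## confounded: expression and methylation correlate
  p0 <- summary(lm(co$methylation[, "cg01"] ~
                     co$expression[, "G1"]))$coefficients[2, 4]
  expect_lt(p0, 1e-10)
  ## oracle OLS: conditioning on the true cell latent removes it
  p1 <- summary(lm(co$methylation[, "cg01"] ~ co$expression[, "G1"] +
                     co$truth$cell_latent))$coefficients[2, 4]
  expect_gt(p1, 0.001)
  ## cell fractions are a simplex
  cf <- as.matrix(co$covariates[, c("cf1", "cf2", "cf3")])
  expect_true(all(cf > 0))
  expect_equal(rowSums(cf), rep(1, nrow(cf)), tolerance = 1e-12)
})

test_that("variance components are realized within Monte-Carlo tolerance", {
  cfg <- world_single_gene(n = 5000, h2 = 0.25, seed = 10)
  co <- simulate_cohort(cfg)
  expect_equal(var(co$truth$genetic_value[, "G1"]), 0.25, tolerance = 0.02)
  expect_equal(var(co$expression[, "G1"]), 1, tolerance = 0.06)
})

test_that("beta-scale methylation is squashed to (0,1) and flagged", {
  cfg <- world_single_gene(n = 200, h2 = 0.1, seed = 12)
  cfg$methylation_scale <- "beta"
  co <- simulate_cohort(cfg)
  expect_true(all(co$methylation > 0 & co$methylation < 1))
  expect_equal(co$methylation_scale, "beta")
})
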