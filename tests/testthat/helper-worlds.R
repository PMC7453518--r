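## Small stated worlds used across the suite; everything is built in code.

## One gene with a single causal cis SNP among n_cis candidates, plus a
## trans probe (phi) and a few null probes on another chromosome.
world_single_gene <- function(n = 1000, h2 = 0.2, n_cis = 6, phi = NULL,
                              n_null_probes = 4, seed = 1L, maf = 0.3,
                              causal_snp = "s3") {
  snp_map <- data.frame(snp = paste0("s", seq_len(n_cis)), chrom = "chr1",
                        pos = round(seq(1.00e6, 1.08e6,
                                        length.out = n_cis)),
                        maf = maf, block = NA, block_r = 0)
  gene_map <- data.frame(gene = "G1", chrom = "chr1", tss = 1.02e6,
                         tes = 1.05e6, h2_cis = h2)
  cis_effects <- data.frame(gene = "G1", snp = causal_snp, effect = 1)
  probe_map <- data.frame(
    probe = sprintf("cg%02d", seq_len(n_null_probes + 1)),
    chrom = "chr2",
    pos = round(seq(5e6, 40e6, length.out = n_null_probes + 1)))
  trans_map <- if (!is.null(phi))
    data.frame(gene = "G1", probe = "cg01", phi = phi)
  sim_config(n_samples = n, snp_map = snp_map, gene_map = gene_map,
             cis_effects = cis_effects, trans_map = trans_map,
             probe_map = probe_map, seed = seed)
}

## The classic bystander situation: gene A causal for one trans probe,
## gene B a neighbour sharing a cis eQTL so their instruments correlate
## ~ `share`; remaining probes are null.
world_shared_pair <- function(n = 600, share = 0.8, h2 = 0.3, phi = 1,
                              n_null_probes = 6, seed = 1L) {
  snp_map <- data.frame(snp = c("sA", "sShared", "sB"), chrom = "chr1",
                        pos = c(0.99e6, 1.025e6, 1.06e6),
                        maf = c(0.3, 0.35, 0.3), block = NA, block_r = 0)
  gene_map <- data.frame(gene = c("GA", "GB"), chrom = "chr1",
                         tss = c(1.00e6, 1.03e6), tes = c(1.02e6, 1.05e6),
                         h2_cis = h2)
  cis_effects <- data.frame(gene = c("GA", "GB"), snp = c("sA", "sB"),
                            effect = 1)
  probe_map <- data.frame(
    probe = sprintf("cg%02d", seq_len(n_null_probes + 1)),
    chrom = "chr2",
    pos = round(seq(5e6, 45e6, length.out = n_null_probes + 1)))
  trans_map <- data.frame(gene = "GA", probe = "cg01", phi = phi)
  sim_config(n_samples = n, snp_map = snp_map, gene_map = gene_map,
             cis_effects = cis_effects, trans_map = trans_map,
             probe_map = probe_map,
             scenarios = list(scenario_shared_eqtl("sShared", "GA", "GB",
                                                   share = share)),
             seed = seed)
}

## Cell-composition confounding: a SNP drives the true cell latent, which
## feeds both one gene's expression and one probe's methylation; no real
## expression-to-methylation effect exists.
world_cell_conf <- function(n = 800, seed = 1L, n_null_probes = 5) {
  snp_map <- data.frame(snp = c("s1", "s2"), chrom = "chr1",
                        pos = c(1.01e6, 1.04e6), maf = c(0.3, 0.25),
                        block = NA, block_r = 0)
  gene_map <- data.frame(gene = "G1", chrom = "chr1", tss = 1.00e6,
                         tes = 1.03e6, h2_cis = 0)
  cis_effects <- data.frame(gene = character(), snp = character(),
                            effect = numeric())
  probe_map <- data.frame(
    probe = sprintf("cg%02d", seq_len(n_null_probes + 1)),
    chrom = "chr2",
    pos = round(seq(5e6, 45e6, length.out = n_null_probes + 1)))
  sim_config(n_samples = n, snp_map = snp_map, gene_map = gene_map,
             cis_effects = cis_effects, probe_map = probe_map,
             scenarios = list(scenario_cell_confounder(
               "s1", "G1", "cg01", snp_share = 0.5,
               cell_to_expr = 0.6, cell_to_meth = 0.7)),
             seed = seed)
}

## End-to-end pipeline run into a throwaway directory.
run_mini <- function(config, seed = 1L, wbc_snps = character(), ...) {
  co <- simulate_cohort(config)
  run_pipeline(co, tempfile("gimeth_run_"),
               pipeline_config(seed = seed, wbc_snps = wbc_snps, ...))
}

## Normal-equations OLS oracle: coefficients and the focal predictor's
## standard error computed from first principles.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = drop(b), se = se, df = length(y) - ncol(X))
}

## Exhaustive hypergeometric two-sided p oracle via binomial coefficients
## (independent of dhyper): sums P(tables with same margins) over tables
## no more probable than the observed one.
fisher_oracle_p <- function(a, b, c_, d) {
  m <- a + b; k <- a + c_; N <- a + b + c_ + d
  support <- max(0, k - (N - m)):min(k, m)
  logp <- lchoose(m, support) + lchoose(N - m, k - support) - lchoose(N, k)
  p_obs <- exp(lchoose(m, a) + lchoose(N - m, k - a) - lchoose(N, k))
  min(1, sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)]))
}
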