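test_that("prune_correlated follows the greedy mean-correlation rule", {
  set.seed(8)
  n <- 2000
  ## engineered correlations: r(1,2) ~ 0.99, r(1,3) ~ 0.3, r(2,3) ~ 0.1
  u <- rnorm(n); v <- rnorm(n); w <- rnorm(n)
  x1 <- u + 0.25 * w
  x2 <- u + 0.08 * v
  x3 <- 0.33 * u + w
  X <- cbind(a = x1, b = x2, c = x3)
  cm <- abs(cor(X))
  expect_gt(cm["a", "b"], 0.95)
  ## column "a" has the larger mean correlation and is removed
  expect_setequal(prune_correlated(X, 0.95), c("b", "c"))
  ## all below cutoff: unchanged
  Y <- cbind(p = rnorm(50), q = rnorm(50))
  expect_equal(prune_correlated(Y, 0.95), c("p", "q"))
  ## duplicated column: exactly one of the pair removed
  Z <- cbind(d1 = u, d2 = u, e = v)
  expect_setequal(prune_correlated(Z, 0.95), c("d2", "e"))
})

test_that("neighbour contexts respect the 1 Mb window and record max |r|", {
  set.seed(9)
  gm <- data.frame(gene = c("A", "B", "C", "D"),
                   chrom = c("chr1", "chr1", "chr1", "chr2"),
                   tss = c(1e6, 1.8e6, 5e6, 1e6),
                   tes = c(1.1e6, 1.9e6, 5.1e6, 1.1e6))
  gi <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, gm$gene))
  ctx <- neighbour_contexts(gi, gm)
  expect_equal(ctx$A$neighbours, "B")   # C is 3.9 Mb away, D other chrom
  expect_equal(ctx$C$neighbours, character())
  expect_equal(ctx$D$neighbours, character())
  expect_equal(ctx$A$max_r, abs(cor(gi[, "A"], gi[, "B"])))
})

test_that("conditional_scan: orthogonal neighbours leave phi unchanged; r = 1 drops", {
  set.seed(10)
  n <- 500
  gi_a <- rnorm(n)
  gi_b <- drop(qr.resid(qr(cbind(1, gi_a)), rnorm(n)))  # orthogonal
  gi <- cbind(A = gi_a, B = gi_b)
  meth <- matrix(0.3 * gi_a + rnorm(n), ncol = 1,
                 dimnames = list(NULL, "cg1"))
  gm <- data.frame(gene = c("A", "B"), chrom = "chr1",
                   tss = c(1e6, 1.5e6), tes = c(1.1e6, 1.6e6))
  ctx <- neighbour_contexts(gi, gm)
  rec <- data.table::data.table(gene = "A", probe = "cg1",
                                phi = NA_real_, z = 0)
  cal <- identity_calibration()
  out <- conditional_scan(rec, gi, meth, NULL, ctx, cal, 1e-4)
  marg <- linear_assoc(meth[, 1], gi_a)
  expect_equal(out$phi_cond, marg$beta, tolerance = 1e-8)
  ## duplicated instrument as neighbour: excluded by the r > 0.95 rule
  gi2 <- cbind(A = gi_a, B = gi_a)
  ctx2 <- neighbour_contexts(gi2, gm)
  out2 <- conditional_scan(rec, gi2, meth, NULL, ctx2, cal, 1e-4)
  expect_true(out2$dropped_corr95)
})

test_that("residual_pleiotropy_filter applies both clauses", {
  set.seed(11)
  n <- 600
  shared <- rnorm(n)
  gi <- cbind(A = shared + 0.5 * rnorm(n), B = shared + 0.5 * rnorm(n))
  expr <- cbind(A = gi[, "A"] + rnorm(n), B = gi[, "B"] + rnorm(n))
  gm <- data.frame(gene = c("A", "B"), chrom = "chr1",
                   tss = c(1e6, 1.5e6), tes = c(1.1e6, 1.6e6))
  ctx <- neighbour_contexts(gi, gm)
  ## constructed records: both genes share target cg1 at the gene level
  rec <- data.table::data.table(
    gene = c("A", "B"), probe = "cg1", p_cond = 1e-12,
    dropped_corr95 = FALSE, conditional_sig = TRUE)
  ## A's GI strongly predicts B's expression (F >> 5) and the target sets
  ## intersect, so both directions of the exclusion fire
  out <- residual_pleiotropy_filter(rec, gi, expr, NULL, ctx,
                                    gene_threshold = 1e-7)
  expect_true(all(out$dropped_residual_pleiotropy))
  ## F clause unmet (huge cutoff): retained
  out2 <- residual_pleiotropy_filter(rec, gi, expr, NULL, ctx,
                                     gene_threshold = 1e-7, f_cut = 1e9)
  expect_false(any(out2$dropped_residual_pleiotropy))
  ## shared CpG but weak prediction: retained (F <= 5 clause)
  gi_w <- cbind(A = rnorm(n), B = rnorm(n))
  ctx_w <- neighbour_contexts(gi_w, gm)
  out_w <- residual_pleiotropy_filter(rec, gi_w, expr, NULL, ctx_w,
                                      gene_threshold = 1e-7)
  expect_false(any(out_w$dropped_residual_pleiotropy))
  ## no significant neighbour (other chromosome): retained
  gm3 <- data.frame(gene = c("A", "B"), chrom = c("chr1", "chr5"),
                    tss = c(1e6, 1e6), tes = c(1.1e6, 1.1e6))
  ctx3 <- neighbour_contexts(gi, gm3)
  out3 <- residual_pleiotropy_filter(rec, gi, expr, NULL, ctx3,
                                     gene_threshold = 1e-7)
  expect_false(any(out3$dropped_residual_pleiotropy))
})

test_that("long_range_filter re-tests only same-chromosome multi-gene CpGs", {
  set.seed(12)
  n <- 700
  shared <- rnorm(n)
  gi <- cbind(A = shared + 0.8 * rnorm(n), B = shared + 0.8 * rnorm(n))
  ## only A is causal for cg1
  meth <- matrix(0.5 * scale(gi[, "A"]) + 0.6 * rnorm(n), ncol = 1,
                 dimnames = list(NULL, "cg1"))
  cal <- identity_calibration()
  ## same chromosome, far apart (not neighbours)
  gm <- data.frame(gene = c("A", "B"), chrom = "chr1",
                   tss = c(1e6, 80e6), tes = c(1.1e6, 80.1e6))
  ctx <- neighbour_contexts(gi, gm)
  rec <- run_scan(gi, meth, NULL, gm,
                  data.frame(probe = "cg1", chrom = "chr2", pos = 1e6))
  rec <- apply_calibration(rec, cal)
  rec <- conditional_scan(rec, gi, meth, NULL, ctx, cal, 1e-4)
  out <- long_range_filter(rec, gi, meth, NULL, ctx, cal, 1e-4, gm)
  expect_false(out$dropped_longrange[out$gene == "A"])
  expect_true(out$dropped_longrange[out$gene == "B"])
  ## different chromosomes: never re-tested
  gm2 <- data.frame(gene = c("A", "B"), chrom = c("chr1", "chr3"),
                    tss = c(1e6, 80e6), tes = c(1.1e6, 80.1e6))
  out2 <- long_range_filter(rec, gi, meth, NULL,
                            neighbour_contexts(gi, gm2), cal, 1e-4, gm2)
  expect_false(any(out2$dropped_longrange))
})

test_that("wbc_filter is a no-op with an empty list and warns on missing SNPs", {
  set.seed(13)
  n <- 400
  gi <- cbind(A = rnorm(n))
  meth <- matrix(0.4 * gi[, "A"] + rnorm(n), ncol = 1,
                 dimnames = list(NULL, "cg1"))
  gm <- data.frame(gene = "A", chrom = "chr1", tss = 1e6, tes = 1.1e6)
  ctx <- neighbour_contexts(gi, gm)
  cal <- identity_calibration()
  rec <- run_scan(gi, meth, NULL, gm,
                  data.frame(probe = "cg1", chrom = "chr2", pos = 1e6))
  rec <- apply_calibration(rec, cal)
  rec <- conditional_scan(rec, gi, meth, NULL, ctx, cal, 1e-4)
  rec <- residual_pleiotropy_filter(rec, gi, cbind(A = rnorm(n)), NULL,
                                    ctx, 1e-3)
  rec <- long_range_filter(rec, gi, meth, NULL, ctx, cal, 1e-4, gm)
  D <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "s1"))
  out0 <- wbc_filter(rec, character(), D, gi, meth, NULL, ctx, cal, 1e-4)
  expect_true(all(out0$final))
  ## an orthogonal SNP leaves significance unchanged
  out1 <- wbc_filter(rec, "s1", D, gi, meth, NULL, ctx, cal, 1e-4)
  expect_true(all(out1$final))
  expect_warning(
    wbc_filter(rec, c("s1", "ghost"), D, gi, meth, NULL, ctx, cal, 1e-4),
    "ghost")
})

test_that("the cascade is monotone and accounts for every record", {
  res <- run_mini(world_shared_pair(n = 600, seed = 14))
  rec <- res$cascade$records
  ## final => conditional_sig => marginal_sig
  expect_true(all(rec$conditional_sig[rec$final]))
  expect_true(all(rec$marginal_sig[rec$final]))
  ## at most one dropped_* flag per record
  drops <- rec$dropped_corr95 + rec$dropped_residual_pleiotropy +
    rec$dropped_longrange + rec$dropped_wbc
  expect_true(all(drops <= 1))
  ## accounting conserves marginal records
  acc <- res$cascade$accounting
  get <- function(s) acc$records[acc$stage == s]
  expect_equal(get("marginal"),
               get("final") + get("corr95") + get("not_conditional") +
                 get("residual_pleiotropy") + get("longrange") + get("wbc"))
})
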