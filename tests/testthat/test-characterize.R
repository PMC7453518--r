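test_that("direction_skew runs exact binomial tests with BH control", {
  signs <- list(all_up = rep(1, 19),
                balanced = rep(c(1, -1), 5),
                too_few = rep(1, 9))
  out <- direction_skew(signs)
  ## 19/0: exact two-sided p = 2 * 0.5^19
  expect_equal(out$p[out$gene == "all_up"], 2 * 0.5^19, tolerance = 1e-12)
  expect_equal(out$p[out$gene == "balanced"], 1)
  expect_false("too_few" %in% out$gene)
  expect_equal(out$direction[out$gene == "all_up"], "increase")
  expect_equal(out$p_adjusted, bh_adjust(out$p))
})

test_that("collapse_regions chains probes below 1 kb and is order-invariant", {
  pp <- data.frame(chrom = "chr1", pos = c(100, 900, 2500))
  out <- collapse_regions(pp)
  expect_equal(out$n_regions, 2)
  expect_equal(out$coloc_fraction, 2 / 3)
  ## singleton
  out1 <- collapse_regions(data.frame(chrom = "chr1", pos = 5))
  expect_equal(out1$n_regions, 1)
  expect_equal(out1$coloc_fraction, 0)
  ## order invariance and idempotence (regions re-collapse to themselves)
  out2 <- collapse_regions(pp[c(3, 1, 2), ])
  expect_equal(out2$regions, out$regions)
  again <- collapse_regions(data.frame(chrom = out$regions$chrom,
                                       pos = out$regions$start))
  expect_equal(again$n_regions, out$n_regions)
  ## exactly 1 kb apart does not chain (strict <)
  out3 <- collapse_regions(data.frame(chrom = "chr1", pos = c(0, 1000)))
  expect_equal(out3$n_regions, 2)
})

test_that("fisher_enrichment matches the enumeration oracle and fisher.test", {
  universe <- paste0("u", 1:1000)
  hits <- universe[1:100]
  ann <- universe[c(1:10, 101:110)]     # a = 10, b = 90, c = 10, d = 890
  e <- fisher_enrichment(hits, ann, universe)
  expect_equal(unlist(e[, c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 90, 10, 890))
  expect_equal(e$odds_ratio, (10 * 890) / (90 * 10), tolerance = 1e-12)
  expect_equal(e$p, fisher_oracle_p(10, 90, 10, 890), tolerance = 1e-12)
  expect_equal(e$p,
               fisher.test(matrix(c(10, 90, 10, 890), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  ## equal hit frequency inside/outside the annotation: OR = 1
  ann2 <- c(universe[1:10], universe[101:190])
  expect_equal(fisher_enrichment(hits, ann2, universe)$odds_ratio, 1)
  ## zero cell: Haldane-Anscombe OR, exact p unchanged
  e0 <- fisher_enrichment(universe[1:5], universe[1:5], universe[1:50])
  expect_equal(e0$odds_ratio, (5.5 * 45.5) / (0.5 * 0.5))
  expect_equal(e0$p, fisher_oracle_p(5, 0, 0, 45), tolerance = 1e-12)
  expect_error(fisher_enrichment("a", "a", character()), "empty universe")
})

test_that("fisher_enrichment equals exhaustive enumeration on small tables", {
  ## every 2x2 table with total N <= 12, against the lchoose oracle
  for (N in 2:12) {
    parts <- expand.grid(a = 0:N, b = 0:N, c_ = 0:N)
    parts <- parts[rowSums(parts) <= N, ]
    for (i in seq_len(nrow(parts))) {
      a <- parts$a[i]; b <- parts$b[i]; c_ <- parts$c_[i]
      d <- N - a - b - c_
      expect_equal(gimeth:::.fisher_p(a, b, c_, d),
                   fisher_oracle_p(a, b, c_, d), tolerance = 1e-10)
    }
  }
})

test_that("simes_combine and bh_adjust follow their definitions", {
  expect_equal(simes_combine(0.2), 0.2)
  expect_equal(simes_combine(c(0.01, 0.02, 0.03)), 0.03)
  expect_equal(simes_combine(c(0.04, 0.5)), 0.08)
  expect_error(simes_combine(numeric()), "empty")
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    s <- simes_combine(p)
    expect_gte(s, min(p))
    expect_lte(s, length(p) * min(p) + 1e-15)
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("gc_matched_background matches the target GC histogram", {
  universe <- data.frame(probe = paste0("p", 1:400),
                         gc = rep(c(0.32, 0.62), each = 200))
  ## all targets in one bin: background entirely from that bin
  bg <- gc_matched_background(paste0("p", 1:20), universe,
                              n_background = 500, seed = 1)
  expect_true(all(bg %in% paste0("p", 1:200)))
  ## two equally populated bins: ~50/50 with multinomial noise
  bg2 <- gc_matched_background(paste0("p", c(1:10, 201:210)), universe,
                               n_background = 2000, seed = 2)
  frac_low <- mean(bg2 %in% paste0("p", 1:200))
  expect_lt(abs(frac_low - 0.5), 3 * sqrt(0.25 / 2000))
  ## determinism
  expect_identical(bg, gc_matched_background(paste0("p", 1:20), universe,
                                             n_background = 500, seed = 1))
  ## empty universe bin borrows from the nearest with a warning (targets
  ## scored separately from the sampling universe)
  uni2 <- data.frame(probe = c("x1", "x2"), gc = c(0.62, 0.63))
  expect_warning(bg3 <- gc_matched_background("t1", uni2,
                                              n_background = 50, seed = 3,
                                              target_gc = 0.10),
                 "borrowing")
  expect_true(all(bg3 %in% c("x1", "x2")))
})

test_that("tfbs_enrichment detects planted peak overlap via Simes/BH", {
  set.seed(16)
  universe <- data.frame(probe = paste0("p", 1:500), chrom = "chr1",
                         pos = seq(1000, 500000, length.out = 500),
                         gc = runif(500, 0.3, 0.7))
  targets <- universe$probe[universe$pos < 50000]   # 50 targets
  ## peaks covering every target probe and ~10% of the rest
  peak_all <- data.frame(chrom = "chr1", start = 0, end = 50000)
  sprinkle <- universe[universe$pos > 50000, ][1:45, ]
  peaks <- list(
    TF1 = list(exp1 = rbind(peak_all,
                            data.frame(chrom = "chr1",
                                       start = sprinkle$pos - 1,
                                       end = sprinkle$pos + 1))),
    TF2 = list(exp1 = data.frame(chrom = "chr1", start = 400000,
                                 end = 400100)))
  out <- tfbs_enrichment(list(TF1 = targets, TF2 = targets,
                              TF3 = targets[1]),   # TF3 < 2 targets
                         peaks, universe, n_background = 5000, seed = 4)
  expect_false("TF3" %in% out$tf)
  expect_true(out$significant[out$tf == "TF1"])
  expect_false(isTRUE(out$significant[out$tf == "TF2"]))
  ## single experiment: TF p equals that experiment's Fisher p (Simes m=1)
  expect_equal(out$p_simes[out$tf == "TF1"],
               min(out$p_simes[out$tf == "TF1"]))
  ## a TF without peak data is reported untested
  out2 <- tfbs_enrichment(list(TFX = targets), peaks, universe,
                          n_background = 1000, seed = 5)
  expect_false(out2$tested[out2$tf == "TFX"])
})

test_that("chromatin_state_annotation takes the modal state with canonical ties", {
  seg <- function(state) data.frame(chrom = "chr1", start = 0, end = 1000,
                                    state = state)
  expect_equal(chromatin_state_annotation("chr1", 500,
                                          list(a = seg("Quies"), b = seg("Quies"),
                                               c = seg("Quies")))$state, "Quies")
  out <- chromatin_state_annotation("chr1", 500,
                                    list(a = seg("Enh"), b = seg("Enh"),
                                         c = seg("TssA")))
  expect_equal(out$state, "Enh")
  expect_false(out$tie)
  tie <- chromatin_state_annotation("chr1", 500,
                                    list(a = seg("Enh"), b = seg("TssA")))
  expect_true(tie$tie)
  expect_equal(tie$state, "TssA")    # canonical order: TssA before Enh
  none <- chromatin_state_annotation("chr2", 500, list(a = seg("Enh")))
  expect_equal(none$state, "unannotated")
})

test_that("cis_expression_links tests only genes within 250 kb", {
  set.seed(17)
  n <- 400
  expr <- cbind(near = rnorm(n), far = rnorm(n))
  meth <- matrix(0.5 * expr[, "near"] + rnorm(n), ncol = 1)
  gene_map <- data.frame(gene = c("near", "far"), chrom = "chr1",
                         tss = c(1.1e6, 2e6), tes = c(1.15e6, 2.05e6))
  x_map <- data.frame(id = "cg1", chrom = "chr1", pos = 1.0e6)
  out <- cis_expression_links(meth, x_map, expr, gene_map, C = NULL)
  expect_equal(out$gene, "near")           # "far" is 750 kb away
  expect_true(out$significant)
  expect_gt(out$beta, 0)                   # sign matches construction
})
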