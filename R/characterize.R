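## Downstream statistics on final genes and their target CpGs.

#' Direction-of-effect skew per gene
#'
#' For each gene with at least `min_cpgs` target CpGs, an exact two-sided
#' binomial test of the split between positive and negative effect signs
#' against 0.5, with Benjamini-Hochberg control across eligible genes.
#'
#' @param target_signs named list: per gene, a vector of effect signs
#'   (+1/-1) over its target CpGs.
#' @param alpha_fdr FDR level for the `significant` call (default 0.05).
#' @param min_cpgs eligibility threshold (default 10 targets).
#' @return data.frame gene, n_pos, n_neg, p, p_adjusted, direction,
#'   significant; ineligible genes are absent.
#' @export
direction_skew <- function(target_signs, alpha_fdr = 0.05, min_cpgs = 10) {
  elig <- Filter(function(s) length(s) >= min_cpgs, target_signs)
  if (length(elig) == 0) {
    return(data.frame(gene = character(), n_pos = integer(),
                      n_neg = integer(), p = numeric(),
                      p_adjusted = numeric(), direction = character(),
                      significant = logical()))
  }
  rows <- lapply(names(elig), function(g) {
    s <- sign(elig[[g]])
    np <- sum(s > 0); nn <- sum(s < 0)
    p <- binom.test(np, np + nn, 0.5)$p.value
    data.frame(gene = g, n_pos = np, n_neg = nn, p = p,
               direction = if (np >= nn) "increase" else "decrease")
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p_adjusted < alpha_fdr
  out[, c("gene", "n_pos", "n_neg", "p", "p_adjusted", "direction",
          "significant")]
}

#' Collapse target CpGs into regions and measure co-localization
#'
#' Single-linkage chaining per chromosome: consecutive probes strictly
#' less than `gap` apart join one region.  The co-localization fraction is
#' the share of probes with at least one other target probe within the
#' gap.  Invariant to input order and idempotent.
#'
#' @param probe_positions data.frame with `chrom` and `pos` (one row per
#'   target probe).
#' @param gap chaining distance (default 1 kb, strict <).
#' @return list with `regions` (data.frame chrom, start, end, n_probes),
#'   `n_regions`, and `coloc_fraction`.
#' @export
collapse_regions <- function(probe_positions, gap = 1000) {
  pp <- as.data.frame(probe_positions)
  stopifnot(all(c("chrom", "pos") %in% names(pp)))
  pp <- pp[order(pp$chrom, pp$pos), ]
  regions <- list()
  coloc <- 0
  for (ch in unique(pp$chrom)) {
    pos <- pp$pos[pp$chrom == ch]
    if (length(pos) == 0) next
    d <- diff(pos)
    new_region <- c(TRUE, d >= gap)
    id <- cumsum(new_region)
    for (r in unique(id)) {
      p <- pos[id == r]
      regions[[length(regions) + 1]] <-
        data.frame(chrom = ch, start = min(p), end = max(p),
                   n_probes = length(p))
    }
    near <- c(d < gap, FALSE) | c(FALSE, d < gap)
    coloc <- coloc + sum(near)
  }
  regions <- do.call(rbind, regions)
  list(regions = regions, n_regions = nrow(regions),
       coloc_fraction = coloc / nrow(pp))
}

#' Fisher's exact enrichment of a hit set in an annotation set
#'
#' Two-sided exact test on the 2x2 table (hit/annotated) over a stated
#' universe.  The odds ratio is the sample `ad/bc`; with a zero cell the
#' Haldane-Anscombe +0.5 correction is applied to the reported OR while
#' the p-value remains the exact test.
#'
#' @param hits,annotation,universe id vectors; `hits` and `annotation`
#'   must be subsets of `universe`.
#' @param label carried through to the result.
#' @return object of class `gimeth_enrichment` (a one-row data.frame:
#'   label, a, b, c, d, odds_ratio, p, method).
#' @export
fisher_enrichment <- function(hits, annotation, universe,
                              label = "enrichment") {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits); annotation <- unique(annotation)
  stopifnot(all(hits %in% universe), all(annotation %in% universe))
  a <- length(intersect(hits, annotation))
  b <- length(hits) - a
  c_ <- length(setdiff(annotation, hits))
  d <- length(universe) - a - b - c_
  p <- .fisher_p(a, b, c_, d)
  or <- if (a * d == 0 || b * c_ == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  structure(data.frame(label = label, a = a, b = b, c = c_, d = d,
                       odds_ratio = or, p = p, method = "fisher_exact"),
            class = c("gimeth_enrichment", "data.frame"))
}

## Conditional two-sided Fisher p: sum of hypergeometric probabilities of
## tables (same margins) no more likely than the observed one, with the
## customary (1 + 1e-7) tolerance on the comparison.
.fisher_p <- function(a, b, c_, d) {
  m <- a + b          # hits
  k <- a + c_         # annotated
  n_tot <- a + b + c_ + d
  support <- max(0, k - (n_tot - m)):min(k, m)
  probs <- dhyper(support, m, n_tot - m, k)
  p_obs <- dhyper(a, m, n_tot - m, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' GC-matched background probe set
#'
#' Samples `n_background` probes from the universe, with replacement, so
#' the background's GC-content histogram (bins of width `bin_width` over
#' \[0,1\]) matches the target set's: each draw picks a GC bin from the
#' targets' empirical bin distribution, then a uniform probe from that bin
#' of the universe.  If the universe has no probe in a populated target
#' bin, the nearest non-empty bin is used with a warning.
#'
#' @param target_probes character ids of the target CpGs.
#' @param universe data.frame with `probe` and `gc` (fraction in \[0,1\])
#'   for all candidate probes.
#' @param n_background background size (default 100000).
#' @param bin_width GC bin width (default 0.05).
#' @param seed sampling seed.
#' @param target_gc optional GC fractions for the targets (same order);
#'   by default looked up from the universe.
#' @return character vector of sampled probe ids (length `n_background`).
#' @export
gc_matched_background <- function(target_probes, universe,
                                  n_background = 1e5, bin_width = 0.05,
                                  seed = 1L, target_gc = NULL) {
  stopifnot(all(c("probe", "gc") %in% names(universe)),
            all(universe$gc >= 0 & universe$gc <= 1))
  if (is.null(target_gc)) {
    stopifnot(all(target_probes %in% universe$probe))
    target_gc <- universe$gc[match(target_probes, universe$probe)]
  }
  stopifnot(length(target_gc) == length(target_probes), !anyNA(target_gc))
  breaks <- seq(0, 1, by = bin_width)
  bin_of <- function(g) pmin(findInterval(g, breaks, rightmost.closed = TRUE),
                             length(breaks) - 1)
  uni_bin <- bin_of(universe$gc)
  tgt_bin <- bin_of(target_gc)
  tgt_tab <- table(tgt_bin)
  probs <- as.numeric(tgt_tab) / length(tgt_bin)
  bins <- as.integer(names(tgt_tab))
  nonempty <- sort(unique(uni_bin))
  withr::with_seed(seed, {
    draw_bins <- bins[sample.int(length(bins), n_background,
                                 replace = TRUE, prob = probs)]
    out <- character(n_background)
    for (b in bins) {
      idx <- which(draw_bins == b)
      if (length(idx) == 0) next
      src <- b
      if (!(b %in% nonempty)) {
        src <- nonempty[which.min(abs(nonempty - b))]
        warning("universe empty in GC bin ", b,
                "; borrowing from bin ", src)
      }
      pool <- universe$probe[uni_bin == src]
      out[idx] <- pool[sample.int(length(pool), length(idx),
                                  replace = TRUE)]
    }
  })
  out
}

#' Simes combination of dependent p-values
#'
#' `min_i m * p_(i) / i` over the sorted p-values; valid under positive
#' dependence, used here to combine the per-experiment tests of one TF.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
simes_combine <- function(p) {
  if (length(p) == 0) stop("empty p-value list")
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  min(m * sort(p) / seq_len(m))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: monotone non-decreasing in the sorted
#' order and capped at 1; discovery order is preserved.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Transcription-factor binding-site enrichment
#'
#' For each TF with two or more target CpGs: per ChIP experiment, a
#' Fisher's exact test of target-CpG overlap with the experiment's peaks
#' against a GC-matched background's overlap; the per-experiment p-values
#' are combined by the Simes procedure (experiments of one TF are
#' correlated); finally BH controls the FDR across TFs.  Overlap is
#' 1-bp point overlap of the CpG coordinate with half-open peak intervals.
#'
#' @param tf_targets named list: per TF, character vector of target CpG
#'   ids (gene-level threshold sets).
#' @param peaks named list: per TF, a list of experiments, each a
#'   data.frame `chrom`, `start`, `end` (BED-style half-open).  TFs
#'   without an entry are reported as untested.
#' @param universe data.frame `probe`, `chrom`, `pos`, `gc`.
#' @param n_background,bin_width,seed background controls (see
#'   [gc_matched_background()]).
#' @param alpha_fdr FDR level (default 0.05).
#' @return data.frame tf, n_targets, n_experiments, odds_ratio (best
#'   experiment), p_simes, p_adjusted, significant, tested.
#' @export
tfbs_enrichment <- function(tf_targets, peaks, universe,
                            n_background = 1e5, bin_width = 0.05,
                            seed = 1L, alpha_fdr = 0.05) {
  tf_targets <- Filter(function(x) length(x) >= 2, tf_targets)
  rows <- list()
  for (tf in names(tf_targets)) {
    tgt <- unique(tf_targets[[tf]])
    exps <- peaks[[tf]]
    if (is.null(exps) || length(exps) == 0) {
      rows[[tf]] <- data.frame(tf = tf, n_targets = length(tgt),
                               n_experiments = 0, odds_ratio = NA_real_,
                               p_simes = NA_real_, tested = FALSE)
      next
    }
    bg <- gc_matched_background(tgt, universe, n_background = n_background,
                                bin_width = bin_width,
                                seed = .child_seed(seed, match(tf, names(tf_targets))))
    pos <- setNames(universe$pos, universe$probe)
    chrom <- setNames(universe$chrom, universe$probe)
    pvals <- ors <- numeric(length(exps))
    for (e in seq_along(exps)) {
      pk <- exps[[e]]
      in_peak <- function(ids) {
        vapply(ids, function(id) {
          any(pk$chrom == chrom[id] & pk$start <= pos[id] &
                pos[id] < pk$end)
        }, logical(1))
      }
      a <- sum(in_peak(tgt)); b <- length(tgt) - a
      cc <- sum(in_peak(bg)); d <- length(bg) - cc
      pvals[e] <- .fisher_p(a, b, cc, d)
      ors[e] <- if (a * d == 0 || b * cc == 0)
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)) else
          (a * d) / (b * cc)
    }
    rows[[tf]] <- data.frame(tf = tf, n_targets = length(tgt),
                             n_experiments = length(exps),
                             odds_ratio = ors[which.min(pvals)],
                             p_simes = simes_combine(pvals), tested = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- NA_real_
  tested <- which(out$tested)
  if (length(tested)) out$p_adjusted[tested] <- bh_adjust(out$p_simes[tested])
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha_fdr
  out
}

## Canonical Roadmap 15-state ordering used to break annotation ties.
.roadmap_states <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG",
                     "Enh", "ZNF/Rpts", "Het", "TssBiv", "BivFlnk",
                     "EnhBiv", "ReprPC", "ReprPCWk", "Quies")

#' Chromatin-state annotation of a probe
#'
#' The modal state across cell types at the probe position (1-bp point
#' overlap with half-open segments).  Ties are broken by the canonical
#' Roadmap 15-state order and flagged; a probe outside all segments is
#' `"unannotated"`.
#'
#' @param chrom,pos probe coordinate.
#' @param segments named list per cell type of data.frames `chrom`,
#'   `start`, `end`, `state`.
#' @return list with `state`, `tie` (logical), `per_celltype`.
#' @export
chromatin_state_annotation <- function(chrom, pos, segments) {
  states <- vapply(segments, function(seg) {
    hit <- seg$chrom == chrom & seg$start <= pos & pos < seg$end
    if (any(hit)) seg$state[which(hit)[1]] else NA_character_
  }, character(1))
  found <- states[!is.na(states)]
  if (length(found) == 0) {
    return(list(state = "unannotated", tie = FALSE,
                per_celltype = states))
  }
  tab <- table(found)
  top <- names(tab)[tab == max(tab)]
  tie <- length(top) > 1
  if (tie) {
    ord <- match(top, .roadmap_states)
    ord[is.na(ord)] <- length(.roadmap_states) + 1
    top <- top[which.min(ord)]
  }
  list(state = top[1], tie = tie, per_celltype = states)
}

#' Associations between target CpGs (or an instrument) and nearby
#' expression
#'
#' Tests every CpG-gene (or instrument-gene) pair within `window` of the
#' gene body by covariate-adjusted linear regression, then applies
#' bias/inflation correction to the resulting statistics and a Bonferroni
#' threshold over the tested pairs.
#'
#' @param x samples x features matrix of predictors: methylation at target
#'   CpGs, or a one-column instrument-score matrix.
#' @param x_map data.frame `id`, `chrom`, `pos` giving a genomic anchor
#'   per predictor column (for an instrument: its gene's TSS).
#' @param expression samples x genes matrix (rank-INT scale).
#' @param gene_map annotation for the expression columns.
#' @param C covariate matrix (for the CpG variant include both expression
#'   and methylation PCs; for the instrument variant base covariates).
#' @param window cis window around the gene body (default 250 kb, strict
#'   <).
#' @param alpha family-wise alpha for the Bonferroni call (default 0.05).
#' @return data.frame id, gene, beta, se, t, p_raw, p_corrected,
#'   significant (empty when no pair is within the window).
#' @export
cis_expression_links <- function(x, x_map, expression, gene_map, C,
                                 window = .gimeth_defaults$cis_link_window,
                                 alpha = 0.05) {
  x <- as.matrix(x)
  rows <- list()
  for (j in seq_len(ncol(x))) {
    anchor <- x_map[j, ]
    gm <- gene_map[gene_map$chrom == anchor$chrom, , drop = FALSE]
    if (nrow(gm) == 0) next
    lo <- pmin(gm$tss, gm$tes); hi <- pmax(gm$tss, gm$tes)
    dist <- pmax(0, pmax(lo - anchor$pos, anchor$pos - hi))
    near <- gm$gene[dist < window]
    for (g in near) {
      fit <- linear_assoc(expression[, g], x[, j], C)
      rows[[length(rows) + 1]] <-
        data.frame(id = anchor$id, gene = g, beta = fit$beta,
                   se = fit$se, t = fit$t, p_raw = fit$p, z = fit$z)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id = character(), gene = character(),
                      beta = numeric(), se = numeric(), t = numeric(),
                      p_raw = numeric(), p_corrected = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  if (nrow(out) >= 1000) {
    ## ensembles too small for a stable mixture fit keep raw statistics
    cal <- suppressWarnings(correct_bias_inflation(out$z, min_tests = 0))
    pc <- apply_calibration(out$z, cal)
    out$p_corrected <- pc$p
  } else {
    out$p_corrected <- out$p_raw
  }
  out$significant <- out$p_corrected < bonferroni_threshold(alpha, nrow(out))
  out
}
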