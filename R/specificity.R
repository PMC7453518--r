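## The LD/pleiotropy specificity cascade: neighbour-GI conditioning,
## correlation exclusion and pruning, residual-pleiotropy, long-range and
## WBC-variant filters.  Flags accumulate on the scan records; a record is
## `final` only if it survives every stage.

#' Greedy pruning of highly correlated columns
#'
#' While any pair of columns exceeds the cutoff in absolute Pearson
#' correlation, the member of the worst pair with the larger mean absolute
#' correlation to all other retained columns is removed (on equal means the
#' earlier column is removed), mirroring caret-style `findCorrelation`
#' pruning.  Deterministic given column order.
#'
#' @param x numeric matrix (>= 1 column).
#' @param cutoff absolute correlation cutoff (default 0.95, strict >).
#' @return character vector of retained column names (or indices as
#'   character when unnamed).
#' @export
prune_correlated <- function(x, cutoff = .gimeth_defaults$r_cutoff) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 1)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  retained <- colnames(x)
  while (length(retained) > 1) {
    cm <- abs(cor(x[, retained, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= cutoff) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    means <- rowMeans(cm)
    i <- worst[["row"]]; j <- worst[["col"]]
    ## larger mean |r| goes; exact tie removes the earlier column
    drop_idx <- if (means[i] > means[j]) i else if (means[j] > means[i]) j
                else min(i, j)
    retained <- retained[-drop_idx]
  }
  retained
}

#' Neighbour context for every instrumented gene
#'
#' Neighbours are other genes with a valid instrument whose gene body lies
#' within `window` of the index gene's body (interval gap, symmetric,
#' inclusive) on the same chromosome.  For each index gene the maximum
#' absolute correlation between its instrument and any neighbour
#' instrument is recorded (against *unpruned* neighbours — the exclusion
#' rule is evaluated before pruning), and the neighbour set is pruned at
#' the correlation cutoff for use as a conditioning design.
#'
#' @param gi_matrix samples x genes matrix of instrument scores.
#' @param gene_map annotation for (at least) the instrumented genes.
#' @param window neighbour window (default 1 Mb).
#' @param cutoff pruning cutoff (default 0.95).
#' @return named list per gene: `neighbours`, `pruned`, `max_r`.
#' @export
neighbour_contexts <- function(gi_matrix, gene_map,
                               window = .gimeth_defaults$neighbour_window,
                               cutoff = .gimeth_defaults$r_cutoff) {
  genes <- colnames(gi_matrix)
  gm <- gene_map[match(genes, gene_map$gene), ]
  lo <- pmin(gm$tss, gm$tes); hi <- pmax(gm$tss, gm$tes)
  out <- list()
  for (i in seq_along(genes)) {
    gap <- pmax(0, pmax(lo[i] - hi, lo - hi[i]))
    nb <- genes[gm$chrom == gm$chrom[i] & gap <= window &
                  genes != genes[i]]
    if (length(nb) == 0) {
      out[[genes[i]]] <- list(neighbours = character(),
                              pruned = character(), max_r = 0)
      next
    }
    r <- abs(cor(gi_matrix[, genes[i]], gi_matrix[, nb, drop = FALSE]))
    pruned <- prune_correlated(gi_matrix[, nb, drop = FALSE], cutoff)
    out[[genes[i]]] <- list(neighbours = nb, pruned = pruned,
                            max_r = max(r))
  }
  out
}

## Vectorized covariate-adjusted association of one predictor against many
## outcomes; equals per-outcome OLS (see run_scan).  Drops collinear extra
## columns instead of failing, reporting which were removed.
.sweep_assoc <- function(x, Y, C) {
  X <- cbind(`(Intercept)` = rep(1, length(x)), C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    message("dropping collinear conditioning column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
  }
  xres <- qr.resid(qx, x)
  Yres <- qr.resid(qx, as.matrix(Y))
  df <- length(x) - ncol(X) - 1
  xx <- sum(xres^2)
  cross <- drop(crossprod(Yres, xres))
  beta <- cross / xx
  rss <- pmax(colSums(Yres^2) - beta * cross, 0)
  se <- sqrt(rss / df / xx)
  t <- ifelse(se > 0, beta / se, 0)
  pz <- .t_to_p_z(t, df)
  list(beta = beta, se = se, t = t, p = pz$p, z = pz$z, df = df)
}

#' Condition significant records on neighbouring instruments
#'
#' For every record of an index gene: if the index instrument is
#' correlated `> 0.95` with any (unpruned) neighbour instrument the gene
#' is excluded (`dropped_corr95`); otherwise the association is refit with
#' the pruned neighbour instruments as additional covariates
#' (`DNAm ~ GI + C + G_neighbours`).  Conditional significance reuses the
#' scan-wide threshold on calibration-corrected p-values (the calibration
#' is not re-estimated).
#'
#' @param records scan records (a `data.table` from [run_scan()]), already
#'   restricted to the marginally eligible set.
#' @param gi_matrix instrument score matrix (must contain every record
#'   gene and all neighbours).
#' @param methylation,C data matrices aligned with `gi_matrix`.
#' @param contexts output of [neighbour_contexts()].
#' @param calibration scan calibration ([correct_bias_inflation()]).
#' @param threshold significance threshold on corrected p (scan-wide
#'   Bonferroni).
#' @param r_cutoff exclusion cutoff for index-neighbour correlation.
#' @param expression optional rank-INT expression matrix (columns named by
#'   gene).  When supplied, each gene's conditional effect and SE are
#'   rescaled by the partial slope of its expression on its instrument
#'   within the same conditioning design, so `phi_cond` stays on the
#'   SD-methylation-per-SD-expression scale (the marginal instrument
#'   calibration is not the right scale once correlated neighbour
#'   instruments are in the model).  Test statistics are scale-free and
#'   unaffected.
#' @return records with `phi_cond`, `se_cond`, `p_cond`, `dropped_corr95`
#'   and `conditional_sig` columns added.
#' @export
conditional_scan <- function(records, gi_matrix, methylation, C, contexts,
                             calibration, threshold,
                             r_cutoff = .gimeth_defaults$r_cutoff,
                             expression = NULL) {
  records <- data.table::as.data.table(records)
  records[, `:=`(phi_cond = NA_real_, se_cond = NA_real_,
                 p_cond = NA_real_, dropped_corr95 = FALSE,
                 conditional_sig = FALSE)]
  for (g in unique(records$gene)) {
    ctx <- contexts[[g]]
    rows <- which(records$gene == g)
    if (ctx$max_r > r_cutoff) {
      records[rows, dropped_corr95 := TRUE]
      next
    }
    extra <- if (length(ctx$pruned))
      gi_matrix[, ctx$pruned, drop = FALSE] else NULL
    probes <- records$probe[rows]
    fit <- .sweep_assoc(gi_matrix[, g],
                        methylation[, probes, drop = FALSE],
                        cbind(C, extra))
    pc <- apply_calibration(fit$z, calibration)
    scale_b <- 1
    if (!is.null(expression) && g %in% colnames(expression)) {
      scale_b <- .sweep_assoc(gi_matrix[, g],
                              expression[, g, drop = FALSE],
                              cbind(C, extra))$beta
      if (!is.finite(scale_b) || abs(scale_b) < 1e-8) scale_b <- 1
    }
    records[rows, `:=`(phi_cond = fit$beta / scale_b,
                       se_cond = fit$se / abs(scale_b),
                       p_cond = pc$p,
                       conditional_sig = pc$p < threshold)]
  }
  records[]
}

## Gene-level target sets: probes conditionally significant at the
## (laxer) gene-level threshold, for genes not excluded by correlation.
.target_sets <- function(records, gene_threshold) {
  recs <- records[records$dropped_corr95 == FALSE &
                    !is.na(records$p_cond) &
                    records$p_cond < gene_threshold, ]
  split(recs$probe, recs$gene)
}

#' Residual-pleiotropy filter
#'
#' Excludes index genes whose instrument still predicts the expression of
#' a neighbouring significant gene: if the two genes' target-CpG sets (at
#' the gene-level threshold) intersect and the index instrument's added
#' F-statistic on the neighbour's expression — over the covariates and the
#' neighbour's pruned neighbour instruments (the index instrument itself
#' excluded from that conditioning set) — exceeds `f_cut`, all records of
#' the index gene are flagged `dropped_residual_pleiotropy`.
#'
#' @param records output of [conditional_scan()].
#' @param gi_matrix,expression,C aligned data matrices (expression on the
#'   rank-INT scale, columns named by gene).
#' @param contexts output of [neighbour_contexts()].
#' @param gene_threshold gene-level Bonferroni threshold used to build the
#'   target sets (e.g. 0.05 / number of probes).
#' @param f_cut weak-predictiveness cutoff (default 5, strict >).
#' @return records with a `dropped_residual_pleiotropy` column.
#' @export
residual_pleiotropy_filter <- function(records, gi_matrix, expression, C,
                                       contexts, gene_threshold,
                                       f_cut = .gimeth_defaults$f_pleio) {
  records <- data.table::as.data.table(records)
  records[, dropped_residual_pleiotropy := FALSE]
  targets <- .target_sets(records, gene_threshold)
  sig_genes <- names(targets)
  for (g in intersect(unique(records$gene), sig_genes)) {
    rows <- which(records$gene == g)
    if (any(records$dropped_corr95[rows])) next
    for (h in intersect(contexts[[g]]$neighbours, sig_genes)) {
      if (length(intersect(targets[[g]], targets[[h]])) == 0) next
      cond <- setdiff(contexts[[h]]$pruned, g)
      Ch <- cbind(C, if (length(cond)) gi_matrix[, cond, drop = FALSE])
      f <- .added_f(expression[, h], gi_matrix[, g], Ch)
      if (is.finite(f) && f > f_cut) {
        records[rows, dropped_residual_pleiotropy := TRUE]
        break
      }
    }
  }
  records[]
}

## Added F (1 numerator df) of x on y over covariates C.
.added_f <- function(y, x, C) {
  rss_red <- sum(.residualize(y, C)^2)
  rss_full <- sum(.residualize(y, cbind(C, x = x))^2)
  df2 <- length(y) - (if (is.null(C)) 0 else ncol(C)) - 2
  (rss_red - rss_full) / (rss_full / df2)
}

#' Long-range pleiotropy/LD filter
#'
#' For every CpG associated with two or more surviving genes from one
#' chromosome, the analysis is re-run including all those instruments in a
#' joint model (plus each index gene's pruned neighbours and the
#' covariates); records that lose scan-wide significance are flagged
#' `dropped_longrange`.
#'
#' @inheritParams conditional_scan
#' @param gene_map annotation (for chromosome lookup).
#' @return records with a `dropped_longrange` column.
#' @export
long_range_filter <- function(records, gi_matrix, methylation, C, contexts,
                              calibration, threshold, gene_map) {
  records <- data.table::as.data.table(records)
  for (col in c("dropped_corr95", "dropped_residual_pleiotropy")) {
    if (is.null(records[[col]])) records[, (col) := FALSE]
  }
  records[, dropped_longrange := FALSE]
  alive <- records$conditional_sig & !records$dropped_corr95 &
    !records$dropped_residual_pleiotropy
  chrom <- setNames(gene_map$chrom, gene_map$gene)
  for (pr in unique(records$probe[alive])) {
    rows <- which(records$probe == pr & alive)
    genes <- records$gene[rows]
    for (ch in unique(chrom[genes])) {
      grp <- genes[chrom[genes] == ch]
      if (length(grp) < 2) next
      for (g in grp) {
        others <- setdiff(grp, g)
        cond <- union(others, setdiff(contexts[[g]]$pruned, g))
        fit <- .sweep_assoc(gi_matrix[, g],
                            methylation[, pr, drop = FALSE],
                            cbind(C, gi_matrix[, cond, drop = FALSE]))
        pc <- apply_calibration(fit$z, calibration)
        if (pc$p >= threshold) {
          records[rows[genes == g], dropped_longrange := TRUE]
        }
      }
    }
  }
  records[]
}

#' White-blood-cell variant filter
#'
#' Re-fits the surviving records with the dosages of SNPs known to be
#' associated with white blood cell composition added to the covariates
#' (on top of each gene's conditional design).  Records losing scan-wide
#' significance are flagged `dropped_wbc`; survivors are flagged `final`.
#'
#' @inheritParams conditional_scan
#' @param wbc_snps SNP ids; ids absent from `dosages` are skipped with a
#'   warning.  An empty list makes the stage a no-op (all survivors
#'   final).
#' @param dosages dosage matrix aligned with the scan samples.
#' @return records with `dropped_wbc` and `final` columns.
#' @export
wbc_filter <- function(records, wbc_snps, dosages, gi_matrix, methylation,
                       C, contexts, calibration, threshold) {
  records <- data.table::as.data.table(records)
  for (col in c("dropped_corr95", "dropped_residual_pleiotropy",
                "dropped_longrange")) {
    if (is.null(records[[col]])) records[, (col) := FALSE]
  }
  records[, `:=`(dropped_wbc = FALSE, final = FALSE)]
  alive <- records$conditional_sig & !records$dropped_corr95 &
    !records$dropped_residual_pleiotropy & !records$dropped_longrange
  missing <- setdiff(wbc_snps, colnames(dosages))
  if (length(missing)) {
    warning("WBC SNP(s) absent from dosages, skipped: ",
            paste(missing, collapse = ", "))
    wbc_snps <- setdiff(wbc_snps, missing)
  }
  if (length(wbc_snps) == 0) {
    records[alive, final := TRUE]
    return(records[])
  }
  W <- dosages[, wbc_snps, drop = FALSE]
  for (g in unique(records$gene[alive])) {
    rows <- which(records$gene == g & alive)
    extra <- if (length(contexts[[g]]$pruned))
      gi_matrix[, contexts[[g]]$pruned, drop = FALSE] else NULL
    fit <- .sweep_assoc(gi_matrix[, g],
                        methylation[, records$probe[rows], drop = FALSE],
                        cbind(C, extra, W))
    pc <- apply_calibration(fit$z, calibration)
    lost <- pc$p >= threshold
    records[rows[lost], dropped_wbc := TRUE]
    records[rows[!lost], final := TRUE]
  }
  records[]
}

#' Run the full specificity cascade
#'
#' Convenience wrapper executing, in order: neighbour conditioning with
#' correlation exclusion, the residual-pleiotropy filter, the long-range
#' joint-model filter and the WBC-variant filter, then stage accounting.
#'
#' @param records calibrated scan records (with `p_corrected`).
#' @param gi_matrix,methylation,expression,C,dosages aligned matrices.
#' @param gene_map annotation.
#' @param calibration scan calibration.
#' @param threshold scan-wide Bonferroni threshold.
#' @param gene_threshold gene-level threshold for target sets.
#' @param wbc_snps SNPs for the WBC stage (default none).
#' @return list with `records` (flagged; restricted to records eligible at
#'   the gene-level threshold), `accounting` (per-stage removal counts)
#'   and `contexts`.
#' @export
run_cascade <- function(records, gi_matrix, methylation, expression, C,
                        dosages, gene_map, calibration, threshold,
                        gene_threshold, wbc_snps = character()) {
  records <- data.table::as.data.table(records)
  records[, marginal_sig := p_corrected < threshold]
  ## conditional refits run on everything eligible at the gene-level
  ## threshold so that gene-level target sets exist for the pleiotropy
  ## stage; cascade flags below only ever remove marginal_sig records.
  eligible <- records[p_corrected < gene_threshold]
  contexts <- neighbour_contexts(
    gi_matrix[, intersect(colnames(gi_matrix), gene_map$gene), drop = FALSE],
    gene_map)
  eligible <- conditional_scan(eligible, gi_matrix, methylation, C,
                               contexts, calibration, threshold,
                               expression = expression)
  eligible <- residual_pleiotropy_filter(eligible, gi_matrix, expression,
                                         C, contexts, gene_threshold)
  eligible <- long_range_filter(eligible, gi_matrix, methylation, C,
                                contexts, calibration, threshold, gene_map)
  eligible <- wbc_filter(eligible, wbc_snps, dosages, gi_matrix,
                         methylation, C, contexts, calibration, threshold)
  eligible[, final := final & marginal_sig & conditional_sig]
  acc <- data.frame(
    stage = c("marginal", "corr95", "not_conditional", "residual_pleiotropy",
              "longrange", "wbc", "final"),
    records = c(sum(eligible$marginal_sig),
                sum(eligible$marginal_sig & eligible$dropped_corr95),
                sum(eligible$marginal_sig & !eligible$dropped_corr95 &
                      !eligible$conditional_sig),
                sum(eligible$marginal_sig & eligible$dropped_residual_pleiotropy &
                      eligible$conditional_sig),
                sum(eligible$marginal_sig & eligible$dropped_longrange &
                      eligible$conditional_sig),
                sum(eligible$marginal_sig & eligible$dropped_wbc &
                      eligible$conditional_sig),
                sum(eligible$final)))
  list(records = eligible[], accounting = acc, contexts = contexts)
}
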