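#' Stratified train/test split
#'
#' Assigns samples to a training and a test set so that every cohort-by-sex
#' stratum contributes the same training fraction (to within one sample),
#' keeping cohorts and sexes equally represented in both sets.
#'
#' @param samples sample ids.
#' @param cohort,sex stratification labels, one per sample.
#' @param ratio training fraction (default 1/3).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return object of class `gimeth_split`: list with `assignment` (named
#'   character vector, "train"/"test"), `train`, `test`, `ratio`, `seed`.
#' @export
split_train_test <- function(samples, cohort, sex, ratio = 1 / 3,
                             seed = 1L) {
  if (length(samples) == 0) stop("empty sample list")
  stopifnot(ratio > 0, ratio < 1,
            length(cohort) == length(samples),
            length(sex) == length(samples))
  assignment <- setNames(rep("test", length(samples)), samples)
  strata <- split(seq_along(samples), paste(cohort, sex, sep = "\r"))
  withr::with_seed(seed, {
    for (idx in strata) {
      n_train <- round(ratio * length(idx))
      picked <- sample(idx, n_train)
      assignment[picked] <- "train"
    }
  })
  structure(list(assignment = assignment,
                 train = samples[assignment == "train"],
                 test = samples[assignment == "test"],
                 ratio = ratio, seed = seed),
            class = "gimeth_split")
}

#' Select SNPs in a gene's cis window
#'
#' SNPs on the gene's chromosome with position in
#' \[min(TSS, TES) - window, max(TSS, TES) + window\], boundaries
#' inclusive (a SNP exactly `window` away is in).
#'
#' @param gene gene id.
#' @param gene_map annotation data.frame with `gene`, `chrom`, `tss`, `tes`.
#' @param snp_map annotation data.frame with `snp`, `chrom`, `pos`.
#' @param window flank size in bp (default 100 kb).
#' @return character vector of SNP ids (possibly empty).
#' @export
select_cis_snps <- function(gene, gene_map, snp_map,
                            window = .gimeth_defaults$cis_window) {
  g <- gene_map[gene_map$gene == gene, , drop = FALSE]
  if (nrow(g) == 0) stop("gene '", gene, "' absent from annotation")
  lo <- min(g$tss, g$tes) - window
  hi <- max(g$tss, g$tes) + window
  snp_map$snp[snp_map$chrom == g$chrom &
                snp_map$pos >= lo & snp_map$pos <= hi]
}

## Build the unpenalized covariate design used for instrument fitting and
## validation: age, sex, cohort dummies, cell fractions (one dropped to
## avoid the sum-to-one collinearity) and k expression PCs computed on the
## training samples and projected onto the rest.
#' Covariate design with projected expression PCs
#'
#' Expands age/sex/cohort/cell-fraction covariates to a numeric matrix and
#' appends the top `k` principal components of the (column-centred)
#' training-sample expression matrix, projected onto all samples via the
#' training loadings.
#'
#' @param covariates data.frame with `age`, `sex`, `cohort` and cell
#'   fraction columns (`cf*`); one cell fraction column is dropped
#'   (fractions sum to one).
#' @param expression samples x genes matrix used for the PCs (typically
#'   rank-INT expression).
#' @param train_idx indices of training samples on which PCs are learned
#'   (default: all samples).
#' @param k number of PCs (default 5).
#' @return numeric matrix, samples x covariate columns.
#' @export
covariate_design <- function(covariates, expression = NULL,
                             train_idx = NULL, k = 5) {
  cf <- grep("^cf", names(covariates), value = TRUE)
  if (length(cf) > 1) covariates <- covariates[setdiff(names(covariates), cf[length(cf)])]
  C <- .covariate_matrix(covariates)
  if (!is.null(expression)) {
    expression <- as.matrix(expression)
    if (is.null(train_idx)) train_idx <- seq_len(nrow(expression))
    ## covariate PCs are meant to capture global structure (cell mixtures,
    ## batch), which presumes many features per component; with few
    ## features they would model individual genes/probes and absorb the
    ## very signal under study, so allow one PC per 100 features
    k <- min(k, floor(ncol(expression) / 100))
    if (k < 1) return(C)
    pcs <- compute_pcs(expression[train_idx, , drop = FALSE], k = k)
    centre <- colMeans(expression[train_idx, , drop = FALSE])
    scores <- sweep(expression, 2, centre, "-") %*% pcs$loadings
    colnames(scores) <- paste0("exprPC", seq_len(ncol(scores)))
    C <- cbind(C, scores)
  }
  C
}

#' Fit a per-gene genetic instrument by two-step LASSO
#'
#' Step 1 runs LASSO on the cis SNPs with unpenalized covariates, choosing
#' the penalty that minimizes five-fold cross-validated MSE, and keeps the
#' SNPs with non-zero weights.  Step 2 re-runs LASSO on those SNPs only and
#' applies the one-standard-error rule — the largest penalty whose CV error
#' is within one SE of the minimum — under the constraint that at least one
#' SNP keeps a non-zero weight (falling back to the largest penalty on the
#' path that retains one).  Weights are reported on the original dosage
#' scale; predictors are standardized internally so the penalty is
#' scale-free.
#'
#' @param dosages training dosage matrix (samples x SNPs).
#' @param expr training expression vector (rank-INT scale).
#' @param C training covariate matrix (unpenalized; include cell fractions
#'   and expression PCs, see [covariate_design()]).
#' @param cis_snps SNP ids to consider.
#' @param cv_folds folds for cross-validation (default 5).
#' @param seed seed for the fold assignment (seeded shuffle then modulo).
#' @return a `gimeth_instrument` (gene, snps, weights, lambda1, lambda2,
#'   n_train) or NULL when no SNP is available/selected (gene skipped).
#' @export
fit_instrument <- function(dosages, expr, C, cis_snps, cv_folds = 5,
                           seed = 1L, gene = "gene") {
  if (length(cis_snps) == 0) {
    message("gene ", gene, ": no cis SNPs; skipped")
    return(NULL)
  }
  D <- as.matrix(dosages[, cis_snps, drop = FALSE])
  keep <- apply(D, 2, sd) > 0
  D <- D[, keep, drop = FALSE]
  if (ncol(D) == 0) {
    message("gene ", gene, ": all cis SNPs monomorphic; skipped")
    return(NULL)
  }
  n <- nrow(D)
  foldid <- withr::with_seed(seed, sample(seq_len(n)) %% cv_folds + 1L)
  pf <- c(rep(0, ncol(C)), rep(1, ncol(D)))
  x <- cbind(C, D)
  cv1 <- glmnet::cv.glmnet(x, expr, foldid = foldid, penalty.factor = pf,
                           standardize = TRUE)
  b1 <- coef(cv1, s = "lambda.min")[-1]
  sel <- which(b1[ncol(C) + seq_len(ncol(D))] != 0)
  if (length(sel) == 0) {
    message("gene ", gene, ": step-1 LASSO selected no SNP; skipped")
    return(NULL)
  }
  D2 <- D[, sel, drop = FALSE]
  pf2 <- c(rep(0, ncol(C)), rep(1, ncol(D2)))
  x2 <- cbind(C, D2)
  cv2 <- glmnet::cv.glmnet(x2, expr, foldid = foldid, penalty.factor = pf2,
                           standardize = TRUE)
  ## one-SE rule constrained to >= 1 non-zero SNP weight; ties and the
  ## fallback both resolve toward the sparser (larger-lambda) model
  bmat <- as.matrix(coef(cv2, s = cv2$lambda))[-1, , drop = FALSE]
  snp_nz <- colSums(bmat[ncol(C) + seq_len(ncol(D2)), , drop = FALSE] != 0) > 0
  imin <- which.min(cv2$cvm)
  ok_1se <- cv2$cvm <= cv2$cvm[imin] + cv2$cvsd[imin]
  cand <- which(ok_1se & snp_nz)
  if (length(cand) == 0) cand <- which(snp_nz)
  if (length(cand) == 0) {
    message("gene ", gene, ": one-SE model retains no SNP; skipped")
    return(NULL)
  }
  pick <- cand[which.max(cv2$lambda[cand])]
  beta <- bmat[ncol(C) + seq_len(ncol(D2)), pick]
  nz <- which(beta != 0)
  structure(list(gene = gene,
                 snps = colnames(D2)[nz],
                 weights = unname(beta[nz]),
                 lambda1 = cv1$lambda.min,
                 lambda2 = cv2$lambda[pick],
                 n_train = n),
            class = "gimeth_instrument")
}

#' Score a genetic instrument on a dosage matrix
#'
#' The instrument value is the weighted sum of SNP dosages,
#' `GI = D %*% beta`, using the training weights unchanged.
#'
#' @param instrument a `gimeth_instrument`.
#' @param dosages samples x SNPs matrix containing the instrument's SNPs.
#' @return numeric vector of instrument scores.
#' @export
instrument_scores <- function(instrument, dosages) {
  drop(as.matrix(dosages[, instrument$snps, drop = FALSE]) %*%
         instrument$weights)
}

#' Validate an instrument on the test split
#'
#' Compares covariates-only vs covariates-plus-instrument linear models on
#' test-set expression by ANOVA: `F = (RSS_red - RSS_full) /
#' (RSS_full / (n - p - 1))` with one numerator df, and partial R-squared
#' `(RSS_red - RSS_full) / RSS_red`.  The instrument is valid when
#' `F > 10` (strict).
#'
#' @param instrument a `gimeth_instrument`.
#' @param dosages,expr,C test-set dosages, expression and covariate matrix
#'   (test samples must be disjoint from training samples).
#' @param f_valid validity cutoff (default 10).
#' @return the instrument with `f_test`, `partial_r2`, `n_test`, `valid`
#'   (and `invalid_reason` when degenerate) filled in.
#' @export
validate_instrument <- function(instrument, dosages, expr, C,
                                f_valid = .gimeth_defaults$f_valid) {
  gi <- instrument_scores(instrument, dosages)
  if (sd(gi) == 0) {
    instrument$f_test <- NA_real_
    instrument$partial_r2 <- NA_real_
    instrument$valid <- FALSE
    instrument$invalid_reason <- "constant_gi"
    return(instrument)
  }
  n <- length(expr)
  res_red <- .residualize(expr, C)
  res_full <- .residualize(expr, cbind(C, gi = gi))
  rss_red <- sum(res_red^2)
  rss_full <- sum(res_full^2)
  p <- ncol(C) + 1                       # covariates + the instrument
  df2 <- n - p - 1
  f <- (rss_red - rss_full) / (rss_full / df2)
  instrument$f_test <- f
  instrument$partial_r2 <- (rss_red - rss_full) / rss_red
  instrument$n_test <- n
  instrument$valid <- is.finite(f) && f > f_valid
  instrument
}

#' Build and validate instruments for many genes
#'
#' Convenience loop: for every gene in `gene_map`, select cis SNPs, fit
#' the two-step LASSO on the training split and validate on the test
#' split.  Genes without cis SNPs or without a step-1 selection are
#' skipped.
#'
#' @param dosages,expr full dosage matrix and rank-INT expression matrix.
#' @param covariates covariate data.frame (see [covariate_design()]).
#' @param gene_map,snp_map annotations.
#' @param split a `gimeth_split` over `rownames(expr)` order (assignment
#'   by position when matrices are unnamed).
#' @param window cis window (default 100 kb).
#' @param seed base seed; per-gene fold seeds are derived from it.
#' @param n_pcs expression PCs in the covariate design (default 5).
#' @return list with `instruments` (named list of validated instruments)
#'   and `summary` (data.frame gene, n_snps, lambda1, lambda2, f_test,
#'   partial_r2, valid).
#' @export
build_instruments <- function(dosages, expr, covariates, gene_map, snp_map,
                              split, window = .gimeth_defaults$cis_window,
                              seed = 1L, n_pcs = 5) {
  idx_train <- which(split$assignment == "train")
  idx_test <- which(split$assignment == "test")
  C <- covariate_design(covariates, expression = expr,
                        train_idx = idx_train, k = n_pcs)
  out <- list()
  for (j in seq_len(nrow(gene_map))) {
    g <- gene_map$gene[j]
    cis <- select_cis_snps(g, gene_map, snp_map, window = window)
    gi <- fit_instrument(dosages[idx_train, , drop = FALSE],
                         expr[idx_train, g], C[idx_train, , drop = FALSE],
                         cis, seed = .child_seed(seed, j), gene = g)
    if (is.null(gi)) next
    gi <- validate_instrument(gi, dosages[idx_test, , drop = FALSE],
                              expr[idx_test, g],
                              C[idx_test, , drop = FALSE])
    out[[g]] <- gi
  }
  summary <- do.call(rbind, lapply(out, function(gi) {
    data.frame(gene = gi$gene, n_snps = length(gi$snps),
               lambda1 = gi$lambda1, lambda2 = gi$lambda2,
               f_test = gi$f_test, partial_r2 = gi$partial_r2,
               valid = gi$valid)
  }))
  rownames(summary) <- NULL
  list(instruments = out, summary = summary)
}
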