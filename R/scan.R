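#' Covariate-adjusted linear association
#'
#' Ordinary least squares of `y` on `x` plus covariates; reports the
#' coefficient of `x` with its standard error, t statistic and two-sided p
#' from the t distribution on `n - p - 1` degrees of freedom (`p` = number
#' of predictors including `x`).
#'
#' @param y outcome vector.
#' @param x predictor of interest.
#' @param C optional covariate matrix (no intercept column; one is added).
#' @return list with `beta`, `se`, `t`, `p`, `df`.
#' @export
linear_assoc <- function(y, x, C = NULL) {
  stopifnot(!anyNA(y), !anyNA(x))
  X <- cbind(`(Intercept)` = rep(1, length(y)), C, x = x)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- length(y)
  df <- n - ncol(X)
  if (df < 1) stop("not enough samples for the design")
  coefs <- qr.coef(qx, y)
  res <- y - drop(X %*% coefs)
  sigma2 <- sum(res^2) / df
  XtXinv_xx <- chol2inv(qr.R(qx))[ncol(X), ncol(X)]
  se <- sqrt(sigma2 * XtXinv_xx)
  beta <- coefs[["x"]]
  t <- if (se > 0) beta / se else 0
  pz <- .t_to_p_z(t, df)
  list(beta = beta, se = se, t = t, p = pz$p, z = pz$z, df = df)
}

#' Enumerate trans gene-probe pairs
#'
#' A probe is in trans to a gene when it lies on a different chromosome,
#' or on the same chromosome outside the gene body with
#' `min(|pos - TSS|, |pos - TES|)` strictly greater than `min_distance`.
#'
#' @param gene_map,probe_map annotation data.frames.
#' @param min_distance trans distance (default 10 Mb, strict).
#' @return data.frame with columns `gene`, `probe`.
#' @export
trans_pairs <- function(gene_map, probe_map,
                        min_distance = .gimeth_defaults$trans_distance) {
  out <- lapply(seq_len(nrow(gene_map)), function(j) {
    g <- gene_map[j, ]
    ok <- vapply(seq_len(nrow(probe_map)), function(k) {
      .is_trans(g$chrom, g$tss, g$tes, probe_map$chrom[k],
                probe_map$pos[k], min_distance)
    }, logical(1))
    if (!any(ok)) return(NULL)
    data.frame(gene = g$gene, probe = probe_map$probe[ok])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(gene = character(), probe = character())
  out
}

#' Genome-wide directed trans association scan
#'
#' Regresses methylation at every trans CpG on every valid genetic
#' instrument with covariate adjustment (model `DNAm ~ GI + C`), one
#' record per trans pair.  Implemented by residualizing both sides on the
#' covariates once and sweeping instruments over probes, which equals
#' per-pair OLS with degrees of freedom `n - p_C - 2`.  Signed z-scores
#' are the normal quantiles of the halved p-values with the sign of t,
#' computed in log space so genome-wide-significant records do not
#' underflow.
#'
#' @param gi_matrix samples x instruments matrix of instrument scores
#'   (columns named by gene; only valid instruments should be supplied).
#' @param methylation samples x probes matrix (rank-INT scale).
#' @param C covariate matrix.
#' @param gene_map,probe_map annotations restricted to the scanned
#'   genes/probes.
#' @param min_distance trans distance (default 10 Mb).
#' @return `data.table` of association records: gene, probe, phi, se, t,
#'   p_raw, z.
#' @export
run_scan <- function(gi_matrix, methylation, C, gene_map, probe_map,
                     min_distance = .gimeth_defaults$trans_distance) {
  gi_matrix <- as.matrix(gi_matrix)
  methylation <- as.matrix(methylation)
  if (nrow(gi_matrix) != nrow(methylation)) {
    stop("sample misalignment between instruments and methylation")
  }
  n <- nrow(methylation)
  Gres <- .residualize(gi_matrix, C)
  Mres <- .residualize(methylation, C)
  df <- n - (if (is.null(C)) 0 else ncol(C)) - 2
  ssy <- colSums(Mres^2)
  pairs <- trans_pairs(gene_map[gene_map$gene %in% colnames(gi_matrix), ],
                       probe_map[probe_map$probe %in% colnames(methylation), ],
                       min_distance)
  recs <- lapply(split(pairs$probe, pairs$gene), function(probes) probes)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    g <- names(recs)[i]
    probes <- recs[[i]]
    x <- Gres[, g]
    xx <- sum(x^2)
    cross <- drop(crossprod(Mres[, probes, drop = FALSE], x))
    beta <- cross / xx
    rss <- pmax(ssy[probes] - beta * cross, 0)
    sigma2 <- rss / df
    se <- sqrt(sigma2 / xx)
    t <- ifelse(se > 0, beta / se, 0)
    pz <- .t_to_p_z(t, df)
    out[[i]] <- data.table::data.table(gene = g, probe = probes,
                                       phi = beta, se = se, t = t,
                                       p_raw = pz$p, z = pz$z)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0) {
    res <- data.table::data.table(gene = character(), probe = character(),
                                  phi = numeric(), se = numeric(),
                                  t = numeric(), p_raw = numeric(),
                                  z = numeric())
  }
  res[]
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
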