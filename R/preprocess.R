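#' Filter genes on median expression level
#'
#' Retains genes that are at least moderately expressed: median
#' counts-per-million across samples at or above `min_median_cpm`.  When the
#' gene annotation carries a `biotype` column, only the biotypes listed in
#' `keep_biotypes` are eligible.
#'
#' @param counts numeric matrix of raw counts, samples in rows, genes in
#'   columns.
#' @param min_median_cpm retention threshold on the per-gene median CPM
#'   (default 1; the boundary is inclusive).
#' @param gene_annotation optional data.frame with rownames or a `gene`
#'   column matching `colnames(counts)` and a `biotype` column.
#' @param keep_biotypes biotypes retained when annotation is supplied.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, min_median_cpm = 1,
                             gene_annotation = NULL,
                             keep_biotypes = c("protein_coding", "lincRNA")) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    stop("all-zero library for sample(s): ",
         paste(head(which(lib == 0)), collapse = ", "))
  }
  cpm <- counts / lib * 1e6
  med <- apply(cpm, 2, median)
  keep <- med >= min_median_cpm
  genes <- colnames(counts)
  if (is.null(genes)) genes <- as.character(seq_len(ncol(counts)))
  retained <- genes[keep]
  if (!is.null(gene_annotation) && "biotype" %in% names(gene_annotation)) {
    ids <- if ("gene" %in% names(gene_annotation)) gene_annotation$gene else
      rownames(gene_annotation)
    ok <- ids[gene_annotation$biotype %in% keep_biotypes]
    retained <- retained[retained %in% ok]
  }
  retained
}

#' Rank-based inverse normal transform within cohorts
#'
#' Maps values to normal quantiles of their within-cohort ranks using the
#' Blom offset c = 3/8: `qnorm((rank - 3/8) / (n + 1/4))`.  Ties receive
#' average ranks.  Robustifies downstream linear-model inference against
#' outliers and per-cohort scale differences.
#'
#' @param values numeric vector, or a matrix (samples x features) transformed
#'   column-wise.
#' @param cohort vector of cohort labels, one per sample (default: a single
#'   cohort).
#' @return transformed object of the same shape.
#' @export
rank_inverse_normal <- function(values, cohort = NULL) {
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    out <- apply(values, 2, rank_inverse_normal, cohort = cohort)
    dimnames(out) <- dimnames(values)
    return(out)
  }
  if (is.null(cohort)) cohort <- rep(1L, length(values))
  stopifnot(length(cohort) == length(values), !anyNA(values))
  out <- numeric(length(values))
  for (g in unique(cohort)) {
    idx <- which(cohort == g)
    v <- values[idx]
    if (length(unique(v)) < 2) {
      stop("constant values within cohort '", g, "'; cannot rank-transform")
    }
    r <- rank(v, ties.method = "average")
    n <- length(v)
    out[idx] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  }
  out
}

#' Principal component scores of a data matrix
#'
#' Top-`k` left singular scores of the column-centred matrix, the standard
#' expression/methylation covariate PCs.  Signs follow the convention that
#' each component's largest-magnitude loading is positive, making the
#' decomposition deterministic.
#'
#' @param x numeric matrix, samples in rows.
#' @param k number of components (default 5). If `k` exceeds the matrix
#'   rank, the available components are returned with a warning.
#' @return list with `scores` (n x k), `loadings` (p x k) and
#'   `var_explained` (length k, fractions of total variance).
#' @export
compute_pcs <- function(x, k = 5) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x), "-")
  sv <- svd(xc)
  pos <- sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1]
  r <- sum(pos)
  if (k > r) {
    warning("requested ", k, " components but rank is ", r)
    k <- r
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- sweep(u, 2, d, "*")
  colnames(scores) <- colnames(v) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = v,
       var_explained = d^2 / sum(sv$d^2))
}
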