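#' Simulate genotype dosages with LD blocks
#'
#' Draws a latent multivariate Gaussian per LD block (compound symmetry at
#' the block's `block_r`) and trichotomizes each SNP at its Hardy-Weinberg
#' quantiles, yielding dosages in \{0, 1, 2\} with the requested minor
#' allele frequency and controllable within-block dosage correlation;
#' across blocks correlations are approximately zero.
#'
#' @param config a [sim_config()].
#' @param seed overrides the config seed stream for this stage.
#' @return list with `dosages` (n x SNPs matrix) and `snp_map`.
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- .child_seed(config$seed, 1L)
  sm <- config$snp_map
  n <- config$n_samples
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * nrow(sm)), nrow = n)
    blocks <- split(seq_len(nrow(sm)), paste(sm$chrom, sm$block))
    for (idx in blocks) {
      r <- sm$block_r[idx[1]]
      if (length(idx) > 1 && !is.na(sm$block[idx[1]]) && r > 0) {
        shared <- rnorm(n)
        Z[, idx] <- sqrt(r) * shared + sqrt(1 - r) * Z[, idx]
      }
    }
  })
  D <- matrix(0L, nrow = n, ncol = nrow(sm),
              dimnames = list(NULL, sm$snp))
  for (j in seq_len(nrow(sm))) {
    p <- sm$maf[j]
    ## genotype 0 with prob (1-p)^2, 1 with 2p(1-p), 2 with p^2 (HWE)
    t0 <- qnorm((1 - p)^2)
    t1 <- qnorm(1 - p^2)
    D[, j] <- (Z[, j] > t0) + (Z[, j] > t1)
  }
  list(dosages = D, snp_map = sm)
}

#' Simulate cohort covariates and cell composition
#'
#' Age, sex, a balanced cohort label, and three cell fractions obtained by
#' softmax of perturbed logits.  The biological cell-composition driver is
#' a unit-variance latent; the measured fractions are built from a noisy
#' copy of it (`cell_reliability` = squared correlation between the two),
#' so adjusting for measured fractions leaves residual confounding — the
#' situation the WBC-variant filter addresses.  A
#' [scenario_cell_confounder()] puts its SNP into the true latent.
#'
#' @inheritParams simulate_genotypes
#' @param dosages dosage matrix (needed when a cell-confounder scenario is
#'   present).
#' @return list with `covariates` (data.frame: age, sex, cohort,
#'   cf1..cf3), `cell_latent` (true driver) and `cell_latent_obs`.
#' @export
simulate_covariates <- function(config, dosages = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- .child_seed(config$seed, 2L)
  n <- config$n_samples
  conf <- Filter(function(s) s$kind == "cell_composition_confounder",
                 config$scenarios)
  if (length(conf) > 1) {
    stop("at most one cell_composition_confounder scenario is supported")
  }
  withr::with_seed(seed, {
    age <- rnorm(n, 55, 8)
    sex <- rbinom(n, 1, 0.5)
    cohort <- rep_len(paste0("C", seq_len(config$n_cohorts)), n)
    w <- rnorm(n)
    if (length(conf) == 1) {
      sc <- conf[[1]]
      if (is.null(dosages)) stop("dosages required for cell confounder")
      d <- .force_var(dosages[, sc$snp], 1)
      w <- sqrt(sc$snp_share) * d + sqrt(1 - sc$snp_share) * w
      w <- .force_var(w, 1)
    }
    rel <- config$cell_reliability
    w_obs <- sqrt(rel) * w + sqrt(1 - rel) * rnorm(n)
    base <- c(1.2, 0.4, 0)
    load <- c(0.35, -0.2, -0.1)
    logits <- matrix(base, n, 3, byrow = TRUE) +
      outer(w_obs, load) + matrix(rnorm(n * 3, sd = 0.15), n)
    fr <- exp(logits)
    fr <- fr / rowSums(fr)
  })
  covariates <- data.frame(age = age, sex = sex, cohort = cohort,
                           cf1 = fr[, 1], cf2 = fr[, 2], cf3 = fr[, 3])
  list(covariates = covariates, cell_latent = w, cell_latent_obs = w_obs)
}

## Numeric versions of named covariates for effect injection.  Discrete
## covariates (sex, cohort) use centred level coding so that an effect of
## e separates adjacent groups by exactly e; continuous covariates are
## standardized to unit variance ("per SD of the covariate").
.covariate_signal <- function(name, covariates) {
  v <- switch(name,
              cohort = as.integer(factor(covariates$cohort)),
              covariates[[name]])
  if (is.null(v)) stop("unknown covariate '", name, "' in covariate_effects")
  if (name %in% c("cohort", "sex")) v - mean(v) else .force_var(v, 1)
}

## Apply shared-eQTL scenarios to the cis-effect table: the shared SNP
## carries fraction `share` of each involved gene's cis-genetic variance.
.apply_shared_eqtl <- function(cis, scenarios) {
  for (sc in Filter(function(s) s$kind == "shared_eqtl", scenarios)) {
    for (g in c(sc$gene_a, sc$gene_b)) {
      own <- cis$gene == g & cis$snp != sc$snp
      if (!any(own)) {
        stop("shared_eqtl gene ", g, " needs at least one private cis SNP")
      }
      w2 <- sum(cis$effect[own]^2)
      shared_w <- sqrt(sc$share / (1 - sc$share) * w2)
      hit <- cis$gene == g & cis$snp == sc$snp
      if (any(hit)) {
        cis$effect[hit] <- shared_w
      } else {
        cis <- rbind(cis, data.frame(gene = g, snp = sc$snp,
                                     effect = shared_w))
      }
    }
  }
  cis
}

#' Simulate gene expression from cis genotypes and covariates
#'
#' Per gene: a cis-genetic component (weighted sum of standardized
#' dosages, rescaled so its realized variance equals `h2_cis` under the
#' simulated LD), covariate effects, scenario terms, and Gaussian noise
#' scaled so the latent trait has unit total variance.  A pseudo-count
#' matrix (Poisson around an exponentiated, library-scaled latent) is
#' emitted alongside so the median-CPM filter is exercisable.
#'
#' @inheritParams simulate_covariates
#' @param dosages dosage matrix from [simulate_genotypes()].
#' @param covar_sim output of [simulate_covariates()] (generated if NULL).
#' @return list with `latent` (n x genes), `counts`, `genetic_value`
#'   (the true per-gene genetic score, i.e. the oracle instrument) and
#'   `cis_effects_realized` (rescaled per-SD-dosage weights).
#' @export
simulate_expression <- function(dosages, config, covar_sim = NULL,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- .child_seed(config$seed, 3L)
  if (is.null(covar_sim)) covar_sim <- simulate_covariates(config, dosages)
  n <- config$n_samples
  gm <- config$gene_map
  cis <- .apply_shared_eqtl(config$cis_effects, config$scenarios)
  conf <- Filter(function(s) s$kind == "cell_composition_confounder",
                 config$scenarios)
  ce <- config$covariate_effects$expression
  latent <- genetic <- matrix(0, n, nrow(gm),
                              dimnames = list(NULL, gm$gene))
  counts <- matrix(0L, n, nrow(gm), dimnames = list(NULL, gm$gene))
  realized <- list()
  withr::with_seed(seed, {
    libfac <- exp(rnorm(n, 0, 0.2))
    for (j in seq_len(nrow(gm))) {
      g <- gm$gene[j]
      h2 <- gm$h2_cis[j]
      if (h2 >= 1) stop("h2_cis >= 1 for gene ", g)
      rows <- cis[cis$gene == g, , drop = FALSE]
      G <- rep(0, n)
      if (nrow(rows) > 0 && h2 > 0) {
        Ds <- .std_cols(dosages[, rows$snp, drop = FALSE])
        G <- drop(Ds %*% rows$effect)
        sdG <- sd(G)
        if (sdG > 0) {
          fac <- sqrt(h2) / sdG
          G <- G * fac
          rows$effect <- rows$effect * fac
        }
      }
      realized[[g]] <- rows
      signal <- G
      if (!is.null(ce)) {
        for (i in which(ce$gene == g)) {
          signal <- signal +
            ce$effect[i] * .covariate_signal(ce$covariate[i],
                                             covar_sim$covariates)
        }
      }
      for (sc in conf) {
        if (sc$gene == g) signal <- signal + sc$cell_to_expr * covar_sim$cell_latent
      }
      vs <- var(signal)
      if (vs >= 1) stop("variance budget exceeded for gene ", g)
      latent[, j] <- signal + rnorm(n, sd = sqrt(1 - vs))
      genetic[, j] <- G
      counts[, j] <- rpois(n, lambda = libfac *
                             exp(gm$base_log_cpm[j] + 0.5 * latent[, j]))
    }
  })
  list(latent = latent, counts = counts, genetic_value = genetic,
       cis_effects_realized = do.call(rbind, realized))
}

#' Simulate DNA methylation from expression, genotypes and covariates
#'
#' Per probe: trans effects of regulator expression (`phi` SD methylation
#' per SD expression), covariate effects, scenario terms (direct
#' SNP-to-CpG dosage effects; cell-composition confounding through the
#' true cell latent), and Gaussian noise scaled to unit total variance.
#' By default the latent-normal scale is returned (the pipeline rank-INTs
#' methylation regardless); `methylation_scale = "beta"` squashes through
#' an inverse logit for I/O realism and flags it.
#'
#' @inheritParams simulate_expression
#' @param expression output of [simulate_expression()].
#' @return list with `methylation` (n x probes) and `scale` flag.
#' @export
simulate_methylation <- function(expression, dosages, config,
                                 covar_sim = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- .child_seed(config$seed, 4L)
  if (is.null(covar_sim)) covar_sim <- simulate_covariates(config, dosages)
  n <- config$n_samples
  pm <- config$probe_map
  tm <- config$trans_map
  me <- config$covariate_effects$methylation
  M <- matrix(0, n, nrow(pm), dimnames = list(NULL, pm$probe))
  withr::with_seed(seed, {
    for (k in seq_len(nrow(pm))) {
      pr <- pm$probe[k]
      signal <- rep(0, n)
      for (i in which(tm$probe == pr)) {
        signal <- signal +
          tm$phi[i] * .force_var(expression$latent[, tm$gene[i]], 1)
      }
      if (!is.null(me)) {
        for (i in which(me$probe == pr)) {
          signal <- signal +
            me$effect[i] * .covariate_signal(me$covariate[i],
                                             covar_sim$covariates)
        }
      }
      for (sc in config$scenarios) {
        if (sc$kind == "direct_snp_to_cpg" && sc$probe == pr) {
          signal <- signal + sc$effect * .force_var(dosages[, sc$snp], 1)
        }
        if (sc$kind == "cell_composition_confounder" && sc$probe == pr) {
          signal <- signal + sc$cell_to_meth * covar_sim$cell_latent
        }
      }
      vs <- var(signal)
      if (vs > 1 + 1e-8) stop("variance budget exceeded for probe ", pr)
      M[, k] <- signal + rnorm(n, sd = sqrt(max(0, 1 - vs)))
    }
  })
  if (config$methylation_scale == "beta") {
    M <- 1 / (1 + exp(-2 * M))
  }
  list(methylation = M, scale = config$methylation_scale)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the genotype, covariate, expression and methylation generators
#' under one seed stream and assembles a `gimeth_cohort`: aligned matrices
#' plus annotations and a `truth` component (true regulators, realized cis
#' weights, true genetic scores, scenario labels) that downstream pipeline
#' stages never read.
#'
#' @inheritParams simulate_genotypes
#' @return object of class `gimeth_cohort`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  geno <- simulate_genotypes(config)
  cv <- simulate_covariates(config, geno$dosages)
  ex <- simulate_expression(geno$dosages, config, cv)
  me <- simulate_methylation(ex, geno$dosages, config, cv)
  structure(list(
    dosages = geno$dosages,
    expression = ex$latent,
    expression_counts = ex$counts,
    methylation = me$methylation,
    methylation_scale = me$scale,
    covariates = cv$covariates,
    snp_map = config$snp_map,
    gene_map = config$gene_map,
    probe_map = config$probe_map,
    truth = list(trans_map = config$trans_map,
                 cis_effects = ex$cis_effects_realized,
                 genetic_value = ex$genetic_value,
                 scenarios = config$scenarios,
                 cell_latent = cv$cell_latent),
    config = config
  ), class = "gimeth_cohort")
}

#' @export
print.gimeth_cohort <- function(x, ...) {
  cat("gimeth_cohort:", nrow(x$dosages), "samples,",
      ncol(x$dosages), "SNPs,", ncol(x$expression), "genes,",
      ncol(x$methylation), "probes\n")
  cat("  methylation scale:", x$methylation_scale,
      "| scenarios:", length(x$truth$scenarios), "\n")
  invisible(x)
}
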