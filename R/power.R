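#' Analytic power of the instrument-to-CpG test
#'
#' Power to detect a trans effect of `effect_sd` (SD methylation per SD
#' expression) at two-sided level `alpha`, given sample size `n` and the
#' fraction `r2_gi` of expression variance explained by the instrument.
#'
#' Under the generator's convention — methylation standardized to unit
#' total variance with the expression term included — the instrument
#' explains `r2_m = effect_sd^2 * r2_gi` of methylation variance, and the
#' test statistic follows a non-central F(1, n - 2) with
#' `ncp = n * r2_m / (1 - r2_m)`.  Power is the upper-tail mass beyond the
#' central critical value.  The denominator df deliberately ignores the
#' covariate count (covariates reduce residual variance in practice,
#' making this slightly conservative).
#'
#' @param n sample size (> 3).
#' @param r2_gi instrument R-squared on expression, in \[0, 1).  For the
#'   neighbour-corrected analysis pass the partial R-squared.
#' @param effect_sd effect size; `|effect_sd| * sqrt(r2_gi)` must be < 1.
#' @param alpha two-sided level (default the scan-wide threshold
#'   0.05 / (8644 * 428126)).
#' @return power in \[0, 1\]; equals `alpha` at `effect_sd = 0`.
#' @export
analytic_power <- function(n, r2_gi, effect_sd,
                           alpha = bonferroni_threshold(0.05, 8644 * 428126)) {
  stopifnot(n > 3, r2_gi >= 0, r2_gi < 1, alpha > 0, alpha < 1)
  r2_m <- effect_sd^2 * r2_gi
  if (r2_m >= 1) stop("effect_sd^2 * r2_gi must be < 1")
  ncp <- n * r2_m / (1 - r2_m)
  crit <- qf(alpha, 1, n - 2, lower.tail = FALSE)
  pf(crit, 1, n - 2, ncp = ncp, lower.tail = FALSE)
}

#' Per-gene power profile over an effect-size grid
#'
#' One row per gene and analysis mode: `uncorrected` uses the marginal
#' instrument R-squared, `corrected` the partial R-squared given
#' neighbouring instruments (power is never higher in the corrected
#' mode when the partial R-squared is smaller).
#'
#' @param summaries data.frame with columns `gene`, `r2_marginal` and
#'   `r2_partial`.
#' @param n sample size of the scan.
#' @param effects effect-size grid (default 0.25, 0.5, 1 SD).
#' @param alpha two-sided level (default scan-wide threshold).
#' @return data.frame gene, mode, r2, and one `power_<effect>` column per
#'   grid point.
#' @export
power_profile <- function(summaries, n, effects = c(0.25, 0.5, 1),
                          alpha = bonferroni_threshold(0.05, 8644 * 428126)) {
  stopifnot(all(c("gene", "r2_marginal", "r2_partial") %in%
                  names(summaries)))
  modes <- data.frame(
    gene = rep(summaries$gene, 2),
    mode = rep(c("uncorrected", "corrected"), each = nrow(summaries)),
    r2 = c(summaries$r2_marginal, summaries$r2_partial))
  for (e in effects) {
    modes[[paste0("power_", e)]] <-
      vapply(modes$r2, function(r2) analytic_power(n, r2, e, alpha),
             numeric(1))
  }
  modes
}

#' Monte-Carlo power of the instrument-to-CpG test
#'
#' Simulates the full test under the population version of the
#' generator's model (`expr = sqrt(r2) * GI + noise`; `meth = effect *
#' expr + noise`, both unit population variance) and returns the
#' rejection frequency of the simple regression of methylation on the
#' instrument at level `alpha`.  Serves as the independent oracle for
#' [analytic_power()].
#'
#' @param n,r2_gi,effect_sd,alpha as in [analytic_power()].
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed RNG seed.
#' @param chunk replicates per block (memory control).
#' @return rejection frequency.
#' @export
mc_power <- function(n, r2_gi, effect_sd, alpha, reps = 10000, seed = 1L,
                     chunk = 500) {
  crit <- qf(alpha, 1, n - 2, lower.tail = FALSE)
  tcrit2 <- crit                       # t^2 ~ F(1, n-2)
  hits <- 0
  withr::with_seed(seed, {
    done <- 0
    while (done < reps) {
      m <- min(chunk, reps - done)
      G <- matrix(rnorm(n * m), n)
      ## population-unit-variance structural equations: expr and meth both
      ## have variance 1, effect_sd in SD-methylation per SD-expression
      E <- sqrt(r2_gi) * G + sqrt(1 - r2_gi) * matrix(rnorm(n * m), n)
      noise_var <- max(0, 1 - effect_sd^2)
      M <- effect_sd * E + sqrt(noise_var) * matrix(rnorm(n * m), n)
      M <- M / sqrt(effect_sd^2 + noise_var)
      Gc <- sweep(G, 2, colMeans(G), "-")
      Mc <- sweep(M, 2, colMeans(M), "-")
      ## correlation-based F = r^2 (n-2) / (1 - r^2)
      r <- colSums(Gc * Mc) / sqrt(colSums(Gc^2) * colSums(Mc^2))
      f <- r^2 * (n - 2) / (1 - r^2)
      hits <- hits + sum(f > tcrit2)
      done <- done + m
    }
  })
  hits / reps
}
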