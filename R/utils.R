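## Internal numerical helpers shared across modules.

## Two-sided p-value and signed z-score from a t statistic, computed on the
## log scale so that extreme statistics (|t| ~ 40 at n ~ 4000 gives
## p ~ 1e-250) survive without underflow in the z conversion.  p itself is
## clamped to the smallest positive double so it stays in (0, 1].
.t_to_p_z <- function(t, df) {
  log_p_one <- pt(-abs(t), df = df, log.p = TRUE)     # one-sided upper
  log_p_two <- log(2) + log_p_one
  p <- pmax(exp(log_p_two), .Machine$double.xmin)
  z <- -sign(t) * qnorm(log_p_one, log.p = TRUE)       # |z| from tail prob
  z[t == 0] <- 0
  list(p = p, z = z)
}

## Two-sided p from a z-score, log-safe.
.z_to_p <- function(z) {
  pmax(exp(log(2) + pnorm(-abs(z), log.p = TRUE)), .Machine$double.xmin)
}

## Column-standardize, guarding zero-variance columns (left centred).
.std_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

## Scale a vector to have exactly the requested sample variance (no-op on
## zero-variance input). Used by the generator for variance bookkeeping.
.force_var <- function(v, target) {
  s <- sd(v)
  if (s == 0 || target == 0) return(rep(0, length(v)))
  (v - mean(v)) / s * sqrt(target)
}

## Expand a covariate data.frame into a numeric model matrix without
## intercept: factors/characters become treatment dummies, numerics pass
## through.  Column order is deterministic.
.covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates)) return(covariates)
  stopifnot(is.data.frame(covariates))
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        return(NULL)
      }
      m <- sapply(levels(f)[-1], function(l) as.numeric(f == l))
      colnames(m) <- paste0(nm, levels(f)[-1])
    }
    m
  })
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}

## Residualize columns of y on [1, C] via QR; returns matrix of residuals.
.residualize <- function(y, C = NULL) {
  y <- as.matrix(y)
  X <- cbind(`(Intercept)` = rep(1, nrow(y)), C)
  qr.resid(qr(X), y)
}

## Derive a child seed from a parent seed and a stream index, staying well
## inside 32-bit integer range.
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483629L) + 1L
}
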