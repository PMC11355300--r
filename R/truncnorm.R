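# Truncated-normal primitives used by the synthetic-cohort copula.
# All take the latent (untruncated) mean/sd plus truncation bounds.

ptnorm <- function(q, mean, sd, lower, upper) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  p <- (pnorm(pmin(pmax(q, lower), upper), mean, sd) - pa) / (pb - pa)
  pmin(pmax(p, 0), 1)
}

qtnorm <- function(p, mean, sd, lower, upper) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  x <- qnorm(pa + p * (pb - pa), mean, sd)
  pmin(pmax(x, lower), upper)
}

# Mean and SD of N(mean, sd^2) truncated to [lower, upper] (closed form).
tnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for latent (mean, sd) so the truncated distribution has the target
# moments. Needed because truncating N(target_mean, target_sd^2) to the
# observed range shifts its mean (e.g. by > 1 mm for asynclitism degree).
calibrate_tnorm <- function(target_mean, target_sd, lower, upper) {
  stopifnot(lower < upper, target_sd > 0,
            target_mean > lower, target_mean < upper)
  obj <- function(par) {
    mo <- tnorm_moments(par[1], exp(par[2]), lower, upper)
    if (!all(is.finite(mo))) return(1e10)
    ((mo[1] - target_mean) / target_sd)^2 + ((mo[2] - target_sd) / target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  if (fit$value > 1e-6) {
    stop(sprintf(
      "cannot match truncated-normal moments (mean %.4g, sd %.4g on [%.4g, %.4g])",
      target_mean, target_sd, lower, upper))
  }
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

# Repair a correlation matrix that is not positive semi-definite by clipping
# negative eigenvalues and rescaling to unit diagonal.
repair_correlation <- function(R, warn = TRUE) {
  stopifnot(isSymmetric(R))
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(R)
  if (warn) {
    warning("target correlation matrix is not positive semi-definite; ",
            "repaired by eigenvalue clipping", call. = FALSE)
  }
  v <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  (R2 + t(R2)) / 2
}
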