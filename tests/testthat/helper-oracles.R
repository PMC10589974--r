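# Independent oracles, coded directly from the defining formulas and kept
# free of any package internals.

# Exact posterior of an intercept-only Bernoulli-logit model with a
# N(0, prior_sd^2) prior, by dense grid quadrature.
quad_posterior_intercept <- function(successes, n, prior_sd = 10,
                                     lo = -15, hi = 15, m = 8001) {
  g <- seq(lo, hi, length.out = m)
  lp <- stats::dnorm(g, 0, prior_sd, log = TRUE) +
    successes * g - n * log1p(exp(g))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  list(mean = sum(w * g),
       sd = sqrt(sum(w * g^2) - sum(w * g)^2),
       p_mean = sum(w * stats::plogis(g)))
}

# Exact posterior of (intercept, slope) for a single binary covariate,
# independent N(0, prior_sd^2) priors, 2-D grid quadrature.
quad_posterior_2param <- function(y, x, prior_sd = 10, lo = -12, hi = 12,
                                  m = 401) {
  g <- seq(lo, hi, length.out = m)
  grid <- expand.grid(b0 = g, b1 = g)
  eta_mat <- outer(grid$b0, rep(1, length(y))) +
    outer(grid$b1, x)
  ll <- rowSums(eta_mat * rep(y, each = nrow(grid))) -
    rowSums(log1p(exp(eta_mat)))
  lp <- ll + stats::dnorm(grid$b0, 0, prior_sd, log = TRUE) +
    stats::dnorm(grid$b1, 0, prior_sd, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  list(mean = c(sum(w * grid$b0), sum(w * grid$b1)),
       sd = c(sqrt(sum(w * grid$b0^2) - sum(w * grid$b0)^2),
              sqrt(sum(w * grid$b1^2) - sum(w * grid$b1)^2)))
}

# Reference Taylor-linearization variance of a weighted proportion under a
# stratified cluster design (standard linearization formula, independent
# coding with explicit loops).
oracle_prevalence_var <- function(y, w, stratum, psu) {
  W <- sum(w)
  p <- sum(w * y) / W
  u <- w * (y - p) / W
  v <- 0
  for (h in unique(stratum)) {
    rows <- which(stratum == h)
    psus <- unique(psu[rows])
    nh <- length(psus)
    z <- sapply(psus, function(c) sum(u[rows][psu[rows] == c]))
    zbar <- mean(z)
    v <- v + nh / (nh - 1) * sum((z - zbar)^2)
  }
  v
}

# Moran's I from the definition, fully expanded double sum.
oracle_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * z[i] * z[j]
  }
  (n / sum(W)) * num / sum(z^2)
}
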