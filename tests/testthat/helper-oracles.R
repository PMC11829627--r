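# Independent brute-force oracles for the paired model.  These integrate the
# raw joint density over a dense Simpson grid in (delta, log sigma2) without
# any of the analytic reductions the package uses, so agreement is a genuine
# two-route check.

simpson_weights <- function(n, h) {
  stopifnot(n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

# grids wide enough for small-n test datasets
oracle_grids <- function(d, prior, n_u = 2001, n_delta = 801) {
  n <- length(d)
  v <- stats::var(d)
  u <- seq(log(v) - 16, log(v) + 16, length.out = n_u)
  dbar <- mean(d)
  span <- 10 * max(prior$sd, sqrt(v), abs(dbar - prior$mean), 0.5)
  delta <- seq(min(dbar, prior$mean) - span, max(dbar, prior$mean) + span,
               length.out = n_delta)
  list(u = u, wu = simpson_weights(n_u, u[2] - u[1]),
       delta = delta, wd = simpson_weights(n_delta, delta[2] - delta[1]))
}

# log sum_i w_i * exp(lx_i), in log space
oracle_lse <- function(lx, w) {
  m <- max(lx)
  m + log(sum(w * exp(lx - m)))
}

# log p(d | delta, sigma = exp(u/2)) for a vector of delta at one u
oracle_loglik <- function(d, delta, u) {
  sigma <- exp(u / 2)
  colSums(stats::dnorm(outer(d, delta, "-"), 0, sigma, log = TRUE))
}

# log variance prior on the u axis (Jeffreys: flat measure in u)
oracle_log_vprior <- function(u, prior) {
  switch(prior$variance_prior,
    jeffreys = 0,
    half_normal = {
      tau <- prior$variance_scale
      0.5 * log(2 / pi) - log(tau) - exp(u) / (2 * tau^2) + u / 2 - log(2)
    },
    lognormal = stats::dnorm(u, prior$variance_par[1], prior$variance_par[2],
                             log = TRUE)
  )
}

# log marginal likelihood by dense 2-D integration
oracle_log_ml <- function(d, prior, hypothesis = "alternative") {
  g <- oracle_grids(d, prior)
  per_u <- vapply(seq_along(g$u), function(j) {
    u <- g$u[j]
    lp <- oracle_log_vprior(u, prior)
    if (hypothesis == "null") {
      sum(stats::dnorm(d, 0, exp(u / 2), log = TRUE)) + lp
    } else {
      ll <- oracle_loglik(d, g$delta, u) +
        stats::dnorm(g$delta, prior$mean, prior$sd, log = TRUE)
      oracle_lse(ll, g$wd) + lp
    }
  }, numeric(1))
  oracle_lse(per_u, g$wu)
}

# marginal posterior density of delta at given points, by 1-D integration
# over u per point, normalized by the oracle marginal likelihood
oracle_posterior_density <- function(d, prior, at) {
  g <- oracle_grids(d, prior)
  log_ml <- oracle_log_ml(d, prior, "alternative")
  vapply(at, function(dl) {
    per_u <- vapply(g$u, function(u) {
      sum(stats::dnorm(d, dl, exp(u / 2), log = TRUE)) +
        oracle_log_vprior(u, prior)
    }, numeric(1))
    exp(oracle_lse(per_u, g$wu) +
          stats::dnorm(dl, prior$mean, prior$sd, log = TRUE) - log_ml)
  }, numeric(1))
}

# closed-form conjugate posterior for known variance (independent derivation)
oracle_conjugate <- function(d, m0, s0, sigma) {
  n <- length(d)
  prec <- 1 / s0^2 + n / sigma^2
  list(mean = (m0 / s0^2 + n * mean(d) / sigma^2) / prec,
       sd = sqrt(1 / prec))
}

# small random datasets for oracle comparisons
oracle_datasets <- function(n_sets = 20, seed = 4242) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    n <- sample(5:12, 1)
    stats::rnorm(n, mean = stats::runif(1, -0.5, 0.8),
                 sd = stats::runif(1, 0.15, 0.8))
  })
}
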