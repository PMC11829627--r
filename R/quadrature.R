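# Deterministic quadrature machinery for the paired model
#
#   d_i | delta, sigma2 ~ N(delta, sigma2),  delta ~ N(m0, s0^2)
#
# With delta integrated analytically conditional on sigma2, the remaining
# 1-D integral over sigma2 is done by Gauss-Legendre quadrature on the
# log-variance axis, widening the interval until the end-point integrand is
# negligible (added tail mass far below 1e-10 of the total).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

diff_stats <- function(d) {
  n <- length(d)
  dbar <- mean(d)
  list(n = n, dbar = dbar, S = sum((d - dbar)^2))
}

# log p(d | sigma2 = exp(u), hypothesis), delta integrated out (alternative)
# or fixed at 0 (null); vectorized over u
log_cond_ml <- function(u, st, prior, hypothesis) {
  sigma2 <- exp(u)
  if (hypothesis == "null") {
    -0.5 * st$n * (log(2 * pi) + u) - (st$S + st$n * st$dbar^2) / (2 * sigma2)
  } else {
    -0.5 * (st$n - 1) * (log(2 * pi) + u) - 0.5 * log(st$n) -
      st$S / (2 * sigma2) +
      stats::dnorm(st$dbar, prior$mean, sqrt(prior$sd^2 + sigma2 / st$n),
                   log = TRUE)
  }
}

# log prior density of the variance expressed on the u = log(sigma2) axis,
# Jacobian included.  Jeffreys (1/sigma2) is the flat measure in u; it is
# improper, common to both hypotheses, and cancels in Bayes factors.
log_variance_prior_u <- function(u, prior) {
  switch(prior$variance_prior,
    jeffreys = rep(0, length(u)),
    half_normal = {
      tau <- prior$variance_scale
      0.5 * log(2 / pi) - log(tau) - exp(u) / (2 * tau^2) + u / 2 - log(2)
    },
    lognormal = stats::dnorm(u, prior$variance_par[1], prior$variance_par[2],
                             log = TRUE)
  )
}

#' @importFrom pracma gaussLegendre
variance_grid <- function(st, prior, hypothesis, n_nodes = 257L,
                          drop_tol = 60) {
  if (st$S <= 0 && hypothesis == "alternative")
    stop(paste("all differences are identical: the change-score variance is",
               "degenerate; supply a known-variance fitting prior",
               "(sigma_d) instead"), call. = FALSE)
  u0 <- log(max(st$S + st$n * st$dbar^2, .Machine$double.xmin) / st$n)
  if (prior$variance_prior == "lognormal")
    u0 <- (u0 + prior$variance_par[1]) / 2
  lo <- u0 - 8
  hi <- u0 + 8
  for (iter in 1:100) {
    gl <- pracma::gaussLegendre(n_nodes, lo, hi)
    logf <- log_cond_ml(gl$x, st, prior, hypothesis) +
      log_variance_prior_u(gl$x, prior)
    m <- max(logf)
    if (!is.finite(m)) {
      lo <- lo - (hi - lo) / 2
      hi <- hi + (hi - lo) / 2
      next
    }
    if (logf[1] > m - drop_tol || logf[n_nodes] > m - drop_tol) {
      # tails not yet negligible: widen around the current peak
      centre <- gl$x[which.max(logf)]
      half <- 1.4 * (hi - lo) / 2
      lo <- centre - half
      hi <- centre + half
      next
    }
    core <- range(gl$x[logf > m - 55])
    if (diff(core) < (hi - lo) / 8 && iter < 100) {
      # the integrand occupies a sliver of the interval (e.g. a tight
      # variance prior): zoom in so the nodes resolve it
      pad <- 0.5 * max(diff(core), (hi - lo) / n_nodes)
      lo <- core[1] - pad
      hi <- core[2] + pad
      next
    }
    break
  }
  logw <- logf + log(gl$w)
  list(u = gl$x, sigma2 = exp(gl$x), logf = logf,
       log_ml = logsumexp(logw),
       weights = exp(logw - logsumexp(logw)))
}

# conditional conjugate posterior of delta at each variance node, plus the
# node weights: the marginal posterior of delta is this normal mixture
posterior_mixture <- function(d, prior) {
  st <- diff_stats(d)
  if (prior$mode == "known_variance") {
    sigma2 <- prior$sigma_d^2
    prec <- 1 / prior$sd^2 + st$n / sigma2
    return(list(w = 1,
                mu = (prior$mean / prior$sd^2 + st$n * st$dbar / sigma2) / prec,
                tau = sqrt(1 / prec),
                st = st))
  }
  g <- variance_grid(st, prior, "alternative")
  prec <- 1 / prior$sd^2 + st$n / g$sigma2
  list(w = g$weights,
       mu = (prior$mean / prior$sd^2 + st$n * st$dbar / g$sigma2) / prec,
       tau = sqrt(1 / prec),
       st = st)
}

mixture_mean <- function(mix) sum(mix$w * mix$mu)

mixture_sd <- function(mix) {
  m <- mixture_mean(mix)
  sqrt(max(0, sum(mix$w * (mix$tau^2 + mix$mu^2)) - m^2))
}

mixture_cdf <- function(mix, x) {
  vapply(x, function(xi) sum(mix$w * stats::pnorm(xi, mix$mu, mix$tau)),
         numeric(1))
}

mixture_density <- function(mix, x) {
  vapply(x, function(xi) sum(mix$w * stats::dnorm(xi, mix$mu, mix$tau)),
         numeric(1))
}

mixture_quantile <- function(mix, p) {
  m <- mixture_mean(mix)
  s <- max(mixture_sd(mix), .Machine$double.eps)
  vapply(p, function(pi) {
    stats::uniroot(function(x) mixture_cdf(mix, x) - pi,
                   lower = m - 15 * s, upper = m + 15 * s,
                   extendInt = "upX", tol = 1e-12)$root
  }, numeric(1))
}
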