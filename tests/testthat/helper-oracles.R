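# Independent numerical oracles used across the suite. All are built on
# dense-grid quadrature or base-R primitives and never touch the package's
# optimisation path.

# Posterior over z = logit(psi) for one (cell, event) under a Gaussian
# prior, by trapezoid quadrature on a fixed grid. Returns the exact
# posterior median of psi, the log evidence (same multinomial-constant
# convention as splice_loglik, i.e. constant omitted) and E[psi | s].
oracle_posterior <- function(s, L, prior_mean, prior_sd,
                             ngrid = 8001L, zlim = 30) {
  z <- seq(-zlim, zlim, length.out = ngrid)
  ll <- vapply(z, function(zz) splice_loglik(s, stats::plogis(zz), L),
               numeric(1))
  lp <- stats::dnorm(z, prior_mean, prior_sd, log = TRUE) + ll
  m <- max(lp)
  w <- exp(lp - m)
  h <- z[2L] - z[1L]
  tw <- rep(h, ngrid); tw[c(1L, ngrid)] <- h / 2
  Zc <- sum(w * tw)
  cdf <- cumsum(w * tw) / Zc
  zmed <- stats::approx(cdf, z, xout = 0.5, ties = "ordered")$y
  list(psi_median = stats::plogis(zmed),
       log_evidence = m + log(Zc),
       psi_mean = sum(stats::plogis(z) * w * tw) / Zc)
}

# E_{q(z)}[log p(s | z)] for q = N(mu, delta^2), by trapezoid quadrature
# centred on the variational mean.
oracle_expected_loglik <- function(s, L, mu, delta, ngrid = 8001L) {
  z <- mu + delta * seq(-10, 10, length.out = ngrid)
  ll <- vapply(z, function(zz) splice_loglik(s, stats::plogis(zz), L),
               numeric(1))
  q <- stats::dnorm(z, mu, delta)
  h <- z[2L] - z[1L]
  sum(q * ll) * h
}

# KL(N(mu_q, delta_q^2) || N(mu_p, sigma_p^2)) by adaptive quadrature.
oracle_kl <- function(mu_q, delta_q, mu_p, sigma_p) {
  stats::integrate(function(z) {
    stats::dnorm(z, mu_q, delta_q) *
      (stats::dnorm(z, mu_q, delta_q, log = TRUE) -
         stats::dnorm(z, mu_p, sigma_p, log = TRUE))
  }, -Inf, Inf, rel.tol = 1e-11)$value
}

# Rank-based AUROC (equivalent to the Wilcoxon statistic).
oracle_auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-wise AUPRC).
oracle_auprc <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

# Rolling-mean smoother for ELBO traces.
smooth_trace <- function(trace, window = 100L) {
  n <- length(trace)
  if (n < window) return(mean(trace))
  vapply(window:n, function(i) mean(trace[(i - window + 1L):i]), numeric(1))
}
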