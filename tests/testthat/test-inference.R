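test_that("prior_params reproduces the regression prior", {
  # intercept-only with beta_g = 2: every cell shares prior mean 2
  pp <- prior_params(Y = matrix(1, 4, 1), B = matrix(2, 3, 1), sigma = 1.5)
  expect_equal(pp$mean, matrix(2, 4, 3))
  expect_equal(pp$sd, rep(1.5, 3))
  # mode 0: logit-normal centred on 0.5
  p0 <- prior_params(M = 4, N = 3, prior0_scale = 3)
  expect_equal(p0$mean, matrix(0, 4, 3))
  expect_equal(p0$sd, rep(3, 3))
  # zero gene features contribute nothing regardless of A
  px <- prior_params(X = matrix(0, 3, 2), A = matrix(rnorm(8), 4, 2), sigma = 1)
  expect_equal(px$mean, matrix(0, 4, 3))
  expect_error(prior_params(Y = matrix(1, 4, 1), B = matrix(2, 3, 2), sigma = 1),
               "shape mismatch")
})

test_that("kl_gaussian matches closed forms and numerical quadrature", {
  expect_equal(kl_gaussian(0.7, 1.3, 0.7, 1.3), 0)
  expect_equal(kl_gaussian(1, 1, 0, 1), 0.5)
  expect_equal(kl_gaussian(0, 1, 0, 2), log(2) - 3 / 8)
  set.seed(5)
  for (rep in 1:10) {
    mq <- rnorm(1); dq <- runif(1, 0.2, 3)
    mp <- rnorm(1); sp <- runif(1, 0.2, 3)
    expect_equal(kl_gaussian(mq, dq, mp, sp), oracle_kl(mq, dq, mp, sp),
                 tolerance = 1e-6)
  }
  expect_gte(kl_gaussian(rnorm(1), runif(1, 0.1, 2), rnorm(1), runif(1, 0.1, 2)), 0)
  expect_error(kl_gaussian(0, -1, 0, 1), "positive")
})

test_that("elbo_estimate is exact on empty data and unbiased against quadrature", {
  # all counts zero, posterior = prior: KL = 0 and likelihood = 0
  d0 <- make_scd(matrix(0, 3, 2), matrix(0, 3, 2), matrix(0, 3, 2),
                 velocity_lengths())
  expect_identical(elbo_estimate(d0, mu = 0, delta = 3, prior_mean = 0,
                                 prior_sd = 3, R = 5, seed = 1), 0)

  # single cell/event, s = [5, 5, 0]: the MC mean matches quadrature
  L <- velocity_lengths()
  d <- make_scd(matrix(5, 1, 1), matrix(5, 1, 1), matrix(0, 1, 1), L)
  mu <- 0.3; delta <- 0.8; pm <- 0; ps <- 2
  est <- elbo_estimate(d, mu, delta, pm, ps, R = 20000L, seed = 42)
  exact <- -kl_gaussian(mu, delta, pm, ps) +
    oracle_expected_loglik(c(5, 5, 0), L, mu, delta)
  # MC standard error of the likelihood term at this scale
  set.seed(43)
  lls <- vapply(rnorm(2000, mu, delta),
                function(z) splice_loglik(c(5, 5, 0), plogis(z), L), numeric(1))
  se <- sd(lls) / sqrt(20000)
  expect_lt(abs(est - exact), 3 * se + 1e-6)
})

test_that("the ELBO lower-bounds the quadrature evidence", {
  set.seed(51)
  L <- default_L()
  for (rep in 1:10) {
    s <- as.numeric(rmultinom(1, sample(10:60, 1),
                              compute_rho(runif(1, 0.1, 0.9), L)))
    d <- make_scd(matrix(s[1], 1, 1), matrix(s[2], 1, 1), matrix(s[3], 1, 1), L)
    pm <- rnorm(1); ps <- runif(1, 0.5, 2)
    mu <- rnorm(1); delta <- runif(1, 0.2, 1.5)
    R <- 4000L
    est <- elbo_estimate(d, mu, delta, pm, ps, R = R, seed = rep)
    ev <- oracle_posterior(s, L, pm, ps)$log_evidence
    lls <- vapply(rnorm(1000, mu, delta),
                  function(z) splice_loglik(s, plogis(z), L), numeric(1))
    se <- sd(lls) / sqrt(R)
    expect_lte(est, ev + 3 * se + 1e-6)
  }
})

test_that("mode 0 on an all-zero dataset returns the prior exactly", {
  d0 <- make_scd(matrix(0, 4, 3), matrix(0, 4, 3), matrix(0, 4, 3),
                 default_L())
  f <- fit_splicing(d0, config = fit_config(mode = "mode0", seed = 9))
  expect_lt(abs(f$final_elbo), 1e-9)
  expect_identical(unname(stats::plogis(f$mu)), matrix(0.5, 4, 3))
  expect_equal(unname(f$delta), matrix(3, 4, 3), tolerance = 1e-6)
})

test_that("a single well-covered observation is quantified near its MLE", {
  d <- make_scd(matrix(90, 1, 1), matrix(10, 1, 1), matrix(0, 1, 1),
                velocity_lengths())
  f <- fit_splicing(d, config = fit_config(mode = "mode2_quant", seed = 2))
  expect_lt(abs(plogis(f$mu[1, 1]) - 0.9), 0.03)
})

test_that("variational medians track quadrature posterior medians", {
  # scaled-down version of the oracle-equivalence acceptance run
  set.seed(61)
  L <- default_L()
  for (i in 1:5) {
    M <- 10
    psi <- plogis(rnorm(1, 0, 1.5) + rnorm(M))
    n <- 20 + rpois(M, 15)
    d <- make_one_event(psi, n, L, seed = 100 + i)
    f <- fit_splicing(d, config = fit_config(mode = "mode2_quant", seed = i))
    s <- cbind(as.matrix(d$counts$iso1), as.matrix(d$counts$iso2),
               as.matrix(d$counts$ambiguous))
    for (c in 1:M) {
      med <- oracle_posterior(s[c, ], L, f$prior_mean[c, 1], f$sigma[1])$psi_median
      expect_lt(abs(plogis(f$mu[c, 1]) - med), 0.05)
    }
  }
})

test_that("fits are deterministic in the seed", {
  set.seed(71)
  d <- make_one_event(runif(6, 0.2, 0.8), rep(15, 6), default_L(), seed = 3)
  cfg <- fit_config(mode = "mode2_quant", seed = 123, max_iter = 400)
  f1 <- fit_splicing(d, config = cfg)
  f2 <- fit_splicing(d, config = cfg)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$final_elbo, f2$final_elbo)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  f3 <- fit_splicing(d, config = fit_config(mode = "mode2_quant", seed = 124,
                                            max_iter = 400))
  expect_false(identical(f1$final_elbo, f3$final_elbo))
})

test_that("psi_median responds monotonically to the data", {
  L <- velocity_lengths()
  meds <- vapply(c(0, 5, 10, 15, 20), function(s1) {
    d <- make_scd(matrix(s1, 1, 1), matrix(20 - s1, 1, 1), matrix(0, 1, 1), L)
    f <- fit_splicing(d, config = fit_config(mode = "mode2_quant", seed = 4))
    plogis(f$mu[1, 1])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_lt(meds[1], 0.5)
  expect_gt(meds[5], 0.5)
})

test_that("ten-fold deeper counts narrow the posterior", {
  set.seed(81)
  psi <- runif(8, 0.25, 0.75)
  d1 <- make_one_event(psi, rep(10, 8), default_L(), seed = 5)
  d10 <- make_scd(10 * as.matrix(d1$counts$iso1), 10 * as.matrix(d1$counts$iso2),
                  10 * as.matrix(d1$counts$ambiguous), default_L())
  cfg <- fit_config(mode = "mode2_quant", seed = 6)
  f1 <- fit_splicing(d1, config = cfg)
  f10 <- fit_splicing(d10, config = cfg)
  expect_lt(mean(f10$delta), mean(f1$delta))
})

test_that("mode 2-quant equals mode 2-diff with only an intercept", {
  set.seed(91)
  d <- make_one_event(runif(10, 0.2, 0.8), rep(25, 10), default_L(), seed = 7)
  cfg_q <- fit_config(mode = "mode2_quant", seed = 11)
  cfg_d <- fit_config(mode = "mode2_diff", seed = 11)
  fq <- fit_splicing(d, config = cfg_q)
  fd <- fit_splicing(d, cell_features = matrix(1, 10, 1,
                                               dimnames = list(NULL, "intercept")),
                     config = cfg_d)
  expect_identical(fq$final_elbo, fd$final_elbo)
  expect_identical(fq$mu, fd$mu)
})

test_that("the smoothed ELBO trace is non-decreasing over its final 80%", {
  set.seed(95)
  M <- 30; N <- 15
  psi <- matrix(plogis(rnorm(M * N)), M, N)
  n <- matrix(rpois(M * N, 20), M, N)
  L <- default_L()
  rho1 <- apply(psi, c(1, 2), function(p) compute_rho(p, L)[1])
  s1 <- matrix(rbinom(M * N, n, rho1), M, N)
  rho2 <- apply(psi, c(1, 2), function(p) compute_rho(p, L)[2])
  s2 <- matrix(rbinom(M * N, n - s1, pmin(rho2 / (1 - rho1), 1)), M, N)
  d <- make_scd(s1, s2, n - s1 - s2, L)
  f <- fit_splicing(d, config = fit_config(mode = "mode2_quant", seed = 13))
  win <- f$config$window
  sm <- smooth_trace(f$elbo_trace, win)
  tail80 <- sm[floor(length(sm) * 0.2):length(sm)]
  resid <- f$elbo_trace[win:length(f$elbo_trace)] - sm
  mc_se <- sd(resid) / sqrt(win)
  expect_true(all(diff(tail80) >= -2 * mc_se))
})

test_that("psi_summarise returns exact medians and calibrated means", {
  fake <- structure(list(mu = matrix(c(0, 2), 1, 2),
                         delta = matrix(c(1, 1e-6), 1, 2)),
                    class = "splice_fit")
  ps <- psi_summarise(fake, n_samples = 400, seed = 3)
  expect_identical(ps$psi_median[1, 1], 0.5)
  expect_equal(ps$psi_mean[1, 2], plogis(2), tolerance = 1e-4)
  expect_true(all(ps$psi_low <= ps$psi_median & ps$psi_median <= ps$psi_high))

  # mu = 0, delta = 2: MC mean against quadrature E[logistic(z)]
  fake2 <- structure(list(mu = matrix(0), delta = matrix(2)),
                     class = "splice_fit")
  ps2 <- psi_summarise(fake2, n_samples = 4000, seed = 5)
  quad <- integrate(function(z) plogis(z) * dnorm(z, 0, 2), -Inf, Inf)$value
  # var of logistic(z) < 0.25; 3 SE bound
  expect_lt(abs(ps2$psi_mean[1, 1] - quad), 3 * 0.5 / sqrt(4000))
})
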