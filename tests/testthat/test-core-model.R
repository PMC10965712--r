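test_that("build_gain extracts and concatenates vertex blocks", {
  set.seed(1)
  G <- matrix(rnorm(4 * 15), 4)          # 5 vertices x 3 components
  lf <- lead_field(G, n_comp = 3L)
  expect_identical(ncol(build_gain(dipole_config(integer(0)), lf)), 0L)
  expect_identical(build_gain(dipole_config(3L), lf), G[, 7:9])
  g2 <- build_gain(dipole_config(c(1L, 4L)), lf)
  expect_identical(g2, cbind(G[, 1:3], G[, 10:12]))
  # reconstructing a two-dipole field equals the explicit superposition
  q <- matrix(rnorm(6 * 2), 6)
  expect_equal(g2 %*% q, G[, 1:3] %*% q[1:3, ] + G[, 10:12] %*% q[4:6, ])
  expect_error(build_gain(dipole_config(9L), lf), "out of range")
})

test_that("marginal likelihood closed form matches simple limits", {
  y <- meeg_data(matrix(0, 2, 1), 0)
  lf <- lead_field(matrix(c(1, 1), 2, 1), n_comp = 1L)
  nm <- noise_model(1)
  expect_equal(log_marginal_likelihood(dipole_config(), 1, y, lf, nm),
               -log(2 * pi), tolerance = 1e-12)
  # vanishing moment prior recovers the source-free likelihood
  y2 <- meeg_data(matrix(c(0.3, -1.2), 2, 1), 0)
  l0 <- log_marginal_likelihood(dipole_config(), 1, y2, lf, nm)
  l1 <- log_marginal_likelihood(dipole_config(1L), 1e-9, y2, lf, nm)
  expect_equal(l1, l0, tolerance = 1e-8)
  expect_error(log_marginal_likelihood(dipole_config(1L), -1, y2, lf, nm),
               "positive")
})

test_that("marginal likelihood agrees with numerical quadrature over moments", {
  g <- c(0.5, -1.0, 2.0)
  yv <- c(0.7, 1.1, -0.4)
  lf <- lead_field(matrix(g, 3, 1), n_comp = 1L)
  dat <- meeg_data(matrix(yv, 3, 1), 0)
  nm <- noise_model(1)
  analytic <- log_marginal_likelihood(dipole_config(1L), 1, dat, lf, nm)
  integrand <- function(q) vapply(q, function(qi)
    prod(stats::dnorm(yv, g * qi, 1)) * stats::dnorm(qi, 0, 1), numeric(1))
  quad <- log(stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value)
  expect_equal(analytic, quad, tolerance = 1e-6)

  # two source components (two fixed-orientation dipoles), 2-D quadrature
  G2 <- matrix(c(0.5, -1, 2, 1.5, 0.2, -0.7), 3, 2)
  lf2 <- lead_field(G2, n_comp = 1L)
  analytic2 <- log_marginal_likelihood(dipole_config(c(1L, 2L)), 0.8, dat,
                                       lf2, noise_model(0.9))
  inner <- function(q1) vapply(q1, function(a)
    stats::integrate(function(q2) {
      vapply(q2, function(b)
        prod(stats::dnorm(yv, G2 %*% c(a, b), 0.9)) *
          prod(stats::dnorm(c(a, b), 0, 0.8)), numeric(1))
    }, -8, 8, rel.tol = 1e-11, abs.tol = 1e-14)$value, numeric(1))
  quad2 <- log(stats::integrate(inner, -8, 8, rel.tol = 1e-10)$value)
  expect_equal(analytic2, quad2, tolerance = 1e-6)
})

test_that("marginal likelihood is exactly permutation invariant", {
  set.seed(7)
  G <- matrix(rnorm(5 * 8 * 3), 5)
  lf <- lead_field(G, n_comp = 3L)
  dat <- meeg_data(matrix(rnorm(10), 5, 2), c(0, 0.001))
  nm <- noise_model(0.5)
  a <- log_marginal_likelihood(dipole_config(c(2L, 7L, 4L)), 1.3, dat, lf, nm)
  b <- log_marginal_likelihood(dipole_config(c(7L, 4L, 2L)), 1.3, dat, lf, nm)
  expect_identical(a, b)
})

test_that("configuration prior handles counts, weights and exclusions", {
  pr <- source_prior(5, n_max = 3)
  expect_equal(log_prior_config(dipole_config(), pr), log(pr$n_prior_pmf[1]))
  expect_equal(log_prior_config(dipole_config(2L), pr),
               log(pr$n_prior_pmf[2]) - log(5))
  expect_equal(log_prior_config(dipole_config(c(1L, 4L)), pr),
               log(pr$n_prior_pmf[3]) - log(choose(5, 2)))
  expect_identical(log_prior_config(dipole_config(1:4), pr), -Inf)
  prz <- source_prior(5, n_max = 3, vertex_weights = c(0, 1, 1, 1, 1))
  expect_identical(log_prior_config(dipole_config(1L), prz), -Inf)
  # permutation invariance is structural: configs store sorted vertices
  expect_identical(dipole_config(c(4L, 1L)), dipole_config(c(1L, 4L)))
})

test_that("log-uniform hyper-prior has the right density and mass", {
  mp <- moment_prior("hyper", sigma_q_min = 1, range_factor = 1000)
  expect_equal(log_hyperprior(1, mp), log(1 / log(1000)), tolerance = 1e-12)
  expect_identical(log_hyperprior(1000 + 1e-9, mp), -Inf)
  expect_identical(log_hyperprior(0.999, mp), -Inf)
  mass <- stats::integrate(function(s) exp(log_hyperprior(s, mp)), 1, 1000,
                           rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  expect_error(log_hyperprior(1, moment_prior("fixed", sigma_q = 1)), "hyper")
})

test_that("conditional moment posterior solves the ridge normal equations", {
  lf1 <- lead_field(matrix(1, 1, 1), n_comp = 1L)
  d1 <- meeg_data(matrix(2, 1, 1), 0)
  res <- conditional_moment_posterior(dipole_config(1L), 1, d1, lf1,
                                      noise_model(1))
  expect_equal(as.numeric(res$mean), 1.0)
  expect_equal(as.numeric(res$covariance), 0.5)
  # prior-dominated and likelihood-dominated limits
  expect_lt(abs(conditional_moment_posterior(dipole_config(1L), 1e-8, d1, lf1,
                                             noise_model(1))$mean), 1e-10)
  set.seed(3)
  G <- matrix(rnorm(6 * 2), 6)
  lf <- lead_field(G, n_comp = 1L)
  yv <- matrix(rnorm(6), 6, 1)
  dat <- meeg_data(yv, 0)
  ls_fit <- conditional_moment_posterior(dipole_config(c(1L, 2L)), 1, dat, lf,
                                         noise_model(1e-8))
  expect_equal(as.numeric(ls_fit$mean), as.numeric(qr.solve(G, yv)),
               tolerance = 1e-6)
  # normal equations to 1e-10 relative residual
  res2 <- conditional_moment_posterior(dipole_config(c(1L, 2L)), 0.7, dat, lf,
                                       noise_model(0.4))
  A <- crossprod(G) / 0.4^2 + diag(2) / 0.7^2
  rhs <- crossprod(G, yv) / 0.4^2
  expect_lt(norm(A %*% res2$mean - rhs, "F") / norm(rhs, "F"), 1e-10)
  expect_true(all(eigen(res2$covariance)$values > 0))
  expect_error(conditional_moment_posterior(dipole_config(), 1, dat, lf,
                                            noise_model(1)), "empty")
})

test_that("noise level defaults to 20% of the window peak", {
  d <- meeg_data(matrix(c(3, -50, 7, 1), 2, 2), c(0, 0.001))
  expect_equal(estimate_noise_std(d), 10)
  d1 <- meeg_data(matrix(c(0.2, -1, 0.5, 0.1), 2, 2), c(0, 0.001))
  expect_equal(estimate_noise_std(d1), 0.2)
  expect_error(estimate_noise_std(meeg_data(matrix(0, 2, 2), c(0, 0.001))),
               "all-zero")
})

test_that("moment-scale estimate is scale-free in data and lead field", {
  G <- matrix(c(2, 0, 0, 2, 2, 2), 2, 3)   # block norms: 2, 2, sqrt(8)
  lf <- lead_field(G, n_comp = 1L)
  d <- meeg_data(matrix(c(1, -0.5), 2, 1), 0)
  base <- estimate_dip_mom_std(lf, d)
  expect_equal(base, 15 * 1 / sqrt(8))
  d2 <- meeg_data(2 * matrix(c(1, -0.5), 2, 1), 0)
  expect_equal(estimate_dip_mom_std(lf, d2), 2 * base)
  lf2 <- lead_field(2 * G, n_comp = 1L)
  expect_equal(estimate_dip_mom_std(lf2, d), base / 2)
  # rule applied by hand: peak 1, max block norm 4 -> 15/4
  lf3 <- lead_field(matrix(c(4, 0, 1, 1), 2, 2), n_comp = 1L)
  expect_equal(estimate_dip_mom_std(lf3, d), 3.75)
})

test_that("posterior mean of N is non-increasing in the noise level", {
  sim <- tiny_problem(21, n_vertices = 10, n_dipoles = 2, snr = 6)
  peak <- max(abs(window_values(sim$data)))
  mean_n <- vapply(c(0.065, 0.2, 0.65) * peak, function(se) {
    m <- sim$model
    m$noise <- noise_model(se)
    sum(as.numeric(names(enumerate_posterior(m)$n_pmf)) *
          enumerate_posterior(m)$n_pmf)
  }, numeric(1))
  expect_true(all(diff(mean_n) <= 1e-12))
})
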