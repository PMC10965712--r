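test_that("effective sample size closed forms", {
  expect_equal(ess(rep(1 / 100, 100)), 100)
  expect_equal(ess(c(1, 0, 0, 0)), 1)
  expect_equal(ess(c(0.5, 0.5, 0, 0)), 2)
})

test_that("initial particles are reproducible and follow the prior", {
  sim <- tiny_problem(1, n_dipoles = 1)
  st <- sesame_settings(n_particles = 100, seed = 5)
  set.seed(5); a <- initialize_particles(st, sim$model)
  set.seed(5); b <- initialize_particles(st, sim$model)
  expect_identical(a, b)
  expect_equal(a$gamma, 0)
  expect_equal(a$weights, rep(1 / 100, 100))
  # cached marginal likelihoods equal the from-scratch R computation
  for (i in c(1, 7, 50)) {
    expect_equal(a$logml[i],
                 log_marginal_likelihood(dipole_config(a$vertices[[i]]),
                                         a$sigma_q[i], sim$model$data,
                                         sim$model$leadfield,
                                         sim$model$noise),
                 tolerance = 1e-9)
  }
  # empirical frequency of N = 0 over 1e4 prior draws
  st2 <- sesame_settings(n_particles = 10000, seed = 5)
  set.seed(9)
  big <- initialize_particles(st2, sim$model)
  p0 <- sim$model$src_prior$n_prior_pmf[1]
  freq <- mean(lengths(big$vertices) == 0L)
  expect_lt(abs(freq - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
  # one-hot weight map concentrates every dipole on that vertex
  m1 <- sim$model
  m1$src_prior <- source_prior(10, vertex_weights = c(rep(0, 6), 1, rep(0, 3)))
  set.seed(2)
  oh <- initialize_particles(sesame_settings(n_particles = 200, seed = 2), m1)
  expect_true(all(unlist(oh$vertices) == 7L))
})

test_that("adaptive exponent solves the ESS-decay root and caps at 1", {
  sim <- tiny_problem(2)
  st <- sesame_settings(n_particles = 50, seed = 3)
  set.seed(3)
  ps <- initialize_particles(st, sim$model)
  # degenerate spread: identical likelihoods jump straight to 1
  ps0 <- ps; ps0$logml <- rep(-5, 50)
  expect_equal(next_exponent(ps0, st), 1)
  # root condition after solving
  g2 <- next_exponent(ps, st)
  expect_gt(g2, 0)
  if (g2 < 1) {
    lw <- log(ps$weights) + g2 * ps$logml
    w <- exp(lw - max(lw)); w <- w / sum(w)
    expect_lt(abs(ess(w) - st$ess_decay_target * ess(ps$weights)), 0.1)
  }
  # two-particle case against an independent scalar root finder
  ps2 <- manual_particles(list(integer(0), 1L), c(0.5, 0.5),
                          logml = c(0, -4))
  ps2$gamma <- 0
  target <- 0.99 * 2
  f <- function(d) {
    w <- c(0.5 * exp(d * 0), 0.5 * exp(-4 * d)); w <- w / sum(w)
    1 / sum(w^2) - target
  }
  root <- stats::uniroot(f, c(1e-9, 1), tol = 1e-12)$root
  expect_equal(next_exponent(ps2, st), root, tolerance = 1e-5)
  ps2$gamma <- 1
  expect_error(next_exponent(ps2, st), "gamma")
})

test_that("reweighting follows the importance-sampling rule", {
  ps <- manual_particles(list(integer(0), 1L), c(0.5, 0.5),
                         logml = c(log(3), 0))
  ps$gamma <- 0
  same <- reweight(ps, 0)
  expect_equal(same$weights, c(0.5, 0.5))
  up <- reweight(ps, 1)
  expect_equal(up$weights, c(0.75, 0.25), tolerance = 1e-12)
  expect_lt(abs(sum(up$weights) - 1), 1e-12)
  # ordering of weights follows ordering of likelihoods from equal start
  set.seed(1)
  psn <- manual_particles(as.list(rep(1L, 6)), rep(1, 6), logml = rnorm(6))
  psn$gamma <- 0
  rw <- reweight(psn, 0.7)
  expect_equal(order(rw$weights), order(psn$logml))
})

test_that("systematic resampling is exact for degenerate and uniform weights", {
  ps <- manual_particles(list(1L, 2L, 3L, 4L), c(0, 1, 0, 0))
  set.seed(1)
  r <- resample(ps)
  expect_true(all(unlist(r$vertices) == 2L))
  expect_equal(r$weights, rep(0.25, 4))
  psu <- manual_particles(list(1L, 2L, 3L, 4L), rep(0.25, 4))
  for (s in 1:5) {
    set.seed(s)
    expect_equal(sort(unlist(resample(psu)$vertices)), 1:4)
  }
})

test_that("systematic resampling copy counts are unbiased", {
  w <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  ps <- manual_particles(list(1L, 2L, 3L, 4L, 5L), w)
  set.seed(99)
  counts <- matrix(0, 10000, 5)
  for (r in seq_len(10000)) {
    v <- unlist(resample(ps)$vertices)
    counts[r, ] <- tabulate(v, 5)
  }
  m <- colMeans(counts)
  se <- apply(counts, 2, stats::sd) / sqrt(10000)
  expect_true(all(abs(m - 5 * w) <= 3 * pmax(se, 1e-12)))
})

test_that("single-particle moves respect support and caching", {
  sim <- tiny_problem(4, n_dipoles = 1, n_max = 2)
  st <- sesame_settings(move_probabilities = c(1, 0, 0))  # births only
  p <- list(vertices = c(1L, 2L), sigma_q = sim$model$mom_prior$sigma_q,
            logml = log_marginal_likelihood(dipole_config(c(1L, 2L)),
                                            sim$model$mom_prior$sigma_q,
                                            sim$model$data,
                                            sim$model$leadfield,
                                            sim$model$noise))
  set.seed(8)
  for (k in 1:50) {
    p2 <- mcmc_move(p, 0.5, sim$model, st)
    expect_identical(p2$vertices, p$vertices)  # birth beyond n_max: rejected
  }
  # cached logml stays consistent under a mixed move schedule
  stm <- sesame_settings()
  set.seed(12)
  for (k in 1:100) p <- mcmc_move(p, 0.7, sim$model, stm)
  expect_equal(p$logml,
               log_marginal_likelihood(dipole_config(p$vertices), p$sigma_q,
                                       sim$model$data, sim$model$leadfield,
                                       sim$model$noise), tolerance = 1e-9)
})

test_that("the chain at gamma = 0 leaves the prior invariant", {
  sim <- tiny_problem(6, n_vertices = 8, n_dipoles = 1, n_max = 2)
  st <- sesame_settings(n_particles = 10000, seed = 31)
  set.seed(31)
  ps <- initialize_particles(st, sim$model)
  n_before <- lengths(ps$vertices)
  cm <- dipoleSMC:::compile_model(sim$model, st)
  res <- ps
  for (k in 1:5) {
    out <- dipoleSMC:::cpp_sweep(res$vertices, res$sigma_q, res$logml,
                                 cm$G, cm$Y, cm$ncomp, cm$sigma_eps, 0,
                                 cm$log_npmf, cm$log_esp, cm$log_w, cm$w_cum,
                                 cm$n_max, cm$nb_off, cm$nb_ids, cm$nb_probs,
                                 cm$nb_cum, cm$hyper, cm$sq_min,
                                 cm$range_factor, st$hyper_walk_scale,
                                 st$move_probabilities, 1L)
    res$vertices <- out$vertices
    res$sigma_q <- as.numeric(out$sigma_q)
    res$logml <- as.numeric(out$logml)
  }
  n_after <- lengths(res$vertices)
  tab <- rbind(tabulate(n_before + 1L, 3), tabulate(n_after + 1L, 3))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("stationary distribution at gamma = 1 matches exact enumeration", {
  sim <- tiny_problem(13, n_vertices = 5, n_sensors = 5, n_dipoles = 1,
                      snr = 2, n_max = 1)
  ex <- enumerate_posterior(sim$model)
  st <- sesame_settings(n_particles = 4000, seed = 17)
  set.seed(17)
  ps <- initialize_particles(st, sim$model)
  cm <- dipoleSMC:::compile_model(sim$model, st)
  for (k in 1:200) {
    out <- dipoleSMC:::cpp_sweep(ps$vertices, ps$sigma_q, ps$logml,
                                 cm$G, cm$Y, cm$ncomp, cm$sigma_eps, 1,
                                 cm$log_npmf, cm$log_esp, cm$log_w, cm$w_cum,
                                 cm$n_max, cm$nb_off, cm$nb_ids, cm$nb_probs,
                                 cm$nb_cum, cm$hyper, cm$sq_min,
                                 cm$range_factor, st$hyper_walk_scale,
                                 st$move_probabilities, 1L)
    ps$vertices <- out$vertices
    ps$sigma_q <- as.numeric(out$sigma_q)
    ps$logml <- as.numeric(out$logml)
  }
  n <- lengths(ps$vertices)
  expect_within_3se(mean(n == 0L), unname(ex$n_pmf["0"]), 4000 / 10)
  map <- tabulate(unlist(ps$vertices), 5) / sum(n == 1L)
  expect_within_3se(map, ex$location_maps[[1]], 4000 / 10)
})

test_that("compiled and R marginal likelihoods agree", {
  sim <- tiny_problem(3, n_dipoles = 2)
  m <- sim$model
  for (v in list(integer(0), 4L, c(2L, 9L))) {
    r_val <- log_marginal_likelihood(dipole_config(v), 2e-8, m$data,
                                     m$leadfield, m$noise)
    c_val <- dipoleSMC:::cpp_logml(m$leadfield$matrix,
                                   window_values(m$data), v,
                                   m$leadfield$n_comp, 2e-8,
                                   m$noise$sigma_eps)
    expect_equal(c_val, r_val, tolerance = 1e-10)
  }
})

test_that("fixed-orientation shell source spaces are handled end to end", {
  sim <- simulate_experiment(n_vertices = 80, n_sensors = 25, n_dipoles = 1,
                             snr = 10, seed = 19, mode = "shell")
  expect_equal(sim$leadfield$n_comp, 1L)
  fit <- run_sesame(sim$model, sesame_settings(n_particles = 100, seed = 21))
  su <- summarize_posterior(fit)
  expect_equal(su$n_hat, 1L)
  d <- sqrt(sum((sim$space$positions[su$estimated_dipoles$vertex[1], ] -
                   sim$space$positions[sim$truth$config$vertices, ])^2))
  expect_lt(d, 0.02)
})

test_that("full runs are seed-deterministic and converge to gamma = 1", {
  sim <- tiny_problem(10, n_dipoles = 1)
  st <- sesame_settings(n_particles = 200, seed = 4,
                        post_burn_iterations = 3)
  f1 <- run_sesame(sim$model, st)
  f2 <- run_sesame(sim$model, st)
  expect_identical(f1$particles, f2$particles)
  expect_identical(f1$log, f2$log)
  expect_equal(f1$particles$gamma, 1)
  expect_true(all(diff(f1$log$gamma) >= 0))
  expect_lt(abs(sum(f1$particles$weights) - 1), 1e-12)
  # iteration log carries tempering, ESS and acceptance diagnostics
  expect_true(all(c("gamma", "ess", "acc_birth", "acc_death", "acc_update")
                  %in% names(f1$log)))
  err <- tryCatch(run_sesame(sim$model,
                             sesame_settings(n_particles = 50, seed = 1,
                                             max_iterations = 2L)),
                  error = identity)
  expect_s3_class(err, "sesame_convergence_error")
  expect_s3_class(err$state, "particle_set")
})
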