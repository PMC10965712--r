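# Small programmatic fixtures shared across the suite.

# tiny simulated problem with an enumerable posterior (n_max <= 2)
tiny_problem <- function(seed, n_vertices = 10L, n_sensors = 6L,
                         n_dipoles = 1L, snr = 3, n_max = 2L,
                         moment_mode = "fixed", n_times = 5L) {
  sim <- simulate_experiment(n_vertices = n_vertices, n_sensors = n_sensors,
                             n_dipoles = n_dipoles, snr = snr,
                             n_times = n_times, seed = seed)
  m <- sim$model
  m$src_prior <- source_prior(n_vertices, n_max = n_max)
  if (moment_mode == "hyper")
    m$mom_prior <- moment_prior(
      "hyper",
      sigma_q_min = estimate_dip_mom_std(m$leadfield, m$data) / sqrt(1000))
  sim$model <- m
  sim
}

# hand-built two-column lead field with controllable geometry
toy_leadfield <- function(mat, n_comp = 1L) lead_field(mat, n_comp = n_comp)

# a particle set assembled by hand (for summary-layer tests)
manual_particles <- function(vertex_lists, weights, sigma_q = NULL,
                             logml = NULL, n_max = 10L) {
  I <- length(vertex_lists)
  structure(list(vertices = lapply(vertex_lists, as.integer),
                 sigma_q = if (is.null(sigma_q)) rep(1, I) else sigma_q,
                 weights = weights / sum(weights),
                 logml = if (is.null(logml)) rep(0, I) else logml,
                 gamma = 1, iteration = 0L, n_max = n_max),
            class = "particle_set")
}

# wrap a particle set + model into a minimal sesame_fit
manual_fit <- function(particles, model) {
  structure(list(particles = particles,
                 log = data.frame(iteration = 1L, gamma = 1, ess =
                                    ess(particles$weights),
                                  resampled = FALSE, acc_birth = NA_real_,
                                  acc_death = NA_real_, acc_update = NA_real_),
                 settings = sesame_settings(), model = model),
            class = "sesame_fit")
}

# mean nearest-neighbor spacing of a source space (the "grid spacing")
grid_spacing <- function(space) {
  d <- as.matrix(stats::dist(space$positions))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

expect_within_3se <- function(est, exact, n_eff, floor_var = 1e-3) {
  tol <- 3 * sqrt(pmax(exact * (1 - exact), floor_var) / n_eff)
  expect_true(all(abs(est - exact) <= tol),
              label = paste0("max |est - exact| = ",
                             signif(max(abs(est - exact)), 3),
                             " vs tol ", signif(min(tol), 3)))
}
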