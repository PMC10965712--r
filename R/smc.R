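#' Sampler settings
#'
#' @param n_particles population size I (default 100).
#' @param ess_resample_frac resample when ESS falls below this fraction of I.
#' @param ess_decay_target the adaptive tempering step is chosen (by
#'   bisection) so the post-reweight ESS is this fraction of the current ESS.
#' @param max_iterations hard cap on tempering iterations before declaring a
#'   convergence failure. A fast preset of 50 iterations mirrors common
#'   interactive usage; the default is generous.
#' @param post_burn_iterations extra Metropolis-Hastings sweeps at gamma = 1
#'   after the tempering path ends (decorrelates the final population).
#' @param move_probabilities probabilities of the birth / death / update
#'   moves; must sum to 1.
#' @param hyper_walk_scale standard deviation of the log-sigma_q random walk.
#' @param neighbor_kernel_scale_m if non-NULL, rebuild the source-space
#'   neighbor kernel at this spatial scale (meters) before sampling;
#'   default NULL keeps the kernel stored in the source space.
#' @param moves_per_particle Metropolis-Hastings moves applied to each
#'   particle per iteration (default 1 sweep).
#' @param seed integer seed; the whole run is deterministic given it.
#' @export
sesame_settings <- function(n_particles = 100L, ess_resample_frac = 0.5,
                            ess_decay_target = 0.99, max_iterations = 1000L,
                            post_burn_iterations = 0L,
                            move_probabilities = c(1, 1, 1) / 3,
                            hyper_walk_scale = 0.1,
                            neighbor_kernel_scale_m = NULL,
                            moves_per_particle = 1L, seed = 1L) {
  if (n_particles < 2L) stop("need at least 2 particles")
  if (abs(sum(move_probabilities) - 1) > 1e-12 || any(move_probabilities < 0))
    stop("move_probabilities must be non-negative and sum to 1")
  if (hyper_walk_scale <= 0) stop("hyper_walk_scale must be positive")
  if (ess_decay_target <= 0 || ess_decay_target >= 1)
    stop("ess_decay_target must lie in (0, 1)")
  structure(list(n_particles = as.integer(n_particles),
                 ess_resample_frac = ess_resample_frac,
                 ess_decay_target = ess_decay_target,
                 max_iterations = as.integer(max_iterations),
                 post_burn_iterations = as.integer(post_burn_iterations),
                 move_probabilities = move_probabilities,
                 hyper_walk_scale = hyper_walk_scale,
                 neighbor_kernel_scale_m = neighbor_kernel_scale_m,
                 moves_per_particle = as.integer(moves_per_particle),
                 seed = as.integer(seed)),
            class = "sesame_settings")
}

# Flatten model pieces into the plain arrays the C++ kernel consumes.
compile_model <- function(model, settings) {
  sp <- model$space
  if (!is.null(settings$neighbor_kernel_scale_m)) {
    nb <- build_neighbor_kernel(sp$positions, settings$neighbor_kernel_scale_m)
    sp$neighbors <- nb$neighbors
    sp$kernel_scale_m <- nb$scale
  }
  ids <- sp$neighbors$ids
  probs <- sp$neighbors$probs
  w <- model$src_prior$vertex_weights
  mp <- model$mom_prior
  list(G = model$leadfield$matrix,
       Y = window_values(model$data),
       ncomp = model$leadfield$n_comp,
       sigma_eps = model$noise$sigma_eps,
       log_npmf = log(model$src_prior$n_prior_pmf),
       log_esp = model$src_prior$log_esp,
       log_w = log(w),
       w_cum = cumsum(w),
       n_max = model$src_prior$n_max,
       nb_off = c(0L, cumsum(lengths(ids))),
       nb_ids = as.integer(unlist(ids)),
       nb_probs = as.numeric(unlist(probs)),
       nb_cum = cumsum(as.numeric(unlist(probs))),
       hyper = mp$mode == "hyper",
       sq_min = if (mp$mode == "hyper") mp$sigma_q_min else 1,
       range_factor = mp$range_factor,
       sigma_q_fixed = mp$sigma_q,
       n_vertices = sp$n_vertices)
}

#' Draw the initial particle population from the prior
#'
#' Configurations are drawn from p(N) p(R) (iid vertex draws from the weight
#' map, rejected until distinct — exactly the normalized distinct-set prior);
#' in hyper mode sigma_q is drawn from the log-uniform hyper-prior. Weights
#' start equal and gamma at 0. Uses the current R RNG state; seed via
#' `set.seed()` (done by [run_sesame()]).
#'
#' @param settings a [sesame_settings].
#' @param model a [sesame_model].
#' @return object of class `particle_set`: lists `vertices`, vectors
#'   `sigma_q`, `weights`, `logml`, scalar `gamma`, `iteration`.
#' @export
initialize_particles <- function(settings, model) {
  cm <- compile_model(model, settings)
  I <- settings$n_particles
  pmf <- model$src_prior$n_prior_pmf
  w <- model$src_prior$vertex_weights
  nv <- length(w)
  if (nv == 0L) stop("empty source space")
  verts <- vector("list", I)
  sq <- numeric(I)
  for (i in seq_len(I)) {
    n <- sample.int(length(pmf), 1L, prob = pmf) - 1L
    v <- integer(0)
    if (n > 0L) repeat {
      v <- sample.int(nv, n, replace = TRUE, prob = w)
      if (!anyDuplicated(v)) break
    }
    verts[[i]] <- sort(as.integer(v))
    sq[i] <- if (cm$hyper) {
      exp(stats::runif(1, log(cm$sq_min), log(cm$sq_min * cm$range_factor)))
    } else cm$sigma_q_fixed
  }
  logml <- vapply(seq_len(I), function(i)
    cpp_logml(cm$G, cm$Y, verts[[i]], cm$ncomp, sq[i], cm$sigma_eps),
    numeric(1))
  structure(list(vertices = verts, sigma_q = sq,
                 weights = rep(1 / I, I), logml = logml,
                 gamma = 0, iteration = 0L, n_max = cm$n_max),
            class = "particle_set")
}

#' Effective sample size of a normalized weight vector
#'
#' 1 / sum(w_i^2); ranges from 1 (degenerate) to I (uniform). Drives both the
#' adaptive tempering schedule and the resampling trigger.
#' @param weights normalized weights.
#' @export
ess <- function(weights) 1 / sum(weights^2)

ess_after <- function(weights, logml, delta) {
  lw <- log(weights) + delta * logml
  lw <- lw - max(lw)
  w <- exp(lw)
  ess(w / sum(w))
}

#' Next tempering exponent by bisection on the ESS decay
#'
#' Finds the increment delta such that reweighting by likelihood^delta
#' reduces the ESS to `ess_decay_target` times its current value (bisection
#' to 1e-6 on gamma), capped at gamma = 1. Larger spread of the cached
#' log-likelihoods yields smaller increments.
#'
#' @param particles a `particle_set` with gamma < 1.
#' @param settings a [sesame_settings].
#' @return the next exponent in (gamma, 1].
#' @export
next_exponent <- function(particles, settings) {
  g <- particles$gamma
  if (g >= 1) stop("tempering already complete (gamma >= 1)")
  target <- settings$ess_decay_target * ess(particles$weights)
  dmax <- 1 - g
  if (ess_after(particles$weights, particles$logml, dmax) >= target)
    return(1)
  lo <- 0; hi <- dmax
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (ess_after(particles$weights, particles$logml, mid) >= target)
      lo <- mid else hi <- mid
  }
  g + (lo + hi) / 2
}

#' Importance reweighting to a larger tempering exponent
#'
#' w_i gets multiplied by likelihood_i^(gamma_new - gamma) and renormalized
#' (computed in log space).
#'
#' @param particles a `particle_set`.
#' @param gamma_new exponent > current gamma.
#' @export
reweight <- function(particles, gamma_new) {
  if (gamma_new < particles$gamma) stop("gamma must not decrease")
  lw <- log(particles$weights) + (gamma_new - particles$gamma) * particles$logml
  lw <- lw - max(lw)
  w <- exp(lw)
  particles$weights <- w / sum(w)
  particles$gamma <- gamma_new
  particles
}

#' Systematic resampling
#'
#' Discards low-weight particles and duplicates high-weight ones with the
#' lowest-variance standard scheme: one uniform draw stratified over the
#' weight CDF. Expected copy count of particle i is I * w_i; weights reset
#' to 1/I. With equal weights every particle survives exactly once.
#'
#' @param particles a `particle_set` with normalized weights.
#' @export
resample <- function(particles) {
  I <- length(particles$weights)
  u <- stats::runif(1) / I
  pos <- u + (seq_len(I) - 1L) / I
  cum <- cumsum(particles$weights)
  cum[I] <- 1
  idx <- findInterval(pos, cum, left.open = TRUE) + 1L
  particles$vertices <- particles$vertices[idx]
  particles$sigma_q <- particles$sigma_q[idx]
  particles$logml <- particles$logml[idx]
  particles$weights <- rep(1 / I, I)
  particles
}

#' One Metropolis-Hastings move on a single particle
#'
#' Chooses birth / death / update by `move_probabilities` and targets
#' pi_gamma ~ likelihood^gamma * prior. Birth proposes a vertex from the
#' weight map (auto-rejected beyond n_max or onto an occupied or zero-weight
#' vertex); death removes a uniformly chosen dipole; update random-walks one
#' dipole over the spatial neighbor kernel and, in hyper mode, perturbs
#' sigma_q by a log-normal step whose Jacobian cancels the log-uniform
#' hyper-prior inside its support. Acceptance ratios include the
#' forward/reverse proposal densities. Uses the current R RNG state.
#'
#' @param particle list with `vertices` (sorted distinct ids), `sigma_q`,
#'   `logml`.
#' @param gamma tempering exponent in `[0, 1]`.
#' @param model a [sesame_model].
#' @param settings a [sesame_settings].
#' @return the updated particle (state unchanged on rejection), with
#'   attributes `accepted` (logical) and counts per move type.
#' @export
mcmc_move <- function(particle, gamma, model, settings) {
  cm <- compile_model(model, settings)
  res <- cpp_sweep(list(as.integer(particle$vertices)),
                   particle$sigma_q, particle$logml,
                   cm$G, cm$Y, cm$ncomp, cm$sigma_eps, gamma,
                   cm$log_npmf, cm$log_esp, cm$log_w, cm$w_cum, cm$n_max,
                   cm$nb_off, cm$nb_ids, cm$nb_probs, cm$nb_cum,
                   cm$hyper, cm$sq_min, cm$range_factor,
                   settings$hyper_walk_scale, settings$move_probabilities,
                   1L)
  out <- list(vertices = res$vertices[[1L]],
              sigma_q = res$sigma_q[1L], logml = res$logml[1L])
  attr(out, "accepted") <- sum(res$accepts) > 0L
  attr(out, "move_attempts") <- as.integer(res$attempts)
  attr(out, "move_accepts") <- as.integer(res$accepts)
  out
}

#' Run the adaptive-tempering Sequential Monte Carlo sampler
#'
#' Draws the initial population from the prior, then iterates: one
#' Metropolis-Hastings sweep per particle at the current exponent, adaptive
#' choice of the next exponent, importance reweighting, and systematic
#' resampling whenever the ESS drops below `ess_resample_frac * I`; stops
#' when gamma reaches 1 (plus optional post-burn sweeps). Deterministic
#' given `settings$seed`.
#'
#' @param model a [sesame_model].
#' @param settings a [sesame_settings].
#' @return object of class `sesame_fit`: `particles` (final `particle_set`
#'   at gamma = 1), `log` (per-iteration data frame: gamma, ESS, resampled,
#'   acceptance rate per move type), `settings`, `model`.
#' @export
run_sesame <- function(model, settings = sesame_settings()) {
  stopifnot(inherits(model, "sesame_model"), inherits(settings, "sesame_settings"))
  set.seed(settings$seed)
  cm <- compile_model(model, settings)
  ps <- initialize_particles(settings, model)
  I <- settings$n_particles
  cap <- settings$max_iterations + settings$post_burn_iterations
  lg <- list(gamma = numeric(cap), ess = numeric(cap), resampled = logical(cap),
             acc = matrix(NA_real_, cap, 3L))
  iter <- 0L

  sweep_once <- function(ps, gamma) {
    res <- cpp_sweep(ps$vertices, ps$sigma_q, ps$logml,
                     cm$G, cm$Y, cm$ncomp, cm$sigma_eps, gamma,
                     cm$log_npmf, cm$log_esp, cm$log_w, cm$w_cum, cm$n_max,
                     cm$nb_off, cm$nb_ids, cm$nb_probs, cm$nb_cum,
                     cm$hyper, cm$sq_min, cm$range_factor,
                     settings$hyper_walk_scale, settings$move_probabilities,
                     settings$moves_per_particle)
    ps$vertices <- res$vertices
    ps$sigma_q <- as.numeric(res$sigma_q)
    ps$logml <- as.numeric(res$logml)
    attr(ps, "acc") <- ifelse(res$attempts > 0, res$accepts / res$attempts, NA)
    ps
  }

  while (ps$gamma < 1) {
    if (iter >= settings$max_iterations) {
      cond <- structure(class = c("sesame_convergence_error", "error",
                                  "condition"),
                        list(message = paste0(
                          "tempering did not reach gamma = 1 within ",
                          settings$max_iterations, " iterations (gamma = ",
                          signif(ps$gamma, 4), ")"),
                          call = sys.call(-1), state = ps))
      stop(cond)
    }
    iter <- iter + 1L
    ps <- sweep_once(ps, ps$gamma)
    gamma_new <- next_exponent(ps, settings)
    ps <- reweight(ps, gamma_new)
    e <- ess(ps$weights)
    resampled <- e < settings$ess_resample_frac * I
    if (resampled) ps <- resample(ps)
    ps$iteration <- iter
    lg$gamma[iter] <- gamma_new
    lg$ess[iter] <- e
    lg$resampled[iter] <- resampled
    lg$acc[iter, ] <- attr(ps, "acc")
  }
  for (b in seq_len(settings$post_burn_iterations)) {
    iter <- iter + 1L
    ps <- sweep_once(ps, 1)
    ps$iteration <- iter
    lg$gamma[iter] <- 1
    lg$ess[iter] <- ess(ps$weights)
    lg$resampled[iter] <- FALSE
    lg$acc[iter, ] <- attr(ps, "acc")
  }
  attr(ps, "acc") <- NULL
  structure(list(particles = ps,
                 log = data.frame(iteration = seq_len(iter),
                                  gamma = lg$gamma[seq_len(iter)],
                                  ess = lg$ess[seq_len(iter)],
                                  resampled = lg$resampled[seq_len(iter)],
                                  acc_birth = lg$acc[seq_len(iter), 1L],
                                  acc_death = lg$acc[seq_len(iter), 2L],
                                  acc_update = lg$acc[seq_len(iter), 3L]),
                 settings = settings, model = model),
            class = "sesame_fit")
}

#' @export
print.sesame_fit <- function(x, ...) {
  ps <- x$particles
  pmf <- source_number_posterior(ps)
  cat("Multi-dipole SMC fit:", length(ps$weights), "particles,",
      nrow(x$log), "iterations\n")
  cat("p(N | y):", paste0(seq_along(pmf) - 1L, ": ",
                          sprintf("%.3f", pmf))[pmf > 1e-3], "\n")
  invisible(x)
}
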