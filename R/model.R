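#' Gain matrix of a dipole configuration
#'
#' Extracts and horizontally concatenates the lead-field column blocks of the
#' configuration's vertices, realizing the additive forward model
#' y(t) = sum_i G(r_i) q_i(t) + eps(t) for the chosen sources.
#'
#' @param config a [dipole_config].
#' @param leadfield a [lead_field].
#' @return numeric matrix `[n_sensors x (n_dipoles * n_comp)]`; zero columns
#'   for the empty configuration.
#' @export
build_gain <- function(config, leadfield) {
  stopifnot(inherits(config, "dipole_config"), inherits(leadfield, "lead_field"))
  if (config$n_dipoles == 0L)
    return(matrix(0, leadfield$n_sensors, 0L))
  if (any(config$vertices > leadfield$n_vertices))
    stop("vertex id out of range: ", max(config$vertices), " > ",
         leadfield$n_vertices)
  nc <- leadfield$n_comp
  cols <- as.vector(vapply(config$vertices,
                           function(v) ((v - 1L) * nc + 1L):(v * nc),
                           integer(nc)))
  leadfield$matrix[, cols, drop = FALSE]
}

#' Marginal log-likelihood of a configuration (moments integrated out)
#'
#' Under the Gaussian likelihood and the Gaussian moment prior
#' q ~ N(0, sigma_q^2 I), each analyzed sample is marginally
#' y_t ~ N(0, sigma_q^2 G G' + sigma_eps^2 I), with samples conditionally
#' independent given the configuration (an independent moment draw per
#' sample; number and locations stay fixed across the window, only the
#' intensities vary). The Gaussian integral over the moments is closed-form,
#' so the sampler never needs to explore the moment space.
#'
#' @param config a [dipole_config].
#' @param sigma_q positive moment standard deviation, A*m.
#' @param data a [meeg_data].
#' @param leadfield a [lead_field].
#' @param noise a [noise_model].
#' @return finite scalar log-likelihood; exactly permutation-invariant in the
#'   configuration's vertices.
#' @export
log_marginal_likelihood <- function(config, sigma_q, data, leadfield, noise) {
  if (!is.numeric(sigma_q) || sigma_q <= 0)
    stop("sigma_q must be positive")
  y <- window_values(data)
  m <- nrow(y); nt <- ncol(y)
  se2 <- noise$sigma_eps^2
  if (config$n_dipoles == 0L)
    return(-0.5 * (nt * m * log(2 * pi * se2) + sum(y^2) / se2))
  g <- build_gain(config, leadfield)
  cv <- sigma_q^2 * tcrossprod(g)
  diag(cv) <- diag(cv) + se2
  ch <- chol(cv)
  logdet <- 2 * sum(log(diag(ch)))
  quad <- sum(backsolve(ch, y, transpose = TRUE)^2)
  -0.5 * (nt * (m * log(2 * pi) + logdet) + quad)
}

#' Log prior probability of a configuration
#'
#' log p(N) plus the log probability of the unordered set of vertices under
#' the weight map: sum(log w_v) - log e_N(w). Returns `-Inf` when the count
#' exceeds `n_max` or any vertex has zero weight.
#'
#' @param config a [dipole_config].
#' @param prior a [source_prior].
#' @export
log_prior_config <- function(config, prior) {
  n <- config$n_dipoles
  if (n > prior$n_max) return(-Inf)
  lp <- log(prior$n_prior_pmf[n + 1L])
  if (n == 0L) return(lp)
  w <- prior$vertex_weights[config$vertices]
  if (any(w == 0)) return(-Inf)
  lp + sum(log(w)) - prior$log_esp[n + 1L]
}

#' Log density of the log-uniform hyper-prior on sigma_q
#'
#' Density 1 / (sigma_q * log(range_factor)) on
#' `[sigma_q_min, range_factor * sigma_q_min]`, `-Inf` outside; integrates
#' to 1 over the support.
#'
#' @param sigma_q evaluation point (positive).
#' @param prior a [moment_prior] in hyper mode.
#' @export
log_hyperprior <- function(sigma_q, prior) {
  if (prior$mode != "hyper")
    stop("log_hyperprior requires a hyper-mode moment_prior")
  lo <- prior$sigma_q_min
  hi <- prior$range_factor * prior$sigma_q_min
  ifelse(sigma_q >= lo & sigma_q <= hi,
         -log(sigma_q) - log(log(prior$range_factor)), -Inf)
}

#' Conditional posterior of the dipole moments given the configuration
#'
#' The model is conditionally linear Gaussian in the moments: given
#' (N, R, sigma_q) the posterior of Q is Gaussian with
#' covariance (G'G / sigma_eps^2 + I / sigma_q^2)^-1 (shared across samples)
#' and mean_t = Cov * G' y_t / sigma_eps^2.
#'
#' @inheritParams log_marginal_likelihood
#' @return list with `mean` (`[(n_dipoles*n_comp) x n_times]`) and
#'   `covariance` (symmetric positive definite).
#' @export
conditional_moment_posterior <- function(config, sigma_q, data, leadfield,
                                         noise) {
  if (config$n_dipoles == 0L)
    stop("conditional moment posterior is undefined for the empty configuration")
  if (!is.numeric(sigma_q) || sigma_q <= 0) stop("sigma_q must be positive")
  g <- build_gain(config, leadfield)
  y <- window_values(data)
  ridge_moment_posterior(g, y, sigma_q, noise$sigma_eps)
}

# SVD-based ridge solve: mean_t = V diag(d / (d^2 + r)) U' y_t and
# covariance = se^2 V diag(1 / (d^2 + r)) V', with r = se^2 / sq^2.
# Stable for rank-deficient gains (e.g. silent radial moment components of
# magnetometer lead fields) and in the se -> 0 limit, where it converges to
# the minimum-norm least-squares solution.
ridge_moment_posterior <- function(g, y, sigma_q, sigma_eps) {
  p <- ncol(g)
  sv <- svd(g, nu = min(nrow(g), p), nv = p)
  d <- c(sv$d, rep(0, p - length(sv$d)))
  r <- (sigma_eps / sigma_q)^2
  uty <- crossprod(sv$u, y)
  if (nrow(uty) < p)
    uty <- rbind(uty, matrix(0, p - nrow(uty), ncol(y)))
  coef <- d / (d^2 + r)
  coef[!is.finite(coef)] <- 0     # r underflow on an exactly silent direction
  mean <- sv$v %*% (coef * uty)
  cov <- sigma_eps^2 * (sv$v %*% (t(sv$v) / (d^2 + r)))
  list(mean = mean, covariance = (cov + t(cov)) / 2)
}

#' Default noise-level estimate: 20% of the signal peak
#'
#' Rule-of-thumb assessment of the combined measurement-noise and
#' forward-modeling-error level: sigma_eps = 0.2 * max |y| over the analyzed
#' window.
#'
#' @param data a [meeg_data].
#' @return positive scalar, sensor units.
#' @export
estimate_noise_std <- function(data) {
  peak <- max(abs(window_values(data)))
  if (peak == 0)
    stop("cannot estimate a noise level from an all-zero analysis window")
  0.2 * peak
}

#' Data- and lead-field-driven estimate of the moment scale sigma_q
#'
#' sigma_q = 15 * max|y| / max_v ||G_v||_F, where G_v are the per-vertex
#' lead-field blocks: a dipole of strength sigma_q at the most sensitive
#' vertex comfortably explains the data peak. Degree-1 homogeneous in the
#' data and degree-(-1) in the lead field, so the implied source strength is
#' scale-free.
#'
#' @param leadfield a [lead_field].
#' @param data a [meeg_data].
#' @return positive scalar, A*m.
#' @export
estimate_dip_mom_std <- function(leadfield, data) {
  peak <- max(abs(window_values(data)))
  if (peak == 0) stop("all-zero data: moment scale is undefined")
  nc <- leadfield$n_comp
  bn <- vapply(seq_len(leadfield$n_vertices), function(v) {
    cols <- ((v - 1L) * nc + 1L):(v * nc)
    sqrt(sum(leadfield$matrix[, cols]^2))
  }, numeric(1))
  gmax <- max(bn)
  if (gmax == 0) stop("zero lead field: moment scale is undefined")
  15 * peak / gmax
}
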