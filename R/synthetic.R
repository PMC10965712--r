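# Synthetic sensor arrays, source spaces, free-space dipolar lead fields,
# simulated datasets with known ground truth, and the exact brute-force
# posterior used as an oracle on small problems.

fibonacci_directions <- function(n, hemisphere = FALSE) {
  i <- seq_len(n)
  z <- if (hemisphere) (i - 0.5) / n else 2 * (i - 0.5) / n - 1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Synthetic hemispherical sensor array
#'
#' Quasi-uniform (Fibonacci-lattice) magnetometer positions on the upper
#' hemisphere of the given radius, with radial orientations — a stand-in for
#' a MEG helmet. The construction is deterministic; `seed` is accepted for
#' interface symmetry with the other generators.
#'
#' @param n_sensors number of sensors (>= 3).
#' @param radius_m helmet radius in meters (default 0.12).
#' @param seed unused (construction is deterministic).
#' @return list with `positions` and `orientations` (`[n_sensors x 3]`).
#' @export
make_sensor_array <- function(n_sensors, radius_m = 0.12, seed = 1L) {
  if (n_sensors < 3L) stop("need at least 3 sensors")
  u <- fibonacci_directions(n_sensors, hemisphere = TRUE)
  list(positions = radius_m * u, orientations = u)
}

#' Synthetic source space: volumetric ball or spherical shell
#'
#' Volume mode scatters quasi-uniform points in the ball of the given radius
#' (free orientation, 3 moment components). Shell mode places a
#' Fibonacci lattice on the sphere with outward unit orientations — a
#' fixed-orientation stand-in for a cortical surface with sources orthogonal
#' to it.
#'
#' @param n_vertices number of candidate locations (>= 2).
#' @param radius_m ball/shell radius in meters (default 0.08).
#' @param mode `"volume"` or `"shell"`.
#' @param seed RNG seed (volume mode draws positions).
#' @param kernel_scale_m neighbor-kernel spatial scale (meters); enlarged
#'   automatically until the neighbor graph is connected.
#' @return a [source_space].
#' @export
make_source_space <- function(n_vertices, radius_m = 0.08,
                              mode = c("volume", "shell"), seed = 1L,
                              kernel_scale_m = 0.01) {
  mode <- match.arg(mode)
  if (n_vertices < 2L) stop("need at least 2 vertices")
  if (mode == "volume") {
    set.seed(seed)
    pos <- matrix(NA_real_, n_vertices, 3)
    filled <- 0L
    while (filled < n_vertices) {
      cand <- matrix(stats::runif(3 * 2 * (n_vertices - filled), -radius_m,
                                  radius_m), ncol = 3)
      keep <- rowSums(cand^2) <= radius_m^2
      cand <- cand[keep, , drop = FALSE]
      take <- min(nrow(cand), n_vertices - filled)
      if (take > 0L)
        pos[(filled + 1L):(filled + take), ] <- cand[seq_len(take), ]
      filled <- filled + take
    }
    source_space(pos, orientations = NULL, kernel_scale_m = kernel_scale_m)
  } else {
    u <- fibonacci_directions(n_vertices, hemisphere = FALSE)
    source_space(radius_m * u, orientations = u,
                 kernel_scale_m = kernel_scale_m)
  }
}

#' Free-space dipolar lead field
#'
#' Magnetic field of a current dipole in free space,
#' B(r) = (mu0 / 4 pi) q x (r - r0) / ||r - r0||^3, projected on each
#' sensor's orientation. Deliberately simple physics — linear in the moment
#' and analytically checkable pointwise — sufficient for exercising an
#' inverse method that only ever sees the lead-field matrix; it is not a
#' physiologically accurate head model. Free-orientation spaces get 3
#' columns per vertex (unit moments along x, y, z); fixed-orientation
#' spaces 1 (moment along the vertex orientation).
#'
#' @param space a [source_space].
#' @param sensors sensor list from [make_sensor_array()].
#' @return a [lead_field].
#' @export
dipole_leadfield <- function(space, sensors) {
  mu0_4pi <- 1e-7
  spos <- sensors$positions
  sori <- sensors$orientations
  nsens <- nrow(spos)
  fixed <- !is.null(space$orientations)
  nc <- if (fixed) 1L else 3L
  G <- matrix(0, nsens, space$n_vertices * nc)
  for (v in seq_len(space$n_vertices)) {
    r0 <- space$positions[v, ]
    dr <- sweep(spos, 2, r0)           # [nsens x 3]
    dn <- sqrt(rowSums(dr^2))
    if (any(dn < 1e-9))
      stop("sensor coincides with source vertex ", v)
    # field of unit moment e at sensor s: mu0_4pi * dot(e x dr_s, n_s) / dn^3
    # = mu0_4pi * dot(e, dr_s x n_s) / dn^3, so each moment component reads
    # off a component of (dr x n)
    cx <- dr[, 2] * sori[, 3] - dr[, 3] * sori[, 2]
    cy <- dr[, 3] * sori[, 1] - dr[, 1] * sori[, 3]
    cz <- dr[, 1] * sori[, 2] - dr[, 2] * sori[, 1]
    block <- mu0_4pi * cbind(cx, cy, cz) / dn^3
    if (fixed) {
      G[, v] <- block %*% space$orientations[v, ]
    } else {
      G[, ((v - 1L) * 3L + 1L):(v * 3L)] <- block
    }
  }
  lead_field(G, n_comp = nc)
}

#' Ground-truth description of a simulated dataset
#'
#' @param config a [dipole_config] of the true dipoles.
#' @param moments numeric matrix `[(n_dipoles * n_comp) x n_times]`, A*m.
#' @param sigma_eps_true true sensor-noise standard deviation (>= 0).
#' @param seed noise RNG seed.
#' @export
ground_truth <- function(config, moments, sigma_eps_true, seed = 1L) {
  stopifnot(inherits(config, "dipole_config"), sigma_eps_true >= 0)
  moments <- as.matrix(moments)
  structure(list(config = config, moments = moments,
                 sigma_eps_true = sigma_eps_true, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate sensor data from a known dipole configuration
#'
#' Exact forward superposition G_R Q plus iid Gaussian sensor noise of
#' standard deviation `sigma_eps_true`, seeded for reproducibility.
#'
#' @param truth a [ground_truth].
#' @param leadfield a [lead_field] consistent with the truth.
#' @param sample_rate sampling rate in Hz (default 1000); samples start at 0.
#' @return a [meeg_data] covering the full simulated window.
#' @export
simulate_dataset <- function(truth, leadfield, sample_rate = 1000) {
  g <- build_gain(truth$config, leadfield)
  nt <- ncol(truth$moments)
  if (truth$config$n_dipoles > 0L &&
      nrow(truth$moments) != truth$config$n_dipoles * leadfield$n_comp)
    stop("moments have ", nrow(truth$moments), " rows; expected ",
         truth$config$n_dipoles * leadfield$n_comp)
  clean <- if (truth$config$n_dipoles == 0L)
    matrix(0, leadfield$n_sensors, nt) else g %*% truth$moments
  set.seed(truth$seed)
  noise <- matrix(stats::rnorm(length(clean), 0, truth$sigma_eps_true),
                  nrow(clean), ncol(clean))
  if (truth$sigma_eps_true == 0) noise[] <- 0
  times <- (seq_len(nt) - 1L) / sample_rate
  meeg_data(clean + noise, times, window = c(0, nt / sample_rate))
}

#' Signal-to-noise ratio of a simulated dataset
#'
#' ||G_R Q||_F / (sigma_eps sqrt(n_sensors * n_times)).
#' @inheritParams simulate_dataset
#' @export
simulated_snr <- function(truth, leadfield) {
  g <- build_gain(truth$config, leadfield)
  clean <- g %*% truth$moments
  sqrt(sum(clean^2)) / (truth$sigma_eps_true * sqrt(length(clean)))
}

#' Exact posterior by brute-force enumeration (small problems only)
#'
#' Enumerates every configuration with at most `n_max` (<= 2) dipoles,
#' computes its exact marginal likelihood (integrating sigma_q by 200-point
#' log-spaced quadrature in hyper mode) times its prior probability, and
#' normalizes by log-sum-exp. The exact twin of the sampler's target; used
#' as the reference in accuracy tests.
#'
#' @param model a [sesame_model]; its source prior must have `n_max <= 2`.
#' @param max_configs guard on the enumeration size (default 1e4).
#' @return list with `n_pmf`, `location_maps` (list indexed by count, each a
#'   per-vertex conditional probability map), `log_evidence`, and `configs`
#'   (data frame of every configuration with its posterior probability).
#' @export
enumerate_posterior <- function(model, max_configs = 1e4) {
  prior <- model$src_prior
  nmax <- prior$n_max
  if (nmax > 2L)
    stop("enumeration supports n_max <= 2 (got ", nmax, ")")
  nv <- model$space$n_vertices
  support <- which(prior$vertex_weights > 0)
  n_configs <- 1 + length(support) +
    if (nmax >= 2L) choose(length(support), 2) else 0
  if (n_configs > max_configs)
    stop("enumeration would visit ", n_configs, " configurations (guard ",
         max_configs, ")")
  configs <- c(list(integer(0)),
               lapply(support, identity),
               if (nmax >= 2L && length(support) >= 2L)
                 utils::combn(support, 2L, simplify = FALSE))
  mp <- model$mom_prior
  lml <- function(v) {
    cfg <- dipole_config(v)
    if (mp$mode == "fixed")
      return(log_marginal_likelihood(cfg, mp$sigma_q, model$data,
                                     model$leadfield, model$noise))
    # log-uniform hyper-prior: integrate p(y | sigma) over log sigma by the
    # trapezoid rule on a 200-point log-spaced grid
    ls <- seq(log(mp$sigma_q_min), log(mp$sigma_q_min * mp$range_factor),
              length.out = 200L)
    ll <- vapply(exp(ls), function(s)
      log_marginal_likelihood(cfg, s, model$data, model$leadfield,
                              model$noise), numeric(1))
    h <- ls[2L] - ls[1L]
    wts <- rep(h, 200L); wts[c(1L, 200L)] <- h / 2
    logsumexp(ll + log(wts)) - log(log(mp$range_factor))
  }
  log_joint <- vapply(configs, function(v)
    lml(v) + log_prior_config(dipole_config(v), prior), numeric(1))
  lz <- logsumexp(log_joint)
  post <- exp(log_joint - lz)
  nd <- lengths(configs)
  n_pmf <- vapply(0:nmax, function(k) sum(post[nd == k]), numeric(1))
  names(n_pmf) <- 0:nmax
  location_maps <- lapply(seq_len(nmax), function(k) {
    sel <- which(nd == k)
    if (sum(post[sel]) == 0) return(NULL)
    map <- numeric(nv)
    pk <- post[sel] / sum(post[sel])
    for (j in seq_along(sel)) {
      vs <- configs[[sel[j]]]
      map[vs] <- map[vs] + pk[j] / k
    }
    map
  })
  list(n_pmf = n_pmf, location_maps = location_maps, log_evidence = lz,
       configs = data.frame(n = nd,
                            vertices = vapply(configs, paste, character(1),
                                              collapse = ","),
                            posterior = post))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
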