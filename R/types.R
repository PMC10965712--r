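#' Candidate dipole locations with geometry and neighbor structure
#'
#' A source space is the discrete set of candidate dipole locations the
#' sampler explores: cortical-surface vertices or volumetric grid points.
#' Each vertex carries a row of positions (meters), optionally a fixed unit
#' orientation, and a normalized transition kernel over spatial neighbors
#' used by the Metropolis-Hastings update move.
#'
#' @param positions numeric matrix `[n_vertices x 3]`, vertex coordinates in
#'   meters.
#' @param orientations optional numeric matrix `[n_vertices x 3]` of unit
#'   orientation vectors (fixed-orientation mode), or `NULL` (free
#'   orientation).
#' @param neighbors list with components `ids` and `probs`: for each vertex a
#'   vector of neighbor vertex ids and matching transition probabilities
#'   summing to 1. Built automatically from a Gaussian spatial kernel when
#'   `NULL` (see `kernel_scale_m`).
#' @param kernel_scale_m spatial scale s (meters) of the Gaussian neighbor
#'   kernel, transition weight proportional to exp(-d^2 / (2 s^2)) over
#'   vertices within 3 s. If the implied graph is disconnected the scale is
#'   enlarged by factor 1.5 until connectivity is reached.
#'
#' @return object of class `source_space` with fields `positions`,
#'   `orientations`, `neighbors`, `n_vertices`, `kernel_scale_m`.
#' @export
source_space <- function(positions, orientations = NULL, neighbors = NULL,
                         kernel_scale_m = 0.01) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !all(is.finite(positions)))
    stop("positions must be a finite [n x 3] matrix of coordinates in meters")
  n <- nrow(positions)
  if (n < 1L) stop("source space needs at least one vertex")
  if (!is.null(orientations)) {
    orientations <- as.matrix(orientations)
    if (!identical(dim(orientations), dim(positions)))
      stop("orientations must match positions in shape")
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("orientations must have unit norm (tolerance 1e-9)")
  }
  if (is.null(neighbors)) {
    nb <- build_neighbor_kernel(positions, kernel_scale_m)
    neighbors <- nb$neighbors
    kernel_scale_m <- nb$scale
  } else {
    validate_neighbors(neighbors, n)
  }
  structure(list(positions = positions, orientations = orientations,
                 neighbors = neighbors, n_vertices = n,
                 kernel_scale_m = kernel_scale_m),
            class = "source_space")
}

# Gaussian kernel over vertices within 3s of each vertex (self excluded);
# the scale grows by 1.5x until every vertex has a neighbor and the graph
# is connected, so the update move is always ergodic over the space.
build_neighbor_kernel <- function(positions, scale) {
  n <- nrow(positions)
  if (n == 1L)
    return(list(neighbors = list(ids = list(integer(0)),
                                 probs = list(numeric(0))), scale = scale))
  d2 <- as.matrix(stats::dist(positions))^2
  repeat {
    ids <- vector("list", n)
    probs <- vector("list", n)
    ok <- TRUE
    r2 <- (3 * scale)^2
    for (v in seq_len(n)) {
      nb <- which(d2[v, ] <= r2)
      nb <- nb[nb != v]
      if (length(nb) == 0L) { ok <- FALSE; break }
      w <- exp(-d2[v, nb] / (2 * scale^2))
      ids[[v]] <- nb
      probs[[v]] <- w / sum(w)
    }
    if (ok && neighbor_graph_connected(ids, n))
      return(list(neighbors = list(ids = ids, probs = probs), scale = scale))
    scale <- scale * 1.5
  }
}

neighbor_graph_connected <- function(ids, n) {
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in ids[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  all(seen)
}

validate_neighbors <- function(neighbors, n) {
  if (!is.list(neighbors) || !all(c("ids", "probs") %in% names(neighbors)))
    stop("neighbors must be a list with components 'ids' and 'probs'")
  if (length(neighbors$ids) != n || length(neighbors$probs) != n)
    stop("neighbor structure must cover every vertex")
  for (v in seq_len(n)) {
    p <- neighbors$probs[[v]]
    if (length(p) && abs(sum(p) - 1) > 1e-12)
      stop("neighbor probabilities of vertex ", v, " do not sum to 1")
    if (any(neighbors$ids[[v]] < 1L | neighbors$ids[[v]] > n))
      stop("neighbor id out of range at vertex ", v)
  }
  if (!neighbor_graph_connected(neighbors$ids, n))
    stop("neighbor graph is not connected")
  invisible(TRUE)
}

#' Lead field: linear map from dipole moments to sensor readings
#'
#' @param matrix numeric matrix `[n_sensors x (n_vertices * n_comp)]`; column
#'   block k (of width `n_comp`) is the field of the unit moment components of
#'   vertex k, in sensor units per A*m.
#' @param n_comp 3 for free orientation, 1 for fixed orientation.
#' @return object of class `lead_field` with fields `matrix`, `n_comp`,
#'   `n_sensors`, `n_vertices`.
#' @export
lead_field <- function(matrix, n_comp) {
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("lead field must be finite")
  if (!n_comp %in% c(1L, 3L)) stop("n_comp must be 1 (fixed) or 3 (free)")
  if (ncol(matrix) %% n_comp != 0L)
    stop("lead field columns (", ncol(matrix), ") not a multiple of n_comp")
  nv <- ncol(matrix) %/% n_comp
  blk_norm2 <- vapply(seq_len(nv), function(v) {
    cols <- ((v - 1L) * n_comp + 1L):(v * n_comp)
    sum(matrix[, cols]^2)
  }, numeric(1))
  if (any(blk_norm2 == 0))
    stop("lead field has an all-zero vertex block (vertex ",
         which(blk_norm2 == 0)[1L], ")")
  structure(list(matrix = matrix, n_comp = as.integer(n_comp),
                 n_sensors = nrow(matrix), n_vertices = nv),
            class = "lead_field")
}

#' Sensor data restricted to an analysis window
#'
#' @param values numeric matrix `[n_sensors x n_times]` in sensor units.
#' @param sample_times strictly increasing sample times in seconds.
#' @param window length-2 numeric `(t_start, t_end)`: the analyzed sub-window,
#'   half-open `[t_start, t_end)`. Defaults to the full recording.
#' @return object of class `meeg_data` with fields `values`, `sample_times`,
#'   `window`, `window_idx` (column indices inside the window).
#' @export
meeg_data <- function(values, sample_times, window = NULL) {
  values <- as.matrix(values)
  sample_times <- as.numeric(sample_times)
  if (ncol(values) != length(sample_times))
    stop("values has ", ncol(values), " columns but ", length(sample_times),
         " sample times")
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing")
  if (is.null(window))
    window <- c(sample_times[1L],
                sample_times[length(sample_times)] + .Machine$double.eps)
  idx <- which(sample_times >= window[1L] & sample_times < window[2L])
  if (length(idx) == 0L)
    stop("analysis window [", window[1L], ", ", window[2L],
         ") contains no samples")
  structure(list(values = values, sample_times = sample_times,
                 window = window, window_idx = idx),
            class = "meeg_data")
}

#' Analyzed data window as a matrix
#' @param data a [meeg_data] object.
#' @return numeric matrix of the columns inside the analysis window.
#' @export
window_values <- function(data) data$values[, data$window_idx, drop = FALSE]

#' Gaussian sensor-noise model
#'
#' The likelihood standard deviation sigma_eps absorbs both measurement noise
#' and forward-modeling error; it acts as the threshold below which
#' data-misfit is ignored, so larger values favor sparser solutions.
#'
#' @param sigma_eps positive noise standard deviation, sensor units.
#' @export
noise_model <- function(sigma_eps) {
  if (!is.numeric(sigma_eps) || length(sigma_eps) != 1L || sigma_eps <= 0)
    stop("sigma_eps must be a single positive number")
  structure(list(sigma_eps = sigma_eps), class = "noise_model")
}

#' Prior over the number and locations of dipoles
#'
#' The dipole count N carries a pmf on 0..n_max (default: Poisson with mean
#' 0.25 truncated to the support — a mild sparsity prior; the count is known
#' a priori only to be small). Locations carry per-vertex weights; an
#' unordered configuration of distinct vertices has prior probability
#' p(N) * prod(w_v) / e_N(w), with e_N the N-th elementary symmetric
#' polynomial of the weights (the exact normalizer over distinct sets).
#' Non-uniform weights implement user-defined high/low-probability search
#' regions; zero-weight vertices are never proposed.
#'
#' @param n_vertices number of source-space vertices.
#' @param n_max maximum dipole count (default 10).
#' @param n_prior_pmf optional pmf over 0..n_max (length n_max + 1); default
#'   truncated Poisson(0.25).
#' @param vertex_weights optional non-negative per-vertex weights; normalized
#'   to sum 1. Default uniform.
#' @export
source_prior <- function(n_vertices, n_max = 10L, n_prior_pmf = NULL,
                         vertex_weights = NULL) {
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("n_max must be >= 1")
  if (is.null(n_prior_pmf)) {
    lambda <- 0.25
    k <- 0:n_max
    n_prior_pmf <- stats::dpois(k, lambda)
    n_prior_pmf <- n_prior_pmf / sum(n_prior_pmf)
  }
  if (length(n_prior_pmf) != n_max + 1L)
    stop("n_prior_pmf must have length n_max + 1")
  if (any(n_prior_pmf < 0) || abs(sum(n_prior_pmf) - 1) > 1e-12)
    stop("n_prior_pmf must be a probability vector summing to 1")
  if (is.null(vertex_weights)) vertex_weights <- rep(1, n_vertices)
  if (length(vertex_weights) != n_vertices || any(vertex_weights < 0))
    stop("vertex_weights must be non-negative, one per vertex")
  if (sum(vertex_weights) <= 0) stop("vertex_weights must not be all zero")
  w <- vertex_weights / sum(vertex_weights)
  log_esp <- log_elementary_symmetric(w, n_max)
  # a count exceeding the number of positive-weight vertices is impossible
  # (its set-normalizer e_k vanishes): drop its mass and renormalize
  n_prior_pmf <- as.numeric(n_prior_pmf)
  n_prior_pmf[!is.finite(log_esp)] <- 0
  n_prior_pmf <- n_prior_pmf / sum(n_prior_pmf)
  structure(list(n_max = n_max, n_prior_pmf = n_prior_pmf,
                 vertex_weights = w, log_esp = log_esp),
            class = "source_prior")
}

# log of elementary symmetric polynomials e_0..e_k of the weights,
# by the stable DP recurrence on the raw (already normalized) weights.
log_elementary_symmetric <- function(w, k) {
  e <- c(1, rep(0, k))
  for (wv in w[w > 0]) {
    for (j in k:1) e[j + 1L] <- e[j + 1L] + e[j] * wv
  }
  log(e)
}

#' Prior on the dipole-moment standard deviation sigma_q
#'
#' Either a fixed value, or a log-uniform hyper-prior on
#' `[sigma_q_min, range_factor * sigma_q_min]` (default spanning three orders
#' of magnitude), which makes the reconstruction insensitive to the unknown
#' order of magnitude of the source strengths.
#'
#' @param mode `"fixed"` or `"hyper"`.
#' @param sigma_q fixed moment standard deviation, A*m (fixed mode).
#' @param sigma_q_min lower edge of the hyper-prior support (hyper mode).
#' @param range_factor ratio of upper to lower support edge, default 1000.
#' @export
moment_prior <- function(mode = c("fixed", "hyper"), sigma_q = NULL,
                         sigma_q_min = NULL, range_factor = 1000) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(sigma_q) || sigma_q <= 0)
      stop("fixed mode requires a positive sigma_q")
    sigma_q_min <- NA_real_
  } else {
    if (is.null(sigma_q_min) || sigma_q_min <= 0)
      stop("hyper mode requires a positive sigma_q_min")
    if (range_factor <= 1) stop("range_factor must exceed 1")
    sigma_q <- NA_real_
  }
  structure(list(mode = mode, sigma_q = sigma_q, sigma_q_min = sigma_q_min,
                 range_factor = range_factor),
            class = "moment_prior")
}

#' A candidate dipole configuration
#'
#' Holds the dipole count and the (distinct) vertex ids of a candidate
#' solution. Order is non-semantic: vertices are stored sorted, so two
#' configurations with permuted lists compare equal and the marginal
#' likelihood is exactly permutation-invariant.
#'
#' @param vertices integer vector of distinct vertex ids (1-based); may be
#'   empty (the zero-dipole configuration).
#' @export
dipole_config <- function(vertices = integer(0)) {
  vertices <- as.integer(vertices)
  if (anyNA(vertices)) stop("vertex ids must not be NA")
  if (anyDuplicated(vertices))
    stop("duplicate vertices are forbidden within a configuration")
  if (length(vertices) && any(vertices < 1L))
    stop("vertex ids are 1-based positive integers")
  structure(list(n_dipoles = length(vertices), vertices = sort(vertices)),
            class = "dipole_config")
}

#' Bundle model ingredients for the sampler
#'
#' @param leadfield a [lead_field].
#' @param data a [meeg_data] (sensor count must match the lead field).
#' @param space the [source_space] the lead field was computed on.
#' @param noise a [noise_model]; `NULL` resolves via [estimate_noise_std()].
#' @param src_prior a [source_prior]; `NULL` uses defaults.
#' @param mom_prior a [moment_prior]; `NULL` resolves a hyper-prior seeded by
#'   [estimate_dip_mom_std()].
#' @return object of class `sesame_model`.
#' @export
sesame_model <- function(leadfield, data, space, noise = NULL,
                         src_prior = NULL, mom_prior = NULL) {
  stopifnot(inherits(leadfield, "lead_field"), inherits(data, "meeg_data"),
            inherits(space, "source_space"))
  if (nrow(data$values) != leadfield$n_sensors)
    stop("data has ", nrow(data$values), " sensors but lead field has ",
         leadfield$n_sensors)
  if (space$n_vertices != leadfield$n_vertices)
    stop("source space has ", space$n_vertices,
         " vertices but lead field has ", leadfield$n_vertices)
  if (is.null(noise)) noise <- noise_model(estimate_noise_std(data))
  if (is.null(src_prior)) src_prior <- source_prior(space$n_vertices)
  if (is.null(mom_prior)) {
    sq <- estimate_dip_mom_std(leadfield, data)
    mom_prior <- moment_prior("hyper", sigma_q_min = sq / sqrt(1000))
  }
  structure(list(leadfield = leadfield, data = data, space = space,
                 noise = noise, src_prior = src_prior,
                 mom_prior = mom_prior),
            class = "sesame_model")
}
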