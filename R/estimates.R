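particles_of <- function(x) {
  if (inherits(x, "sesame_fit")) x$particles
  else if (inherits(x, "particle_set")) x
  else stop("expected a sesame_fit or particle_set")
}

#' Posterior probability of the number of sources
#'
#' p(N = k | y) = sum of normalized particle weights over particles carrying
#' k dipoles.
#'
#' @param x a `sesame_fit` or `particle_set`.
#' @return probability vector over 0..n_max (named by count).
#' @export
source_number_posterior <- function(x) {
  ps <- particles_of(x)
  n <- lengths(ps$vertices)
  nmax <- if (!is.null(ps$n_max)) ps$n_max else max(n)
  pmf <- vapply(0:nmax, function(k) sum(ps$weights[n == k]), numeric(1))
  names(pmf) <- 0:nmax
  pmf
}

#' Posterior location probability map conditional on a dipole count
#'
#' Restricts to particles with N = `n_cond`, renormalizes their weights and
#' assigns each vertex the weighted fraction of dipoles sitting on it. A
#' highly focused map indicates low location uncertainty (quantified by
#' [spatial_dispersion()]); a widespread map, high uncertainty.
#'
#' @param x a `sesame_fit` or `particle_set`.
#' @param n_cond conditioning dipole count (>= 1) with positive posterior
#'   mass.
#' @param n_vertices number of source-space vertices (inferred from a
#'   `sesame_fit`).
#' @return per-vertex probability vector summing to 1.
#' @export
location_probability_map <- function(x, n_cond, n_vertices = NULL) {
  ps <- particles_of(x)
  if (is.null(n_vertices)) {
    if (inherits(x, "sesame_fit")) n_vertices <- x$model$space$n_vertices
    else stop("n_vertices is required when passing a bare particle_set")
  }
  sel <- lengths(ps$vertices) == n_cond
  wsel <- ps$weights[sel]
  if (!any(sel) || sum(wsel) == 0)
    stop("no posterior mass on N = ", n_cond)
  wsel <- wsel / sum(wsel)
  map <- numeric(n_vertices)
  vs <- ps$vertices[sel]
  for (i in seq_along(vs))
    map[vs[[i]]] <- map[vs[[i]]] + wsel[i] / n_cond
  map
}

#' Greedy peak extraction from a location probability map
#'
#' Repeatedly takes the highest-probability vertex and suppresses every
#' vertex within `exclusion_radius_m`, until `n_hat` peaks are found. Each
#' peak is reported with its credibility mass: the total suppressed
#' neighborhood probability, giving each reported dipole its own uncertainty
#' number.
#'
#' @param map normalized per-vertex probabilities.
#' @param n_hat number of peaks sought (>= 1).
#' @param space the [source_space].
#' @param exclusion_radius_m suppression radius in meters (default 0.02).
#' @return data frame with columns `vertex`, `map_value`, `mass`, sorted by
#'   descending map value; attribute `incomplete` is TRUE (with a warning)
#'   when fewer than `n_hat` separable peaks exist.
#' @export
extract_peaks <- function(map, n_hat, space, exclusion_radius_m = 0.02) {
  stopifnot(n_hat >= 1L, length(map) == space$n_vertices)
  avail <- map > 0
  pos <- space$positions
  out <- list()
  remaining <- map
  while (length(out) < n_hat && any(avail)) {
    v <- which(avail)[which.max(remaining[avail])]
    d <- sqrt(colSums((t(pos) - pos[v, ])^2))
    nbh <- avail & d <= exclusion_radius_m
    out[[length(out) + 1L]] <- data.frame(vertex = v, map_value = map[v],
                                          mass = sum(map[nbh]))
    avail[nbh] <- FALSE
  }
  res <- do.call(rbind, out)
  incomplete <- nrow(res) < n_hat
  if (incomplete)
    warning("only ", nrow(res), " separable peaks found (requested ", n_hat, ")")
  attr(res, "incomplete") <- incomplete
  res
}

#' Posterior source time courses at the estimated dipoles
#'
#' Conditional posterior mean of the dipole moments at the estimated
#' configuration, with sigma_q set to the posterior weighted mean of the
#' particle sigma_q values conditioned on N = length(dipoles). In free
#' orientation mode also returns the moment amplitude per dipole and sample.
#'
#' @param dipoles vertex ids of the estimated dipoles (non-empty).
#' @param x a `sesame_fit` (or `particle_set`, with `model` supplied).
#' @param model a [sesame_model] (inferred from a `sesame_fit`).
#' @return list with `moments` (`[(n*n_comp) x n_times]`, one row block per
#'   dipole, in the order given) and `amplitudes` (`[n x n_times]`).
#' @export
compute_time_courses <- function(dipoles, x, model = NULL) {
  if (length(dipoles) == 0L) stop("dipoles must be non-empty")
  ps <- particles_of(x)
  if (is.null(model)) {
    if (inherits(x, "sesame_fit")) model <- x$model
    else stop("model is required when passing a bare particle_set")
  }
  sel <- lengths(ps$vertices) == length(dipoles)
  sq <- if (any(sel)) {
    sum(ps$weights[sel] * ps$sigma_q[sel]) / sum(ps$weights[sel])
  } else stats::weighted.mean(ps$sigma_q, ps$weights)
  nc <- model$leadfield$n_comp
  # preserve the caller's dipole order: build the gain block by block
  g <- do.call(cbind, lapply(dipoles, function(v)
    build_gain(dipole_config(v), model$leadfield)))
  y <- window_values(model$data)
  mom <- ridge_moment_posterior(g, y, sq, model$noise$sigma_eps)$mean
  amp <- t(vapply(seq_along(dipoles), function(k) {
    rows <- ((k - 1L) * nc + 1L):(k * nc)
    sqrt(colSums(mom[rows, , drop = FALSE]^2))
  }, numeric(ncol(y))))
  list(moments = mom, amplitudes = amp, sigma_q = sq)
}

#' Goodness of fit of a reconstructed field
#'
#' GOF = 1 - ||y - yhat||_F^2 / ||y||_F^2; 1 for a perfect fit, 0 for the
#' null (all-zero) reconstruction.
#'
#' @param data a [meeg_data] or numeric matrix (analyzed window).
#' @param fitted numeric matrix of the same shape.
#' @export
gof <- function(data, fitted) {
  y <- if (inherits(data, "meeg_data")) window_values(data) else as.matrix(data)
  fitted <- as.matrix(fitted)
  if (!all(dim(y) == dim(fitted)))
    stop("data and fitted field differ in shape")
  ss <- sum(y^2)
  if (ss == 0) stop("GOF is undefined for all-zero data")
  1 - sum((y - fitted)^2) / ss
}

# exact min-cost injective assignment of rows (m) into columns (n >= m)
min_assignment_cost <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > m) { best <<- acc; return() }
    ord <- order(cost[i, ])
    for (j in ord) if (!used[j]) {
      used[j] <- TRUE
      recurse(i + 1L, used, acc + cost[i, j])
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(n), 0)
  best
}

#' Optimal subpattern assignment (OSPA) distance between point sets
#'
#' Metric between finite point sets penalizing both localization error and
#' cardinality mismatch. For |X| = m <= |Y| = n:
#' ((min over injective assignments of sum min(d, c)^p + c^p (n - m)) / n)^(1/p).
#' Bounded by the cutoff c; 0 iff the sets coincide.
#'
#' @param x,y numeric matrices (rows are points) or vectors (single point);
#'   either may be empty (`NULL` or 0 rows).
#' @param cutoff_m cutoff distance c in meters (default 0.03).
#' @param order exponent p >= 1 (default 1).
#' @export
ospa <- function(x, y, cutoff_m = 0.03, order = 1) {
  as_pts <- function(p) {
    if (is.null(p) || length(p) == 0L) return(matrix(0, 0L, 0L))
    if (is.null(dim(p))) matrix(p, 1L) else as.matrix(p)
  }
  x <- as_pts(x); y <- as_pts(y)
  m <- nrow(x); n <- nrow(y)
  if (m == 0L && n == 0L) return(0)
  if (m > n) { tmp <- x; x <- y; y <- tmp; m <- nrow(x); n <- nrow(y) }
  if (m == 0L) return(cutoff_m)
  d <- sqrt(pmax(outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y), 0))
  cost <- pmin(d, cutoff_m)^order
  ((min_assignment_cost(cost) + cutoff_m^order * (n - m)) / n)^(1 / order)
}

#' Spatial dispersion of a location probability map
#'
#' Probability-weighted RMS distance of the map mass to the nearest
#' estimated dipole: SD = sqrt(sum_v map_v d(v, nearest dipole)^2), in
#' meters. Zero iff all mass sits exactly on dipole vertices; small SD means
#' a focused map, i.e. low reconstruction uncertainty.
#'
#' @param map normalized per-vertex probabilities.
#' @param dipoles vertex ids of the estimated dipoles (non-empty).
#' @param space the [source_space].
#' @export
spatial_dispersion <- function(map, dipoles, space) {
  stopifnot(length(dipoles) >= 1L, length(map) == space$n_vertices)
  pos <- space$positions
  d2min <- rep(Inf, space$n_vertices)
  for (v in dipoles) {
    d2 <- colSums((t(pos) - pos[v, ])^2)
    d2min <- pmin(d2min, d2)
  }
  sqrt(sum(map * d2min))
}

#' Map localization discrepancy against a known ground truth
#'
#' Mean, over the true dipoles, of the distance to the nearest local peak of
#' the posterior map (peaks via [extract_peaks()] with as many peaks as true
#' dipoles). Zero when every true dipole coincides with a peak. Synthetic-use
#' metric: requires the ground truth.
#'
#' @param map normalized per-vertex probabilities.
#' @param true_dipoles vertex ids of the simulated dipoles.
#' @param space the [source_space].
#' @param exclusion_radius_m passed to [extract_peaks()].
#' @export
map_localization_discrepancy <- function(map, true_dipoles, space,
                                         exclusion_radius_m = 0.02) {
  pk <- suppressWarnings(
    extract_peaks(map, length(true_dipoles), space, exclusion_radius_m))
  ppos <- space$positions[pk$vertex, , drop = FALSE]
  mean(vapply(true_dipoles, function(v) {
    min(sqrt(rowSums((ppos - matrix(space$positions[v, ], nrow(ppos), 3,
                                    byrow = TRUE))^2)))
  }, numeric(1)))
}

#' Full posterior summary of a fitted model
#'
#' Assembles the standard output surface: p(N | y); the most probable count
#' n_hat (ties break toward fewer dipoles — parsimony); the location map
#' conditional on n_hat; the n_hat map peaks with credibility masses; the
#' source time courses; GOF and spatial dispersion; and alternative
#' solutions — one entry for every count whose posterior mass reaches
#' `alt_threshold`, so competing explanations (e.g. a 60/40 split between a
#' one- and a two-dipole model) are surfaced rather than hidden.
#'
#' @param fit a `sesame_fit`.
#' @param alt_threshold minimum posterior mass for a count to be reported as
#'   an alternative solution (default 0.1).
#' @param exclusion_radius_m peak-suppression radius (default 0.02 m).
#' @return object of class `sesame_summary`.
#' @export
summarize_posterior <- function(fit, alt_threshold = 0.1,
                                exclusion_radius_m = 0.02) {
  stopifnot(inherits(fit, "sesame_fit"))
  ps <- fit$particles
  model <- fit$model
  n_pmf <- source_number_posterior(ps)
  n_hat <- as.integer(names(n_pmf)[which.max(n_pmf)])  # which.max: first max
  solve_for <- function(k) {
    if (k == 0L)
      return(list(n = 0L, location_map = NULL, dipoles = NULL,
                  time_courses = NULL, fitted = matrix(0, nrow(model$data$values),
                                                       length(model$data$window_idx))))
    map <- location_probability_map(ps, k, model$space$n_vertices)
    pk <- suppressWarnings(extract_peaks(map, k, model$space,
                                         exclusion_radius_m))
    tc <- compute_time_courses(pk$vertex, ps, model)
    g <- do.call(cbind, lapply(pk$vertex, function(v)
      build_gain(dipole_config(v), model$leadfield)))
    list(n = k, location_map = map, dipoles = pk, time_courses = tc,
         fitted = g %*% tc$moments)
  }
  main <- solve_for(n_hat)
  g_val <- gof(model$data, main$fitted)
  sd_val <- if (n_hat > 0L)
    spatial_dispersion(main$location_map, main$dipoles$vertex, model$space)
  else NA_real_
  alts <- lapply(as.integer(names(n_pmf)[n_pmf >= alt_threshold]), function(k) {
    s <- solve_for(k)
    list(n = k, probability = unname(n_pmf[as.character(k)]),
         location_map = s$location_map, dipoles = s$dipoles)
  })
  structure(list(n_pmf = n_pmf, n_hat = n_hat,
                 location_map = main$location_map,
                 estimated_dipoles = main$dipoles,
                 time_courses = main$time_courses,
                 fitted = main$fitted, gof = g_val, sd = sd_val,
                 alternatives = alts),
            class = "sesame_summary")
}

#' @export
print.sesame_summary <- function(x, ...) {
  cat("Posterior over number of dipoles:\n")
  shown <- x$n_pmf[x$n_pmf > 1e-4]
  cat(paste0("  p(N = ", names(shown), " | y) = ", sprintf("%.4f", shown),
             collapse = "\n"), "\n")
  cat("Estimated N =", x$n_hat, "\n")
  if (x$n_hat > 0L) {
    cat("Estimated dipoles (vertex, map value, credibility mass):\n")
    print(x$estimated_dipoles, row.names = FALSE)
    cat(sprintf("GOF = %.4f, spatial dispersion = %.4f m\n", x$gof, x$sd))
  } else {
    cat(sprintf("GOF = %.4f (null reconstruction)\n", x$gof))
  }
  if (length(x$alternatives) > 1L)
    cat("Alternative solutions at N =",
        paste(vapply(x$alternatives, `[[`, integer(1), "n"), collapse = ", "),
        "\n")
  invisible(x)
}
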