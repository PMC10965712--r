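# Matrix files are plain TSV ('#' comments); results and source spaces are
# self-describing JSON written at full IEEE-754 precision (jsonlite with
# digits = I(17)), so numeric round-trips are bitwise.

RESULT_FORMAT_VERSION <- 1L

#' Read a numeric matrix from a delimited text file
#'
#' Tab- or whitespace-delimited, row-major; lines starting with `#` and
#' blank lines are ignored. Ragged rows are a format error naming the
#' offending row.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines), "[\t ]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stop("ragged matrix in ", path, ": row ", bad, " has ", ncols[bad],
         " values, expected ", ncols[1L])
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) stop("non-numeric entry in ", path)
  matrix(vals, nrow = length(rows), byrow = TRUE)
}

#' Write a numeric matrix as TSV at full precision
#'
#' @param m numeric matrix.
#' @param path output path.
#' @param comment optional `#` header line.
#' @export
write_matrix <- function(m, path, comment = NULL) {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Save a completed run to a self-describing result file
#'
#' JSON layout: `format_version`; `config` (every resolved parameter
#' including the seed, making the run re-executable from its output alone);
#' `posterior` (per-particle dipole counts, concatenated vertex lists with
#' offsets, sigma_q, weights, the gamma schedule and ESS log); `estimates`
#' (n_pmf, location map, dipole table, time courses, GOF, SD). All numbers
#' are written at full precision so [load_result()] reproduces every array
#' bitwise.
#'
#' @param summary a `sesame_summary` from [summarize_posterior()].
#' @param fit the `sesame_fit` the summary came from.
#' @param config named list of resolved run parameters (stored verbatim).
#' @param path output path.
#' @export
save_result <- function(summary, fit, config, path) {
  ps <- fit$particles
  obj <- list(
    format_version = RESULT_FORMAT_VERSION,
    config = config,
    posterior = list(
      n = lengths(ps$vertices),
      vertices = as.integer(unlist(ps$vertices)),
      offsets = c(0L, cumsum(lengths(ps$vertices))),
      sigma_q = ps$sigma_q,
      weights = ps$weights,
      gamma_schedule = fit$log$gamma,
      ess_log = fit$log$ess),
    estimates = list(
      n_pmf = as.numeric(summary$n_pmf),
      n_hat = summary$n_hat,
      location_map = if (is.null(summary$location_map)) numeric(0)
                     else summary$location_map,
      dipole_vertices = if (is.null(summary$estimated_dipoles)) integer(0)
                        else summary$estimated_dipoles$vertex,
      dipole_masses = if (is.null(summary$estimated_dipoles)) numeric(0)
                      else summary$estimated_dipoles$mass,
      time_courses = if (is.null(summary$time_courses)) NULL
                     else list(values = as.numeric(summary$time_courses$moments),
                               nrow = nrow(summary$time_courses$moments)),
      gof = summary$gof,
      sd = summary$sd))
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  invisible(path)
}

#' Load a result file written by [save_result()]
#'
#' @param path result file path.
#' @return list with `config`, `posterior` (including the reassembled
#'   per-particle vertex lists), and `estimates` (time courses restored to
#'   matrix shape).
#' @export
load_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (is.null(obj$format_version))
    stop("not a result file (missing format_version): ", path)
  if (obj$format_version > RESULT_FORMAT_VERSION)
    stop("result file has format version ", obj$format_version,
         "; this build reads up to version ", RESULT_FORMAT_VERSION)
  po <- obj$posterior
  off <- po$offsets
  po$vertex_lists <- lapply(seq_along(po$n), function(i) {
    if (po$n[i] == 0L) integer(0)
    else as.integer(po$vertices[(off[i] + 1L):off[i + 1L]])
  })
  est <- obj$estimates
  if (!is.null(est$time_courses) && length(est$time_courses))
    est$time_courses <- matrix(est$time_courses$values,
                               nrow = est$time_courses$nrow)
  list(config = obj$config, posterior = po, estimates = est,
       format_version = obj$format_version)
}

#' Save / load a source space as JSON
#'
#' @param space a [source_space].
#' @param path file path.
#' @export
save_source_space <- function(space, path) {
  obj <- list(positions = space$positions,
              orientations = space$orientations,
              kernel_scale_m = space$kernel_scale_m)
  writeLines(jsonlite::toJSON(obj, digits = I(17), null = "null"), path)
  invisible(path)
}

#' @rdname save_source_space
#' @export
load_source_space <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  source_space(obj$positions, orientations = obj$orientations,
               kernel_scale_m = obj$kernel_scale_m)
}

#' Read a YAML run configuration
#'
#' Mirrors the CLI flags: paths to `leadfield`, `data`, `source_space`;
#' `window` (two numbers, seconds); `noise_std` (`"auto"`,
#' `"baseline:T0:T1"` or a number); `dip_mom_std` (`"auto"`, `"hyper"` or a
#' number); `n_particles`; `seed`; `output`.
#'
#' @param path YAML file path.
#' @return named list of settings with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(window = NULL, noise_std = "auto", dip_mom_std = "hyper",
                   n_particles = 100L, seed = 1L, n_comp = NULL,
                   output = "result.json")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("leadfield", "data", "source_space"))
    if (is.null(cfg[[k]])) stop("run config is missing required field '", k, "'")
  cfg
}

# Resolve the noise specification: "auto", "baseline:T0:T1" (pooled std over
# that window) or a positive number.
resolve_noise_std <- function(spec, data) {
  if (is.numeric(spec)) {
    if (spec <= 0) stop("noise-std must be positive (got ", spec, ")")
    return(spec)
  }
  if (identical(spec, "auto")) return(estimate_noise_std(data))
  if (grepl("^baseline:", spec)) {
    parts <- as.numeric(strsplit(spec, ":")[[1L]][-1L])
    if (length(parts) != 2L || anyNA(parts))
      stop("baseline spec must be baseline:T0:T1 (got '", spec, "')")
    idx <- which(data$sample_times >= parts[1L] & data$sample_times < parts[2L])
    if (!length(idx)) stop("baseline window contains no samples")
    s <- stats::sd(as.vector(data$values[, idx]))
    if (s == 0) stop("baseline window has zero variance")
    return(s)
  }
  num <- suppressWarnings(as.numeric(spec))
  if (!is.na(num)) return(resolve_noise_std(num, data))
  stop("unrecognized noise-std specification '", spec, "'")
}
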