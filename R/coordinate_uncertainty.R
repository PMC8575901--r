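# ---------------------------------------------------------------------------
# Perturbation-based coordinate precision: structure-factor perturbation,
# coordinate kicking, and geometry statistics over a re-refined ensemble.
# Re-refinement itself is an external hook; the synthetic ensemble
# generator stands in for it in self-contained runs.
# ---------------------------------------------------------------------------

with_seed <- function(seed, expr) {
  # evaluate expr under a private RNG stream, restoring global state after
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a reflection table
#'
#' Plain-text, whitespace-delimited table `h k l F_obs F_model [sigma]`;
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @return data.frame with columns `h`, `k`, `l`, `f_obs`, `f_model`, and
#'   `sigma` when present.
#' @export
read_reflections <- function(path) {
  df <- read.table(path, comment.char = "#", header = FALSE,
                   col.names = c("h", "k", "l", "f_obs", "f_model",
                                 "sigma")[1:min(6, count_fields(path))],
                   fill = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("reflection table needs at least 5 columns")
  if (any(df$f_obs < 0 | df$f_model < 0)) {
    stop("negative structure-factor amplitude in ", basename(path))
  }
  df
}

count_fields <- function(path) {
  for (ln in readLines(path, warn = FALSE)) {
    if (!startsWith(trimws(ln), "#") && nzchar(trimws(ln))) {
      return(length(strsplit(trimws(ln), "\\s+")[[1L]]))
    }
  }
  5L
}

#' Write a reflection table
#' @param records reflection data.frame (see [read_reflections()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(records, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(records), collapse = " ")), con)
  write.table(format(records, digits = 8, trim = TRUE, scientific = FALSE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Perturb observed structure-factor amplitudes
#'
#' Each amplitude is moved by a random fraction of its model discrepancy:
#' `F_obs' = F_obs + u * |F_obs - F_model|` with `u` drawn independently
#' per reflection. The perturbation scale "within plus/minus the model
#' residual" leaves the distribution open; the minimal reading, uniform on
#' `[-1, 1]`, is the default, with a truncated-Gaussian alternative.
#' Negative results are clamped to 0 and counted (attribute `n_clamped`).
#'
#' @param records reflection data.frame with `f_obs` and `f_model`.
#' @param seed integer; fully determines the output.
#' @param dist `"uniform"` (default) or `"gaussian"` (N(0, 0.5^2)
#'   truncated to `[-1, 1]`).
#' @return the records with perturbed `f_obs`; attribute `n_clamped`.
#' @export
perturb_structure_factors <- function(records, seed,
                                      dist = c("uniform", "gaussian")) {
  dist <- match.arg(dist)
  if (is.null(records$f_obs) || is.null(records$f_model)) {
    stop("records must carry f_obs and f_model")
  }
  n <- nrow(records)
  u <- with_seed(seed, {
    if (dist == "uniform") runif(n, -1, 1)
    else {
      v <- rnorm(n, 0, 0.5)
      while (any(bad <- abs(v) > 1)) v[bad] <- rnorm(sum(bad), 0, 0.5)
      v
    }
  })
  newf <- records$f_obs + u * abs(records$f_obs - records$f_model)
  n_clamped <- sum(newf < 0)
  records$f_obs <- pmax(newf, 0)
  attr(records, "n_clamped") <- n_clamped
  records
}

#' Randomly displace atom coordinates
#'
#' Every non-hydrogen atom is displaced by an isotropic Gaussian vector
#' whose root-mean-square length equals `magnitude` (each Cartesian
#' component has sd `magnitude / sqrt(3)`). Used to decorrelate the
#' starting model before each re-refinement trial.
#'
#' @param structure a `psi_structure`.
#' @param magnitude RMS displacement in Angstrom (>= 0).
#' @param seed integer; the output is a pure function of (structure,
#'   magnitude, seed).
#' @return the kicked `psi_structure`.
#' @export
kick_coordinates <- function(structure, magnitude, seed) {
  if (magnitude < 0) stop("kick magnitude must be >= 0")
  if (magnitude == 0) return(structure)
  at <- structure$atoms
  heavy <- !at$hydrogen
  n <- sum(heavy)
  d <- with_seed(seed, matrix(rnorm(3L * n, 0, magnitude / sqrt(3)), n, 3L))
  at$x[heavy] <- at$x[heavy] + d[, 1L]
  at$y[heavy] <- at$y[heavy] + d[, 2L]
  at$z[heavy] <- at$z[heavy] + d[, 3L]
  structure$atoms <- at
  structure
}

#' Geometry statistics across a model ensemble
#'
#' Evaluates a scalar geometry metric on every model of an ensemble (e.g.
#' the 100 re-refined models of a structure-factor perturbation run) and
#' returns the sample mean and standard deviation -- the coordinate
#' precision readout.
#'
#' @param models list of `psi_structure` objects, length >= 2.
#' @param metric function taking a `psi_structure` and returning one
#'   number, e.g. from [make_pocket_metric()].
#' @param metric_label text label for reporting.
#' @return list of class `ensemble_stats`: `metric_label`,
#'   `per_model_values`, `mean`, `sd`, `n_models`.
#' @export
ensemble_geometry_stats <- function(models, metric,
                                    metric_label = "metric") {
  if (length(models) < 2L) stop("ensemble needs at least 2 models")
  vals <- vapply(seq_along(models), function(i) {
    v <- tryCatch(metric(models[[i]]), error = function(e) {
      stop("metric failed on model ", i, ": ", conditionMessage(e))
    })
    as.numeric(v)
  }, numeric(1))
  structure(
    list(metric_label = metric_label, per_model_values = vals,
         mean = mean(vals), sd = sd(vals), n_models = length(vals)),
    class = "ensemble_stats"
  )
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("%s over %d models: %.3f +/- %.3f\n",
              x$metric_label, x$n_models, x$mean, x$sd))
  invisible(x)
}

#' Pocket-geometry metric factory
#'
#' Builds a closure evaluating one stacking quantity (angle or minimum
#' contact) for a named ring pair, suitable for
#' [ensemble_geometry_stats()].
#'
#' @param pair_label e.g. `"PsaB-Phe669/PhQ_B"`.
#' @param registry,dialect passed to [build_cofactor_map()].
#' @param what `"angle"` or `"min_contact"`.
#' @return function of a `psi_structure` returning one number.
#' @export
make_pocket_metric <- function(pair_label, registry = read_registry(),
                               dialect = NULL,
                               what = c("angle", "min_contact")) {
  what <- match.arg(what)
  parts <- strsplit(pair_label, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("pair label must be 'ringA/ringB'")
  pairs <- data.frame(ring_a = parts[1L], ring_b = parts[2L])
  function(model) {
    map <- build_cofactor_map(model, registry, dialect)
    rep <- stacking_report(model, map, pairs)
    rep[[what]][1L]
  }
}

#' External refinement hook
#'
#' Full crystallographic re-refinement is outside this package; the
#' perturbation workflow instead calls a user-supplied command template
#' with the perturbed reflection file and the kicked model, and reads back
#' the refined model. The template must contain the placeholders
#' `{reflections}`, `{model_in}` and `{model_out}`.
#'
#' @param command_template shell command template.
#' @return function `(reflections_path, model_in_path, model_out_path)`
#'   running the command and returning the refined `psi_structure`.
#' @export
refinement_hook <- function(command_template) {
  for (ph in c("{reflections}", "{model_in}", "{model_out}")) {
    if (!grepl(ph, command_template, fixed = TRUE)) {
      stop("command template lacks placeholder ", ph)
    }
  }
  function(reflections_path, model_in_path, model_out_path) {
    cmd <- command_template
    cmd <- sub("{reflections}", reflections_path, cmd, fixed = TRUE)
    cmd <- sub("{model_in}", model_in_path, cmd, fixed = TRUE)
    cmd <- sub("{model_out}", model_out_path, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop("refinement command failed with status ", status)
    read_structure(model_out_path)
  }
}
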