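# Serialization and the command pipeline behind the CLI script
# (inst/cli/retrokin-cli.R).  Field names follow the dimensionless symbols
# (E, Ep, K, Kp, P, KB); cycle indices are 1-based.

ext_of <- function(path) tolower(tools::file_ext(path))

#' Write / read a dimensionless parameter set (YAML or JSON)
#'
#' @param p a `dimensionless_params`.
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(p, path) {
  x <- list(E = p$E, Ep = p$Ep, K = p$K, Kp = p$Kp, P = p$P, KB = p$KB)
  if (ext_of(path) %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  x <- if (ext_of(path) %in% c("yaml", "yml")) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  dimensionless_params(E = unlist(x$E), Ep = unlist(x$Ep), K = unlist(x$K),
                       Kp = unlist(x$Kp), P = unlist(x$P),
                       KB = unlist(x$KB))
}

#' Write / read a parameter space (YAML or JSON)
#'
#' @param space a `parameter_space`.
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path) {
  x <- list(motif = space$spec$motif,
            n = if (space$spec$motif == "extended") 3L else space$spec$n,
            tie_cycles_to_3 = space$tie_cycles_to_3,
            ranges = lapply(space$ranges, function(r)
              list(min = r$min, max = r$max, scale = r$scale)))
  if (ext_of(path) %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  x <- if (ext_of(path) %in% c("yaml", "yml")) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- build_network(x$motif, x$n)
  ranges <- lapply(x$ranges, function(r) c(r$min, r$max))
  scales <- vapply(x$ranges, function(r) r$scale %||% "log", "")
  rng <- mapply(function(nm, b, sc) parameter_range(nm, b[1], b[2], sc),
                names(ranges), ranges, scales, SIMPLIFY = FALSE)
  parameter_space(spec, rng, tie_cycles_to_3 = isTRUE(x$tie_cycles_to_3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validated run configuration
#'
#' Bundles everything a pipeline command needs; validated before any
#' computation and written alongside every output for provenance.
#'
#' @param motif,n network motif and cycle count.
#' @param set fixture name, path, or `dimensionless_params` (curve runs).
#' @param space fixture name, path, or `parameter_space` (batch runs).
#' @param overrides named list of single-parameter overrides applied to
#'   `set`, e.g. `list(K3 = 0.004)`.
#' @param n_sets parameter sets per exploration (>= 1).
#' @param seed integer seed.
#' @param outdir output directory (created if needed at run time).
#' @param threshold,I_low,I_high,n_grid detection settings, see
#'   [detection_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(motif = "vertical", n = 3L, set = NULL, space = NULL,
                       overrides = list(), n_sets = 5000L, seed = 1L,
                       outdir = ".", threshold = 0.10, I_low = 1e-4,
                       I_high = 1e4, n_grid = 61L) {
  spec <- build_network(motif, n)   # validates the topology
  if (n_sets < 1) stop("n_sets must be at least 1")
  if (length(overrides) > 0 && is.null(names(overrides)))
    stop("overrides must be a named list")
  det <- detection_config(threshold, I_low, I_high, n_grid)
  structure(list(motif = motif, n = as.integer(n), spec = spec, set = set,
                 space = space, overrides = overrides,
                 n_sets = as.integer(n_sets), seed = as.integer(seed),
                 outdir = outdir, det = det),
            class = "run_config")
}

resolve_set <- function(config) {
  s <- config$set
  if (is.null(s)) stop("config does not name a parameter set")
  p <- if (inherits(s, "dimensionless_params")) s
       else if (file.exists(s)) read_parameter_set(s)
       else get_parameter_set(s)
  for (nm in names(config$overrides)) p <- set_param(p, nm, config$overrides[[nm]])
  p
}

resolve_space <- function(config) {
  s <- config$space
  if (is.null(s)) stop("config does not name a parameter space")
  if (inherits(s, "parameter_space")) s
  else if (file.exists(s)) read_space(s)
  else get_space(s)
}

config_provenance <- function(config) {
  list(motif = config$motif, n = config$n,
       set = if (is.character(config$set)) config$set else NULL,
       space = if (is.character(config$space)) config$space else NULL,
       overrides = config$overrides, n_sets = config$n_sets,
       seed = config$seed,
       threshold = config$det$threshold, I_low = config$det$I_low,
       I_high = config$det$I_high,
       scaled_down = config$n_sets < 5000L)
}

write_outputs <- function(config, files) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config_provenance(config),
                       file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(files)) {
    path <- file.path(config$outdir, nm)
    obj <- files[[nm]]
    if (ext_of(path) == "csv") {
      write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(file.path(config$outdir, names(files)))
}

#' Pipeline commands
#'
#' The four commands behind the shipped CLI script.  Each resolves and
#' validates its inputs fully before writing anything, then writes its
#' outputs plus the resolved configuration (`config.json`) into
#' `config$outdir`.
#'
#' \describe{
#'   \item{`cmd_curve`}{stimulus-response curve of one parameter set:
#'     `curve.csv` (dose grid, all cycles) and `response.json` (endpoint
#'     deltas, effect sizes, verdicts).}
#'   \item{`cmd_explore`}{LHS exploration of a space: `summary.json` and
#'     per-set `sets.csv`.}
#'   \item{`cmd_perturb`}{full decade sub-range perturbation analysis:
#'     `perturbation.csv` (one row per run, baseline first) and
#'     `perturbation.json`.}
#'   \item{`cmd_amplify`}{extended-network exploration with amplification
#'     categories: `amplification.json`.}
#' }
#'
#' @param config a [run_config()].
#' @return paths of the written files, invisibly.
#' @export
cmd_curve <- function(config) {
  p <- resolve_set(config)
  spec <- config$spec
  curve <- stimulus_response_curve(p, spec, config$det)
  resp <- compute_response(p, spec, config$det)
  summary <- list(
    parameters = as.list(as_param_vector(p)),
    responses = lapply(seq_len(nrow(resp)), function(i)
      list(cycle = resp$cycle[i], dy = resp$dy[i], dystar = resp$dystar[i],
           effect_size = resp$effect_size[i], detected = resp$detected[i])))
  write_outputs(config, list(curve.csv = curve, response.json = summary))
}

#' @rdname cmd_curve
#' @export
cmd_explore <- function(config) {
  space <- resolve_space(config)
  sm <- explore(space, det = config$det, n_sets = config$n_sets,
                seed = config$seed)
  summary <- list(n_sets = sm$n_sets, seed = sm$seed, motif = sm$motif,
                  n = sm$n, detected = as.list(sm$detected),
                  percent = as.list(sm$percent),
                  histogram = as.list(sm$histogram),
                  n_excluded = sm$n_excluded,
                  scaled_down = sm$n_sets < 5000L)
  write_outputs(config, list(summary.json = summary, sets.csv = sm$results))
}

#' @rdname cmd_curve
#' @export
cmd_perturb <- function(config) {
  space <- resolve_space(config)
  plan <- make_plan(space, n_sets = config$n_sets)
  report <- run_perturbation(plan, det = config$det, seed = config$seed)
  js <- list(baseline = as.list(attr(report, "baseline")),
             n_sets = config$n_sets, seed = config$seed,
             scaled_down = config$n_sets < 5000L,
             runs = nrow(report))
  write_outputs(config, list(perturbation.csv = as.data.frame(report),
                             perturbation.json = js))
}

#' @rdname cmd_curve
#' @export
cmd_amplify <- function(config) {
  if (config$motif != "extended")
    stop("amplification analysis requires the extended motif")
  space <- resolve_space(config)
  sm <- explore(space, det = config$det, n_sets = config$n_sets,
                seed = config$seed)
  df <- sm$results
  amp <- df$detected4 & df$effect_size4 > df$effect_size2
  noamp <- df$detected4 & !amp
  summary <- list(
    n_sets = sm$n_sets, seed = sm$seed,
    percent_cycle2 = unname(sm$percent["cycle2"]),
    percent_cycle4 = unname(sm$percent["cycle4"]),
    percent_with_amplification = 100 * sum(amp) / sm$n_sets,
    percent_without_amplification = 100 * sum(noamp) / sm$n_sets,
    n_excluded = sm$n_excluded,
    scaled_down = sm$n_sets < 5000L)
  write_outputs(config, list(amplification.json = summary))
}
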