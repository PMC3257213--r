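#' Partition a parameter range into decade sub-ranges
#'
#' The perturbation method restricts one parameter at a time to a decade:
#' a default range of `[0.01, 100]` yields the four sub-ranges
#' `[0.01, 0.1), [0.1, 1), [1, 10), [10, 100]` and `[0.1, 10]` yields two.
#' Bounds must be powers of ten; sub-ranges are half-open except the last.
#'
#' @param r a `parameter_range` (or `c(min, max)` pair).
#' @return list of `parameter_range` objects, one per decade.
#' @export
partition_subranges <- function(r) {
  if (!inherits(r, "parameter_range"))
    r <- parameter_range("parameter", r[1], r[2])
  lo <- log10(r$min)
  hi <- log10(r$max)
  if (abs(lo - round(lo)) > 1e-9 || abs(hi - round(hi)) > 1e-9)
    stop("decade partitioning requires power-of-ten bounds, got [",
         r$min, ", ", r$max, "]")
  lo <- round(lo); hi <- round(hi)
  if (lo == hi) return(list(r))
  lapply(lo:(hi - 1), function(e)
    parameter_range(r$name, 10^e, 10^(e + 1), r$scale))
}

#' Build a perturbation plan
#'
#' Enumerates one exploration run per (sampled parameter, decade sub-range)
#' plus a single baseline run of the unrestricted space.  For the default
#' three-cycle space this is `13 * 4 + 3 * 2 + 1 = 59` runs; for the
#' extended default space `17 * 4 + 4 * 2 + 1 = 77`.
#'
#' @param space the baseline `parameter_space`.
#' @param n_sets parameter sets per run (default 5000).
#' @return a `perturbation_plan`: data frame with columns `run`,
#'   `parameter` (`"baseline"` for the baseline run), `min`, `max`, and
#'   attribute `space`.
#' @export
make_plan <- function(space, n_sets = 5000L) {
  stopifnot(inherits(space, "parameter_space"))
  rows <- list(data.frame(parameter = "baseline", min = NA_real_,
                          max = NA_real_))
  for (nm in names(space$ranges)) {
    for (sub in partition_subranges(space$ranges[[nm]]))
      rows[[length(rows) + 1L]] <- data.frame(parameter = nm,
                                              min = sub$min, max = sub$max)
  }
  plan <- do.call(rbind, rows)
  plan <- cbind(run = seq_len(nrow(plan)), plan)
  attr(plan, "space") <- space
  attr(plan, "n_sets") <- as.integer(n_sets)
  class(plan) <- c("perturbation_plan", class(plan))
  plan
}

#' Run a perturbation analysis
#'
#' Executes every run of a plan as an independent seeded exploration in
#' which exactly one parameter's sampling range is replaced by its decade
#' sub-range (all other parameters keep the baseline ranges), and compares
#' each run's off-target percentage to the baseline run.  Per-run seeds are
#' drawn reproducibly from `seed`.
#'
#' @param plan a `perturbation_plan` from [make_plan()].
#' @param det a [detection_config()].
#' @param seed integer seed for the whole analysis.
#' @param cfg a [solver_config()].
#' @return a `perturbation_report`: data frame with one row per run
#'   (columns `run`, `parameter`, `min`, `max`, `seed`, one
#'   `percent_cycle<k>` and `delta_cycle<k>` column per monitored cycle,
#'   `n_excluded`), with the baseline percentages as attribute `baseline`.
#' @export
run_perturbation <- function(plan, det = detection_config(), seed,
                             cfg = solver_config()) {
  stopifnot(inherits(plan, "perturbation_plan"))
  space <- attr(plan, "space")
  n_sets <- attr(plan, "n_sets")
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max, nrow(plan))
  cyc <- space$spec$monitored_cycles
  out <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    sp <- space
    if (plan$parameter[r] != "baseline")
      sp <- restrict_range(sp, plan$parameter[r], plan$min[r], plan$max[r])
    sm <- explore(sp, det = det, n_sets = n_sets, seed = run_seeds[r],
                  cfg = cfg)
    row <- data.frame(run = plan$run[r], parameter = plan$parameter[r],
                      min = plan$min[r], max = plan$max[r],
                      seed = run_seeds[r], n_excluded = sm$n_excluded)
    for (k in seq_along(cyc))
      row[[paste0("percent_cycle", cyc[k])]] <- sm$percent[k]
    out[[r]] <- row
  }
  report <- do.call(rbind, out)
  base <- report[report$parameter == "baseline", ]
  for (k in cyc)
    report[[paste0("delta_cycle", k)]] <-
      report[[paste0("percent_cycle", k)]] - base[[paste0("percent_cycle", k)]]
  attr(report, "baseline") <-
    unlist(base[paste0("percent_cycle", cyc)])
  attr(report, "space") <- space
  class(report) <- c("perturbation_report", class(report))
  report
}

#' Restrict a parameter space from perturbation results
#'
#' Applies a restriction rule set (parameter name to decade sub-range) to
#' the baseline space of a perturbation report, producing a space in which
#' every range is either a sub-range chosen by the rules or the untouched
#' baseline range.  An empty rule set returns the baseline space unchanged.
#' The shipped rule set [restriction_rules_default()] reconstructs a region
#' in which off-target effects are far more probable than in the default
#' space.
#'
#' @param report a `perturbation_report` (or a bare `parameter_space` to
#'   restrict directly).
#' @param rules named list of `c(min, max)` sub-ranges.
#' @return a `parameter_space`.
#' @export
build_restricted_space <- function(report, rules = list()) {
  space <- if (inherits(report, "parameter_space")) report
           else attr(report, "space")
  if (is.null(space))
    stop("report carries no baseline space")
  apply_restrictions(space, rules)
}
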