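#' Detection configuration
#'
#' The off-target protocol compares steady states at a near-zero and a
#' saturating normalized drug level and calls an off-target effect in a
#' monitored cycle when either free species there moves by at least the
#' detection threshold (as a fraction of that cycle's total protein).
#'
#' @param threshold detection threshold on the absolute steady-state change
#'   (default 0.10); an effect size exactly equal to the threshold counts
#'   as detected.
#' @param I_low,I_high endpoint doses (defaults 1e-4 and 1e4).  `I = 1e-4`
#'   operationally represents the absence of drug.
#' @param n_grid number of log-spaced dose points for stimulus-response
#'   curves (default 61 over `[I_low, I_high]`).
#' @return a `detection_config` list.
#' @export
detection_config <- function(threshold = 0.10, I_low = 1e-4, I_high = 1e4,
                             n_grid = 61L) {
  stopifnot(threshold > 0, threshold < 1, I_low < I_high, I_low > 0,
            n_grid >= 2)
  structure(list(threshold = threshold, I_low = I_low, I_high = I_high,
                 n_grid = as.integer(n_grid)),
            class = "detection_config")
}

#' Two-endpoint off-target response of the monitored cycles
#'
#' Solves the steady state at `I_low` and `I_high` (exactly two solves) and
#' reports, for every monitored cycle `c`, the signed changes
#' `dy_c = y_c(I_high) - y_c(I_low)` and `dystar_c` likewise, the effect
#' size `max(|dy_c|, |dystar_c|)`, and the detection verdict.
#'
#' @param p a `dimensionless_params`.
#' @param spec a `network_spec`.
#' @param det a [detection_config()].
#' @param cfg a [solver_config()].
#' @return a `response_record`: data frame with one row per monitored cycle
#'   (columns `cycle`, `dy`, `dystar`, `effect_size`, `detected`), plus
#'   attributes `steady_low` / `steady_high` holding the two steady states
#'   and `valid` (FALSE when a solve failed verification).
#' @examples
#' spec <- build_network("vertical", 3)
#' compute_response(get_parameter_set("random_set"), spec)
#' @export
compute_response <- function(p, spec, det = detection_config(),
                             cfg = solver_config()) {
  lo <- try(solve_steady_state_algebraic(p, spec, det$I_low, cfg), silent = TRUE)
  hi <- try(solve_steady_state_algebraic(p, spec, det$I_high, cfg), silent = TRUE)
  cyc <- spec$monitored_cycles
  if (inherits(lo, "try-error") || inherits(hi, "try-error")) {
    rec <- data.frame(cycle = cyc, dy = NA_real_, dystar = NA_real_,
                      effect_size = NA_real_, detected = FALSE)
    attr(rec, "valid") <- FALSE
    class(rec) <- c("response_record", class(rec))
    return(rec)
  }
  dy <- hi$y[cyc] - lo$y[cyc]
  dystar <- hi$ystar[cyc] - lo$ystar[cyc]
  es <- pmax(abs(dy), abs(dystar))
  rec <- data.frame(cycle = cyc, dy = dy, dystar = dystar,
                    effect_size = es, detected = es >= det$threshold)
  attr(rec, "valid") <- TRUE
  attr(rec, "steady_low") <- lo
  attr(rec, "steady_high") <- hi
  class(rec) <- c("response_record", class(rec))
  rec
}

#' Stimulus-response curve over a dose grid
#'
#' Steady states of every cycle over a log-spaced grid of normalized drug
#' levels.  The grid endpoints are `I_low` and `I_high`, so the endpoint
#' differences reproduce [compute_response()] exactly.
#'
#' @inheritParams compute_response
#' @return a data frame with columns `I`, `y1..yn`, `ystar1..ystarn`, and
#'   `converged` (FALSE for dose points where the solve failed; such points
#'   carry `NA` concentrations but the curve is still returned).
#' @export
stimulus_response_curve <- function(p, spec, det = detection_config(),
                                    cfg = solver_config()) {
  grid <- 10^seq(log10(det$I_low), log10(det$I_high), length.out = det$n_grid)
  n <- spec$n
  out <- matrix(NA_real_, det$n_grid, 2 * n)
  ok <- logical(det$n_grid)
  for (j in seq_along(grid)) {
    ss <- try(solve_steady_state_algebraic(p, spec, grid[j], cfg),
              silent = TRUE)
    if (!inherits(ss, "try-error")) {
      out[j, ] <- c(ss$y, ss$ystar)
      ok[j] <- TRUE
    }
  }
  df <- data.frame(I = grid, out, converged = ok)
  names(df) <- c("I", paste0("y", seq_len(n)), paste0("ystar", seq_len(n)),
                 "converged")
  df
}

#' Assess downstream amplification in the extended network
#'
#' In the extended motif a fourth cycle is activated by `y2*`, and the
#' question is whether an off-target response in cycle 2 grows or shrinks
#' as it propagates to cycle 4.  Categories:
#' \describe{
#'   \item{`no_effect`}{cycle 4 not detected (regardless of cycle 2).}
#'   \item{`effect_with_amplification`}{cycle 4 detected and its effect
#'     size strictly exceeds cycle 2's.}
#'   \item{`effect_without_amplification`}{cycle 4 detected with an effect
#'     equal to or attenuated relative to cycle 2.}
#' }
#'
#' @param resp a `response_record` from [compute_response()] on an extended
#'   network (cycles 2 and 4 monitored).
#' @param det the [detection_config()] used (for the threshold).
#' @return an `amplification_record` list with the two effect sizes and the
#'   category.
#' @export
assess_amplification <- function(resp, det = detection_config()) {
  if (!all(c(2L, 4L) %in% resp$cycle))
    stop("amplification requires monitored cycles 2 and 4 ",
         "(extended network)")
  s2 <- resp$effect_size[resp$cycle == 2L]
  s4 <- resp$effect_size[resp$cycle == 4L]
  category <- if (is.na(s4) || s4 < det$threshold) {
    "no_effect"
  } else if (s4 > s2) {
    "effect_with_amplification"
  } else {
    "effect_without_amplification"
  }
  structure(list(size_cycle2 = s2, size_cycle4 = s4, category = category),
            class = "amplification_record")
}
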