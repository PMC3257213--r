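#' Solver configuration
#'
#' Numerical settings shared by the integration and root-finding paths.
#'
#' @param t_max maximum integration horizon in arbitrary time units
#'   (default 100000).
#' @param conv_tol convergence criterion on the maximum normalized rate of
#'   change, `max |d(state)/dt| / pool total` (default 1e-9).
#' @param rtol,atol relative and absolute integrator tolerances
#'   (defaults 1e-10 and 1e-12; the absolute tolerance is further scaled by
#'   the smallest conservation pool).  Tolerances this tight are needed
#'   because residual terms like `y/K` amplify integration error by up to
#'   `1/K` when a Michaelis constant sits at the bottom of its range.
#' @param residual_tol acceptance threshold on the maximum absolute
#'   dimensionless steady-state residual (default 1e-6).
#' @return a `solver_config` list.
#' @export
solver_config <- function(t_max = 1e5, conv_tol = 1e-9, rtol = 1e-10,
                          atol = 1e-12, residual_tol = 1e-6) {
  stopifnot(t_max > 0, conv_tol > 0, rtol > 0, atol > 0, residual_tol > 0)
  structure(list(t_max = t_max, conv_tol = conv_tol, rtol = rtol,
                 atol = atol, residual_tol = residual_tol),
            class = "solver_config")
}

#' Normalized drug dose
#'
#' The inhibitor enters the model only through its normalized total
#' `I = DT / YT_n`.  `I = 1e-4` is the operational "no drug" level: the
#' steady state there is indistinguishable (to well below the detection
#' threshold) from `I = 0`.
#'
#' @param I positive normalized total drug concentration.
#' @return a `drug_dose` scalar.
#' @export
drug_dose <- function(I) {
  if (!is.numeric(I) || length(I) != 1L || is.na(I) || I < 0)
    stop("I must be a non-negative scalar")
  structure(I, class = "drug_dose")
}

#' Exact dimensionless steady-state residual system
#'
#' Eliminating every complex through its own steady-state condition reduces
#' the network's steady state to `2 n` algebraic equations in the normalized
#' free concentrations `(y_i, y_i*)`: one kinase/phosphatase rate balance
#' and one substrate-pool conservation equation per cycle.  For the
#' three-cycle network these are, writing `R'_i = y_i*/(y_i* + Kp_i)`:
#'
#' \deqn{P_1 y_1/(y_1+K_1) - R'_1 = 0}
#' \deqn{-1 + y_1 + y_1^*(1 + y_2/K_2 + y_3/K_3) + E_1 y_1/(y_1+K_1) + E'_1 R'_1 = 0}
#' \deqn{P_i y_i y_1^*/K_i - R'_i = 0, \quad i = 2, 3}
#' \deqn{-1 + y_i (1 + E_i y_1^*/K_i) + y_i^* + E'_i R'_i \,[+\, I y_3^*/(y_3^*+K_B)] = 0}
#'
#' with the drug term present only in the inhibited cycle's pool equation.
#' The generalization to any supported motif replaces `y_1*` by the
#' activating cycle's free active species and adds a term
#' `y_i* \sum_m y_m / K_m` over the cycles `m` activated by cycle `i`
#' (sequestration of `y_i*` as a kinase).  These are exact steady-state
#' conditions, not quasi-steady-state approximations.
#'
#' @param p a `dimensionless_params`.
#' @param spec the matching `network_spec`.
#' @param dose a [drug_dose()] (or bare numeric `I`).
#' @return a function `f(y, ystar)` returning the `2 n` residuals
#'   (rate balances first, then pool conservations, cycle by cycle).
#' @export
build_steady_state_system <- function(p, spec, dose) {
  stopifnot(inherits(p, "dimensionless_params"), inherits(spec, "network_spec"))
  if (length(p$E) != spec$n)
    stop("parameter set has ", length(p$E), " cycles but network has ", spec$n)
  I <- as.numeric(dose)
  n <- spec$n
  kin <- spec$kinase_of
  inhib <- spec$inhibited_cycle
  function(y, ystar) {
    stopifnot(length(y) == n, length(ystar) == n)
    Rp <- ystar / (ystar + p$Kp)
    load <- numeric(n)
    for (i in seq_len(n)[-1]) load[kin[i]] <- load[kin[i]] + y[i] / p$K[i]
    rate <- numeric(n)
    pool <- numeric(n)
    for (i in seq_len(n)) {
      if (i == 1L) {
        sat <- y[1] / (y[1] + p$K[1])
        rate[i] <- p$P[1] * sat - Rp[1]
        bound <- p$E[1] * sat
      } else {
        act <- ystar[kin[i]]
        rate[i] <- p$P[i] * y[i] * act / p$K[i] - Rp[i]
        bound <- p$E[i] * y[i] * act / p$K[i]
      }
      drug <- if (i == inhib) I * ystar[i] / (ystar[i] + p$KB) else 0
      pool[i] <- -1 + y[i] + bound + ystar[i] * (1 + load[i]) +
        p$Ep[i] * Rp[i] + drug
    }
    c(rbind(rate, pool))
  }
}

# Normalized complex occupancies implied by a free-species steady state:
# each complex divided by the substrate total of the cycle it belongs to.
complex_occupancies <- function(y, ystar, p, spec, I) {
  n <- spec$n
  kin <- spec$kinase_of
  ck <- numeric(n)
  ck[1] <- p$E[1] * y[1] / (y[1] + p$K[1])
  for (i in seq_len(n)[-1]) ck[i] <- p$E[i] * y[i] * ystar[kin[i]] / p$K[i]
  cp <- p$Ep * ystar / (ystar + p$Kp)
  cD <- I * ystar[spec$inhibited_cycle] /
    (ystar[spec$inhibited_cycle] + p$KB)
  list(kinase = ck, phosphatase = cp, drug = cD)
}

new_steady_state <- function(y, ystar, p, spec, I, residual, method,
                             t_converged = NA_real_) {
  structure(list(y = y, ystar = ystar,
                 complexes = complex_occupancies(y, ystar, p, spec, I),
                 I = I, residual = residual, method = method,
                 t_converged = t_converged),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  n <- length(x$y)
  cat(sprintf("<steady_state> I = %g, method = %s, residual = %.2e\n",
              x$I, x$method, x$residual))
  m <- rbind(y = x$y, ystar = x$ystar)
  colnames(m) <- paste0("cycle", seq_len(n))
  print(signif(m, 5))
  invisible(x)
}

#' Solve the steady state algebraically
#'
#' Direct solution of the exact dimensionless steady-state system using the
#' network's chain structure: each cascade hanging off cycle 1 is solved by
#' a shooting sweep bracketed on the bottom cycle's activity, and cycle 1's
#' own conservation equation is bracketed on `y1*`.  Every scalar solve is
#' a bisection on `[0, 1]`, so the method cannot diverge; the result is
#' verified against the full residual system and, if verification fails,
#' the solver falls back to stiff time integration.
#'
#' @param p a `dimensionless_params`.
#' @param spec the matching `network_spec`.
#' @param dose a [drug_dose()] or bare numeric `I`.
#' @param cfg a [solver_config()].
#' @param fallback if `TRUE` (default), fall back to
#'   [integrate_to_steady_state()] when the algebraic residual exceeds
#'   `cfg$residual_tol`.
#' @return a `steady_state` object (all `y`, `ystar` and complex
#'   occupancies in `[0, 1]`).
#' @seealso [integrate_to_steady_state()] for the integrate-then-verify
#'   path used as an independent check.
#' @examples
#' spec <- build_network("vertical", 3)
#' p <- get_parameter_set("random_set")
#' solve_steady_state_algebraic(p, spec, drug_dose(1e-4))
#' @export
solve_steady_state_algebraic <- function(p, spec, dose,
                                         cfg = solver_config(),
                                         fallback = TRUE) {
  stopifnot(inherits(p, "dimensionless_params"), inherits(spec, "network_spec"))
  I <- as.numeric(dose)
  sol <- ss_solve_cpp(p$E, p$Ep, p$K, p$Kp, p$P, p$KB, I,
                      spec$chains, spec$inhibited_cycle)
  if (sol$residual <= cfg$residual_tol)
    return(new_steady_state(sol$y, sol$ystar, p, spec, I,
                            sol$residual, "root"))
  if (fallback)
    return(integrate_to_steady_state(p, spec, dose, cfg))
  stop("steady-state root finding failed: residual ", signif(sol$residual, 3),
       " exceeds tolerance ", cfg$residual_tol)
}
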