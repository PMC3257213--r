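#' Create a dimensionless parameter set
#'
#' The steady state of a network depends only on five dimensionless
#' parameters per cycle plus one drug-binding constant:
#' \describe{
#'   \item{`E[i]`}{total kinase to total substrate ratio, `EkT_i / YT_i`.}
#'   \item{`Ep[i]`}{total phosphatase to total substrate ratio, `EpT_i / YT_i`.}
#'   \item{`K[i]`}{Michaelis constant of the kinase reaction normalized by
#'     the substrate total, `Km_k,i / YT_i`.}
#'   \item{`Kp[i]`}{normalized Michaelis constant of the phosphatase
#'     reaction, `Km_p,i / YT_i`.}
#'   \item{`P[i]`}{ratio of the kinase to the phosphatase reaction Vmax.}
#'   \item{`KB`}{drug dissociation constant normalized by the targeted
#'     cycle's substrate total, `koff / (kon * YT_n)`.}
#' }
#' All values must be strictly positive; there is no upper bound (literature
#' derived sets may fall outside the default sampling ranges and are still
#' valid).
#'
#' @param E,Ep,K,Kp,P numeric vectors, one value per cycle.
#' @param KB positive scalar.
#' @return An object of class `dimensionless_params`.
#' @examples
#' dimensionless_params(E = c(1, 1, 1), Ep = c(1, 1, 1), K = c(1, 1, 1),
#'                      Kp = c(1, 1, 1), P = c(1, 1, 1), KB = 1)
#' @export
dimensionless_params <- function(E, Ep, K, Kp, P, KB) {
  n <- length(E)
  for (nm in c("E", "Ep", "K", "Kp", "P")) {
    v <- get(nm)
    if (length(v) != n)
      stop("parameter vector '", nm, "' must have one value per cycle (", n, ")")
    if (!is.numeric(v) || anyNA(v) || any(v <= 0))
      stop("parameter '", nm, "' must be strictly positive and finite")
  }
  if (!is.numeric(KB) || length(KB) != 1L || is.na(KB) || KB <= 0)
    stop("parameter 'KB' must be a strictly positive scalar")
  structure(list(E = as.numeric(E), Ep = as.numeric(Ep), K = as.numeric(K),
                 Kp = as.numeric(Kp), P = as.numeric(P), KB = as.numeric(KB)),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  n <- length(x$E)
  cat(sprintf("<dimensionless_params> %d cycles (%d parameters)\n", n, 5 * n + 1))
  m <- rbind(E = x$E, Ep = x$Ep, K = x$K, Kp = x$Kp, P = x$P)
  colnames(m) <- paste0("cycle", seq_len(n))
  print(signif(m, 4))
  cat("KB =", signif(x$KB, 4), "\n")
  invisible(x)
}

#' Convert a dimensionless parameter set to a flat named vector
#'
#' @param p a `dimensionless_params`.
#' @return named numeric vector in the order `E1..En, Ep1..Epn, K1..Kn,
#'   Kp1..Kpn, P1..Pn, KB`.
#' @export
as_param_vector <- function(p) {
  n <- length(p$E)
  v <- c(p$E, p$Ep, p$K, p$Kp, p$P, p$KB)
  i <- seq_len(n)
  names(v) <- c(paste0("E", i), paste0("Ep", i), paste0("K", i),
                paste0("Kp", i), paste0("P", i), "KB")
  v
}

#' Rebuild a dimensionless parameter set from a flat named vector
#'
#' @param v named numeric vector as produced by [as_param_vector()].
#' @return a `dimensionless_params`.
#' @export
from_param_vector <- function(v) {
  n <- (length(v) - 1L) %/% 5L
  i <- seq_len(n)
  dimensionless_params(E = unname(v[paste0("E", i)]),
                       Ep = unname(v[paste0("Ep", i)]),
                       K = unname(v[paste0("K", i)]),
                       Kp = unname(v[paste0("Kp", i)]),
                       P = unname(v[paste0("P", i)]),
                       KB = unname(v[["KB"]]))
}

#' Modify single entries of a dimensionless parameter set
#'
#' Convenience for single-parameter what-if studies, e.g.
#' `set_param(p, "K3", 0.004)`.
#'
#' @param p a `dimensionless_params`.
#' @param name flat parameter name (e.g. `"E2"`, `"Kp1"`, `"KB"`).
#' @param value positive replacement value.
#' @return the modified `dimensionless_params`.
#' @export
set_param <- function(p, name, value) {
  v <- as_param_vector(p)
  if (!name %in% names(v))
    stop("unknown parameter '", name, "'; available: ",
         paste(names(v), collapse = ", "))
  v[name] <- value
  from_param_vector(v)
}

#' Map dimensionless parameters to a dimensional realization
#'
#' The dimensionless steady state fixes concentrations and rates only up to
#' a choice of concentration and time scale, so infinitely many dimensional
#' parameterizations are consistent with one dimensionless set.  This
#' canonical mapping picks one:
#' \itemize{
#'   \item `YT[1] = y1_total` (default 1) sets the concentration scale; the
#'     remaining substrate totals follow from `E[i] = EkT_i / YT_i` and the
#'     kinase assignment (`EkT_i` is the total of the activating cycle's
#'     protein, or the dedicated kinase total for cycle 1);
#'   \item `kp_rate` (the phosphatase catalytic rate, default 1) sets the
#'     timescale; kinase catalytic rates follow from `P`;
#'   \item dissociation rates are tied to catalytic rates (`d = k`), which
#'     is unconstrained by the Michaelis constants `(d + k)/a`;
#'   \item `kon = 1`, `koff = KB * kon * YT_n`.
#' }
#' Steady states are invariant to these choices (see the methods vignette);
#' the mapping matters only for the arbitrary time units of trajectories.
#'
#' @param p a `dimensionless_params`.
#' @param spec the matching `network_spec`.
#' @param y1_total total concentration of cycle 1's protein (default 1).
#' @param kp_rate phosphatase catalytic rate constant (default 1).
#' @return An object of class `dimensional_params` with per-cycle rate
#'   constants `a, d, k` (kinase reaction), `ap, dp, kp` (phosphatase
#'   reaction), totals `YT`, `EpT`, `Ek1T`, and drug kinetics `kon`, `koff`.
#' @export
map_to_dimensional <- function(p, spec, y1_total = 1, kp_rate = 1) {
  stopifnot(inherits(p, "dimensionless_params"), inherits(spec, "network_spec"))
  if (length(p$E) != spec$n)
    stop("parameter set has ", length(p$E), " cycles but network has ", spec$n)
  if (y1_total <= 0 || kp_rate <= 0)
    stop("y1_total and kp_rate must be positive")
  n <- spec$n
  YT <- numeric(n)
  YT[1] <- y1_total
  # substrate totals follow the kinase assignment in activation order
  for (i in seq_len(n)[-1]) {
    EkT_i <- YT[spec$kinase_of[i]]
    YT[i] <- EkT_i / p$E[i]
  }
  EkT <- c(p$E[1] * YT[1], YT[spec$kinase_of[-1]])
  EpT <- p$Ep * YT
  kp <- rep(kp_rate, n)
  k <- p$P * kp * EpT / EkT
  d <- k
  dp <- kp
  a <- (d + k) / (p$K * YT)
  ap <- (dp + kp) / (p$Kp * YT)
  structure(list(a = a, d = d, k = k, ap = ap, dp = dp, kp = kp,
                 YT = YT, EpT = EpT, Ek1T = EkT[1],
                 kon = 1, koff = p$KB * 1 * YT[spec$inhibited_cycle]),
            class = "dimensional_params")
}

#' Recover the dimensionless parameters of a dimensional realization
#'
#' Inverse of [map_to_dimensional()]; used to verify that mappings round
#' trip exactly.
#'
#' @param dp a `dimensional_params`.
#' @param spec the matching `network_spec`.
#' @return a `dimensionless_params`.
#' @export
dimensionless_from_dimensional <- function(dp, spec) {
  n <- spec$n
  EkT <- c(dp$Ek1T, dp$YT[spec$kinase_of[-1]])
  Km_k <- (dp$d + dp$k) / dp$a
  Km_p <- (dp$dp + dp$kp) / dp$ap
  dimensionless_params(
    E = EkT / dp$YT,
    Ep = dp$EpT / dp$YT,
    K = Km_k / dp$YT,
    Kp = Km_p / dp$YT,
    P = (dp$k * EkT) / (dp$kp * dp$EpT),
    KB = dp$koff / (dp$kon * dp$YT[spec$inhibited_cycle])
  )
}
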