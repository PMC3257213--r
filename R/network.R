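#' Build a network topology
#'
#' Constructs the wiring of a signaling network made of `n` covalent
#' modification cycles.  Cycle 1 is activated by a dedicated kinase; its
#' active species `y1*` is the shared activator of cycles 2 and 3, which
#' always lie in distinct cascades.  The competitive inhibitor targets the
#' active species of one cycle (`yn*`, or `y3*` for the extended motif).
#'
#' Three motifs are supported:
#' \describe{
#'   \item{`vertical`}{the inhibited cascade is a chain: cycle `i > 3` is
#'     activated by cycle `i - 1`'s active species, and the drug targets
#'     cycle `n` at the bottom of the chain.}
#'   \item{`lateral`}{a fan-out: cycles `2..n` are all single cycles
#'     activated by `y1*`, and the drug targets cycle `n`.}
#'   \item{`extended`}{the three-cycle network plus a fourth cycle activated
#'     by `y2*`, used to test downstream amplification; the drug stays on
#'     cycle 3 and both cycles 2 and 4 are monitored.}
#' }
#' With `n = 3` the vertical and lateral motifs coincide.
#'
#' @param motif one of `"vertical"`, `"lateral"`, `"extended"`.
#' @param n cycle count (at least 3; the extended motif requires `n = 3` and
#'   yields a fixed four-cycle network).
#' @return An object of class `network_spec` with fields `motif`, `n`
#'   (number of cycles actually present), `kinase_of` (integer vector;
#'   0 denotes the dedicated kinase of cycle 1), `inhibited_cycle`,
#'   `monitored_cycles`, and `chains` (list of cycle-index chains hanging
#'   off cycle 1, used by the solver).
#' @examples
#' build_network("vertical", 3)
#' build_network("lateral", 5)
#' build_network("extended", 3)
#' @export
build_network <- function(motif = c("vertical", "lateral", "extended"), n = 3L) {
  motif <- match.arg(motif)
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop("invalid topology: need at least 3 cycles, got ", n)
  if (motif == "extended") {
    if (n != 3L)
      stop("invalid topology: the extended motif is the fixed 4-cycle ",
           "variant of the n = 3 network; use n = 3")
    n_cycles <- 4L
    kinase_of <- c(0L, 1L, 1L, 2L)
    inhibited <- 3L
    monitored <- c(2L, 4L)
  } else {
    n_cycles <- n
    kinase_of <- integer(n)
    kinase_of[1] <- 0L
    if (n >= 2) kinase_of[2] <- 1L
    if (n >= 3) kinase_of[3] <- 1L
    if (n > 3) {
      kinase_of[4:n] <- if (motif == "vertical") 3:(n - 1L) else 1L
    }
    inhibited <- n
    monitored <- 2L
  }
  structure(
    list(motif = motif, n = n_cycles, kinase_of = kinase_of,
         inhibited_cycle = inhibited, monitored_cycles = monitored,
         chains = derive_chains(kinase_of)),
    class = "network_spec"
  )
}

# Decompose the cycles activated (directly or transitively) by cycle 1 into
# simple chains: each chain starts at a child of cycle 1 and follows unique
# children downward.  All supported motifs decompose this way.
derive_chains <- function(kinase_of) {
  n <- length(kinase_of)
  children <- lapply(seq_len(n), function(i) which(kinase_of == i))
  if (any(lengths(children[-1]) > 1))
    stop("invalid topology: a cycle other than cycle 1 activates ",
         "more than one cycle")
  chains <- list()
  for (top in children[[1]]) {
    chain <- top
    repeat {
      kids <- children[[chain[length(chain)]]]
      if (length(kids) == 0) break
      chain <- c(chain, kids)
    }
    chains[[length(chains) + 1L]] <- as.integer(chain)
  }
  if (length(unique(c(1L, unlist(chains)))) != n)
    stop("invalid topology: unreachable cycles")
  chains
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s motif, %d cycles\n", x$motif, x$n))
  act <- ifelse(x$kinase_of == 0, "dedicated kinase",
                sprintf("y%d*", x$kinase_of))
  for (i in seq_len(x$n))
    cat(sprintf("  cycle %d: activated by %s%s\n", i, act[i],
                if (i == x$inhibited_cycle) "  [inhibited]" else ""))
  cat("  monitored cycles:", paste(x$monitored_cycles, collapse = ", "), "\n")
  invisible(x)
}

#' Number of dimensionless parameters of a network
#'
#' Five per-cycle parameters plus the shared drug dissociation constant
#' `KB`: `5 n + 1` in total (21 for the extended motif's four cycles).
#'
#' @param spec a `network_spec`.
#' @return integer parameter count.
#' @export
n_parameters <- function(spec) 5L * spec$n + 1L

#' Flat parameter names of a network
#'
#' Column order used throughout batch interfaces:
#' `E1..En, Ep1..Epn, K1..Kn, Kp1..Kpn, P1..Pn, KB`.
#'
#' @param spec a `network_spec`.
#' @return character vector of length `5 n + 1`.
#' @export
parameter_names <- function(spec) {
  i <- seq_len(spec$n)
  c(paste0("E", i), paste0("Ep", i), paste0("K", i), paste0("Kp", i),
    paste0("P", i), "KB")
}
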