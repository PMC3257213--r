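# Ready-made parameter sets and parameter spaces.
#
# "random_set" is a randomly drawn three-cycle set whose off-target response
# is large; "xenopus_set" derives from the Huang & Ferrell (1996) Xenopus
# oocyte MAPK cascade model: concentration totals give the E ratios
# (e.g. E2 = 3 nM MAPKKK / 1200 nM MAPKK), shared Michaelis constants of
# ~300 nM give the normalized K values, and equal catalytic constants make
# each Vmax ratio the corresponding enzyme-total ratio (so P2 = 3/0.3 = 10
# and P3 = 3/120 = 0.025).  Several of its enzyme:substrate ratios fall
# outside the default sampling ranges; that is deliberate and the set is
# still valid.

fixture_parameter_sets <- function() {
  list(
    random_set = dimensionless_params(
      E  = c(4.87, 32.56, 0.28),
      Ep = c(0.05, 1.26, 0.29),
      K  = c(5.07, 28.18, 0.04),
      Kp = c(66.34, 9.33, 0.59),
      P  = c(0.21, 3.43, 0.42),
      KB = 0.05),
    xenopus_set = dimensionless_params(
      E  = c(0.1, 0.0025, 0.0025),
      Ep = c(0.1, 0.00025, 0.1),
      K  = c(100, 0.25, 0.25),
      Kp = c(100, 0.25, 0.25),
      P  = c(1, 10, 0.025),
      KB = 0.0833)
  )
}

# Default per-parameter sampling ranges: E, Ep, K, Kp, KB over [0.01, 100],
# P over [0.1, 10].
default_ranges <- function(spec) {
  rng <- list()
  for (i in seq_len(spec$n)) {
    rng[[paste0("E", i)]] <- c(0.01, 100)
    rng[[paste0("Ep", i)]] <- c(0.01, 100)
    rng[[paste0("K", i)]] <- c(0.01, 100)
    rng[[paste0("Kp", i)]] <- c(0.01, 100)
    rng[[paste0("P", i)]] <- c(0.1, 10)
  }
  rng[["KB"]] <- c(0.01, 100)
  rng
}

#' Default parameter space of a motif
#'
#' @param motif,n as in [build_network()].
#' @param tie_cycles_to_3 homogeneous tying rule for `n > 3` (default: on
#'   for `n > 3`, so larger networks keep a 16-dimensional sampled space).
#' @return a `parameter_space` with the default ranges.
#' @export
default_space <- function(motif = "vertical", n = 3L,
                          tie_cycles_to_3 = (motif != "extended" && n > 3)) {
  spec <- build_network(motif, n)
  parameter_space(spec, default_ranges(spec),
                  tie_cycles_to_3 = tie_cycles_to_3)
}

# Decade restrictions of the cycle-1/2/3 ranges that favor an off-target
# response in cycle 2, assembled from the perturbation analysis of the
# default three-cycle space: the targeted cycle 3 saturated (small K3, Kp3,
# sub-unity E3, Ep3) and leaning to deactivation (P3 < 1); cycle 1 leaning
# to activation with an efficient kinase and inefficient phosphatase (small
# K1, large Kp1, P1 > 1); cycle 2's kinase reaction in the linear regime
# (large K2).
#' Restriction rules reconstructing a high off-target-probability space
#'
#' @return named list of `c(min, max)` decade ranges, suitable for
#'   [build_restricted_space()].
#' @export
restriction_rules_default <- function() {
  list(K3 = c(0.01, 0.1), Kp3 = c(0.01, 0.1),
       E3 = c(0.01, 1), Ep3 = c(0.01, 1), P3 = c(0.1, 1),
       K1 = c(0.01, 0.1), Kp1 = c(10, 100), P1 = c(1, 10),
       K2 = c(1, 10))
}

#' Look up a shipped parameter set
#'
#' @param name `"random_set"` or `"xenopus_set"`.
#' @return a `dimensionless_params`.
#' @examples
#' get_parameter_set("random_set")
#' @export
get_parameter_set <- function(name) {
  sets <- fixture_parameter_sets()
  if (!name %in% names(sets))
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  sets[[name]]
}

#' Look up a shipped parameter space
#'
#' Available spaces: `default_n3`, `default_extended_n3`,
#' `default_vertical_n5`, `default_vertical_n7`, `default_lateral_n5`,
#' `default_lateral_n7` (all with the default ranges; the `n > 3` spaces
#' carry the homogeneous tying rule), and `restricted_n3_reconstruction`
#' (the default three-cycle space with [restriction_rules_default()]
#' applied).
#'
#' @param name space name.
#' @return a `parameter_space`.
#' @examples
#' get_space("default_n3")
#' @export
get_space <- function(name) {
  builders <- list(
    default_n3 = function() default_space("vertical", 3),
    default_extended_n3 = function() default_space("extended", 3),
    default_vertical_n5 = function() default_space("vertical", 5),
    default_vertical_n7 = function() default_space("vertical", 7),
    default_lateral_n5 = function() default_space("lateral", 5),
    default_lateral_n7 = function() default_space("lateral", 7),
    restricted_n3_reconstruction = function()
      apply_restrictions(default_space("vertical", 3),
                         restriction_rules_default())
  )
  if (!name %in% names(builders))
    stop("unknown parameter space '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  builders[[name]]()
}

apply_restrictions <- function(space, rules) {
  for (nm in names(rules)) {
    r <- rules[[nm]]
    base <- space$ranges[[nm]]
    if (is.null(base))
      stop("restriction names unknown parameter '", nm, "'")
    if (r[1] < base$min || r[2] > base$max)
      stop("restricted range for '", nm, "' is not inside the baseline range")
    space <- restrict_range(space, nm, r[1], r[2])
  }
  space
}
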