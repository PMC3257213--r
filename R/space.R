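#' Parameter sampling range
#'
#' @param name flat parameter name (e.g. `"K3"`).
#' @param min,max positive bounds, `min <= max`.
#' @param scale sampling scale: `"log"` (default, log10-uniform) or
#'   `"linear"`.
#' @return a `parameter_range` list.
#' @export
parameter_range <- function(name, min, max, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!is.numeric(min) || !is.numeric(max) || min <= 0 || min > max)
    stop("range for '", name, "' needs 0 < min <= max")
  structure(list(name = name, min = min, max = max, scale = scale),
            class = "parameter_range")
}

#' Parameter space of a network
#'
#' A sampling range for every dimensionless parameter of a network, plus an
#' optional homogeneous-tying rule under which cycles 4 and above copy the
#' values sampled for cycle 3 (used for the larger vertical and lateral
#' networks so the effective sampling dimension stays at 16).
#'
#' @param spec a `network_spec`.
#' @param ranges named list of `c(min, max)` pairs (or
#'   [parameter_range()] objects) covering every parameter in
#'   [parameter_names()]; tied parameters may be omitted.
#' @param tie_cycles_to_3 if `TRUE`, cycles `>= 4` copy cycle 3's sampled
#'   values (only meaningful for vertical/lateral networks with `n > 3`).
#' @param scale default sampling scale for plain `c(min, max)` ranges.
#' @return a `parameter_space` object.
#' @export
parameter_space <- function(spec, ranges, tie_cycles_to_3 = FALSE,
                            scale = "log") {
  stopifnot(inherits(spec, "network_spec"))
  if (tie_cycles_to_3 && (spec$motif == "extended" || spec$n <= 3))
    stop("the homogeneous tying rule applies only to vertical/lateral ",
         "networks with more than 3 cycles")
  all_names <- parameter_names(spec)
  free <- free_parameter_names(spec, tie_cycles_to_3)
  rng <- list()
  for (nm in names(ranges)) {
    if (!nm %in% all_names)
      stop("unknown parameter '", nm, "' in ranges; expected among: ",
           paste(all_names, collapse = ", "))
    r <- ranges[[nm]]
    if (!inherits(r, "parameter_range"))
      r <- parameter_range(nm, r[1], r[2], scale)
    rng[[nm]] <- r
  }
  missing <- setdiff(free, names(rng))
  if (length(missing) > 0)
    stop("no range given for parameter(s): ", paste(missing, collapse = ", "))
  structure(list(spec = spec, ranges = rng[free],
                 tie_cycles_to_3 = tie_cycles_to_3),
            class = "parameter_space")
}

free_parameter_names <- function(spec, tie_cycles_to_3) {
  nms <- parameter_names(spec)
  if (!tie_cycles_to_3) return(nms)
  tied <- as.vector(outer(c("E", "Ep", "K", "Kp", "P"), 4:spec$n, paste0))
  setdiff(nms, tied)
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("<parameter_space> %s motif, %d cycles, %d sampled parameters%s\n",
              x$spec$motif, x$spec$n, length(x$ranges),
              if (x$tie_cycles_to_3) " (cycles >= 4 tied to cycle 3)" else ""))
  df <- do.call(rbind, lapply(x$ranges, function(r)
    data.frame(parameter = r$name, min = r$min, max = r$max, scale = r$scale)))
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' Replace one parameter's sampling range
#'
#' @param space a `parameter_space`.
#' @param name parameter to restrict.
#' @param min,max new bounds.
#' @return the modified space.
#' @export
restrict_range <- function(space, name, min, max) {
  if (!name %in% names(space$ranges))
    stop("unknown parameter '", name, "'; sampled parameters: ",
         paste(names(space$ranges), collapse = ", "))
  old <- space$ranges[[name]]
  space$ranges[[name]] <- parameter_range(name, min, max, old$scale)
  space
}

#' Latin hypercube sample of a parameter space
#'
#' Draws `n_sets` parameter sets with one-dimensional Latin hypercube
#' stratification per sampled parameter: each parameter's range is cut into
#' `n_sets` equal strata on its sampling scale (log10 by default) and every
#' stratum is hit exactly once.  The homogeneous tying rule, when present,
#' is applied after sampling.
#'
#' @param space a `parameter_space`.
#' @param n_sets number of parameter sets (>= 1).
#' @param seed integer seed; identical `(space, n_sets, seed)` give
#'   identical samples.
#' @return a numeric matrix with `n_sets` rows and one column per network
#'   parameter (flat names, [parameter_names()] order).
#' @examples
#' sp <- get_space("default_n3")
#' x <- lhs_sample(sp, 10, seed = 1)
#' @export
lhs_sample <- function(space, n_sets, seed) {
  stopifnot(inherits(space, "parameter_space"), n_sets >= 1)
  free <- names(space$ranges)
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(as.integer(n_sets), length(free))
  X <- matrix(NA_real_, n_sets, length(free), dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    r <- space$ranges[[j]]
    if (r$scale == "log") {
      X[, j] <- 10^(log10(r$min) + U[, j] * (log10(r$max) - log10(r$min)))
    } else {
      X[, j] <- r$min + U[, j] * (r$max - r$min)
    }
  }
  full <- parameter_names(space$spec)
  out <- matrix(NA_real_, n_sets, length(full), dimnames = list(NULL, full))
  out[, free] <- X
  if (space$tie_cycles_to_3) {
    for (ty in c("E", "Ep", "K", "Kp", "P"))
      for (i in 4:space$spec$n)
        out[, paste0(ty, i)] <- out[, paste0(ty, 3)]
  }
  out
}

#' Explore a parameter space
#'
#' Runs the two-endpoint off-target protocol on an LHS batch and summarizes
#' the fraction of parameter sets producing a detected off-target effect in
#' each monitored cycle, together with the distribution of effect sizes.
#' Parameter sets whose steady-state solve fails verification are excluded
#' from detection (counted as non-effects) and reported.
#'
#' @param space a `parameter_space`.
#' @param det a [detection_config()].
#' @param n_sets number of parameter sets (default 5000).
#' @param seed integer seed.
#' @param cfg a [solver_config()].
#' @return an `exploration_summary` with fields `n_sets`, `seed`,
#'   `detected` / `percent` (named by monitored cycle), `histogram`
#'   (cycle-2 effect-size counts in bins `[0.1, 0.2), ..., [0.9, 1.0]`),
#'   `n_excluded`, and `results` (per-set data frame: parameters, deltas,
#'   effect sizes, verdicts).
#' @examples
#' \donttest{
#' summary <- explore(get_space("default_n3"), n_sets = 500, seed = 7)
#' summary$percent
#' }
#' @export
explore <- function(space, det = detection_config(), n_sets = 5000L, seed,
                    cfg = solver_config()) {
  stopifnot(inherits(space, "parameter_space"), n_sets >= 1)
  spec <- space$spec
  X <- lhs_sample(space, n_sets, seed)
  res <- batch_response_cpp(X, spec$chains, spec$inhibited_cycle, spec$n,
                            det$I_low, det$I_high)
  valid <- res$residual <= cfg$residual_tol
  cyc <- spec$monitored_cycles
  df <- as.data.frame(X)
  detected <- integer(length(cyc))
  names(detected) <- paste0("cycle", cyc)
  for (k in seq_along(cyc)) {
    c_ <- cyc[k]
    dy <- res$dy[, c_]
    dys <- res$dystar[, c_]
    es <- pmax(abs(dy), abs(dys))
    hit <- valid & es >= det$threshold
    detected[k] <- sum(hit)
    df[[paste0("dy", c_)]] <- dy
    df[[paste0("dystar", c_)]] <- dys
    df[[paste0("effect_size", c_)]] <- es
    df[[paste0("detected", c_)]] <- hit
  }
  df$valid <- valid
  # bins [0.10, 0.20), ..., [0.90, 1.00] on the monitored cycle's effect size
  es2 <- df[[paste0("effect_size", cyc[1])]][df[[paste0("detected", cyc[1])]]]
  lower <- seq(det$threshold, 1 - det$threshold, by = det$threshold)
  hist_counts <- as.integer(table(cut(es2, breaks = c(lower, 1 + 1e-9),
                                      right = FALSE)))
  names(hist_counts) <- sprintf("[%.2f,%.2f)", lower, lower + det$threshold)
  structure(list(n_sets = as.integer(n_sets), seed = as.integer(seed),
                 motif = spec$motif, n = spec$n,
                 detected = detected,
                 percent = 100 * detected / n_sets,
                 histogram = hist_counts,
                 n_excluded = sum(!valid),
                 results = df),
            class = "exploration_summary")
}

#' @export
print.exploration_summary <- function(x, ...) {
  cat(sprintf("<exploration_summary> %s motif, %d cycles, %d sets (seed %d)\n",
              x$motif, x$n, x$n_sets, x$seed))
  for (k in seq_along(x$percent))
    cat(sprintf("  off-target in %s: %d / %d = %.2f%%\n",
                names(x$percent)[k], x$detected[k], x$n_sets, x$percent[k]))
  if (x$n_excluded > 0)
    cat("  excluded (unverified solves, counted as non-effects):",
        x$n_excluded, "\n")
  invisible(x)
}
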