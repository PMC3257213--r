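# Shared test helpers.

spec_n3 <- function() build_network("vertical", 3)

# Hand-transcribed residual system of the three-cycle network, written
# directly from the six dimensionless steady-state equations and kept
# independent of build_steady_state_system().
residuals_n3_by_hand <- function(p, I, y, ys) {
  with(p, c(
    P[1] * y[1] / (y[1] + K[1]) - ys[1] / (ys[1] + Kp[1]),
    -1 + y[1] + ys[1] * (1 + y[2] / K[2] + y[3] / K[3]) +
      E[1] * y[1] / (y[1] + K[1]) + Ep[1] * ys[1] / (ys[1] + Kp[1]),
    P[2] * y[2] * ys[1] / K[2] - ys[2] / (ys[2] + Kp[2]),
    -1 + y[2] * (1 + E[2] * ys[1] / K[2]) + ys[2] +
      Ep[2] * ys[2] / (ys[2] + Kp[2]),
    P[3] * y[3] * ys[1] / K[3] - ys[3] / (ys[3] + Kp[3]),
    -1 + y[3] * (1 + E[3] * ys[1] / K[3]) + ys[3] +
      Ep[3] * ys[3] / (ys[3] + Kp[3]) + I * ys[3] / (ys[3] + KB)
  ))
}

# Random strictly positive parameter set drawn log-uniformly from the
# default ranges (plain draws, no LHS stratification).
random_params <- function(n = 3) {
  lg <- function(lo, hi, k) 10^runif(k, log10(lo), log10(hi))
  dimensionless_params(E = lg(0.01, 100, n), Ep = lg(0.01, 100, n),
                       K = lg(0.01, 100, n), Kp = lg(0.01, 100, n),
                       P = lg(0.1, 10, n), KB = lg(0.01, 100, 1))
}

expect_valid_steady_state <- function(ss, tol = 1e-6) {
  expect_true(all(ss$y >= 0 & ss$y <= 1))
  expect_true(all(ss$ystar >= 0 & ss$ystar <= 1))
  expect_true(all(unlist(ss$complexes) >= 0 & unlist(ss$complexes) <= 1))
  expect_lte(ss$residual, tol)
}
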