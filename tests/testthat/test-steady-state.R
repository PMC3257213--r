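test_that("residual system matches a hand-transcribed copy of the n=3 equations", {
  spec <- spec_n3()
  set.seed(42)
  for (rep in 1:20) {
    p <- random_params()
    I <- 10^runif(1, -4, 4)
    f <- build_steady_state_system(p, spec, I)
    y <- runif(3)
    ys <- runif(3)
    expect_equal(f(y, ys), residuals_n3_by_hand(p, I, y, ys),
                 tolerance = 1e-12)
  }
})

test_that("rate balance is zeroed by symmetry and broken by perturbation", {
  spec <- spec_n3()
  p <- dimensionless_params(E = rep(1, 3), Ep = rep(1, 3),
                            K = c(0.7, 1, 1), Kp = c(0.7, 1, 1),
                            P = c(1, 1, 1), KB = 1)
  f <- build_steady_state_system(p, spec, 1e-4)
  # P1 = 1 and K1 = Kp1: y1 = y1* zeroes cycle 1's rate balance
  r <- f(c(0.3, 0.5, 0.5), c(0.3, 0.5, 0.5))
  expect_equal(r[1], 0)
  # a converged solution perturbed in y1 violates the conservation equation
  ss <- solve_steady_state_algebraic(p, spec, 1e-4)
  at_root <- f(ss$y, ss$ystar)
  expect_lt(max(abs(at_root)), 1e-6)
  nudged <- f(ss$y + c(0.01, 0, 0), ss$ystar)
  expect_gt(abs(nudged[2]), 1e-4)
})

test_that("algebraic solver returns verified states in [0,1] for shipped sets", {
  spec <- spec_n3()
  for (nm in c("random_set", "xenopus_set")) {
    p <- get_parameter_set(nm)
    for (I in c(1e-4, 1e4)) {
      ss <- solve_steady_state_algebraic(p, spec, I, fallback = FALSE)
      expect_valid_steady_state(ss)
      expect_identical(ss$method, "root")
    }
  }
})

test_that("symmetric single cycle equilibrates at y1 = y1*", {
  # huge K2, K3 decouple the downstream cycles; cycle 1 fully symmetric
  spec <- spec_n3()
  p <- dimensionless_params(E = c(0.5, 1, 1), Ep = c(0.5, 1, 1),
                            K = c(0.3, 1e9, 1e9), Kp = c(0.3, 1, 1),
                            P = c(1, 1, 1), KB = 1)
  ss <- solve_steady_state_algebraic(p, spec, 1e-4)
  expect_equal(ss$y[1], ss$ystar[1], tolerance = 1e-7)
})

test_that("sequestered drug complex responds monotonically to dose", {
  spec <- spec_n3()
  set.seed(31)
  for (rep in 1:10) {
    p <- random_params()
    lo <- solve_steady_state_algebraic(p, spec, 1e-4)
    hi <- solve_steady_state_algebraic(p, spec, 1e4)
    # saturating drug leaves less free active target than no drug
    expect_lte(hi$ystar[3], lo$ystar[3] + 1e-9)
  }
  # no drug, no drug complex
  p <- get_parameter_set("random_set")
  ss <- solve_steady_state_algebraic(p, spec, 0)
  expect_equal(ss$complexes$drug, 0)
})

test_that("deep vertical and extended chains solve to verified residuals", {
  set.seed(91)
  for (case in list(list("vertical", 7), list("lateral", 7),
                    list("extended", 3))) {
    spec <- build_network(case[[1]], case[[2]])
    for (rep in 1:10) {
      p <- random_params(spec$n)
      for (I in c(1e-4, 1e4)) {
        ss <- solve_steady_state_algebraic(p, spec, I, fallback = FALSE)
        expect_valid_steady_state(ss)
      }
    }
  }
})

test_that("solver output is deterministic", {
  spec <- spec_n3()
  p <- get_parameter_set("random_set")
  a <- solve_steady_state_algebraic(p, spec, 1e2)
  b <- solve_steady_state_algebraic(p, spec, 1e2)
  expect_identical(a$y, b$y)
  expect_identical(a$ystar, b$ystar)
})
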