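test_that("rate function conserves every pool exactly at random states", {
  set.seed(13)
  for (case in list(list("vertical", 3), list("extended", 3),
                    list("vertical", 5))) {
    spec <- build_network(case[[1]], case[[2]])
    p <- random_params(spec$n)
    dp <- map_to_dimensional(p, spec)
    sys <- build_ode_system(dp, spec, drug_dose(1))
    state <- runif(length(sys$y0), 0.01, 2)
    d <- unlist(sys$func(0, state, NULL))
    for (pool in sys$pools)
      expect_lt(abs(sum(d[pool$members])), 1e-12 * max(abs(d), 1))
  }
})

test_that("without drug the drug complex stays empty", {
  spec <- spec_n3()
  p <- get_parameter_set("random_set")
  dp <- map_to_dimensional(p, spec)
  sys <- build_ode_system(dp, spec, drug_dose(0))
  d <- unlist(sys$func(0, sys$y0, NULL))
  expect_identical(unname(d[length(d)]), 0)   # dCD/dt at CD = 0, DT = 0
  expect_error(sys$func(0, sys$y0[-1], NULL), "state vector")
})

test_that("pool conservation holds along trajectories to 1e-6", {
  spec <- spec_n3()
  set.seed(17)
  p <- random_params()
  dp <- map_to_dimensional(p, spec)
  sys <- build_ode_system(dp, spec, drug_dose(10))
  out <- deSolve::ode(y = sys$y0, times = c(0, 1, 10, 100, 1000),
                      func = sys$func, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  for (pool in sys$pools) {
    if (pool$total == 0) next
    sums <- rowSums(out[, 1 + pool$members, drop = FALSE])
    expect_lt(max(abs(sums / pool$total - 1)), 1e-6)
  }
})

test_that("integration endpoint satisfies the algebraic system", {
  spec <- spec_n3()
  set.seed(19)
  for (rep in 1:5) {
    p <- random_params()
    ss <- integrate_to_steady_state(p, spec, 1e-4)
    expect_valid_steady_state(ss)
    expect_identical(ss$method, "integration")
  }
})

test_that("steady states are invariant to the dimensional mapping", {
  spec <- spec_n3()
  tight <- solver_config(conv_tol = 1e-13, rtol = 1e-12, atol = 1e-14)
  set.seed(23)
  for (rep in 1:3) {
    p <- random_params()
    s1 <- integrate_to_steady_state(p, spec, 1e-4, tight)
    s2 <- integrate_to_steady_state(p, spec, 1e-4, tight, y1_total = 10,
                                    kp_rate = 5)
    expect_lt(max(abs(c(s1$y - s2$y, s1$ystar - s2$ystar))), 1e-8)
  }
})

test_that("I = 1e-4 operationally equals the drug-free system", {
  spec <- spec_n3()
  p <- get_parameter_set("random_set")
  near <- solve_steady_state_algebraic(p, spec, 1e-4)
  zero <- solve_steady_state_algebraic(p, spec, 0)
  expect_equal(near$y[2], zero$y[2], tolerance = 1e-3)
  expect_equal(near$ystar[2], zero$ystar[2], tolerance = 1e-3)
})
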