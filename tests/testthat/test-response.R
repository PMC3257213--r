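test_that("threshold is inclusive and effect size combines both species", {
  spec <- spec_n3()
  p <- get_parameter_set("random_set")
  r <- compute_response(p, spec)
  expect_equal(r$effect_size, max(abs(r$dy), abs(r$dystar)))
  expect_true(r$detected)
  expect_true(attr(r, "valid"))
  # a detection threshold exactly equal to the measured effect size still
  # triggers: the comparison is "greater than or equal to"
  at_boundary <- detection_config(threshold = r$effect_size)
  expect_true(compute_response(p, spec, at_boundary)$detected)
  above <- detection_config(threshold = r$effect_size + 1e-9)
  expect_false(compute_response(p, spec, above)$detected)
})

test_that("swapping the dose order negates deltas, keeps effect sizes", {
  spec <- spec_n3()
  p <- get_parameter_set("random_set")
  fwd <- compute_response(p, spec, detection_config())
  swapped_lo <- solve_steady_state_algebraic(p, spec, 1e4)
  swapped_hi <- solve_steady_state_algebraic(p, spec, 1e-4)
  expect_equal(swapped_hi$ystar[2] - swapped_lo$ystar[2], -fwd$dystar)
  expect_equal(max(abs(swapped_hi$ystar[2] - swapped_lo$ystar[2]),
                   abs(swapped_hi$y[2] - swapped_lo$y[2])),
               fwd$effect_size)
})

test_that("curve endpoints reproduce the two-endpoint response exactly", {
  spec <- spec_n3()
  p <- get_parameter_set("random_set")
  det <- detection_config(n_grid = 21)
  curve <- stimulus_response_curve(p, spec, det)
  resp <- compute_response(p, spec, det)
  expect_true(all(curve$converged))
  expect_equal(curve$ystar2[nrow(curve)] - curve$ystar2[1], resp$dystar)
  expect_equal(curve$y2[nrow(curve)] - curve$y2[1], resp$dy)
  # most of the transition happens within I in [0.1, 10]
  y2s_01 <- curve$ystar2[which.min(abs(curve$I - 0.1))]
  y2s_10 <- curve$ystar2[which.min(abs(curve$I - 10))]
  expect_gte(abs(y2s_10 - y2s_01), 0.5 * abs(resp$dystar))
  # and the response is monotone across the grid for this set
  expect_true(all(diff(curve$ystar2) >= -1e-9) ||
              all(diff(curve$ystar2) <= 1e-9))
})

test_that("rescaling cycle 3's Michaelis constants decouples cycle 2", {
  # sequestration is the only coupling route: making cycle 3's enzymes
  # operate far from saturation removes the off-target response
  spec <- spec_n3()
  p <- get_parameter_set("random_set")
  decoupled <- set_param(set_param(p, "K3", p$K[3] * 1e6),
                         "Kp3", p$Kp[3] * 1e6)
  r <- compute_response(decoupled, spec)
  expect_lt(r$effect_size, 1e-2)
})

test_that("amplification categories follow the cycle-4 vs cycle-2 comparison", {
  det <- detection_config()
  mk <- function(s2, s4) {
    data.frame(cycle = c(2L, 4L), dy = c(s2, s4), dystar = c(0, 0),
               effect_size = c(s2, s4),
               detected = c(s2, s4) >= det$threshold)
  }
  expect_equal(assess_amplification(mk(0.15, 0.30), det)$category,
               "effect_with_amplification")
  expect_equal(assess_amplification(mk(0.30, 0.30), det)$category,
               "effect_without_amplification")
  expect_equal(assess_amplification(mk(0.50, 0.08), det)$category,
               "no_effect")
  expect_error(assess_amplification(mk(0.5, 0.5)[1, ], det), "cycles 2 and 4")
})

test_that("extended-network responses cover both monitored cycles", {
  spec <- build_network("extended", 3)
  set.seed(47)
  p <- random_params(4)
  r <- compute_response(p, spec)
  expect_equal(r$cycle, c(2L, 4L))
  amp <- assess_amplification(r)
  expect_true(amp$category %in% c("no_effect", "effect_with_amplification",
                                  "effect_without_amplification"))
})
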