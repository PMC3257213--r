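test_that("LHS stratifies each parameter once per stratum on the log scale", {
  sp <- get_space("default_n3")
  x <- lhs_sample(sp, 4, seed = 3)
  # 4 samples over [0.01, 100] log-uniform: exactly one per decade
  for (nm in c("K3", "E1", "KB"))
    expect_equal(sort(floor(log10(x[, nm]))), c(-2, -1, 0, 1))
})

test_that("samples respect bounds and the tying rule", {
  sp <- get_space("default_vertical_n5")
  x <- lhs_sample(sp, 50, seed = 9)
  expect_equal(colnames(x), parameter_names(sp$spec))
  for (nm in names(sp$ranges)) {
    r <- sp$ranges[[nm]]
    expect_true(all(x[, nm] >= r$min & x[, nm] <= r$max))
  }
  # homogeneous tying: cycles 4 and 5 copy cycle 3's sampled values
  for (ty in c("E", "Ep", "K", "Kp", "P")) {
    expect_identical(x[, paste0(ty, 4)], x[, paste0(ty, 3)])
    expect_identical(x[, paste0(ty, 5)], x[, paste0(ty, 3)])
  }
})

test_that("log-uniform marginals are uniform in log10", {
  sp <- get_space("default_n3")
  x <- lhs_sample(sp, 5000, seed = 21)
  u <- (log10(x[, "E1"]) + 2) / 4   # map [0.01, 100] to [0, 1]
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("sampling and exploration are seed-deterministic", {
  sp <- get_space("default_n3")
  expect_identical(lhs_sample(sp, 25, seed = 77), lhs_sample(sp, 25, seed = 77))
  a <- explore(sp, n_sets = 40, seed = 55)
  b <- explore(sp, n_sets = 40, seed = 55)
  expect_identical(a$percent, b$percent)
  expect_identical(a$results, b$results)
  expect_false(identical(explore(sp, n_sets = 40, seed = 56)$results,
                         a$results))
})

test_that("exploration summary invariants hold on a small batch", {
  sm <- explore(get_space("restricted_n3_reconstruction"),
                n_sets = 200, seed = 15)
  expect_equal(sm$percent, 100 * sm$detected / sm$n_sets)
  # histogram mass equals the detected count, bins are decade tenths
  expect_equal(sum(sm$histogram), unname(sm$detected["cycle2"]))
  expect_length(sm$histogram, 9L)
  expect_true(all(sm$results$effect_size2 >= 0 &
                  sm$results$effect_size2 <= 1, na.rm = TRUE))
})

test_that("space validation rejects bad ranges and incomplete coverage", {
  spec <- spec_n3()
  expect_error(parameter_range("E1", -1, 10), "0 < min")
  expect_error(parameter_space(spec, list(E1 = c(0.01, 100))), "no range")
  full <- get_space("default_n3")
  bad <- lapply(full$ranges, function(r) c(r$min, r$max))
  bad$Z9 <- c(1, 2)
  expect_error(parameter_space(spec, bad), "unknown parameter")
  expect_error(restrict_range(get_space("default_n3"), "Q1", 1, 2),
               "unknown parameter")
})
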