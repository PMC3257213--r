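test_that("decade partitioning reproduces the canonical sub-ranges", {
  four <- partition_subranges(parameter_range("K3", 0.01, 100))
  expect_length(four, 4L)
  expect_equal(t(sapply(four, function(r) c(r$min, r$max))),
               cbind(c(0.01, 0.1, 1, 10), c(0.1, 1, 10, 100)),
               tolerance = 1e-12, ignore_attr = TRUE)
  two <- partition_subranges(parameter_range("P3", 0.1, 10))
  expect_length(two, 2L)
  expect_equal(two[[1]]$min, 0.1)
  expect_equal(two[[2]]$max, 10)
  one <- partition_subranges(parameter_range("X", 1, 10))
  expect_length(one, 1L)
  expect_error(partition_subranges(parameter_range("X", 0.3, 10)),
               "power")
})

test_that("plan enumerates every sub-range once plus a single baseline", {
  plan3 <- make_plan(get_space("default_n3"), n_sets = 100)
  expect_equal(nrow(plan3), 59L)   # 13 * 4 + 3 * 2 + 1
  expect_equal(sum(plan3$parameter == "baseline"), 1L)
  expect_false(any(duplicated(plan3[plan3$parameter != "baseline",
                                    c("parameter", "min", "max")])))

  plan_ext <- make_plan(get_space("default_extended_n3"), n_sets = 100)
  expect_equal(nrow(plan_ext), 77L)  # 17 * 4 + 4 * 2 + 1

  toy_spec <- spec_n3()
  toy_ranges <- lapply(get_space("default_n3")$ranges,
                       function(r) c(r$min, r$max))
  toy_ranges[names(toy_ranges) != "K3"] <-
    rep(list(c(1, 10)), sum(names(toy_ranges) != "K3"))
  # single-decade parameters contribute one run each: K3's 4 decades +
  # 15 one-decade parameters + baseline
  toy <- parameter_space(toy_spec, toy_ranges)
  expect_equal(nrow(make_plan(toy)), 4L + 15L + 1L)
})

test_that("perturbation report covers the plan and deltas reference baseline", {
  plan <- make_plan(get_space("default_n3"), n_sets = 60)
  report <- run_perturbation(plan, seed = 5)
  expect_equal(nrow(report), nrow(plan))
  expect_equal(sum(report$parameter == "baseline"), 1L)
  base <- report$percent_cycle2[report$parameter == "baseline"]
  expect_equal(report$delta_cycle2, report$percent_cycle2 - base)
  expect_equal(unname(attr(report, "baseline")["percent_cycle2"]), base)
  # per-run seeds are distinct and recorded
  expect_false(any(duplicated(report$seed)))
})

test_that("restricted spaces are sub-ranges of the baseline", {
  base <- get_space("default_n3")
  same <- build_restricted_space(base, list())
  expect_equal(same$ranges, base$ranges)
  rules <- restriction_rules_default()
  restricted <- build_restricted_space(base, rules)
  for (nm in names(restricted$ranges)) {
    expect_gte(restricted$ranges[[nm]]$min, base$ranges[[nm]]$min)
    expect_lte(restricted$ranges[[nm]]$max, base$ranges[[nm]]$max)
  }
  expect_error(build_restricted_space(base, list(Q1 = c(1, 2))), "unknown")
  expect_error(build_restricted_space(base, list(K3 = c(0.001, 0.1))),
               "not inside")
})

test_that("pooling a parameter's sub-range strata recovers the baseline rate", {
  # restricting K3 to each decade in turn and averaging the four detected
  # percentages equals sampling K3 from the full range, up to sampling error
  sp <- get_space("default_n3")
  n_per <- 400
  subs <- partition_subranges(sp$ranges[["K3"]])
  pcts <- vapply(seq_along(subs), function(i) {
    spi <- restrict_range(sp, "K3", subs[[i]]$min, subs[[i]]$max)
    explore(spi, n_sets = n_per, seed = 300 + i)$percent[["cycle2"]]
  }, 0)
  pooled <- mean(pcts)
  full <- explore(sp, n_sets = 4 * n_per, seed = 299)$percent[["cycle2"]]
  se <- 100 * sqrt(full / 100 * (1 - full / 100) / (4 * n_per))
  expect_lt(abs(pooled - full), max(4 * se, 1.5))
})
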