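test_that("the Falconer decomposition applies the doubling formula", {
  f <- falconer_decomposition(0.8, 0.5)
  expect_equal(c(f$a2, f$c2, f$e2), c(0.6, 0.2, 0.2))
  expect_false(f$out_of_bounds)
  f2 <- falconer_decomposition(0.5, 0.25)
  expect_equal(c(f2$a2, f2$c2, f2$e2), c(0.5, 0, 0.5))
  # rDZ < rMZ / 2 forces a negative c2, flagged rather than truncated
  f3 <- falconer_decomposition(0.8, 0.3)
  expect_equal(c(f3$a2, f3$c2, f3$e2), c(1.0, -0.2, 0.2))
  expect_true(f3$out_of_bounds)
})

test_that("ML recovers the generating components and agrees with Falconer", {
  cfg <- sim_config(pairs = c(MZm = 1250, MZf = 1250, DZm = 1250,
                              DZf = 1250), a2 = 0.6, c2 = 0.2, seed = 1)
  sim <- simulate_continuous(cfg, "y")
  fit <- fit_ace_ml(sim, "y")
  est <- setNames(fit$components$estimate, fit$components$component)
  expect_within(unname(est), c(0.6, 0.2, 0.2), 0.05)
  expect_equal(sum(est), 1, tolerance = 1e-8)
  expect_true(all(fit$components$lower <= fit$components$estimate + 1e-8))
  expect_true(all(fit$components$estimate <= fit$components$upper + 1e-8))
  expect_true(fit$convergence)
  # moment estimator from the observed correlations lands within 0.02
  cors <- twin_correlations(sim, "y")
  fal <- falconer_decomposition(cors$r[cors$group == "MZ"],
                                cors$r[cors$group == "DZ"])
  expect_within(est[["a2"]], fal$a2, 0.02)
  expect_within(est[["c2"]], fal$c2, 0.02)
})

test_that("a pure-noise cohort is attributed to non-shared environment", {
  cfg <- sim_config(pairs = c(MZf = 2000, DZm = 2000), a2 = 0, c2 = 0,
                    seed = 2)
  fit <- fit_ace_ml(simulate_continuous(cfg, "y"), "y", ci = character(0))
  expect_gt(fit$components$estimate[3], 0.98)
})

test_that("submodels drop the right parameters and warn on thin strata", {
  cfg <- sim_config(pairs = c(MZm = 400, DZf = 400), a2 = 0.5, c2 = 0.2,
                    seed = 3)
  sim <- simulate_continuous(cfg, "y")
  ae <- fit_ace_ml(sim, "y", "AE", ci = character(0))
  expect_equal(ae$components$estimate[2], 0)
  expect_equal(ae$npar, 3L)
  ce <- fit_ace_ml(sim, "y", "CE", ci = character(0))
  expect_equal(ce$components$estimate[1], 0)
  small <- sim[c(1:10, 401:440), ]
  expect_warning(fit_ace_ml(small, "y", ci = character(0)),
                 "fewer than 20")
  expect_error(fit_ace_ml(sim[1:400, ], "y"), "DZ-type")
})

test_that("likelihood-ratio tests respect nesting, dominance and boundaries", {
  cfg <- sim_config(pairs = c(MZm = 500, DZf = 500), a2 = 0.5, c2 = 0.2,
                    seed = 4)
  sim <- simulate_continuous(cfg, "y")
  ace <- fit_ace_ml(sim, "y", "ACE", ci = character(0))
  ae <- fit_ace_ml(sim, "y", "AE", ci = character(0))
  e <- fit_ace_ml(sim, "y", "E", ci = character(0))
  self <- likelihood_ratio_test(ace, ace)
  expect_equal(self$statistic, 0)
  expect_equal(self$df, 0L)
  lrt <- likelihood_ratio_test(ace, ae)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1L)
  expect_true(lrt$boundary)
  expect_true(lrt$p_boundary <= lrt$p_value + 1e-12)
  # strong familiality: dropping A and C is firmly rejected
  expect_lt(likelihood_ratio_test(ace, e)$p_value, 1e-10)
  ce <- fit_ace_ml(sim, "y", "CE", ci = character(0))
  expect_error(likelihood_ratio_test(ae, ce), "not nested")
})
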