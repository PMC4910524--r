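test_that("a sex-homogeneous cohort matches the pooled univariate fit", {
  cfg <- sim_config(pairs = c(MZm = 5000, MZf = 5000, DZm = 5000,
                              DZf = 5000, DZos = 10000),
                    a2 = 0.6, c2 = 0.2, seed = 1)
  sim <- simulate_continuous(cfg, "y")
  pooled <- fit_ace_ml(sim, "y", ci = character(0))
  sl <- fit_sex_limitation(sim, "y", ci = character(0))
  pooled_est <- setNames(pooled$components$estimate,
                         pooled$components$component)
  for (sex in c("M", "F")) {
    e <- sl$estimates[sl$estimates$sex == sex, ]
    expect_within(setNames(e$estimate, e$component), pooled_est, 0.05)
  }
  # the homogeneous submodel IS the pooled model: same maximum likelihood
  expect_within(sl$fits$homogeneous$loglik, pooled$loglik, 1e-4)
  # nesting chain: log-likelihood can only fall as constraints accumulate
  ll <- vapply(sl$fits[c("full", "qualitative_constrained",
                         "quantitative_equal", "homogeneous")],
               function(f) f$loglik, numeric(1))
  expect_true(all(diff(ll) <= 1e-6))
})

test_that("the liability sex-limitation chain is ordered and sane", {
  cfg <- sim_config(pairs = c(MZm = 1000, MZf = 1000, DZm = 1000,
                              DZf = 1000, DZos = 2000),
                    a2 = 0.5, c2 = 0.3, seed = 2)
  sim <- simulate_binary_choice(cfg, "ch")
  sl <- fit_sex_limitation(sim, "ch", ci = character(0))
  expect_equal(sl$type, "liability")
  ll <- vapply(sl$fits[c("full", "qualitative_constrained",
                         "quantitative_equal", "homogeneous")],
               function(f) f$loglik, numeric(1))
  expect_true(all(diff(ll) <= 1e-6))
  for (sex in c("M", "F")) {
    e <- sl$estimates[sl$estimates$sex == sex, ]
    expect_equal(sum(e$estimate), 1, tolerance = 1e-6)
    expect_within(setNames(e$estimate, e$component),
                  c(a2 = 0.5, c2 = 0.3, e2 = 0.2), 0.12)
  }
})

test_that("a depressed DZos genetic correlation is detected", {
  cfg <- sim_config(pairs = c(MZm = 1000, MZf = 1000, DZm = 1000,
                              DZf = 1000, DZos = 3000),
                    a2 = 0.6, c2 = 0.2, rg = 0.2, seed = 3)
  sim <- simulate_continuous(cfg, "y")
  sl <- fit_sex_limitation(sim, "y", ci = character(0))
  expect_lt(sl$r_free, 0.35)
  p_qual <- sl$lrt_chain$p_value[
    sl$lrt_chain$model == "qualitative_constrained"]
  expect_lt(p_qual, 0.05)
})

test_that("the quantitative test keeps its nominal size under homogeneity", {
  rejections <- 0L
  for (i in 1:200) {
    cfg <- sim_config(pairs = c(MZm = 250, MZf = 250, DZm = 250,
                                DZf = 250, DZos = 500),
                      a2 = 0.6, c2 = 0.2, seed = 3000 + i)
    sim <- simulate_continuous(cfg, "y")
    sl <- fit_sex_limitation(sim, "y", ci = character(0),
                             models = c("full", "quantitative_equal"))
    p <- sl$lrt_chain$p_value[sl$lrt_chain$model == "quantitative_equal"]
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_within(rejections / 200, 0.05, 0.03)
})

test_that("small-sample sex contrasts come with overlapping intervals", {
  # a heritability contrast like the one seen for mathematics, at the
  # scale of a subject chosen by a minority of the cohort
  cfg <- sim_config(pairs = c(MZm = 170, MZf = 170, DZm = 170, DZf = 170,
                              DZos = 330),
                    a2_m = 0.51, a2_f = 0.70, c2_m = 0.15, c2_f = 0.05,
                    seed = 4)
  sim <- simulate_continuous(cfg, "y")
  sl <- fit_sex_limitation(sim, "y")
  am <- sl$estimates[sl$estimates$component == "a2" &
                       sl$estimates$sex == "M", ]
  af <- sl$estimates[sl$estimates$component == "a2" &
                       sl$estimates$sex == "F", ]
  expect_true(am$lower <= af$upper && af$lower <= am$upper)
  expect_gt(af$upper - af$lower, 0.1)  # wide: the contrast is underpowered
})

test_that("the model demands opposite-sex pairs and flags thin groups", {
  cfg <- sim_config(pairs = c(MZm = 100, MZf = 100, DZm = 100, DZf = 100),
                    seed = 5)
  sim <- simulate_continuous(cfg, "y")
  expect_error(fit_sex_limitation(sim, "y"), "opposite-sex")
  cfg2 <- sim_config(pairs = c(MZm = 100, MZf = 100, DZm = 100, DZf = 100,
                               DZos = 10), seed = 5)
  sim2 <- simulate_continuous(cfg2, "y")
  expect_warning(fit_sex_limitation(sim2, "y", ci = character(0),
                                    models = "full"),
                 "underpowered")
})
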