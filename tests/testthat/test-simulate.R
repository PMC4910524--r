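test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- sim_config(pairs = c(MZm = 50, DZf = 50, DZos = 50), seed = 9)
  expect_identical(simulate_continuous(cfg, "y"),
                   simulate_continuous(cfg, "y"))
  expect_identical(simulate_teds_like(cfg), simulate_teds_like(cfg))
  cfg2 <- sim_config(pairs = c(MZm = 50, DZf = 50, DZos = 50), seed = 10)
  expect_false(identical(simulate_continuous(cfg, "y"),
                         simulate_continuous(cfg2, "y")))
})

test_that("twin correlations converge to the ACE expectations", {
  # pure non-shared environment: twins uncorrelated
  cfg0 <- sim_config(pairs = c(MZm = 5000, MZf = 5000), a2 = 0, c2 = 0,
                     seed = 1)
  g <- pair_values(simulate_continuous(cfg0, "y"), "y")
  expect_lt(abs(cor(g[, 1], g[, 2])), 0.03)
  # rMZ = a2 + c2, rDZ = 0.5 a2 + c2 at large n
  cfg <- sim_config(pairs = c(MZm = 25000, MZf = 25000, DZm = 25000,
                              DZf = 25000), a2 = 0.6, c2 = 0.2, seed = 2)
  sim <- simulate_continuous(cfg, "y")
  mz <- pair_values(sim[substr(sim$zygosity, 1, 2) == "MZ", ], "y")
  dz <- pair_values(sim[substr(sim$zygosity, 1, 2) == "DZ", ], "y")
  expect_within(cor(mz[, 1], mz[, 2]), 0.8, 0.01)
  expect_within(cor(dz[, 1], dz[, 2]), 0.5, 0.01)
  # marginal variance is 1 before mean effects
  expect_within(var(c(mz)), 1, 0.02)
})

test_that("DZos cross-twin covariance follows rg, rc and sex-specific paths", {
  cfg <- sim_config(pairs = c(DZos = 40000),
                    a2_m = 0.5, c2_m = 0.3, a2_f = 0.3, c2_f = 0.2,
                    rg = 0.3, rc = 0.8, seed = 3)
  g <- pair_values(simulate_continuous(cfg, "y"), "y")
  want <- 0.3 * sqrt(0.5 * 0.3) + 0.8 * sqrt(0.3 * 0.2)
  expect_within(cov(g[, 1], g[, 2]), want, 0.015)
})

test_that("binary choice respects the liability threshold", {
  cfg <- sim_config(pairs = c(MZm = 5000, DZf = 5000), prevalence = 0.5,
                    seed = 4)
  ch <- pair_values(simulate_binary_choice(cfg, "ch"), "ch", "choice")
  expect_within(mean(ch), 0.5, 0.02)
  cfg2 <- sim_config(pairs = c(MZm = 5000), prevalence = 0.2, seed = 4)
  ch2 <- pair_values(simulate_binary_choice(cfg2, "ch"), "ch", "choice")
  expect_within(mean(ch2), 0.2, 0.02)
  expect_error(sim_config(prevalence = 1), "strictly inside")
  expect_error(sim_config(a2 = 0.8, c2 = 0.4), "\\[0, 1\\]")
})

test_that("the cohort generator reproduces the study design", {
  sim <- simulate_teds_like(sim_config(seed = 5))
  zyg <- table(sim$zygosity)
  expect_equal(unname(zyg[c("MZm", "MZf")] |> sum()), 2318)
  expect_equal(unname(zyg[c("DZm", "DZf")] |> sum()), 2146)
  expect_equal(unname(zyg[["DZos"]]), 2120)
  ch <- pair_values(sim, "alevel", "choice")
  gr <- pair_values(sim, "alevel", "grade")
  # achievement observed only in choosers, on the 1-6 scale
  expect_true(all(is.na(gr[ch == 0])))
  expect_true(all(!is.na(gr[ch == 1])))
  expect_true(all(gr[!is.na(gr)] %in% 1:6))
  expect_within(mean(ch), 0.5, 0.02)
})
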