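test_that("the sex-by-choice chi-square matches the closed form", {
  # pairs concordant for choice, so any twin selection gives the table
  # [[10, 20], [20, 10]]: chi2 = n (ad - bc)^2 / (r1 r2 c1 c2) = 6.667
  pairs <- bind_pairs(
    make_pairs("MZm", 10, choice = c(1, 1)),
    make_pairs("MZm", 20, choice = c(0, 0)),
    make_pairs("MZf", 20, choice = c(1, 1)),
    make_pairs("MZf", 10, choice = c(0, 0)))
  res <- chisq_one_per_pair(pairs, "alevel", seed = 1)
  expect_equal(res$statistic, 60 * (10 * 10 - 20 * 20)^2 /
                 (30 * 30 * 30 * 30), tolerance = 1e-10)
  expect_equal(res$df, 1)
  # deterministic under the selection seed
  cfg <- sim_config(pairs = c(MZm = 200, MZf = 200, DZos = 200), seed = 2)
  sim <- simulate_binary_choice(cfg, "alevel")
  expect_identical(chisq_one_per_pair(sim, "alevel", 7),
                   chisq_one_per_pair(sim, "alevel", 7))
  # a degenerate margin is an error, not NaN
  allch <- bind_pairs(make_pairs("DZos", 30, choice = c(1, 1)))
  expect_error(chisq_one_per_pair(allch, "alevel", 1), "margin")
})

test_that("the chi-square keeps its nominal type-I rate when choice is sex-independent", {
  rejections <- 0L
  for (i in 1:1000) {
    cfg <- sim_config(pairs = c(MZm = 120, MZf = 120, DZos = 260),
                      a2 = 0.4, c2 = 0.3, seed = 5000 + i)
    sim <- simulate_binary_choice(cfg, "ch")
    p <- chisq_one_per_pair(sim, "ch", seed = i)$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_within(rejections / 1000, 0.05, 0.02)
})

test_that("sex x zygosity ANOVA recovers a known variance share", {
  # beta chosen so sex explains ~5% of variance: b^2/4 / (1 + b^2/4) = .05
  b <- 2 * sqrt(0.05 / 0.95)
  cfg <- sim_config(pairs = c(MZm = 1250, MZf = 1250, DZm = 1250,
                              DZf = 1250), a2 = 0.5, c2 = 0.2,
                    beta_sex = b, seed = 6)
  sim <- simulate_continuous(cfg, "y")
  rep <- anova_sex_zygosity(sim, "y", seed = 1)
  expect_within(rep$r_squared, 0.05, 0.02)
  expect_gt(rep$F_sex, 1)
  expect_identical(rep$r_squared,
                   anova_sex_zygosity(sim, "y", seed = 1)$r_squared)
  # null design: all terms explain next to nothing
  cfg0 <- sim_config(pairs = c(MZm = 1000, MZf = 1000, DZm = 1000,
                               DZf = 1000), a2 = 0.5, c2 = 0.2, seed = 7)
  rep0 <- anova_sex_zygosity(simulate_continuous(cfg0, "y"), "y", seed = 1)
  expect_lt(rep0$r_squared, 0.01)
})

test_that("sequential sums of squares partition the total", {
  cfg <- sim_config(pairs = c(MZm = 300, MZf = 300, DZm = 300, DZf = 300),
                    beta_sex = 0.3, seed = 8)
  rep <- anova_sex_zygosity(simulate_continuous(cfg, "y"), "y", seed = 2)
  ss <- rep$anova_table[["Sum Sq"]]
  y_ss <- sum(ss)
  expect_equal(sum(ss[-length(ss)]) / y_ss + ss[length(ss)] / y_ss, 1,
               tolerance = 1e-12)
  expect_true(rep$r_squared >= 0 && rep$r_squared <= 1)
})
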