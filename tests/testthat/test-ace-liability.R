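test_that("probandwise concordance follows its definition", {
  pairs <- bind_pairs(
    make_pairs("MZm", 50, choice = c(1, 1)),
    make_pairs("MZm", 25, choice = c(1, 0)),
    make_pairs("MZm", 25, choice = c(0, 1)),
    make_pairs("MZm", 100, choice = c(0, 0)))
  cs <- concordance_summary(pairs, "alevel")
  mz <- cs[cs$group == "MZ", ]
  expect_equal(mz$probandwise, 100 / 150)
  expect_equal(unlist(mz[c("n11", "n10", "n01", "n00")], use.names = FALSE),
               c(50, 25, 25, 100))
  perfect <- bind_pairs(make_pairs("DZf", 30, choice = c(1, 1)),
                        make_pairs("DZf", 10, choice = c(0, 0)))
  expect_equal(concordance_summary(perfect, "alevel")$probandwise[
    concordance_summary(perfect, "alevel")$group == "DZ"], 1)
})

test_that("MZ concordance exceeds DZ concordance under genetic influence", {
  cfg <- sim_config(pairs = c(MZm = 2000, MZf = 2000, DZm = 2000,
                              DZf = 2000), a2 = 0.5, c2 = 0.2, seed = 1)
  sim <- simulate_binary_choice(cfg, "ch")
  cs <- concordance_summary(sim, "ch")
  expect_gt(cs$probandwise[cs$group == "MZ"],
            cs$probandwise[cs$group == "DZ"])
})

test_that("the liability model recovers components and threshold", {
  cfg <- sim_config(pairs = c(MZm = 1500, MZf = 1500, DZm = 1500,
                              DZf = 1500), a2 = 0.44, c2 = 0.47,
                    prevalence = 0.5, seed = 3)
  sim <- simulate_binary_choice(cfg, "ch")
  fit <- fit_liability_ace(sim, "ch")
  est <- setNames(fit$components$estimate, fit$components$component)
  expect_within(unname(est), c(0.44, 0.47, 0.09), 0.07)
  expect_equal(sum(est), 1, tolerance = 1e-8)
  expect_within(fit$threshold, 0, 0.03)
  expect_true(all(fit$components$lower <= fit$components$estimate + 1e-8))
  expect_true(all(fit$components$estimate <= fit$components$upper + 1e-8))
  # implied group correlations agree with direct tetrachoric fits
  cs <- concordance_summary(sim, "ch")
  for (grp in c("MZ", "DZ")) {
    row <- cs[cs$group == grp, ]
    direct <- fit_tetrachoric(unlist(row[c("n11", "n10", "n01", "n00")]))
    implied <- if (grp == "MZ") fit$r_mz else fit$r_dz
    expect_within(implied, direct$r, 0.03)
  }
})

test_that("degenerate prevalence in a stratum is refused", {
  pairs <- bind_pairs(make_pairs("MZm", 30, choice = c(1, 1)),
                      make_pairs("DZf", 30, choice = c(1, 0)))
  expect_error(fit_liability_ace(pairs, "alevel"), "degenerate prevalence")
})

test_that("a forced CE fit is rejected against ACE when heritability is real", {
  cfg <- sim_config(pairs = c(MZm = 2500, MZf = 2500, DZm = 2500,
                              DZf = 2500), a2 = 0.6, c2 = 0, seed = 4)
  sim <- simulate_binary_choice(cfg, "ch")
  ace <- fit_liability_ace(sim, "ch", "ACE", ci = character(0))
  ce <- fit_liability_ace(sim, "ch", "CE", ci = character(0))
  # the CE model absorbs DZ resemblance into c2 but misfits the MZ table
  expect_gt(ce$components$estimate[2], 0.3)
  expect_lt(likelihood_ratio_test(ace, ce)$p_value, 1e-6)
})
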