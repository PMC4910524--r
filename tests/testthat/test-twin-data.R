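test_that("a minimal two-row file parses to one MZf pair", {
  path <- write_long_csv(c(
    "family_id,twin,zygosity,sex,age,choice_alevel",
    "fam1,1,MZf,F,18.2,1",
    "fam1,2,MZf,F,18.2,1"))
  pairs <- read_twin_table(path)
  expect_s3_class(pairs, "twin_pairs")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$zygosity, "MZf")
  expect_equal(pairs$choice_alevel_1, 1)
  expect_equal(pairs$choice_alevel_2, 1)
})

test_that("malformed input is rejected with an informative error", {
  # MZ pair with discordant sexes violates the zygosity invariant
  bad_sex <- write_long_csv(c(
    "family_id,twin,zygosity,sex,age",
    "fam1,1,MZm,M,18", "fam1,2,MZm,F,18"))
  expect_error(read_twin_table(bad_sex), "discordant sexes.*fam1")
  # family with a single row
  lone <- write_long_csv(c(
    "family_id,twin,zygosity,sex,age",
    "fam1,1,MZm,M,18", "fam1,2,MZm,M,18", "fam2,1,DZf,F,17"))
  expect_error(read_twin_table(lone), "malformed pair.*fam2")
  # unknown zygosity code
  odd <- write_long_csv(c(
    "family_id,twin,zygosity,sex,age",
    "fam1,1,XX,M,18", "fam1,2,XX,M,18"))
  expect_error(read_twin_table(odd), "unknown zygosity")
  # DZos with concordant sexes
  conc <- write_long_csv(c(
    "family_id,twin,zygosity,sex,age",
    "fam1,1,DZos,M,18", "fam1,2,DZos,M,18"))
  expect_error(read_twin_table(conc), "DZos.*concordant")
  # grade observed for a non-chooser
  orphan <- write_long_csv(c(
    "family_id,twin,zygosity,sex,age,choice_alevel,grade_alevel",
    "fam1,1,MZm,M,18,0,4", "fam1,2,MZm,M,18,1,5"))
  expect_error(read_twin_table(orphan), "without choice")
  # grade off the 1-6 scale
  off <- write_long_csv(c(
    "family_id,twin,zygosity,sex,age,choice_alevel,grade_alevel",
    "fam1,1,MZm,M,18,1,7", "fam1,2,MZm,M,18,1,5"))
  expect_error(read_twin_table(off), "outside")
})

test_that("write then read round-trips simulated cohorts exactly", {
  cfg <- sim_config(pairs = c(MZm = 2, MZf = 2, DZm = 2, DZf = 2,
                              DZos = 2), seed = 42)
  sim <- simulate_teds_like(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_twin_table(sim, path)
  back <- read_twin_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim))
  # continuous phenotypes (unbounded scale) round-trip with the range
  # check disabled, missingness preserved
  simc <- simulate_continuous(cfg, "y")
  simc$grade_y_2[3] <- NA_real_
  write_twin_table(simc, path)
  backc <- read_twin_table(path, grade_range = NULL)
  expect_equal(as.data.frame(backc), as.data.frame(simc))
  expect_true(is.na(backc$grade_y_2[3]))
})

test_that("chooser shares use the chooser denominator and partition to 100%", {
  pairs <- bind_pairs(
    make_pairs("MZf", 3, choice = c(1, 1)),   # 6 female choosers
    make_pairs("MZm", 2, choice = c(1, 0)),   # 2 male choosers
    make_pairs("DZm", 2, choice = c(0, 0)),
    make_pairs("DZos", 1, choice = c(1, 1)))  # 1 male + 1 female chooser
  s <- summarize_counts(pairs, "alevel")
  expect_equal(s$n_choosers, 10)
  expect_equal(s$n_individuals, 16)
  expect_equal(s$pct_choosing, round(100 * 10 / 16, 1))
  expect_equal(s$by_sex$choosers, c(3, 7))
  expect_equal(s$by_sex$pct_of_choosers, c(30, 70))
  # the five zygosity groups partition the choosers
  expect_equal(sum(s$by_group$choosers), s$n_choosers)
  expect_equal(sum(s$by_group$pct_of_choosers), 100, tolerance = 0.011)
  expect_error(summarize_counts(pairs, "nope"), "unknown choice trait")
})

test_that("a trait nobody chose yields zero shares without division errors", {
  pairs <- bind_pairs(make_pairs("MZm", 4, choice = c(0, 0)))
  s <- summarize_counts(pairs, "alevel")
  expect_equal(s$n_choosers, 0)
  expect_equal(s$pct_choosing, 0)
  expect_true(all(s$by_sex$pct_of_choosers == 0))
  expect_true(all(is.finite(s$by_group$pct_of_choosers)))
})
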