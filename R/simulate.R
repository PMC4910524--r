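# Synthetic twin cohorts with known ACE structure.
#
# Latent model per individual: standardized additive-genetic (A), shared-
# environment (C) and non-shared (E) scores combine as
#   y = a*A + c*C + e*E  (+ optional age/sex mean effects),
# with cross-twin correlations Cor(A1,A2) = 1 (MZ), 0.5 (DZ same-sex),
# rg (DZos; rg is the DZos genetic correlation, expected 0.5) and
# Cor(C1,C2) = 1 except rc for DZos. E is independent within pairs.

#' Simulation configuration for a synthetic twin cohort
#'
#' Defaults emulate a large UK volunteer twin cohort assessed at age 18:
#' 6584 pairs split 2318 MZ / 2146 DZ same-sex / 2120 DZ opposite-sex
#' (MZ and DZss split evenly by sex), choice prevalence 0.5, exam grades
#' on a 1-6 scale with mean 3.9 and SD 1.16, and an achievement ACE
#' decomposition of (0.59, 0.07, 0.34).
#'
#' @param pairs Named integer vector of pair counts per zygosity group
#'   (names from [zygosity_levels()]).
#' @param a2,c2 Standardized variance proportions of the additive-genetic
#'   and shared-environment components (per-sex values may be supplied via
#'   `a2_m`/`a2_f`, `c2_m`/`c2_f`); `e2 = 1 - a2 - c2` per sex.
#' @param a2_m,c2_m,a2_f,c2_f Optional sex-specific proportions; default to
#'   the common `a2`/`c2`.
#' @param rg DZ opposite-sex additive-genetic correlation in \[0, 1\];
#'   0.5 (the default) is the value expected when the same genetic factors
#'   operate in both sexes.
#' @param rc DZ opposite-sex shared-environment correlation in \[0, 1\];
#'   1 under a common shared environment.
#' @param prevalence Population prevalence K of a binary choice (threshold
#'   at the upper-K standard-normal quantile); strictly inside (0, 1).
#' @param grade_mean,grade_sd Location and scale used when discretizing a
#'   continuous achievement phenotype to the 1-6 grade scale.
#' @param age_range Pair ages drawn uniformly from this range (years).
#' @param beta_age,beta_sex Optional linear mean effects of (centered) age
#'   and of female sex, added after the latent ACE part.
#' @param seed Integer seed; a fixed seed makes every simulator
#'   deterministic (single pseudo-random stream per run).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(pairs = c(MZm = 1159, MZf = 1159, DZm = 1073,
                                 DZf = 1073, DZos = 2120),
                       a2 = 0.59, c2 = 0.07,
                       a2_m = a2, c2_m = c2, a2_f = a2, c2_f = c2,
                       rg = 0.5, rc = 1,
                       prevalence = 0.5,
                       grade_mean = 3.9, grade_sd = 1.16,
                       age_range = c(18, 18.99),
                       beta_age = 0, beta_sex = 0,
                       seed = 1L) {
  if (is.null(names(pairs)) || !all(names(pairs) %in% zygosity_levels()))
    stop("pairs must be named by zygosity group", call. = FALSE)
  full <- stats::setNames(rep(0L, 5), zygosity_levels())
  full[names(pairs)] <- as.integer(pairs)
  if (any(full < 0)) stop("pair counts must be >= 0", call. = FALSE)
  for (s in c("m", "f")) {
    p <- get(paste0("a2_", s)); q <- get(paste0("c2_", s))
    if (p < 0 || q < 0 || p + q > 1 + 1e-12)
      stop("a2 + c2 must lie in [0, 1] for each sex (e2 = 1 - a2 - c2)",
           call. = FALSE)
  }
  if (rg < 0 || rg > 1 || rc < 0 || rc > 1)
    stop("rg and rc must lie in [0, 1]", call. = FALSE)
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(pairs = full,
                 a2_m = a2_m, c2_m = c2_m, e2_m = 1 - a2_m - c2_m,
                 a2_f = a2_f, c2_f = c2_f, e2_f = 1 - a2_f - c2_f,
                 rg = rg, rc = rc, prevalence = prevalence,
                 grade_mean = grade_mean, grade_sd = grade_sd,
                 age_range = age_range,
                 beta_age = beta_age, beta_sex = beta_sex,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw the latent standardized phenotype pair for each family of one group
sim_group_latents <- function(n, zyg, config) {
  sexes <- zyg_sexes(zyg)
  rho_a <- if (zyg == "DZos") config$rg else zygosity_gamma(zyg)
  rho_c <- if (zyg == "DZos") config$rc else 1
  A1 <- stats::rnorm(n)
  A2 <- rho_a * A1 + sqrt(1 - rho_a^2) * stats::rnorm(n)
  C1 <- stats::rnorm(n)
  C2 <- rho_c * C1 + sqrt(1 - rho_c^2) * stats::rnorm(n)
  path <- function(s) {
    suf <- if (s == "M") "m" else "f"
    c(a = sqrt(config[[paste0("a2_", suf)]]),
      c = sqrt(config[[paste0("c2_", suf)]]),
      e = sqrt(config[[paste0("e2_", suf)]]))
  }
  p1 <- path(sexes[1]); p2 <- path(sexes[2])
  y1 <- p1["a"] * A1 + p1["c"] * C1 + p1["e"] * stats::rnorm(n)
  y2 <- p2["a"] * A2 + p2["c"] * C2 + p2["e"] * stats::rnorm(n)
  list(y = cbind(y1, y2), sexes = sexes)
}

sim_frame <- function(config, fill_trait) {
  groups <- zygosity_levels()
  counts <- config$pairs[groups]
  out <- vector("list", length(groups))
  id0 <- 0L
  mid_age <- mean(config$age_range)
  for (gi in seq_along(groups)) {
    zyg <- groups[gi]; n <- counts[[gi]]
    if (n == 0L) next
    lat <- sim_group_latents(n, zyg, config)
    age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 2)
    sex_eff <- ifelse(lat$sexes == "F", config$beta_sex, 0)
    y <- lat$y
    y[, 1] <- y[, 1] + sex_eff[1] + config$beta_age * (age - mid_age)
    y[, 2] <- y[, 2] + sex_eff[2] + config$beta_age * (age - mid_age)
    df <- data.frame(
      family_id = sprintf("F%05d", id0 + seq_len(n)),
      zygosity = zyg,
      sex1 = lat$sexes[1], sex2 = lat$sexes[2],
      age = age, stringsAsFactors = FALSE)
    out[[gi]] <- fill_trait(df, y)
    id0 <- id0 + n
  }
  twin_pairs(do.call(rbind, out[!vapply(out, is.null, logical(1))]),
             validate = FALSE)
}

#' Simulate a continuous twin phenotype
#'
#' Draws pairs with the ACE covariance structure of `config`; the phenotype
#' is standardized (unit variance before mean effects) and stored in
#' `grade_<trait>` columns.
#'
#' @param config A [sim_config()].
#' @param trait Trait name for the output columns.
#' @return A `twin_pairs` table with `grade_<trait>_1/2` columns.
#' @export
simulate_continuous <- function(config, trait = "pheno") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, sim_frame(config, function(df, y) {
    df[[paste0("grade_", trait, "_1")]] <- y[, 1]
    df[[paste0("grade_", trait, "_2")]] <- y[, 2]
    df
  }))
}

#' Simulate a binary choice trait via the liability-threshold model
#'
#' A standardized ACE-structured liability is thresholded at the upper-K
#' standard-normal quantile, `K = config$prevalence`: choice = 1 iff
#' liability exceeds the threshold.
#'
#' @inheritParams simulate_continuous
#' @return A `twin_pairs` table with `choice_<trait>_1/2` columns.
#' @export
simulate_binary_choice <- function(config, trait = "choice") {
  stopifnot(inherits(config, "sim_config"))
  thr <- stats::qnorm(1 - config$prevalence)
  withr::with_seed(config$seed, sim_frame(config, function(df, y) {
    df[[paste0("choice_", trait, "_1")]] <- as.integer(y[, 1] > thr)
    df[[paste0("choice_", trait, "_2")]] <- as.integer(y[, 2] > thr)
    df
  }))
}

#' Simulate a cohort with choice-dependent achievement observation
#'
#' Emulates the structure of a national twin study of post-16 education:
#' every twin has a binary choice indicator (liability-threshold model at
#' prevalence `config$prevalence`, ACE structure `choice_a2`/`choice_c2`),
#' and an exam grade on the 1-6 scale is observed ONLY for twins who chose
#' (`choice == 1`). Selection into achievement is driven by the same
#' liability that determines choice, so the missingness is familial; the
#' grade phenotype itself is an independent ACE draw with the `config`
#' components, discretized around `grade_mean`/`grade_sd` and clipped to
#' \[1, 6\].
#'
#' @inheritParams simulate_continuous
#' @param trait Name shared by the choice indicator and the grade columns.
#' @param choice_a2,choice_c2 ACE proportions of the choice liability
#'   (defaults: moderate heritability 0.44 with an equally large shared
#'   environment 0.47, the structure reported for the choice to continue
#'   to A-levels).
#' @return A `twin_pairs` table with `choice_<trait>` and `grade_<trait>`
#'   columns; grades are NA for non-choosers.
#' @export
simulate_teds_like <- function(config = sim_config(), trait = "alevel",
                               choice_a2 = 0.44, choice_c2 = 0.47) {
  stopifnot(inherits(config, "sim_config"))
  choice_cfg <- config
  choice_cfg$a2_m <- choice_cfg$a2_f <- choice_a2
  choice_cfg$c2_m <- choice_cfg$c2_f <- choice_c2
  choice_cfg$e2_m <- choice_cfg$e2_f <- 1 - choice_a2 - choice_c2
  if (choice_cfg$e2_m < 0)
    stop("choice_a2 + choice_c2 must be <= 1", call. = FALSE)
  thr <- stats::qnorm(1 - config$prevalence)
  withr::with_seed(config$seed, sim_frame(config, function(df, y) {
    n <- nrow(df)
    zyg <- df$zygosity[1]
    liab <- sim_group_latents(n, zyg, choice_cfg)$y
    ch <- matrix(as.integer(liab > thr), n, 2)
    gr <- round(config$grade_mean + config$grade_sd * y)
    gr[] <- pmin(pmax(gr, 1), 6)
    gr[ch == 0] <- NA_real_
    df[[paste0("choice_", trait, "_1")]] <- ch[, 1]
    df[[paste0("choice_", trait, "_2")]] <- ch[, 2]
    df[[paste0("grade_", trait, "_1")]] <- gr[, 1]
    df[[paste0("grade_", trait, "_2")]] <- gr[, 2]
    df
  }))
}
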