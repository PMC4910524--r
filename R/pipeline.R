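# End-to-end orchestration: descriptive tables, liability fits for choice
# traits, continuous ACE fits for achievement among choosers, and a
# simulation-based power estimator.

#' Analysis configuration
#'
#' @param choice_traits Binary choice traits to analyze with the liability
#'   threshold model.
#' @param grade_traits Grade traits to analyze with the continuous ACE
#'   model on the chooser subset; every grade trait must have a same-named
#'   choice trait (selection into achievement follows choice).
#' @param recipe A [correction_recipe()] applied to each grade trait.
#' @param model Variance-component model to fit ("ACE" by default).
#' @param sex_limitation Also fit the five-group sex-limitation model per
#'   trait.
#' @param seed Integer seed driving the one-twin-per-pair selections.
#' @param conf_level Confidence level for all intervals.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(choice_traits = character(),
                            grade_traits = character(),
                            recipe = correction_recipe(),
                            model = "ACE",
                            sex_limitation = FALSE,
                            seed = 1L,
                            conf_level = 0.95) {
  if (!length(choice_traits) && !length(grade_traits))
    stop("at least one trait must be configured", call. = FALSE)
  structure(list(choice_traits = choice_traits,
                 grade_traits = grade_traits,
                 recipe = recipe, model = model,
                 sex_limitation = sex_limitation,
                 seed = as.integer(seed), conf_level = conf_level),
            class = "analysis_config")
}

#' Run the full twin analysis on a pair table
#'
#' For every configured choice trait: chooser counts, sex-difference
#' chi-square (one twin per pair), concordance summary, and the liability
#' ACE fit. For every grade trait: sex x zygosity ANOVA, phenotype
#' corrections per the recipe, twin correlations, Falconer decomposition,
#' and the continuous ACE ML fit on pairs where both twins have grades.
#' The result is deterministic given the config seed; a manifest records
#' the seed and package version so a run can be reproduced exactly.
#'
#' @param config An [analysis_config()].
#' @param data A `twin_pairs` object (e.g. from [read_twin_table()] or
#'   [simulate_teds_like()]).
#' @param out_dir Optional directory: component tables are written as CSV
#'   and the whole bundle as JSON.
#' @return A list of class `twin_analysis`: `choice` and `grade` blocks
#'   per trait, `components` (one tidy row per trait x component with CI),
#'   and `manifest`.
#' @export
run_full_analysis <- function(config, data, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (!inherits(data, "twin_pairs")) data <- twin_pairs(data)
  missing_traits <- c(
    setdiff(config$choice_traits, pair_traits(data, "choice")),
    setdiff(config$grade_traits, pair_traits(data, "grade")))
  for (tr in missing_traits)
    warning("trait '", tr, "' not found in data: skipped", call. = FALSE)
  choice_traits <- intersect(config$choice_traits,
                             pair_traits(data, "choice"))
  grade_traits <- intersect(config$grade_traits,
                            pair_traits(data, "grade"))
  if (!length(choice_traits) && !length(grade_traits))
    stop("no configured trait present in the data", call. = FALSE)
  bad_pairing <- setdiff(grade_traits, pair_traits(data, "choice"))
  if (length(bad_pairing))
    warning("grade trait(s) without a paired choice trait: ",
            paste(bad_pairing, collapse = ", "), call. = FALSE)
  choice <- list(); grade <- list(); rows <- list()
  for (tr in choice_traits) {
    fit <- fit_liability_ace(data, tr, config$model,
                             conf_level = config$conf_level)
    block <- list(
      counts = summarize_counts(data, tr),
      chisq_sex = chisq_one_per_pair(data, tr, config$seed),
      concordance = concordance_summary(data, tr),
      fit = fit)
    if (isTRUE(config$sex_limitation))
      block$sex_limitation <- fit_sex_limitation(data, tr,
                                                 type = "liability")
    choice[[tr]] <- block
    rows[[paste0("choice_", tr)]] <-
      cbind(trait = tr, scale = "liability", fit$components)
  }
  for (tr in grade_traits) {
    corrected <- apply_corrections(data, tr, config$recipe)
    fit <- fit_ace_ml(corrected, tr, config$model,
                      conf_level = config$conf_level)
    cors <- twin_correlations(corrected, tr, config$conf_level)
    rmz <- cors$r[cors$group == "MZ"]
    rdz <- cors$r[cors$group == "DZ"]
    block <- list(
      anova = anova_sex_zygosity(data, tr, config$seed),
      covariate_effects = attr(corrected, "effects"),
      correlations = cors,
      falconer = falconer_decomposition(rmz, rdz),
      fit = fit)
    if (isTRUE(config$sex_limitation))
      block$sex_limitation <- fit_sex_limitation(corrected, tr,
                                                 type = "continuous")
    grade[[tr]] <- block
    rows[[paste0("grade_", tr)]] <-
      cbind(trait = tr, scale = "continuous", fit$components)
  }
  components <- do.call(rbind, rows)
  rownames(components) <- NULL
  manifest <- list(seed = config$seed, model = config$model,
                   conf_level = config$conf_level,
                   choice_traits = choice_traits,
                   grade_traits = grade_traits,
                   n_pairs = nrow(data),
                   package_version =
                     as.character(utils::packageVersion("twinace")))
  result <- structure(list(choice = choice, grade = grade,
                           components = components, manifest = manifest),
                      class = "twin_analysis")
  if (!is.null(out_dir)) write_analysis_bundle(result, out_dir)
  result
}

write_analysis_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$components,
                   file.path(out_dir, "components.csv"), row.names = FALSE)
  for (tr in names(result$choice))
    utils::write.csv(result$choice[[tr]]$concordance,
                     file.path(out_dir, paste0("concordance_", tr, ".csv")),
                     row.names = FALSE)
  for (tr in names(result$grade))
    utils::write.csv(result$grade[[tr]]$correlations,
                     file.path(out_dir, paste0("correlations_", tr, ".csv")),
                     row.names = FALSE)
  bundle <- analysis_as_list(result)
  jsonlite::write_json(bundle, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# serializable view of a twin_analysis (used for the JSON bundle and for
# byte-identity checks between runs)
analysis_as_list <- function(result) {
  strip <- function(x) {
    if (inherits(x, "anova_report")) x <- x[setdiff(names(x), "anova_table")]
    if (is.list(x) && !is.data.frame(x)) return(lapply(unclass(x), strip))
    if (is.table(x)) return(as.data.frame(x))
    x
  }
  strip(list(choice = result$choice, grade = result$grade,
             components = result$components, manifest = result$manifest))
}

#' @export
print.twin_analysis <- function(x, ...) {
  cat("Twin analysis bundle\n")
  ct <- x$components
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %-12s %-10s %s = %.3f (95%% CI %.3f, %.3f)\n",
                ct$trait[i], ct$scale[i], ct$component[i], ct$estimate[i],
                ct$lower[i], ct$upper[i]))
  invisible(x)
}

#' Power of the twin design by simulation
#'
#' Simulates twin cohorts of continuous phenotypes under a generating ACE
#' model, tests the chosen component by a boundary-corrected likelihood-
#' ratio test at level `alpha`, and reports the rejection fraction with an
#' exact binomial CI.
#'
#' @param a2,c2 Generating standardized components (e2 = 1 - a2 - c2).
#' @param n_mz,n_dz Pairs per zygosity stratum per replicate.
#' @param test Component whose absence is tested: "A" (AE vs E when c2 is
#'   absent, otherwise ACE vs CE) or "C" (ACE vs AE).
#' @param alpha Test level.
#' @param replicates Number of simulated cohorts (>= 50).
#' @param seed Integer seed.
#' @return A list of class `power_estimate`: `power`, `ci`, `rejections`,
#'   `replicates`, `test`, `alpha`.
#' @export
power_by_simulation <- function(a2, c2, n_mz = 1000, n_dz = 1000,
                                test = c("A", "C"), alpha = 0.05,
                                replicates = 200, seed = 1L) {
  test <- match.arg(test)
  if (replicates < 50)
    stop("need at least 50 replicates for a stable power estimate",
         call. = FALSE)
  if (a2 < 0 || c2 < 0 || a2 + c2 > 1)
    stop("generating model must satisfy a2, c2 >= 0 and a2 + c2 <= 1",
         call. = FALSE)
  if (test == "A" && a2 + c2 >= 1 - 1e-9 && a2 == 0)
    stop("degenerate generating model for testing A", call. = FALSE)
  full_model <- if (test == "C") "ACE" else "ACE"
  reduced_model <- if (test == "C") "AE" else "CE"
  seeds <- seed + seq_len(replicates) - 1L
  rejections <- 0L
  for (i in seq_len(replicates)) {
    cfg <- sim_config(pairs = c(MZm = ceiling(n_mz / 2),
                                MZf = floor(n_mz / 2),
                                DZm = ceiling(n_dz / 2),
                                DZf = floor(n_dz / 2)),
                      a2 = a2, c2 = c2, seed = seeds[i])
    sim <- simulate_continuous(cfg, trait = "y")
    full <- fit_ace_ml(sim, "y", full_model, ci = character(0))
    reduced <- fit_ace_ml(sim, "y", reduced_model, ci = character(0))
    lrt <- likelihood_ratio_test(full, reduced)
    if (lrt$p_boundary < alpha) rejections <- rejections + 1L
  }
  bt <- stats::binom.test(rejections, replicates)
  structure(list(power = rejections / replicates,
                 ci = unname(bt$conf.int), rejections = rejections,
                 replicates = replicates, test = test, alpha = alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "Power to detect %s at alpha = %.2g: %.3f (95%% CI %.3f, %.3f; %d/%d replicates)\n",
    x$test, x$alpha, x$power, x$ci[1], x$ci[2], x$rejections,
    x$replicates))
  invisible(x)
}
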