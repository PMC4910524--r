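# Univariate ACE models for continuous twin phenotypes.
#
# Likelihood: within each zygosity stratum the pair phenotypes are
# bivariate normal with common mean mu and variance v = a^2 + c^2 + e^2,
# and cross-twin covariance gamma * a^2 + c^2 (gamma = 1 for MZ, 0.5 for
# DZ, including opposite-sex pairs in combined-sex fits). The likelihood
# depends on the data only through per-stratum sufficient statistics, so
# fits cost O(1) in the number of pairs after one pass over the data.

#' Falconer variance decomposition from twin correlations
#'
#' The quick moment estimator: heritability a2 = 2(rMZ - rDZ); shared
#' environment c2 = rMZ - a2; non-shared environment e2 = 1 - rMZ.
#' Values outside \[0, 1\] are returned as-is with `out_of_bounds = TRUE`
#' (no silent truncation).
#'
#' @param rMZ,rDZ Twin correlations for MZ and DZ pairs, in \[-1, 1\].
#' @return A list of class `falconer`: `a2`, `c2`, `e2`, `out_of_bounds`.
#' @export
falconer_decomposition <- function(rMZ, rDZ) {
  stopifnot(abs(rMZ) <= 1, abs(rDZ) <= 1)
  a2 <- 2 * (rMZ - rDZ)
  c2 <- rMZ - a2
  e2 <- 1 - rMZ
  comps <- c(a2 = a2, c2 = c2, e2 = e2)
  structure(list(a2 = a2, c2 = c2, e2 = e2,
                 out_of_bounds = any(comps < 0 | comps > 1)),
            class = "falconer")
}

#' @export
print.falconer <- function(x, ...) {
  cat(sprintf("Falconer decomposition: a2 = %.3f, c2 = %.3f, e2 = %.3f%s\n",
              x$a2, x$c2, x$e2,
              if (x$out_of_bounds) " [out of bounds]" else ""))
  invisible(x)
}

#' Per-group twin correlations for a continuous trait
#'
#' Intraclass-type correlations: within each group the mean and variance
#' are pooled over both twins (twin order is arbitrary), and the
#' correlation is the cross-twin covariance over the pooled variance.
#' CIs use the Fisher z approximation with n = pairs.
#'
#' @param pairs A `twin_pairs` object.
#' @param trait Grade trait name.
#' @param conf_level Confidence level for the Fisher-z CI.
#' @return Data frame with one row per zygosity group present plus pooled
#'   `MZ` and `DZ` rows: `group`, `n`, `r`, `lower`, `upper`.
#' @export
twin_correlations <- function(pairs, trait, conf_level = 0.95) {
  g <- pair_values(pairs, trait, "grade")
  ok <- stats::complete.cases(g)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  one <- function(sel) {
    n <- sum(sel)
    if (n < 3) return(c(n = n, r = NA, lower = NA, upper = NA))
    x <- g[sel, , drop = FALSE]
    m <- mean(x); s2 <- mean((x - m)^2)
    r <- mean((x[, 1] - m) * (x[, 2] - m)) / s2
    z <- atanh(min(max(r, -0.9999), 0.9999))
    ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
    c(n = n, r = r, lower = ci[1], upper = ci[2])
  }
  groups <- c(zygosity_levels(), "MZ", "DZ")
  rows <- lapply(groups, function(gr) {
    sel <- ok & switch(gr,
      MZ = substr(pairs$zygosity, 1, 2) == "MZ",
      DZ = substr(pairs$zygosity, 1, 2) == "DZ",
      pairs$zygosity == gr)
    one(sel)
  })
  out <- data.frame(group = groups, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  out[out$n > 0, , drop = FALSE]
}

# per-stratum sufficient statistics: n, S1 = sum(x1 + x2),
# S2 = sum(x1^2 + x2^2), S12 = sum(x1 * x2)
ace_suffstats <- function(pairs, trait) {
  g <- pair_values(pairs, trait, "grade")
  ok <- stats::complete.cases(g)
  gam <- zygosity_gamma(pairs$zygosity)
  out <- lapply(c(MZ = 1, DZ = 0.5), function(gamma) {
    x <- g[ok & gam == gamma, , drop = FALSE]
    list(gamma = gamma, n = nrow(x),
         S1 = sum(x), S2 = sum(x^2), S12 = sum(x[, 1] * x[, 2]))
  })
  out[vapply(out, function(s) s$n > 0, logical(1))]
}

# negative log-likelihood from sufficient statistics
ace_negll_stats <- function(mu, v, cov_of_gamma, stats_list) {
  nll <- 0
  for (s in stats_list) {
    cv <- cov_of_gamma(s$gamma)
    det <- v^2 - cv^2
    if (!is.finite(det) || det <= 0 || v <= 0) return(1e10)
    Q <- (v * (s$S2 - 2 * mu * s$S1 + 2 * s$n * mu^2) -
            2 * cv * (s$S12 - mu * s$S1 + s$n * mu^2)) / det
    nll <- nll + s$n * log(2 * pi) + s$n * log(det) / 2 + Q / 2
  }
  nll
}

ace_model_letters <- function(model) {
  switch(model, ACE = c("a", "c", "e"), AE = c("a", "e"),
         CE = c("c", "e"), E = "e",
         stop("model must be one of ACE, AE, CE, E", call. = FALSE))
}

# paths (a, c, e) with zeros for components absent from the model
ace_expand_paths <- function(par_paths, letters) {
  p <- c(a = 0, c = 0, e = 0)
  p[letters] <- par_paths
  p
}

#' Maximum-likelihood ACE model for a continuous trait
#'
#' Fits the chosen variance-component model by ML over the MZ (gamma = 1)
#' and DZ (gamma = 0.5; opposite-sex pairs pooled with same-sex DZ) strata
#' with a common mean and total variance, maximizing over nonnegative path
#' coefficients from five deterministic starts spanning the variance
#' simplex (ties broken toward the lowest a2). Standardized components
#' a2 + c2 + e2 = 1 are reported with profile-likelihood CIs (bisection on
#' the likelihood-ratio boundary).
#'
#' @param pairs A `twin_pairs` object; complete pairs only enter the fit.
#' @param trait Grade trait name.
#' @param model "ACE", "AE", "CE" or "E".
#' @param ci Components to compute profile CIs for (subset of
#'   `c("a2","c2","e2")`); `character(0)` skips CIs (fast, e.g. inside
#'   simulations).
#' @param conf_level Confidence level.
#' @return An object of class `ace_fit`: `model`, `trait`, `loglik`,
#'   `npar`, `n_pairs` (per stratum), `convergence`, `mean`, `variance`,
#'   `paths`, and `components` (data frame with estimate/lower/upper).
#' @export
fit_ace_ml <- function(pairs, trait, model = c("ACE", "AE", "CE", "E"),
                       ci = c("a2", "c2", "e2"), conf_level = 0.95) {
  model <- match.arg(model)
  if (length(ci)) ci <- match.arg(ci, c("a2", "c2", "e2"), several.ok = TRUE)
  st <- ace_suffstats(pairs, trait)
  gammas <- vapply(st, function(s) s$gamma, numeric(1))
  if (!any(gammas == 1) || !any(gammas == 0.5))
    stop("need both an MZ-type and a DZ-type stratum with complete pairs",
         call. = FALSE)
  if (any(vapply(st, function(s) s$n, numeric(1)) < 20))
    warning("fewer than 20 complete pairs in a stratum: estimates will be imprecise",
            call. = FALSE)
  n_tot <- sum(vapply(st, function(s) s$n, numeric(1)))
  mu0 <- sum(vapply(st, function(s) s$S1, numeric(1))) / (2 * n_tot)
  v0 <- sum(vapply(st, function(s) s$S2, numeric(1))) / (2 * n_tot) - mu0^2
  letters <- ace_model_letters(model)
  negll_par <- function(par) {
    paths <- ace_expand_paths(par[-1], letters)
    v <- sum(paths^2)
    ace_negll_stats(par[1], v,
                    function(g) g * paths["a"]^2 + paths["c"]^2, st)
  }
  start_props <- list(c(a = 1, c = 1, e = 1) / 3,
                      c(a = .6, c = .2, e = .2),
                      c(a = .2, c = .6, e = .2),
                      c(a = .2, c = .2, e = .6),
                      c(a = .05, c = .05, e = .9))
  best <- NULL
  for (pr in start_props) {
    pr <- pr[letters] / sum(pr[letters])
    start <- c(mu0, sqrt(pr * v0))
    op <- stats::optim(start, negll_par, method = "L-BFGS-B",
                       lower = c(-Inf, rep(0, length(letters))),
                       control = list(maxit = 500, factr = 1e4))
    op$a2 <- ace_expand_paths(op$par[-1], letters)[["a"]]^2 /
      sum(ace_expand_paths(op$par[-1], letters)^2)
    if (is.null(best) || op$value < best$value - 1e-8 ||
        (abs(op$value - best$value) <= 1e-8 && op$a2 < best$a2)) best <- op
  }
  paths <- ace_expand_paths(best$par[-1], letters)
  v <- sum(paths^2)
  comps <- paths^2 / v
  names(comps) <- c("a2", "c2", "e2")
  ll <- -best$value
  crit <- ll - stats::qchisq(conf_level, 1) / 2
  comp_tab <- data.frame(component = c("a2", "c2", "e2"),
                         estimate = unname(comps),
                         lower = NA_real_, upper = NA_real_,
                         stringsAsFactors = FALSE)
  for (comp in ci) {
    i <- match(comp, comp_tab$component)
    letter <- substr(comp, 1, 1)
    if (!(letter %in% letters)) {  # pinned at zero by the model
      comp_tab$lower[i] <- 0; comp_tab$upper[i] <- 0
      next
    }
    prof <- function(p) -ace_profile_negll(p, comp, st, model,
                                           mu0 = best$par[1], v0 = v,
                                           q0 = ace_split_q(comps, comp))
    comp_tab$lower[i] <- profile_bound(prof, comps[[comp]], crit,
                                       lower_limit = 0, upper = FALSE)
    comp_tab$upper[i] <- profile_bound(prof, comps[[comp]], crit,
                                       upper_limit = 1, upper = TRUE)
  }
  structure(list(model = model, trait = trait, loglik = ll,
                 npar = 1L + length(letters),
                 n_pairs = stats::setNames(
                   vapply(st, function(s) s$n, numeric(1)),
                   ifelse(gammas == 1, "MZ", "DZ")),
                 convergence = best$convergence == 0,
                 mean = best$par[1], variance = v,
                 paths = paths, components = comp_tab),
            class = "ace_fit")
}

# proportion of the non-profiled variance assigned to the first remaining
# component, used as a starting value for profile re-optimization
ace_split_q <- function(comps, comp) {
  others <- setdiff(c("a2", "c2", "e2"), comp)
  rest <- comps[others[1]] + comps[others[2]]
  if (rest > 1e-10) comps[[others[1]]] / rest else 0.5
}

# minimized negative log-likelihood with the standardized component `comp`
# fixed at proportion p; free parameters are the mean, the log total
# variance, and (when two other components are free) the split q.
ace_profile_negll <- function(p, comp, st, model, mu0, v0, q0) {
  letters <- ace_model_letters(model)
  comp_letter <- substr(comp, 1, 1)
  others <- setdiff(c("a", "c", "e"), comp_letter)
  free_others <- intersect(others, letters)
  obj <- function(par) {
    mu <- par[1]; v <- exp(par[2])
    q <- if (length(free_others) == 2) min(max(par[3], 0), 1)
         else if (length(free_others) == 1 && free_others == others[1]) 1
         else 0
    prop <- c(a = 0, c = 0, e = 0)
    prop[comp_letter] <- p
    prop[others[1]] <- q * (1 - p)
    prop[others[2]] <- (1 - q) * (1 - p)
    ace_negll_stats(mu, v,
                    function(g) (g * prop["a"] + prop["c"]) * v, st)
  }
  start <- c(mu0, log(max(v0, 1e-8)))
  if (length(free_others) == 2) start <- c(start, q0)
  op <- stats::optim(start, obj, method = "L-BFGS-B",
                     lower = c(-Inf, -Inf, if (length(start) == 3) 0),
                     upper = c(Inf, Inf, if (length(start) == 3) 1),
                     control = list(maxit = 300, factr = 1e5))
  op$value
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s model for '%s' (%s pairs): loglik = %.2f\n",
              x$model, x$trait,
              paste(sprintf("%d %s", x$n_pairs, names(x$n_pairs)),
                    collapse = " + "), x$loglik))
  ct <- x$components
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %s = %.3f%s\n", ct$component[i], ct$estimate[i],
                if (is.na(ct$lower[i])) ""
                else sprintf(" (95%% CI %.3f, %.3f)", ct$lower[i],
                             ct$upper[i])))
  invisible(x)
}

ace_nesting <- list(
  ACE = c("AE", "CE", "E"), AE = "E", CE = "E",
  full = c("qualitative_constrained", "quantitative_equal", "homogeneous"),
  qualitative_constrained = c("quantitative_equal", "homogeneous"),
  quantitative_equal = "homogeneous")

# models whose reduction pins a variance component at a zero boundary
ace_boundary_pair <- function(full, reduced) {
  full %in% c("ACE", "AE", "CE") && reduced %in% c("AE", "CE", "E")
}

#' Likelihood-ratio test between nested twin-model fits
#'
#' Statistic 2(ll_full - ll_reduced) compared to a chi-square with df equal
#' to the parameter-count difference. When the reduced model pins a
#' variance component at its zero boundary the naive chi-square is
#' conservative; a boundary-corrected p from the 50:50 mixture of
#' chi-square(df) and chi-square(df - 1) is reported alongside.
#'
#' @param full,reduced Fits with `loglik`, `npar` and `model` fields
#'   ([fit_ace_ml()], [fit_liability_ace()], or one element of a
#'   [fit_sex_limitation()] chain); `reduced` must be nested in `full` and
#'   fitted to the same data.
#' @param alpha Level used to label the preferred model.
#' @param boundary Force the boundary interpretation; default guesses from
#'   the model labels.
#' @return A list of class `lrt_result`: `statistic`, `df`, `p_value`
#'   (naive), `p_boundary` (mixture), `boundary`, `preferred`.
#' @export
likelihood_ratio_test <- function(full, reduced, alpha = 0.05,
                                  boundary = NULL) {
  if (identical(full$model, reduced$model)) {
    if (abs(full$loglik - reduced$loglik) > 1e-6)
      stop("same model label but different log-likelihoods", call. = FALSE)
    return(structure(list(statistic = 0, df = 0L, p_value = 1,
                          p_boundary = 1, boundary = FALSE,
                          preferred = reduced$model),
                     class = "lrt_result"))
  }
  allowed <- ace_nesting[[full$model]]
  if (is.null(allowed) || !(reduced$model %in% allowed))
    stop("'", reduced$model, "' is not nested in '", full$model, "'",
         call. = FALSE)
  if (!is.null(full$n_pairs) && !is.null(reduced$n_pairs) &&
      sum(full$n_pairs) != sum(reduced$n_pairs))
    stop("fits use different numbers of pairs", call. = FALSE)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$npar - reduced$npar
  if (df <= 0) stop("reduced model must have fewer parameters", call. = FALSE)
  pchisq_up <- function(q, d) {
    if (d <= 0) return(as.numeric(q <= 1e-12))
    stats::pchisq(q, d, lower.tail = FALSE)
  }
  p_naive <- pchisq_up(stat, df)
  p_mix <- 0.5 * pchisq_up(stat, df) + 0.5 * pchisq_up(stat, df - 1)
  if (is.null(boundary)) boundary <- ace_boundary_pair(full$model,
                                                       reduced$model)
  p_use <- if (boundary) p_mix else p_naive
  structure(list(statistic = stat, df = df, p_value = p_naive,
                 p_boundary = p_mix, boundary = boundary,
                 preferred = if (p_use < alpha) full$model
                             else reduced$model),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "LRT: chi2 = %.3f, df = %d, p = %.4g%s; preferred model: %s\n",
    x$statistic, x$df, x$p_value,
    if (x$boundary) sprintf(" (boundary-corrected p = %.4g)", x$p_boundary)
    else "", x$preferred))
  invisible(x)
}
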