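# Five-group sex-limitation models: sex-specific ACE components with the
# DZ opposite-sex group informing qualitative sex differences through the
# cross-sex genetic correlation rg (expected 0.5) or shared-environment
# correlation rc (expected 1.0). Works on continuous phenotypes (bivariate
# normal likelihood per group) and on binary choice traits (liability
# threshold, multinomial likelihood per group's concordance table).

SEXLIM_MODELS <- c("full", "qualitative_constrained", "quantitative_equal",
                   "homogeneous")

sexlim_stats_cont <- function(pairs, trait) {
  g <- pair_values(pairs, trait, "grade")
  ok <- stats::complete.cases(g)
  same <- lapply(c("MZm", "MZf", "DZm", "DZf"), function(z) {
    x <- g[ok & pairs$zygosity == z, , drop = FALSE]
    list(group = z, sex = zyg_sexes(z)[1], gamma = zygosity_gamma(z),
         n = nrow(x), S1 = sum(x), S2 = sum(x^2),
         S12 = sum(x[, 1] * x[, 2]))
  })
  sel <- ok & pairs$zygosity == "DZos"
  x <- g[sel, , drop = FALSE]
  # orient DZos pairs male-first regardless of storage order
  flip <- pairs$sex1[sel] == "F"
  xm <- ifelse(flip, x[, 2], x[, 1])
  xf <- ifelse(flip, x[, 1], x[, 2])
  dzos <- list(n = length(xm), Sm = sum(xm), Smm = sum(xm^2),
               Sf = sum(xf), Sff = sum(xf^2), Smf = sum(xm * xf))
  list(same = same, dzos = dzos)
}

sexlim_tables_liab <- function(pairs, trait) {
  ch <- pair_values(pairs, trait, "choice")
  same <- lapply(c("MZm", "MZf", "DZm", "DZf"), function(z) {
    list(group = z, sex = zyg_sexes(z)[1], gamma = zygosity_gamma(z),
         counts = conc_counts(ch, pairs$zygosity == z))
  })
  sel <- pairs$zygosity == "DZos"
  x <- ch[sel & stats::complete.cases(ch), , drop = FALSE]
  flip <- pairs$sex1[sel & stats::complete.cases(ch)] == "F"
  cm <- ifelse(flip, x[, 2], x[, 1])
  cf <- ifelse(flip, x[, 1], x[, 2])
  dzos <- c(n11 = sum(cm == 1 & cf == 1), n10 = sum(cm == 1 & cf == 0),
            n01 = sum(cm == 0 & cf == 1), n00 = sum(cm == 0 & cf == 0))
  list(same = same, dzos = dzos)
}

# continuous negative log-likelihood for a full parameter set
# par: list(mu_m, mu_f, paths_m = c(a,c,e), paths_f, rg, rc)
sexlim_negll_cont <- function(par, st) {
  nll <- 0
  for (s in st$same) {
    if (s$n == 0) next
    p <- if (s$sex == "M") par$paths_m else par$paths_f
    mu <- if (s$sex == "M") par$mu_m else par$mu_f
    v <- sum(p^2)
    cv <- s$gamma * p[1]^2 + p[2]^2
    det <- v^2 - cv^2
    if (!is.finite(det) || det <= 0 || v <= 0) return(1e10)
    Q <- (v * (s$S2 - 2 * mu * s$S1 + 2 * s$n * mu^2) -
            2 * cv * (s$S12 - mu * s$S1 + s$n * mu^2)) / det
    nll <- nll + s$n * log(2 * pi) + s$n * log(det) / 2 + Q / 2
  }
  d <- st$dzos
  if (d$n > 0) {
    pm <- par$paths_m; pf <- par$paths_f
    vm <- sum(pm^2); vf <- sum(pf^2)
    w <- par$rg * pm[1] * pf[1] + par$rc * pm[2] * pf[2]
    det <- vm * vf - w^2
    if (!is.finite(det) || det <= 0 || vm <= 0 || vf <= 0) return(1e10)
    Qmm <- d$Smm - 2 * par$mu_m * d$Sm + d$n * par$mu_m^2
    Qff <- d$Sff - 2 * par$mu_f * d$Sf + d$n * par$mu_f^2
    Qmf <- d$Smf - par$mu_m * d$Sf - par$mu_f * d$Sm +
      d$n * par$mu_m * par$mu_f
    Q <- (vf * Qmm - 2 * w * Qmf + vm * Qff) / det
    nll <- nll + d$n * log(2 * pi) + d$n * log(det) / 2 + Q / 2
  }
  nll
}

# liability negative log-likelihood
# par: list(t_m, t_f, prop_m = c(a2, c2), prop_f, rg, rc)
sexlim_negll_liab <- function(par, tb) {
  nll <- 0
  for (s in tb$same) {
    if (sum(s$counts) == 0) next
    pr <- if (s$sex == "M") par$prop_m else par$prop_f
    t <- if (s$sex == "M") par$t_m else par$t_f
    r <- min(s$gamma * pr[1] + pr[2], 1 - 1e-9)
    p <- bvn_cell_probabilities(r, t, t)
    nll <- nll - sum(s$counts * log(pmax(p, 1e-300)))
  }
  d <- tb$dzos
  if (sum(d) > 0) {
    pm <- par$prop_m; pf <- par$prop_f
    r <- par$rg * sqrt(pm[1] * pf[1]) + par$rc * sqrt(pm[2] * pf[2])
    r <- min(max(r, -1 + 1e-9), 1 - 1e-9)
    p <- bvn_cell_probabilities(r, par$t_m, par$t_f)
    nll <- nll - sum(d * log(pmax(p, 1e-300)))
  }
  nll
}

# parameterization of each nested model (continuous scale):
# returns list(n_par, lower, upper, start(s), unpack(par_vec) -> par list)
sexlim_model_def_cont <- function(model, free, base) {
  fixed_rg <- 0.5; fixed_rc <- 1
  unpack_r <- function(r_free) {
    if (free == "rg") list(rg = r_free, rc = fixed_rc)
    else list(rg = fixed_rg, rc = r_free)
  }
  p0 <- base$paths; mu0 <- base$mu
  r0 <- if (free == "rg") 0.5 else 1
  switch(model,
    full = list(
      npar = 9L,
      lower = c(-Inf, -Inf, rep(0, 6), 0), upper = c(rep(Inf, 8), 1),
      starts = lapply(c(r0, 0.25, 0.9), function(r)
        c(mu0, mu0, p0, p0 * 1.05, min(r, 1))),
      unpack = function(x) c(list(mu_m = x[1], mu_f = x[2],
                                  paths_m = x[3:5], paths_f = x[6:8]),
                             unpack_r(x[9]))),
    qualitative_constrained = list(
      npar = 8L,
      lower = c(-Inf, -Inf, rep(0, 6)), upper = rep(Inf, 8),
      starts = list(c(mu0, mu0, p0, p0 * 1.05), c(mu0, mu0, p0 * 0.8, p0)),
      unpack = function(x) list(mu_m = x[1], mu_f = x[2],
                                paths_m = x[3:5], paths_f = x[6:8],
                                rg = fixed_rg, rc = fixed_rc)),
    quantitative_equal = list(
      npar = 5L,
      lower = c(-Inf, -Inf, rep(0, 3)), upper = rep(Inf, 5),
      starts = list(c(mu0, mu0, p0), c(mu0, mu0, rev(p0))),
      unpack = function(x) list(mu_m = x[1], mu_f = x[2],
                                paths_m = x[3:5], paths_f = x[3:5],
                                rg = fixed_rg, rc = fixed_rc)),
    homogeneous = list(
      npar = 4L,
      lower = c(-Inf, rep(0, 3)), upper = rep(Inf, 4),
      starts = list(c(mu0, p0), c(mu0, rev(p0))),
      unpack = function(x) list(mu_m = x[1], mu_f = x[1],
                                paths_m = x[2:4], paths_f = x[2:4],
                                rg = fixed_rg, rc = fixed_rc)))
}

# liability-scale counterpart; components parameterized as (pa, q) with
# c2 = q * (1 - pa), keeping a2 + c2 <= 1 inside box constraints
sexlim_model_def_liab <- function(model, free, base) {
  fixed_rg <- 0.5; fixed_rc <- 1
  unpack_r <- function(r_free) {
    if (free == "rg") list(rg = r_free, rc = fixed_rc)
    else list(rg = fixed_rg, rc = r_free)
  }
  prop2 <- function(pa, q) c(pa, q * (1 - pa))
  t0 <- base$t; pa0 <- base$pa; q0 <- base$q
  r0 <- if (free == "rg") 0.5 else 1
  switch(model,
    full = list(
      npar = 7L,
      lower = c(-Inf, -Inf, rep(0, 4), 0), upper = c(Inf, Inf, rep(1, 5)),
      starts = lapply(c(r0, 0.25, 0.9), function(r)
        c(t0, t0, pa0, q0, pa0, q0, min(r, 1))),
      unpack = function(x) c(list(t_m = x[1], t_f = x[2],
                                  prop_m = prop2(x[3], x[4]),
                                  prop_f = prop2(x[5], x[6])),
                             unpack_r(x[7]))),
    qualitative_constrained = list(
      npar = 6L,
      lower = c(-Inf, -Inf, rep(0, 4)), upper = c(Inf, Inf, rep(1, 4)),
      starts = list(c(t0, t0, pa0, q0, pa0, q0),
                    c(t0, t0, 0.3, 0.5, 0.3, 0.5)),
      unpack = function(x) list(t_m = x[1], t_f = x[2],
                                prop_m = prop2(x[3], x[4]),
                                prop_f = prop2(x[5], x[6]),
                                rg = fixed_rg, rc = fixed_rc)),
    quantitative_equal = list(
      npar = 4L,
      lower = c(-Inf, -Inf, 0, 0), upper = c(Inf, Inf, 1, 1),
      starts = list(c(t0, t0, pa0, q0), c(t0, t0, 0.3, 0.5)),
      unpack = function(x) list(t_m = x[1], t_f = x[2],
                                prop_m = prop2(x[3], x[4]),
                                prop_f = prop2(x[3], x[4]),
                                rg = fixed_rg, rc = fixed_rc)),
    homogeneous = list(
      npar = 3L,
      lower = c(-Inf, 0, 0), upper = c(Inf, 1, 1),
      starts = list(c(t0, pa0, q0), c(t0, 0.3, 0.5)),
      unpack = function(x) list(t_m = x[1], t_f = x[1],
                                prop_m = prop2(x[2], x[3]),
                                prop_f = prop2(x[2], x[3]),
                                rg = fixed_rg, rc = fixed_rc)))
}

std_comps <- function(paths) {
  v <- sum(paths^2)
  stats::setNames(paths^2 / v, c("a2", "c2", "e2"))
}

#' Five-group sex-limitation model
#'
#' Fits a chain of nested models over the five zygosity groups (MZm, MZf,
#' DZm, DZf, DZos): `full` (sex-specific components and means/thresholds
#' with the chosen cross-sex correlation free), `qualitative_constrained`
#' (rg fixed at 0.5, or rc at 1.0 — the values expected when the same
#' factors operate in both sexes), `quantitative_equal` (male and female
#' components equated), and `homogeneous` (means/thresholds equated too).
#' Likelihood-ratio tests of each reduction against the full model form
#' the qualitative and quantitative tests of sex differences.
#'
#' Exactly one cross-sex correlation is free in the full model (`free`):
#' rg and rc are not jointly identified from twin data.
#'
#' @param pairs A `twin_pairs` object containing all five zygosity groups.
#' @param trait Trait name; continuous (grade columns) or binary (choice
#'   columns), chosen automatically unless `type` is given.
#' @param free Which DZos cross-sex correlation to estimate: "rg" (genetic,
#'   rc fixed at 1) or "rc" (shared-environment, rg fixed at 0.5).
#' @param type "continuous" or "liability"; default inferred from the
#'   available columns.
#' @param models Subset of the four model labels to fit ("full" is always
#'   included).
#' @param ci Sex-specific heritabilities to compute profile CIs for in the
#'   full model: subset of `c("a2_m", "a2_f")`; `character(0)` skips them.
#' @param conf_level Confidence level.
#' @return An object of class `sexlim_fit`: `estimates` (a2/c2/e2 per sex
#'   from the full model, with any profile CIs), `r_free` (rg or rc
#'   estimate), `fits` (per-model loglik/npar/parameters), and
#'   `lrt_chain` (each reduction tested against the full model).
#' @export
fit_sex_limitation <- function(pairs, trait, free = c("rg", "rc"),
                               type = NULL, models = SEXLIM_MODELS,
                               ci = c("a2_m", "a2_f"),
                               conf_level = 0.95) {
  free <- match.arg(free)
  models <- union("full", match.arg(models, SEXLIM_MODELS,
                                    several.ok = TRUE))
  if (!any(pairs$zygosity == "DZos"))
    stop("sex-limitation model requires DZ opposite-sex pairs",
         call. = FALSE)
  if (length(ci)) ci <- match.arg(ci, c("a2_m", "a2_f"), several.ok = TRUE)
  if (is.null(type)) {
    type <- if (trait %in% pair_traits(pairs, "grade")) "continuous"
            else "liability"
  }
  type <- match.arg(type, c("continuous", "liability"))
  counts <- table(factor(pairs$zygosity, levels = zygosity_levels()))
  if (any(counts < 20))
    warning("fewer than 20 pairs in some zygosity group: the sex-limitation ",
            "analysis is underpowered", call. = FALSE)
  if (type == "continuous") {
    st <- sexlim_stats_cont(pairs, trait)
    negll <- function(par) sexlim_negll_cont(par, st)
    pooled <- fit_ace_ml(pairs, trait, "ACE", ci = character(0))
    base <- list(mu = pooled$mean, paths = unname(pooled$paths))
    model_def <- function(m) sexlim_model_def_cont(m, free, base)
  } else {
    st <- sexlim_tables_liab(pairs, trait)
    negll <- function(par) sexlim_negll_liab(par, st)
    pooled <- fit_liability_ace(pairs, trait, "ACE", ci = character(0))
    cp <- pooled$components$estimate
    base <- list(t = pooled$threshold, pa = cp[1],
                 q = if (cp[2] + cp[3] > 1e-10) cp[2] / (cp[2] + cp[3])
                     else 0.5)
    model_def <- function(m) sexlim_model_def_liab(m, free, base)
  }
  n_pairs <- stats::setNames(as.integer(counts), names(counts))
  fits <- list()
  for (m in models) {
    def <- model_def(m)
    best <- NULL
    for (s0 in def$starts) {
      op <- stats::optim(s0, function(x) negll(def$unpack(x)),
                         method = "L-BFGS-B",
                         lower = def$lower, upper = def$upper,
                         control = list(maxit = 1000, factr = 1e5))
      if (is.null(best) || op$value < best$value - 1e-8) best <- op
    }
    par <- def$unpack(best$par)
    fits[[m]] <- list(model = m, loglik = -best$value, npar = def$npar,
                      n_pairs = n_pairs,
                      convergence = best$convergence == 0, par = par)
  }
  fullfit <- fits[["full"]]
  par <- fullfit$par
  if (type == "continuous") {
    comps_m <- std_comps(par$paths_m)
    comps_f <- std_comps(par$paths_f)
    location <- c(mu_m = par$mu_m, mu_f = par$mu_f)
  } else {
    comps_m <- c(a2 = par$prop_m[1], c2 = par$prop_m[2],
                 e2 = 1 - sum(par$prop_m))
    comps_f <- c(a2 = par$prop_f[1], c2 = par$prop_f[2],
                 e2 = 1 - sum(par$prop_f))
    location <- c(t_m = par$t_m, t_f = par$t_f)
  }
  est <- data.frame(component = rep(c("a2", "c2", "e2"), 2),
                    sex = rep(c("M", "F"), each = 3),
                    estimate = c(unname(comps_m), unname(comps_f)),
                    lower = NA_real_, upper = NA_real_,
                    stringsAsFactors = FALSE)
  crit <- fullfit$loglik - stats::qchisq(conf_level, 1) / 2
  for (which_ci in ci) {
    sex <- toupper(substr(which_ci, 4, 4))
    i <- which(est$component == "a2" & est$sex == sex)
    a2_hat <- est$estimate[i]
    prof <- function(p) -sexlim_profile_negll(p, sex, type, free, st,
                                              fullfit$par, negll)
    est$lower[i] <- profile_bound(prof, a2_hat, crit,
                                  lower_limit = 0, upper = FALSE)
    est$upper[i] <- profile_bound(prof, a2_hat, crit,
                                  upper_limit = 1, upper = TRUE)
  }
  chain <- lapply(setdiff(names(fits), "full"), function(m)
    data.frame(model = m,
               loglik = fits[[m]]$loglik, npar = fits[[m]]$npar,
               statistic = max(0, 2 * (fullfit$loglik - fits[[m]]$loglik)),
               df = fullfit$npar - fits[[m]]$npar,
               p_value = stats::pchisq(
                 max(0, 2 * (fullfit$loglik - fits[[m]]$loglik)),
                 fullfit$npar - fits[[m]]$npar, lower.tail = FALSE),
               stringsAsFactors = FALSE))
  chain <- rbind(data.frame(model = "full", loglik = fullfit$loglik,
                            npar = fullfit$npar, statistic = NA_real_,
                            df = NA_integer_, p_value = NA_real_,
                            stringsAsFactors = FALSE),
                 do.call(rbind, chain))
  structure(list(trait = trait, type = type, free = free,
                 estimates = est, location = location,
                 r_free = unname(if (free == "rg") par$rg else par$rc),
                 fits = fits, lrt_chain = chain, n_pairs = n_pairs),
            class = "sexlim_fit")
}

# profile over the standardized a2 of one sex in the full model: that
# sex's variance is reparameterized as (scale, split) with a2 fixed at p,
# everything else stays free
sexlim_profile_negll <- function(p, sex, type, free, st, par_hat, negll) {
  if (type == "continuous") {
    paths_fix <- if (sex == "M") par_hat$paths_m else par_hat$paths_f
    v0 <- sum(paths_fix^2)
    c2 <- paths_fix[2]^2 / v0; e2 <- paths_fix[3]^2 / v0
    q0 <- if (c2 + e2 > 1e-10) c2 / (c2 + e2) else 0.5
    other <- if (sex == "M") par_hat$paths_f else par_hat$paths_m
    r0 <- if (free == "rg") par_hat$rg else par_hat$rc
    obj <- function(x) {
      v <- exp(x[3]); q <- x[4]
      paths <- sqrt(c(p, q * (1 - p), (1 - q) * (1 - p)) * v)
      pl <- list(mu_m = x[1], mu_f = x[2])
      if (sex == "M") { pl$paths_m <- paths; pl$paths_f <- x[5:7] }
      else { pl$paths_f <- paths; pl$paths_m <- x[5:7] }
      r <- x[8]
      pl$rg <- if (free == "rg") r else 0.5
      pl$rc <- if (free == "rc") r else 1
      negll(pl)
    }
    start <- c(par_hat$mu_m, par_hat$mu_f, log(v0), q0, other,
               min(max(r0, 0), 1))
    op <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = c(-Inf, -Inf, -Inf, 0, 0, 0, 0, 0),
                       upper = c(Inf, Inf, Inf, 1, Inf, Inf, Inf, 1),
                       control = list(maxit = 500, factr = 1e6))
  } else {
    prop_fix <- if (sex == "M") par_hat$prop_m else par_hat$prop_f
    c2 <- prop_fix[2]; e2 <- 1 - sum(prop_fix)
    q0 <- if (c2 + e2 > 1e-10) c2 / (c2 + e2) else 0.5
    other <- if (sex == "M") par_hat$prop_f else par_hat$prop_m
    pa_o <- other[1]
    q_o <- if (1 - pa_o > 1e-10) other[2] / (1 - pa_o) else 0
    r0 <- if (free == "rg") par_hat$rg else par_hat$rc
    obj <- function(x) {
      prop <- c(p, x[3] * (1 - p))
      prop_other <- c(x[4], x[5] * (1 - x[4]))
      pl <- list(t_m = x[1], t_f = x[2])
      if (sex == "M") { pl$prop_m <- prop; pl$prop_f <- prop_other }
      else { pl$prop_f <- prop; pl$prop_m <- prop_other }
      r <- x[6]
      pl$rg <- if (free == "rg") r else 0.5
      pl$rc <- if (free == "rc") r else 1
      negll(pl)
    }
    start <- c(par_hat$t_m, par_hat$t_f, q0, pa_o, min(max(q_o, 0), 1),
               min(max(r0, 0), 1))
    op <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = c(-Inf, -Inf, 0, 0, 0, 0),
                       upper = c(Inf, Inf, 1, 1, 1, 1),
                       control = list(maxit = 500, factr = 1e6))
  }
  op$value
}

#' @export
print.sexlim_fit <- function(x, ...) {
  cat(sprintf("Sex-limitation (%s) fit for '%s', free = %s (%s = %.3f)\n",
              x$type, x$trait, x$free, x$free, x$r_free))
  for (sex in c("M", "F")) {
    e <- x$estimates[x$estimates$sex == sex, ]
    cat(sprintf("  %s: a2 = %.3f, c2 = %.3f, e2 = %.3f\n", sex,
                e$estimate[1], e$estimate[2], e$estimate[3]))
  }
  cat("  nested fits vs full:\n")
  ch <- x$lrt_chain
  for (i in seq_len(nrow(ch)))
    cat(sprintf("    %-24s loglik = %.2f, npar = %d%s\n", ch$model[i],
                ch$loglik[i], ch$npar[i],
                if (is.na(ch$p_value[i])) ""
                else sprintf(", LRT chi2 = %.2f (df %d), p = %.4g",
                             ch$statistic[i], ch$df[i], ch$p_value[i])))
  invisible(x)
}
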