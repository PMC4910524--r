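# ACE decomposition of binary choice traits on the liability scale:
# the joint multinomial likelihood over the MZ and DZ 2x2 concordance
# tables, with cell probabilities from bivariate-normal orthants at a
# shared threshold t and group liability correlation gamma * a2 + c2.

# 2x2 concordance counts (n11, n10, n01, n00) for a selection of pairs
conc_counts <- function(ch, sel) {
  x <- ch[sel & stats::complete.cases(ch), , drop = FALSE]
  c(n11 = sum(x[, 1] == 1 & x[, 2] == 1),
    n10 = sum(x[, 1] == 1 & x[, 2] == 0),
    n01 = sum(x[, 1] == 0 & x[, 2] == 1),
    n00 = sum(x[, 1] == 0 & x[, 2] == 0))
}

#' Concordance tables and probandwise concordance for a choice trait
#'
#' @param pairs A `twin_pairs` object.
#' @param trait Choice trait name.
#' @return Data frame with one row per zygosity group present plus pooled
#'   `MZ` and `DZ` rows: the four cell counts, `n` pairs, and
#'   `probandwise` = 2 n11 / (2 n11 + n10 + n01).
#' @export
concordance_summary <- function(pairs, trait) {
  ch <- pair_values(pairs, trait, "choice")
  groups <- c(zygosity_levels(), "MZ", "DZ")
  rows <- lapply(groups, function(gr) {
    sel <- switch(gr,
      MZ = substr(pairs$zygosity, 1, 2) == "MZ",
      DZ = substr(pairs$zygosity, 1, 2) == "DZ",
      pairs$zygosity == gr)
    n <- conc_counts(ch, sel)
    denom <- 2 * n[1] + n[2] + n[3]
    c(n, n_pairs = sum(n),
      probandwise = if (denom > 0) unname(2 * n[1] / denom) else NA_real_)
  })
  out <- data.frame(group = groups, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$n_pairs > 0, , drop = FALSE]
}

liab_negll <- function(t, pa, pc, tables) {
  nll <- 0
  for (tb in tables) {
    r <- min(tb$gamma * pa + pc, 1 - 1e-9)
    p <- bvn_cell_probabilities(r, t, t)
    nll <- nll - sum(tb$counts * log(pmax(p, 1e-300)))
  }
  nll
}

liab_tables <- function(pairs, trait) {
  ch <- pair_values(pairs, trait, "choice")
  gam <- zygosity_gamma(pairs$zygosity)
  tables <- lapply(c(MZ = 1, DZ = 0.5), function(gamma) {
    n <- conc_counts(ch, gam == gamma)
    list(gamma = gamma, counts = n)
  })
  tables <- tables[vapply(tables, function(tb) sum(tb$counts) > 0,
                          logical(1))]
  for (tb in tables) {
    n <- tb$counts
    if ((n[1] + n[2] + n[3]) == 0 || (n[2] + n[3] + n[4]) == 0)
      stop("degenerate prevalence: all choosers or no choosers in a stratum",
           call. = FALSE)
  }
  tables
}

#' Liability-threshold ACE model for a binary choice trait
#'
#' Maximizes the joint multinomial likelihood of the MZ and DZ concordance
#' tables over the threshold t and standardized liability components
#' (a2 + c2 + e2 = 1), with group tetrachoric correlations
#' gamma * a2 + c2. Opposite-sex DZ pairs are pooled with same-sex DZ at
#' gamma = 0.5; the threshold is equated across zygosity groups (zygosity
#' should not shift prevalence). Profile-likelihood CIs per component.
#'
#' @inheritParams fit_ace_ml
#' @param trait Choice trait name.
#' @return An object of class `liability_fit`: `model`, `trait`,
#'   `threshold`, `components` (with CIs), implied `r_mz`/`r_dz`,
#'   `loglik`, `npar`, `n_pairs`, `convergence`.
#' @export
fit_liability_ace <- function(pairs, trait,
                              model = c("ACE", "AE", "CE", "E"),
                              ci = c("a2", "c2", "e2"),
                              conf_level = 0.95) {
  model <- match.arg(model)
  if (length(ci)) ci <- match.arg(ci, c("a2", "c2", "e2"), several.ok = TRUE)
  tables <- liab_tables(pairs, trait)
  gammas <- vapply(tables, function(tb) tb$gamma, numeric(1))
  if (!any(gammas == 1) || !any(gammas == 0.5))
    stop("need both MZ-type and DZ-type concordance tables", call. = FALSE)
  n_all <- Reduce(`+`, lapply(tables, function(tb) tb$counts))
  prev <- (2 * n_all[1] + n_all[2] + n_all[3]) / (2 * sum(n_all))
  t0 <- stats::qnorm(1 - prev)
  letters <- ace_model_letters(model)
  # parameters: t, then (pa, q) restricted by the model;
  # pa = a2, c2 = q * (1 - pa)
  has_a <- "a" %in% letters; has_c <- "c" %in% letters
  negll_par <- function(par) {
    t <- par[1]
    pa <- if (has_a) par[2] else 0
    q <- if (has_a && has_c) par[3] else if (has_c) par[2] else 0
    pc <- q * (1 - pa)
    liab_negll(t, pa, pc, tables)
  }
  npar <- 1L + has_a + has_c
  starts <- list(c(0.33, 0.5), c(0.6, 0.3), c(0.1, 0.8), c(0.8, 0.05))
  best <- NULL
  for (s0 in starts) {
    start <- c(t0, if (has_a) s0[1],
               if (has_c) (if (has_a) s0[2] else s0[1]))
    op <- stats::optim(start, negll_par, method = "L-BFGS-B",
                       lower = c(-Inf, rep(0, npar - 1L)),
                       upper = c(Inf, rep(1, npar - 1L)),
                       control = list(maxit = 500, factr = 1e5))
    op$a2_cand <- if (has_a) op$par[2] else 0
    if (is.null(best) || op$value < best$value - 1e-8 ||
        (abs(op$value - best$value) <= 1e-8 &&
         op$a2_cand < best$a2_cand)) best <- op
  }
  t_hat <- best$par[1]
  pa <- if (has_a) best$par[2] else 0
  q <- if (has_a && has_c) best$par[3] else if (has_c) best$par[2] else 0
  pc <- q * (1 - pa)
  comps <- c(a2 = unname(pa), c2 = unname(pc),
             e2 = unname(1 - pa - pc))
  ll <- -best$value
  crit <- ll - stats::qchisq(conf_level, 1) / 2
  comp_tab <- data.frame(component = c("a2", "c2", "e2"),
                         estimate = unname(comps),
                         lower = NA_real_, upper = NA_real_,
                         stringsAsFactors = FALSE)
  for (comp in ci) {
    i <- match(comp, comp_tab$component)
    letter <- substr(comp, 1, 1)
    if (!(letter %in% letters)) {
      comp_tab$lower[i] <- 0; comp_tab$upper[i] <- 0
      next
    }
    prof <- function(p) -liab_profile_negll(p, comp, tables, model,
                                            t0 = t_hat,
                                            q0 = ace_split_q(comps, comp))
    comp_tab$lower[i] <- profile_bound(prof, comps[[comp]], crit,
                                       lower_limit = 0, upper = FALSE)
    comp_tab$upper[i] <- profile_bound(prof, comps[[comp]], crit,
                                       upper_limit = 1, upper = TRUE)
  }
  structure(list(model = model, trait = trait, threshold = t_hat,
                 components = comp_tab,
                 r_mz = unname(comps["a2"] + comps["c2"]),
                 r_dz = unname(0.5 * comps["a2"] + comps["c2"]),
                 loglik = ll, npar = npar,
                 n_pairs = stats::setNames(
                   vapply(tables, function(tb) sum(tb$counts), numeric(1)),
                   ifelse(gammas == 1, "MZ", "DZ")),
                 convergence = best$convergence == 0),
            class = "liability_fit")
}

# profile negative log-likelihood with one standardized liability
# component fixed at p; free parameters are t and the split q of the
# remaining variance between the other two components present in the model
liab_profile_negll <- function(p, comp, tables, model, t0, q0) {
  letters <- ace_model_letters(model)
  comp_letter <- substr(comp, 1, 1)
  others <- setdiff(c("a", "c", "e"), comp_letter)
  free_others <- intersect(others, letters)
  obj <- function(par) {
    t <- par[1]
    q <- if (length(free_others) == 2) min(max(par[2], 0), 1)
         else if (length(free_others) == 1 && free_others == others[1]) 1
         else 0
    prop <- c(a = 0, c = 0, e = 0)
    prop[comp_letter] <- p
    prop[others[1]] <- q * (1 - p)
    prop[others[2]] <- (1 - q) * (1 - p)
    liab_negll(t, prop[["a"]], prop[["c"]], tables)
  }
  start <- c(t0, if (length(free_others) == 2) q0)
  op <- stats::optim(start, obj, method = "L-BFGS-B",
                     lower = c(-Inf, if (length(start) == 2) 0),
                     upper = c(Inf, if (length(start) == 2) 1),
                     control = list(maxit = 300, factr = 1e6))
  op$value
}

#' @export
print.liability_fit <- function(x, ...) {
  cat(sprintf(
    "Liability %s model for '%s' (%s pairs): t = %.3f, loglik = %.2f\n",
    x$model, x$trait,
    paste(sprintf("%d %s", x$n_pairs, names(x$n_pairs)), collapse = " + "),
    x$threshold, x$loglik))
  ct <- x$components
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %s = %.3f%s\n", ct$component[i], ct$estimate[i],
                if (is.na(ct$lower[i])) ""
                else sprintf(" (95%% CI %.3f, %.3f)", ct$lower[i],
                             ct$upper[i])))
  cat(sprintf("  implied tetrachoric rMZ = %.3f, rDZ = %.3f\n",
              x$r_mz, x$r_dz))
  invisible(x)
}
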