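# Tetrachoric correlation: ML inversion of a 2x2 concordance table under
# the bivariate-normal liability model.

#' Quadrant probabilities of the standardized bivariate normal
#'
#' Probabilities of the four quadrants of a standard bivariate normal with
#' correlation `r`, cut at thresholds `t1` (variable 1) and `t2`
#' (variable 2). Returned in the order (both above, 1 above/2 below,
#' 1 below/2 above, both below) — for twin concordance tables these are
#' (both chose, only twin 1, only twin 2, neither).
#'
#' The upper-upper mass is computed by one-dimensional quadrature of
#' `phi(x) * Phi((r*x - t2) / sqrt(1 - r^2))` over `x > t1` with absolute
#' tolerance 1e-10; the remaining cells follow from the margins. The
#' degenerate cases `r = +/-1` use exact expressions.
#'
#' @param r Correlation, |r| <= 1.
#' @param t1,t2 Thresholds on the two standard-normal margins.
#' @return Numeric vector `c(p11, p10, p01, p00)` summing to 1.
#' @export
bvn_cell_probabilities <- function(r, t1, t2) {
  stopifnot(is.finite(r), abs(r) <= 1, is.finite(t1), is.finite(t2))
  p1 <- stats::pnorm(t1, lower.tail = FALSE)  # P(X1 > t1)
  p2 <- stats::pnorm(t2, lower.tail = FALSE)
  if (r >= 1 - 1e-12) {
    p11 <- stats::pnorm(max(t1, t2), lower.tail = FALSE)
  } else if (r <= -1 + 1e-12) {
    p11 <- max(0, stats::pnorm(-t2) - stats::pnorm(t1))
  } else {
    s <- sqrt(1 - r^2)
    f <- function(x) stats::dnorm(x) * stats::pnorm((r * x - t2) / s)
    p11 <- stats::integrate(f, t1, Inf, abs.tol = 1e-10,
                            rel.tol = 1e-10)$value
  }
  p11 <- min(max(p11, 0), min(p1, p2))
  p10 <- p1 - p11
  p01 <- p2 - p11
  p00 <- 1 - p11 - p10 - p01
  c(p11 = p11, p10 = max(p10, 0), p01 = max(p01, 0), p00 = max(p00, 0))
}

as_conc_counts <- function(table) {
  n <- if (is.matrix(table)) c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
       else as.numeric(table)
  if (length(n) != 4 || any(n < 0))
    stop("table must give 4 nonnegative counts (n11, n10, n01, n00)",
         call. = FALSE)
  n
}

#' Two-by-two twin concordance table
#'
#' @param n11,n10,n01,n00 Counts: both chose, only twin 1, only twin 2,
#'   neither.
#' @param group Optional group label.
#' @return A list of class `concordance2x2`.
#' @export
concordance2x2 <- function(n11, n10, n01, n00, group = NA_character_) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be nonnegative with positive total", call. = FALSE)
  structure(list(counts = counts, group = group), class = "concordance2x2")
}

tetra_negll <- function(par, n) {
  r <- tanh(par[1])
  p <- bvn_cell_probabilities(r, par[2], par[3])
  -sum(n * log(pmax(p, 1e-300)))
}

#' Maximum-likelihood tetrachoric correlation
#'
#' Estimates the correlation of liability `r` and the two thresholds
#' `(t1, t2)` that maximize the multinomial likelihood of a 2x2 table
#' under the bivariate-normal liability model. The search runs on a
#' transformed scale (Fisher z for `r`; thresholds unconstrained) so the
#' optimum stays interior; a boundary flag is set when `|r|` reaches 1
#' within tolerance. The 95% CI for `r` is obtained by profile likelihood.
#'
#' @param table A [concordance2x2()], a 2x2 matrix
#'   (`rbind(c(n11, n10), c(n01, n00))`), or a length-4 count vector
#'   `(n11, n10, n01, n00)`.
#' @param conf_level Confidence level for the profile CI.
#' @return A list of class `tetrachoric_fit`: `r`, `t1`, `t2`, `loglik`,
#'   `ci` (lower/upper for `r`), `boundary`, `n`.
#' @export
fit_tetrachoric <- function(table, conf_level = 0.95) {
  n <- if (inherits(table, "concordance2x2")) table$counts
       else as_conc_counts(table)
  N <- sum(n)
  pm1 <- (n[1] + n[2]) / N  # margin: P(twin 1 chose)
  pm2 <- (n[1] + n[3]) / N
  if (pm1 <= 0 || pm1 >= 1 || pm2 <= 0 || pm2 >= 1)
    stop("degenerate margin: a row or column of the table is empty",
         call. = FALSE)
  t1_0 <- stats::qnorm(1 - pm1)
  t2_0 <- stats::qnorm(1 - pm2)
  # start r from the odds-ratio cosine approximation, falling back to 0
  r0 <- if (all(n > 0)) {
    cos(pi / (1 + sqrt(n[1] * n[4] / (n[2] * n[3]))))
  } else 0
  starts <- unique(pmin(pmax(c(r0, 0, 0.7, -0.7), -0.99), 0.99))
  best <- NULL
  for (r_start in starts) {
    op <- stats::optim(c(atanh(r_start), t1_0, t2_0), tetra_negll, n = n,
                       method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || op$value < best$value - 1e-9) best <- op
  }
  if (best$convergence != 0)
    stop("tetrachoric ML did not converge (optim code ", best$convergence,
         ")", call. = FALSE)
  z_hat <- best$par[1]
  r_hat <- tanh(z_hat)
  ll_hat <- -best$value
  boundary <- abs(r_hat) > 1 - 1e-4
  # profile likelihood CI for r (thresholds re-optimized at each r)
  prof <- function(r) {
    op <- stats::optim(best$par[2:3],
                       function(tt) tetra_negll(c(atanh(r), tt), n),
                       method = "BFGS", control = list(reltol = 1e-12))
    -op$value
  }
  crit <- ll_hat - stats::qchisq(conf_level, 1) / 2
  ci <- c(
    profile_bound(prof, r_hat, crit, lower_limit = -0.9999, upper = FALSE),
    profile_bound(prof, r_hat, crit, upper_limit = 0.9999, upper = TRUE))
  structure(list(r = r_hat, t1 = best$par[2], t2 = best$par[3],
                 loglik = ll_hat, ci = ci, boundary = boundary, n = N),
            class = "tetrachoric_fit")
}

#' @export
print.tetrachoric_fit <- function(x, ...) {
  cat(sprintf(
    "Tetrachoric r = %.3f (95%% CI %.3f, %.3f), thresholds (%.3f, %.3f), n = %d%s\n",
    x$r, x$ci[1], x$ci[2], x$t1, x$t2, x$n,
    if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

# Bisection for the value where the profile log-likelihood crosses `crit`,
# between the ML estimate and a hard limit. `prof` must be the profile
# log-likelihood; returns the limit itself when the profile never drops
# below crit before reaching it.
profile_bound <- function(prof, est, crit,
                          lower_limit = NULL, upper_limit = NULL,
                          upper = TRUE, tol = 1e-4, max_iter = 60L) {
  lim <- if (upper) upper_limit else lower_limit
  if (abs(lim - est) < tol) return(lim)
  if (prof(lim) >= crit) return(lim)
  lo <- if (upper) est else lim
  hi <- if (upper) lim else est
  # invariant: prof at the estimate side >= crit, at the limit side < crit
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (prof(mid) >= crit) {
      if (upper) lo <- mid else hi <- mid
    } else {
      if (upper) hi <- mid else lo <- mid
    }
  }
  (lo + hi) / 2
}
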