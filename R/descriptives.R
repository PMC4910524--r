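# Descriptive tests computed on one randomly selected twin per pair, so
# that observations are independent across families.

select_one_per_pair <- function(pairs, seed) {
  withr::with_seed(as.integer(seed),
                   sample(c(1L, 2L), nrow(pairs), replace = TRUE))
}

#' Sex-difference chi-square for a choice trait, one twin per pair
#'
#' Samples one twin uniformly per pair (twins are not independent
#' observations) and computes the Pearson chi-square, without continuity
#' correction, on the resulting 2x2 sex-by-choice table.
#'
#' @param pairs A `twin_pairs` object.
#' @param trait Choice trait name.
#' @param seed Integer seed for the twin selection.
#' @return List with `statistic`, `df` (= 1), `p_value`, and the 2x2
#'   `table` (rows sex, columns choice 0/1).
#' @export
chisq_one_per_pair <- function(pairs, trait, seed) {
  idx <- select_one_per_pair(pairs, seed)
  ch <- pair_values(pairs, trait, "choice")
  sel_choice <- ch[cbind(seq_len(nrow(pairs)), idx)]
  sel_sex <- ifelse(idx == 1L, pairs$sex1, pairs$sex2)
  ok <- !is.na(sel_choice)
  tab <- table(factor(sel_sex[ok], levels = c("M", "F")),
               factor(sel_choice[ok], levels = c(0, 1)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined statistic: a margin of the 2x2 table is zero",
         call. = FALSE)
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}

#' Sex x zygosity ANOVA for a grade trait, one twin per pair
#'
#' Two-factor fixed-effects ANOVA of the grade on sex, zygosity (MZ vs DZ)
#' and their interaction, with sequential (type-I) sums of squares in that
#' order, on one randomly selected twin per pair. R^2 is the proportion of
#' variance explained jointly by the three terms.
#'
#' @inheritParams chisq_one_per_pair
#' @param trait Grade trait name.
#' @return An `anova_report` list: per-term `F` and `p_value`, `r_squared`,
#'   `n`, and the underlying anova table.
#' @export
anova_sex_zygosity <- function(pairs, trait, seed) {
  idx <- select_one_per_pair(pairs, seed)
  g <- pair_values(pairs, trait, "grade")
  y <- g[cbind(seq_len(nrow(pairs)), idx)]
  sex <- factor(ifelse(idx == 1L, pairs$sex1, pairs$sex2),
                levels = c("M", "F"))
  zyg <- factor(ifelse(substr(pairs$zygosity, 1, 2) == "MZ", "MZ", "DZ"),
                levels = c("MZ", "DZ"))
  ok <- !is.na(y)
  if (!sum(ok)) stop("no non-missing grades for trait '", trait, "'",
                     call. = FALSE)
  d <- data.frame(y = y[ok], sex = sex[ok], zyg = zyg[ok])
  with_interaction <- all(table(d$sex, d$zyg) > 0)
  form <- if (with_interaction) y ~ sex + zyg + sex:zyg else y ~ sex + zyg
  if (!with_interaction)
    warning("empty sex x zygosity cell: interaction dropped", call. = FALSE)
  at <- stats::anova(stats::lm(form, data = d))
  ss <- at[["Sum Sq"]]
  terms <- rownames(at)
  effect <- terms != "Residuals"
  get_term <- function(tn) {
    i <- match(tn, terms)
    if (is.na(i)) c(F = NA_real_, p = NA_real_)
    else c(F = at[["F value"]][i], p = at[["Pr(>F)"]][i])
  }
  structure(list(
    F_sex = unname(get_term("sex")["F"]),
    p_sex = unname(get_term("sex")["p"]),
    F_zygosity = unname(get_term("zyg")["F"]),
    p_zygosity = unname(get_term("zyg")["p"]),
    F_interaction = unname(get_term("sex:zyg")["F"]),
    p_interaction = unname(get_term("sex:zyg")["p"]),
    r_squared = sum(ss[effect]) / sum(ss),
    n = nrow(d),
    anova_table = at), class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf(
    "Sex x zygosity ANOVA (n = %d): F_sex = %.2f, F_zyg = %.2f, F_int = %.2f, R^2 = %.4f\n",
    x$n, x$F_sex, x$F_zygosity,
    if (is.na(x$F_interaction)) NA_real_ else x$F_interaction, x$r_squared))
  invisible(x)
}
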