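# Phenotype corrections applied before twin-model fitting.

#' Age/sex residualization of a phenotype
#'
#' Regresses a phenotype on age and sex by ordinary least squares over all
#' individuals pooled (age is pair-constant, and MZ pairs are always
#' same-sex, so uncorrected age/sex mean effects would inflate the shared-
#' environment estimate), then standardizes the residuals to mean 0, SD 1.
#' Missing phenotype values stay missing.
#'
#' @param values Numeric phenotype vector (NA allowed).
#' @param age Numeric age vector aligned with `values`.
#' @param sex Sex indicator aligned with `values`: "M"/"F" or 0/1.
#' @return Numeric vector of standardized residuals (NA preserved). When
#'   the regression fits the data exactly the residuals are identically
#'   zero and standardization short-circuits to zeros.
#' @export
residualize_age_sex <- function(values, age, sex) {
  stopifnot(length(values) == length(age), length(values) == length(sex))
  sex_num <- if (is.numeric(sex)) sex else as.numeric(sex == "F")
  ok <- !is.na(values) & !is.na(age) & !is.na(sex_num)
  if (sum(ok) < 3)
    stop("need at least 3 non-missing observations", call. = FALSE)
  X <- cbind(1, age[ok], sex_num[ok])
  if (qr(X)$rank < 2)
    stop("degenerate design: covariates constant and collinear with the intercept",
         call. = FALSE)
  fit <- stats::lm.fit(X, values[ok])
  res <- fit$residuals
  s <- stats::sd(res)
  out <- rep(NA_real_, length(values))
  out[ok] <- if (s > 1e-12) (res - mean(res)) / s else 0
  out
}

#' Rank-based inverse-normal (van der Waerden) transform
#'
#' The value with rank r among n non-missing entries maps to the standard-
#' normal quantile at r/(n+1); ties receive the quantile of their average
#' rank. Order is preserved; missing values stay missing.
#'
#' @param values Numeric vector (NA allowed).
#' @return Numeric vector of normal scores.
#' @export
van_der_waerden <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct non-missing values", call. = FALSE)
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm(r / (length(x) + 1))
  out
}

#' Phenotype correction recipe
#'
#' @param covariates Covariates to regress out (subset of "age", "sex").
#' @param inverse_normal Apply the van der Waerden transform after
#'   residualization.
#' @param standardize Restandardize to mean 0, SD 1 at the end.
#' @return A list of class `correction_recipe`.
#' @export
correction_recipe <- function(covariates = c("age", "sex"),
                              inverse_normal = TRUE,
                              standardize = TRUE) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  structure(list(covariates = covariates,
                 inverse_normal = inverse_normal,
                 standardize = standardize),
            class = "correction_recipe")
}

#' Apply a correction recipe to one grade trait
#'
#' Individuals from both twins are pooled, corrected identically
#' (residualization, then optional inverse-normal transform, then optional
#' restandardization) and written back into the pair table.
#'
#' @param pairs A `twin_pairs` object.
#' @param trait Grade trait name.
#' @param recipe A [correction_recipe()].
#' @return `pairs` with the corrected `grade_<trait>` columns; the fitted
#'   covariate effects are attached as attribute `"effects"`.
#' @export
apply_corrections <- function(pairs, trait, recipe = correction_recipe()) {
  stopifnot(inherits(recipe, "correction_recipe"))
  g <- pair_values(pairs, trait, "grade")
  n <- nrow(pairs)
  values <- c(g[, 1], g[, 2])
  age <- rep(pairs$age, 2)
  sex <- c(pairs$sex1, pairs$sex2)
  effects <- NULL
  if (length(recipe$covariates)) {
    ok <- !is.na(values)
    sex_num <- as.numeric(sex == "F")
    X <- cbind(intercept = 1,
               if ("age" %in% recipe$covariates) age else NULL,
               if ("sex" %in% recipe$covariates) sex_num else NULL)
    colnames(X) <- c("intercept", recipe$covariates)
    fit <- stats::lm.fit(X[ok, , drop = FALSE], values[ok])
    effects <- fit$coefficients
    res <- rep(NA_real_, length(values))
    res[ok] <- fit$residuals
    s <- stats::sd(res, na.rm = TRUE)
    values <- if (s > 1e-12) res / s else res * 0
  }
  if (recipe$inverse_normal) values <- van_der_waerden(values)
  if (recipe$standardize) {
    m <- mean(values, na.rm = TRUE); s <- stats::sd(values, na.rm = TRUE)
    if (s > 1e-12) values <- (values - m) / s
  }
  pairs[[paste0("grade_", trait, "_1")]] <- values[seq_len(n)]
  pairs[[paste0("grade_", trait, "_2")]] <- values[n + seq_len(n)]
  attr(pairs, "effects") <- effects
  pairs
}
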