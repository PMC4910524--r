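#' @keywords internal
"_PACKAGE"

# Zygosity bookkeeping ---------------------------------------------------

#' Zygosity group labels
#'
#' The five zygosity groups of the classical twin design: monozygotic male
#' (`MZm`) and female (`MZf`) pairs, dizygotic same-sex male (`DZm`) and
#' female (`DZf`) pairs, and dizygotic opposite-sex (`DZos`) pairs.
#'
#' @return Character vector of the five group labels, in canonical order.
#' @export
zygosity_levels <- function() c("MZm", "MZf", "DZm", "DZf", "DZos")

#' Genetic-relatedness coefficient of a zygosity group
#'
#' MZ twins share all segregating genes (coefficient 1); DZ twins, like
#' ordinary siblings, share half on average (coefficient 0.5).
#'
#' @param zygosity Character vector of group labels (see [zygosity_levels()]).
#' @return Numeric vector: 1 for MZ groups, 0.5 for DZ groups.
#' @export
zygosity_gamma <- function(zygosity) {
  stopifnot(all(zygosity %in% zygosity_levels()))
  ifelse(substr(zygosity, 1L, 2L) == "MZ", 1, 0.5)
}

# expected twin sexes for each group; DZos is stored male-first
zyg_sexes <- function(zygosity) {
  switch(zygosity,
    MZm  = c("M", "M"),
    MZf  = c("F", "F"),
    DZm  = c("M", "M"),
    DZf  = c("F", "F"),
    DZos = c("M", "F"),
    stop("unknown zygosity code: '", zygosity, "'", call. = FALSE)
  )
}

# twin_pairs container ---------------------------------------------------

#' Construct a twin-pair table
#'
#' A `twin_pairs` object is a data frame with one row per twin pair:
#' columns `family_id`, `zygosity` (one of [zygosity_levels()]), `sex1`,
#' `sex2`, `age` (shared within a pair), and per trait the columns
#' `choice_<trait>_1` / `choice_<trait>_2` (0/1/NA) and/or
#' `grade_<trait>_1` / `grade_<trait>_2` (numeric, NA when unobserved).
#'
#' @param df Data frame with the columns above.
#' @param validate Check pair invariants (see [validate_twin_pairs()]).
#' @param grade_range Length-2 numeric bounds for grade values, or NULL to
#'   accept any numeric phenotype (e.g. standardized residuals).
#' @return A `twin_pairs` data frame.
#' @export
twin_pairs <- function(df, validate = TRUE, grade_range = NULL) {
  stopifnot(is.data.frame(df))
  required <- c("family_id", "zygosity", "sex1", "sex2", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  df$family_id <- as.character(df$family_id)
  df$zygosity <- as.character(df$zygosity)
  out <- structure(as.data.frame(df, stringsAsFactors = FALSE),
                   class = c("twin_pairs", "data.frame"))
  if (validate) validate_twin_pairs(out, grade_range = grade_range)
  out
}

#' Trait names present in a twin-pair table
#'
#' @param pairs A `twin_pairs` object.
#' @param type "choice", "grade", or "any".
#' @return Character vector of trait names.
#' @export
pair_traits <- function(pairs, type = c("any", "choice", "grade")) {
  type <- match.arg(type)
  nm <- names(pairs)
  choice <- unique(sub("^choice_(.*)_[12]$", "\\1",
                       grep("^choice_.*_[12]$", nm, value = TRUE)))
  grade <- unique(sub("^grade_(.*)_[12]$", "\\1",
                      grep("^grade_.*_[12]$", nm, value = TRUE)))
  switch(type, choice = choice, grade = grade, any = union(choice, grade))
}

#' Extract a pair-value matrix for one trait
#'
#' @param pairs A `twin_pairs` object.
#' @param trait Trait name.
#' @param type "grade" for the continuous phenotype, "choice" for the
#'   binary indicator.
#' @return Numeric matrix with one row per pair and columns twin 1, twin 2.
#' @export
pair_values <- function(pairs, trait, type = c("grade", "choice")) {
  type <- match.arg(type)
  cols <- paste0(type, "_", trait, "_", 1:2)
  if (!all(cols %in% names(pairs)))
    stop("trait '", trait, "' has no ", type, " columns", call. = FALSE)
  m <- cbind(as.numeric(pairs[[cols[1]]]), as.numeric(pairs[[cols[2]]]))
  colnames(m) <- cols
  m
}

#' Validate twin-pair invariants
#'
#' Checks that zygosity codes are known, sexes match the zygosity group
#' (MZ and DZ same-sex pairs concordant, DZos discordant), choice flags are
#' 0/1/NA, grades are observed only for choosers when the same-named choice
#' trait exists, and grades lie within `grade_range` when given.
#'
#' @inheritParams twin_pairs
#' @param pairs A `twin_pairs` object.
#' @return Invisibly, `pairs`; errors describe the first offending family.
#' @export
validate_twin_pairs <- function(pairs, grade_range = NULL) {
  bad <- !(pairs$zygosity %in% zygosity_levels())
  if (any(bad))
    stop("unknown zygosity code '", pairs$zygosity[which(bad)[1]],
         "' in family ", pairs$family_id[which(bad)[1]], call. = FALSE)
  if (anyDuplicated(pairs$family_id))
    stop("duplicated family_id: ",
         pairs$family_id[anyDuplicated(pairs$family_id)], call. = FALSE)
  exp_sex <- t(vapply(pairs$zygosity, zyg_sexes, character(2)))
  same_sex <- pairs$zygosity != "DZos"
  mism <- same_sex & (pairs$sex1 != pairs$sex2)
  if (any(mism))
    stop("same-sex zygosity group with discordant sexes in family ",
         pairs$family_id[which(mism)[1]], call. = FALSE)
  mism <- same_sex & (pairs$sex1 != exp_sex[, 1])
  if (any(mism))
    stop("sex inconsistent with zygosity label in family ",
         pairs$family_id[which(mism)[1]], call. = FALSE)
  mism <- !same_sex & (pairs$sex1 == pairs$sex2)
  if (any(mism))
    stop("DZos pair with concordant sexes in family ",
         pairs$family_id[which(mism)[1]], call. = FALSE)
  for (tr in pair_traits(pairs, "choice")) {
    ch <- pair_values(pairs, tr, "choice")
    if (!all(ch %in% c(0, 1, NA)))
      stop("choice_", tr, " contains values other than 0/1/NA", call. = FALSE)
    gcols <- paste0("grade_", tr, "_", 1:2)
    if (all(gcols %in% names(pairs))) {
      gr <- pair_values(pairs, tr, "grade")
      orphan <- !is.na(gr) & (is.na(ch) | ch == 0)
      if (any(orphan)) {
        i <- which(rowSums(orphan) > 0)[1]
        stop("grade_", tr, " observed without choice_", tr,
             " == 1 in family ", pairs$family_id[i], call. = FALSE)
      }
    }
  }
  if (!is.null(grade_range)) {
    for (tr in pair_traits(pairs, "grade")) {
      gr <- pair_values(pairs, tr, "grade")
      out <- !is.na(gr) & (gr < grade_range[1] | gr > grade_range[2])
      if (any(out)) {
        i <- which(rowSums(out) > 0)[1]
        stop("grade_", tr, " outside [", grade_range[1], ", ",
             grade_range[2], "] in family ", pairs$family_id[i],
             call. = FALSE)
      }
    }
  }
  invisible(pairs)
}

# reading / writing ------------------------------------------------------

#' Read a long-format twin table
#'
#' The on-disk format is one row per individual with columns `family_id`,
#' `twin` (1 or 2), `zygosity`, `sex`, `age`, then trait columns
#' `choice_<name>` (0/1) and `grade_<name>`. Empty cells and the string
#' "NA" are both read as missing. Every family must appear exactly twice
#' (complete pairs only); incomplete families are an error, not dropped.
#'
#' @param source Path or connection to a CSV file.
#' @param grade_range Bounds for raw grade values (default the 1-6 exam
#'   scale); NULL disables the range check, e.g. for standardized scores.
#' @return A validated `twin_pairs` object.
#' @export
read_twin_table <- function(source, grade_range = c(1, 6)) {
  # sex must be read as character: bare "F" would otherwise parse as FALSE
  long <- utils::read.csv(source, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"),
                          colClasses = c(family_id = "character",
                                         zygosity = "character",
                                         sex = "character"))
  required <- c("family_id", "twin", "zygosity", "sex", "age")
  missing_cols <- setdiff(required, names(long))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  counts <- table(long$family_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad))
    stop("malformed pair: family ", bad[1], " has ", counts[bad[1]],
         " row(s), expected 2", call. = FALSE)
  if (!all(long$twin %in% c(1L, 2L)))
    stop("twin index must be 1 or 2", call. = FALSE)
  long <- long[order(long$family_id, long$twin), , drop = FALSE]
  t1 <- long[long$twin == 1L, , drop = FALSE]
  t2 <- long[long$twin == 2L, , drop = FALSE]
  if (!identical(t1$family_id, t2$family_id))
    stop("each family needs one twin-1 and one twin-2 row; family ",
         setdiff(t1$family_id, t2$family_id)[1], " does not", call. = FALSE)
  if (any(t1$zygosity != t2$zygosity))
    stop("zygosity differs within family ",
         t1$family_id[which(t1$zygosity != t2$zygosity)[1]], call. = FALSE)
  if (any(abs(t1$age - t2$age) > 1e-8, na.rm = TRUE))
    stop("ages differ within family ",
         t1$family_id[which(abs(t1$age - t2$age) > 1e-8)[1]], call. = FALSE)
  trait_cols <- grep("^(choice|grade)_", names(long), value = TRUE)
  wide <- data.frame(family_id = t1$family_id, zygosity = t1$zygosity,
                     sex1 = t1$sex, sex2 = t2$sex, age = t1$age,
                     stringsAsFactors = FALSE)
  for (cc in trait_cols) {
    wide[[paste0(cc, "_1")]] <- t1[[cc]]
    wide[[paste0(cc, "_2")]] <- t2[[cc]]
  }
  twin_pairs(wide, validate = TRUE, grade_range = grade_range)
}

#' Write a twin table in long format
#'
#' Inverse of [read_twin_table()]: one row per individual, missing values
#' written as "NA".
#'
#' @param pairs A `twin_pairs` object.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_twin_table <- function(pairs, path) {
  trait_cols <- grep("^(choice|grade)_.*_[12]$", names(pairs), value = TRUE)
  base_cols <- sub("_[12]$", "", trait_cols)
  base_unique <- unique(base_cols)
  row_for <- function(i) {
    d <- data.frame(family_id = pairs$family_id,
                    twin = i,
                    zygosity = pairs$zygosity,
                    sex = pairs[[paste0("sex", i)]],
                    age = pairs$age,
                    stringsAsFactors = FALSE)
    for (b in base_unique) d[[b]] <- pairs[[paste0(b, "_", i)]]
    d
  }
  long <- rbind(row_for(1L), row_for(2L))
  long <- long[order(long$family_id, long$twin), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, na = "NA")
  invisible(path)
}

# descriptive counts -----------------------------------------------------

#' Chooser counts and shares for a binary choice trait
#'
#' Tabulates, for one choice trait, the number of choosers overall, by sex,
#' and by zygosity group. Shares by sex and by group are expressed as a
#' percentage of choosers (the convention of published choice tables);
#' the overall share is a percentage of all individuals with a non-missing
#' indicator.
#'
#' @param pairs A `twin_pairs` object.
#' @param trait Choice trait name.
#' @return An object of class `choice_summary`: a list with `trait`,
#'   `n_choosers`, `n_individuals`, `pct_choosing`, and data frames
#'   `by_sex` and `by_group` (count plus `pct_of_choosers`). Percentages
#'   are carried to one decimal; `print()` rounds to integers.
#' @export
summarize_counts <- function(pairs, trait) {
  if (!(trait %in% pair_traits(pairs, "choice")))
    stop("unknown choice trait: '", trait, "'", call. = FALSE)
  ch <- pair_values(pairs, trait, "choice")
  sex <- cbind(pairs$sex1, pairs$sex2)
  zyg <- cbind(pairs$zygosity, pairs$zygosity)
  keep <- !is.na(ch)
  chooser <- keep & ch == 1
  n_choosers <- sum(chooser)
  n_ind <- sum(keep)
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else 0
  by_sex <- data.frame(
    sex = c("M", "F"),
    choosers = c(sum(chooser & sex == "M"), sum(chooser & sex == "F")),
    stringsAsFactors = FALSE)
  by_sex$pct_of_choosers <- vapply(by_sex$choosers, pct, numeric(1),
                                   den = n_choosers)
  by_group <- data.frame(
    group = zygosity_levels(),
    choosers = vapply(zygosity_levels(),
                      function(g) sum(chooser & zyg == g), numeric(1)),
    stringsAsFactors = FALSE)
  by_group$pct_of_choosers <- vapply(by_group$choosers, pct, numeric(1),
                                     den = n_choosers)
  structure(list(trait = trait,
                 n_choosers = n_choosers,
                 n_individuals = n_ind,
                 pct_choosing = pct(n_choosers, n_ind),
                 by_sex = by_sex,
                 by_group = by_group),
            class = "choice_summary")
}

#' @export
print.choice_summary <- function(x, ...) {
  cat(sprintf("Choice trait '%s': %d of %d individuals (%d%%)\n",
              x$trait, x$n_choosers, x$n_individuals,
              round(x$pct_choosing)))
  sx <- x$by_sex
  cat(sprintf("  by sex (%% of choosers): M %d (%d%%), F %d (%d%%)\n",
              sx$choosers[1], round(sx$pct_of_choosers[1]),
              sx$choosers[2], round(sx$pct_of_choosers[2])))
  g <- x$by_group
  cat("  by zygosity group (% of choosers):\n")
  for (i in seq_len(nrow(g)))
    cat(sprintf("    %-4s %6d (%d%%)\n", g$group[i], g$choosers[i],
                round(g$pct_of_choosers[i])))
  invisible(x)
}
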