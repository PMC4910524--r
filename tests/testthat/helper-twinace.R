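# Small hand-built pair tables for unit tests.

# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_within <- function(actual, expected, tol) {
  expect_lte(max(abs(actual - expected)), tol)
}

# n pairs of one zygosity group with constant choice/grade values
make_pairs <- function(zygosity, n, choice = NULL, grade = NULL,
                       trait = "alevel", id0 = 0L) {
  sexes <- switch(zygosity, MZm = , DZm = c("M", "M"),
                  MZf = , DZf = c("F", "F"), DZos = c("M", "F"))
  df <- data.frame(family_id = sprintf("T%05d", id0 + seq_len(n)),
                   zygosity = zygosity, sex1 = sexes[1], sex2 = sexes[2],
                   age = 18, stringsAsFactors = FALSE)
  if (!is.null(choice)) {
    df[[paste0("choice_", trait, "_1")]] <- choice[1]
    df[[paste0("choice_", trait, "_2")]] <- choice[2]
  }
  if (!is.null(grade)) {
    df[[paste0("grade_", trait, "_1")]] <- grade[1]
    df[[paste0("grade_", trait, "_2")]] <- grade[2]
  }
  df
}

bind_pairs <- function(...) {
  dfs <- list(...)
  n <- 0L
  for (i in seq_along(dfs)) {
    dfs[[i]]$family_id <- sprintf("T%05d", n + seq_len(nrow(dfs[[i]])))
    n <- n + nrow(dfs[[i]])
  }
  twin_pairs(do.call(rbind, dfs))
}

# long-format CSV written to a temp file
write_long_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(rows, path)
  path
}
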