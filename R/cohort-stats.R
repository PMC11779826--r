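# Baseline characterization: absolute standardized differences (ASD) and
# outcome-label summaries. ASDs use the standard pooled-variance definitions;
# an ASD above 10% flags meaningful imbalance between outcome groups.

#' Absolute standardized difference for a binary variable
#'
#' `100 * |p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)` with `p_i = count_i/n_i`.
#' Returns 0 when both proportions are equal (including the degenerate 0/0
#' and 1/1 cases where the pooled variance vanishes). Symmetric in group
#' order and invariant to flipping the 0/1 coding.
#'
#' @param count1,n1 event count and size of the first group.
#' @param count2,n2 event count and size of the second group.
#' @return the ASD in percent (non-negative scalar).
#' @export
asd_binary <- function(count1, n1, count2, n2) {
  .assert(n1 >= 1 && n2 >= 1, "group sizes must be at least 1")
  .assert(count1 >= 0 && count1 <= n1 && count2 >= 0 && count2 <= n2,
          "counts must lie in [0, n]")
  p1 <- count1 / n1
  p2 <- count2 / n2
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v == 0) {
    if (p1 == p2) return(0)
    stop("zero pooled variance with unequal proportions", call. = FALSE)
  }
  100 * abs(p1 - p2) / sqrt(v)
}

#' Absolute standardized difference for a continuous variable
#'
#' `100 * |mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)`. Symmetric in group
#' order; equal means give 0 regardless of the SDs.
#'
#' @param mean1,sd1 summary of the first group.
#' @param mean2,sd2 summary of the second group.
#' @return the ASD in percent.
#' @export
asd_continuous <- function(mean1, sd1, mean2, sd2) {
  .assert(sd1 >= 0 && sd2 >= 0, "standard deviations must be non-negative")
  if (mean1 == mean2) return(0)
  .assert(sd1 > 0 || sd2 > 0,
          "ASD undefined: unequal means with both SDs zero")
  100 * abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Baseline characteristics table by outcome group
#'
#' One row per binary/continuous feature and per categorical level, with the
#' group summaries (count and proportion, or mean and SD), the ASD computed
#' by feature kind, and the >10% imbalance flag.
#'
#' @param cohort an `ehr_cohort`.
#' @param group_by name of the binary label column to group by (default
#'   `"y"`).
#' @return a data frame of class `baseline_table` with columns `variable`,
#'   `level`, `kind`, `g0_count`, `g0_prop`, `g0_mean`, `g0_sd`, `g1_*`,
#'   `asd_percent`, `imbalanced`.
#' @export
baseline_table <- function(cohort, group_by = "y") {
  g <- cohort[[group_by]]
  .assert(!is.null(g), "unknown label column: ", group_by)
  i0 <- which(g == 0L)
  i1 <- which(g == 1L)
  .assert(length(i0) > 0 && length(i1) > 0,
          "both outcome groups must be non-empty")
  n0 <- length(i0); n1 <- length(i1)
  rows <- list()
  for (sp in cohort$specs) {
    x <- cohort$features[[sp$name]]
    if (sp$kind == "continuous") {
      m0 <- mean(x[i0]); s0 <- stats::sd(x[i0])
      m1 <- mean(x[i1]); s1 <- stats::sd(x[i1])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = sp$name, level = NA_character_, kind = "continuous",
        g0_count = NA_real_, g0_prop = NA_real_, g0_mean = m0, g0_sd = s0,
        g1_count = NA_real_, g1_prop = NA_real_, g1_mean = m1, g1_sd = s1,
        asd_percent = asd_continuous(m0, s0, m1, s1),
        stringsAsFactors = FALSE)
    } else {
      levs <- if (sp$kind == "binary") list(NA_character_) else
        as.list(sp$categories)
      for (lev in levs) {
        ind <- if (is.na(lev)) as.numeric(x) else as.numeric(x == lev)
        c0 <- sum(ind[i0]); c1 <- sum(ind[i1])
        rows[[length(rows) + 1L]] <- data.frame(
          variable = sp$name, level = lev, kind = sp$kind,
          g0_count = c0, g0_prop = c0 / n0, g0_mean = NA_real_, g0_sd = NA_real_,
          g1_count = c1, g1_prop = c1 / n1, g1_mean = NA_real_, g1_sd = NA_real_,
          asd_percent = asd_binary(c0, n0, c1, n1),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$imbalanced <- out$asd_percent > 10
  attr(out, "group_sizes") <- c(g0 = n0, g1 = n1)
  attr(out, "group_by") <- group_by
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Write a baseline table as CSV and aligned text
#'
#' @param table a `baseline_table`.
#' @param path output CSV path; an aligned plain-text rendering is written
#'   alongside with extension `.txt`.
#' @return `path` invisibly.
#' @export
write_baseline_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  writeLines(format_baseline_table(table),
             paste0(tools::file_path_sans_ext(path), ".txt"))
  invisible(path)
}

#' Render a baseline table as aligned text
#'
#' @param table a `baseline_table`.
#' @return character vector of lines (ASD rounded to integer percent,
#'   Table-1 style; imbalance marked with `*`).
#' @export
format_baseline_table <- function(table) {
  ns <- attr(table, "group_sizes")
  summ <- function(row, side) {
    if (row$kind == "continuous") {
      sprintf("%.1f ± %.1f", row[[paste0(side, "_mean")]],
              row[[paste0(side, "_sd")]])
    } else {
      sprintf("%d (%.0f%%)", row[[paste0(side, "_count")]],
              100 * row[[paste0(side, "_prop")]])
    }
  }
  labels <- ifelse(is.na(table$level), table$variable,
                   paste0(table$variable, ": ", table$level))
  lines <- sprintf("%-28s %18s %18s %6.0f%s",
                   labels,
                   vapply(seq_len(nrow(table)),
                          function(i) summ(table[i, ], "g0"), ""),
                   vapply(seq_len(nrow(table)),
                          function(i) summ(table[i, ], "g1"), ""),
                   round(table$asd_percent),
                   ifelse(table$imbalanced, " *", ""))
  header <- sprintf("%-28s %18s %18s %6s", "Variable",
                    sprintf("No (N=%d)", ns[["g0"]]),
                    sprintf("Yes (N=%d)", ns[["g1"]]), "ASD%")
  c(header, strrep("-", nchar(header)), lines)
}

#' @export
print.baseline_table <- function(x, ...) {
  writeLines(format_baseline_table(x))
  invisible(x)
}

#' Outcome label summary
#'
#' Counts and percentages (one decimal) for the combined, note-derived and
#' code-derived outcome labels, plus the corroboration rate: the share of
#' code-derived cases that are also note-derived. With no coded cases the
#' corroboration is reported as not available (`NA`).
#'
#' @param cohort an `ehr_cohort`.
#' @return a list with `table` (data frame: label, count, percent) and
#'   `corroboration_percent`.
#' @export
outcome_summary <- function(cohort) {
  n <- cohort_size(cohort)
  counts <- c(y = sum(cohort$y),
              y_documented = sum(cohort$y_documented),
              y_coded = sum(cohort$y_coded))
  tab <- data.frame(
    label = names(counts),
    count = as.integer(counts),
    percent = round(100 * counts / n, 1),
    row.names = NULL, stringsAsFactors = FALSE)
  corr <- if (counts[["y_coded"]] > 0) {
    round(100 * mean(cohort$y_documented[cohort$y_coded == 1L]), 1)
  } else NA_real_
  list(table = tab, corroboration_percent = corr, n = n)
}
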