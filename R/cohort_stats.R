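#' Compare the path distributions of two cohorts
#'
#' Chi-square test of homogeneity on the `2 x k` table of path counts of
#' two cohorts on the same protocol.  The usual validity caveat — each
#' cell should carry a minimal expected count — is handled by pooling:
#' path categories whose smallest expected cell falls below `min_expected`
#' are merged, smallest first, into a single `"other"` category until all
#' expected counts reach the threshold.  Every pooling step is logged in
#' the result.  A Monte-Carlo p-value (conditional on the margins) can be
#' requested instead of the asymptotic one.
#'
#' @param table1,table2 [path_count_table()]s on the same protocol, both
#'   with `N > 0`.
#' @param min_expected Minimum expected cell count before pooling stops
#'   (default 5).
#' @param monte_carlo If `TRUE`, the p-value is simulated (`B` draws)
#'   instead of taken from the chi-square distribution.
#' @param B Number of Monte-Carlo draws.
#' @return A list of class `path_comparison` with the test `statistic`,
#'   `df`, `p.value`, the `observed` (pooled) count matrix, the category
#'   names, and the `pooling_log`.
#' @examples
#' compare_path_distributions(load_fixture("bcm_paths"),
#'                            load_fixture("acm_paths"))
#' @export
compare_path_distributions <- function(table1, table2, min_expected = 5,
                                       monte_carlo = FALSE, B = 2000) {
  stop_if_degenerate(table1)
  stop_if_degenerate(table2)
  if (!identical(table1$protocol$labels, table2$protocol$labels))
    stop("cohorts are on different protocols", call. = FALSE)

  m <- rbind(cohort1 = table1$counts, cohort2 = table2$counts)
  keep <- colSums(m) > 0                 # empty-in-both paths carry no info
  m <- m[, keep, drop = FALSE]
  log <- character(0)

  repeat {
    if (ncol(m) < 2)
      stop("fewer than 2 path categories remain after pooling", call. = FALSE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    min_by_cat <- apply(expected, 2, min)
    if (all(min_by_cat >= min_expected)) break
    # merge the sparsest category into "other"
    ord <- order(min_by_cat)
    victim <- setdiff(colnames(m)[ord], "other")[1]
    if (is.null(victim) || is.na(victim)) break
    if (!"other" %in% colnames(m)) {
      colnames(m)[colnames(m) == victim] <- "other"
      log <- c(log, sprintf("category %s renamed to 'other'", victim))
    } else {
      m[, "other"] <- m[, "other"] + m[, victim]
      m <- m[, colnames(m) != victim, drop = FALSE]
      log <- c(log, sprintf("category %s pooled into 'other'", victim))
    }
  }

  if (identical(table1$counts / table1$N, table2$counts / table2$N)) {
    # identical distributions: statistic exactly 0
    res <- list(statistic = 0, parameter = ncol(m) - 1L, p.value = 1)
  } else {
    res <- suppressWarnings(
      if (monte_carlo) stats::chisq.test(m, simulate.p.value = TRUE, B = B)
      else stats::chisq.test(m, correct = FALSE))
  }
  structure(list(statistic = unname(res$statistic),
                 df = if (monte_carlo) NA_integer_
                      else as.integer(ncol(m) - 1L),
                 p.value = unname(res$p.value),
                 observed = m, categories = colnames(m),
                 pooling_log = log, min_expected = min_expected,
                 monte_carlo = monte_carlo),
            class = "path_comparison")
}

#' @export
print.path_comparison <- function(x, ...) {
  cat(sprintf("Path-distribution homogeneity: X^2 = %.3f, df = %s, p = %.4g%s\n",
              x$statistic, ifelse(is.na(x$df), "MC", x$df), x$p.value,
              if (x$monte_carlo) " (Monte-Carlo)" else ""))
  if (length(x$pooling_log)) {
    cat("pooling (expected <", x$min_expected, "):\n")
    for (l in x$pooling_log) cat(" -", l, "\n")
  }
  invisible(x)
}

#' Serialize a path comparison to JSON
#'
#' Includes the pooling log, so the category construction is auditable.
#'
#' @param comparison A [compare_path_distributions()] result.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_path_comparison_json <- function(comparison, file) {
  obj <- list(statistic = comparison$statistic, df = comparison$df,
              p.value = comparison$p.value,
              categories = comparison$categories,
              observed = apply(comparison$observed, 1, as.list),
              pooling_log = comparison$pooling_log,
              min_expected = comparison$min_expected)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(file)
}

#' Two-sample test of equal proportions
#'
#' Pearson chi-square test (two-sided, without continuity correction by
#' default) that two binomial proportions are equal — used for comparing a
#' single type-specific ratio, a caesarean rate, or any outcome proportion
#' between cohorts.
#'
#' @param k1,n1 Successes and total in cohort 1.
#' @param k2,n2 Successes and total in cohort 2.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A list of class `proportion_test` with `statistic`, `p.value`,
#'   `estimate` (the two proportions) and a `note` for degenerate margins
#'   (all successes or all failures pooled: statistic 0, p = 1).
#' @examples
#' compare_proportions(215, 637, 317, 1375)
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  est <- c(p1 = k1 / n1, p2 = k2 / n2)
  tot_k <- k1 + k2
  if (tot_k == 0 || tot_k == n1 + n2) {
    return(structure(list(statistic = 0, p.value = 1, estimate = est,
                          note = "degenerate margins: no variation in outcome"),
                     class = "proportion_test"))
  }
  res <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = correct))
  structure(list(statistic = unname(res$statistic),
                 p.value = unname(res$p.value), estimate = est,
                 note = NULL),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("Two-sample proportion test: p1 = %.4f, p2 = %.4f, X^2 = %.3f, p = %.4g\n",
              x$estimate["p1"], x$estimate["p2"], x$statistic, x$p.value))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
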