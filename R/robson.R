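#' Robson class vocabulary
#'
#' The ten-group classification splits an obstetric population by parity,
#' previous caesarean, labour onset, gestation, presentation and
#' plurality.  The vocabulary used here includes the common subdivision of
#' groups II and IV by onset (induced vs pre-labour caesarean).
#'
#' @return Character vector of the accepted class labels.
#' @export
robson_classes <- function() {
  c("I", "IIa", "IIb", "III", "IVa", "IVb", "V", "VI", "VII", "VIII",
    "IX", "X")
}

validate_robson_counts <- function(classes) {
  req <- c("class", "women", "caesareans")
  if (!is.data.frame(classes) || !all(req %in% names(classes)))
    stop("Robson counts need columns class, women, caesareans",
         call. = FALSE)
  unknown <- setdiff(classes$class, robson_classes())
  if (length(unknown))
    stop("unknown Robson class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(classes$class))
    stop("duplicated Robson class rows", call. = FALSE)
  with(classes, {
    if (any(women < 0) || any(caesareans < 0) || any(caesareans > women))
      stop("need 0 <= caesareans <= women in every class", call. = FALSE)
  })
  if (sum(classes$women) <= 0)
    stop("no women in any class", call. = FALSE)
  classes
}

#' Standard Robson ten-group report
#'
#' From per-class counts of women and caesarean sections, derives the four
#' standard columns of a Robson report: the relative size of each group
#' (% of all women), the caesarean rate within the group, the contribution
#' of the group to the overall caesarean rate (group caesareans / all
#' women), and the share of all caesareans performed in the group.  A
#' totals row closes the table.  All derived columns are recomputed from
#' the integer counts.
#'
#' @param classes Data frame with columns `class`, `women`, `caesareans`
#'   (one row per Robson class present).
#' @return An object of class `robson_report`: a data frame with the four
#'   derived percentage columns and a `Total` row; the overall caesarean
#'   rate is in `attr(, "overall_cs_rate")`.
#' @examples
#' robson_report(load_fixture("bcm_robson"))
#' @export
robson_report <- function(classes) {
  classes <- validate_robson_counts(classes)
  total_women <- sum(classes$women)
  total_cs <- sum(classes$caesareans)
  rel_size <- 100 * classes$women / total_women
  cs_rate <- ifelse(classes$women > 0,
                    100 * classes$caesareans / classes$women, NA_real_)
  contribution <- 100 * classes$caesareans / total_women
  pct_of_cs <- if (total_cs > 0) 100 * classes$caesareans / total_cs
               else rep(NA_real_, nrow(classes))
  out <- data.frame(class = c(classes$class, "Total"),
                    women = c(classes$women, total_women),
                    caesareans = c(classes$caesareans, total_cs),
                    relative_size = c(rel_size, 100),
                    cs_rate = c(cs_rate, 100 * total_cs / total_women),
                    contribution = c(contribution,
                                     100 * total_cs / total_women),
                    pct_of_cs = c(pct_of_cs,
                                  if (total_cs > 0) 100 else NA_real_),
                    stringsAsFactors = FALSE)
  structure(out, class = c("robson_report", "data.frame"),
            overall_cs_rate = 100 * total_cs / total_women)
}

#' @export
print.robson_report <- function(x, ...) {
  shown <- as.data.frame(x)
  for (col in c("relative_size", "cs_rate", "contribution", "pct_of_cs"))
    shown[[col]] <- round(shown[[col]], 1)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Directly standardized treatment ratio across Robson classes
#'
#' Crude ratios of two cohorts are confounded by case mix: a cohort with
#' more women in high-intervention Robson classes will show a higher crude
#' ratio even with identical class-specific practice.  Direct
#' standardization removes this by averaging the class-specific
#' functionals with a fixed set of reference weights:
#' `H_std = sum_c w_c * H(c) / sum_c w_c`.
#' The default reference is the pooled class distribution of the two
#' cohorts.
#'
#' @param tables1,tables2 Named lists of [path_count_table()]s, one per
#'   Robson class, for the two cohorts.
#' @param weights Optional named nonnegative weights per class (any scale;
#'   they are normalised).  Classes with positive weight must be present
#'   with `N > 0` in both cohorts.
#' @param functional `"H"` or a character vector of protocol labels (as in
#'   [stepwise_replacement()]).
#' @return A list of class `standardized_ratio` with the per-class values,
#'   the weights used, the standardized value for each cohort and their
#'   difference.
#' @export
standardized_ratio <- function(tables1, tables2, weights = NULL,
                               functional = "H") {
  if (is.null(names(tables1)) || is.null(names(tables2)))
    stop("class tables must be named by Robson class", call. = FALSE)
  if (is.null(weights)) {
    classes <- union(names(tables1), names(tables2))
    weights <- vapply(classes, function(cl)
      (if (cl %in% names(tables1)) tables1[[cl]]$N else 0) +
      (if (cl %in% names(tables2)) tables2[[cl]]$N else 0), numeric(1))
  }
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  active <- names(weights)[weights > 0]

  value_in <- function(tables, cl, cohort) {
    if (!cl %in% names(tables) || tables[[cl]]$N == 0)
      stop("class ", cl, " has weight > 0 but no women in cohort ", cohort,
           call. = FALSE)
    if (identical(functional, "H")) overall_treatment_ratio(tables[[cl]])$H
    else aggregate_ratio(tables[[cl]], functional)
  }
  v1 <- vapply(active, value_in, numeric(1), tables = tables1, cohort = 1)
  v2 <- vapply(active, value_in, numeric(1), tables = tables2, cohort = 2)
  w <- weights[active] / sum(weights[active])
  structure(list(per_class = data.frame(class = active, weight = w,
                                        cohort1 = v1, cohort2 = v2,
                                        row.names = NULL),
                 cohort1 = sum(w * v1), cohort2 = sum(w * v2),
                 difference = sum(w * (v2 - v1)), functional = functional),
            class = "standardized_ratio")
}

#' @export
print.standardized_ratio <- function(x, ...) {
  fname <- if (identical(x$functional, "H")) "H"
           else paste0("H_", paste(x$functional, collapse = "+"))
  cat("Directly standardized", fname, "\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("standardized: cohort 1 = %.4f, cohort 2 = %.4f, difference = %.4f\n",
              x$cohort1, x$cohort2, x$difference))
  invisible(x)
}

#' Read Robson class counts from CSV
#'
#' Expects columns `class`, `women`, `caesareans`; validates labels against
#' [robson_classes()] and count consistency.
#'
#' @param file Path to the CSV file.
#' @return A validated data frame.
#' @export
read_robson_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_robson_counts(d)
}
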