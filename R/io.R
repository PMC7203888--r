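#' Read a path-count CSV
#'
#' Dialect: UTF-8, comma-separated, point decimals, header row; one 0/1
#' column per protocol label plus a `count` column.  When no protocol is
#' given, the labels are taken to be every column except `count`, in file
#' order.
#'
#' @param file Path to the CSV file.
#' @param protocol Optional [intervention_protocol()].
#' @return A [path_count_table()].
#' @export
read_path_counts <- function(file, protocol = NULL) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"count" %in% names(d))
    stop("path-count CSV needs a 'count' column (", file, ")", call. = FALSE)
  if (is.null(protocol))
    protocol <- intervention_protocol(setdiff(names(d), "count"))
  path_count_table(d, protocol)
}

#' Write a path-count table as CSV
#'
#' Canonical path order; read back with [read_path_counts()] for an exact
#' round trip.
#'
#' @param table A [path_count_table()].
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_path_counts <- function(table, file) {
  stopifnot(inherits(table, "path_count_table"))
  d <- as.data.frame(table)
  d$treatments <- NULL
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read per-woman records from CSV
#'
#' One row per woman; required 0/1 columns named after the protocol labels
#' (or raw `amniotomy`/`oxytocin` columns, which
#' [path_table_from_records()] merges into augmentation); optional
#' `woman_id` and `robson_class` columns.
#'
#' @param file Path to the CSV file.
#' @return A data frame (validation happens at aggregation time, with row
#'   and column named in any error).
#' @export
read_woman_records <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

resolve_cohort <- function(source, protocol) {
  if (inherits(source, "path_count_table")) return(source)
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source))
      stop("no such cohort file: ", source, call. = FALSE)
    return(read_path_counts(source, protocol))
  }
  if (is.data.frame(source))
    return(path_table_from_records(source,
                                   protocol %||% intervention_protocol()))
  stop("cannot interpret cohort source of class ",
       paste(class(source), collapse = "/"), call. = FALSE)
}

#' Full two-cohort comparison
#'
#' Runs the whole pipeline on two cohorts: per-cohort measure reports,
#' the multiplicative treated-proportion decomposition, progression
#' proportions with stepwise-replacement decompositions for the requested
#' functionals, and the path-distribution homogeneity test.  This is the
#' programmatic core of the command-line `compare` verb.
#'
#' @param cohort1,cohort2 Each a [path_count_table()], a path-count CSV
#'   path, or a per-woman record data frame.
#' @param protocol Optional [intervention_protocol()]; protocols of the
#'   two cohorts must agree.
#' @param functionals List of functionals for [stepwise_replacement()]
#'   (default the OTR, the caesarean ratio and the operative-delivery
#'   aggregate for a 3-intervention protocol; just `"H"` otherwise).
#' @param order Replacement order (default natural order).
#' @param min_expected Pooling threshold for the path-distribution test.
#' @return A list of class `comparison_report` with components `cohort1`,
#'   `cohort2` (measure reports), `form1`, `pps1`, `pps2`, `stepwise`
#'   (one decomposition per functional), and `path_test`.
#' @examples
#' run_compare(load_fixture("bcm_paths"), load_fixture("acm_paths"))
#' @export
run_compare <- function(cohort1, cohort2, protocol = NULL,
                        functionals = NULL, order = NULL, min_expected = 5) {
  t1 <- resolve_cohort(cohort1, protocol)
  t2 <- resolve_cohort(cohort2, protocol)
  if (!identical(t1$protocol$labels, t2$protocol$labels))
    stop("cohorts are on different protocols: ",
         paste(t1$protocol$labels, collapse = ","), " vs ",
         paste(t2$protocol$labels, collapse = ","), call. = FALSE)
  if (is.null(functionals)) {
    functionals <- if (t1$protocol$n == 3 &&
                       identical(t1$protocol$labels, c("A", "V", "C")))
      list("H", "C", c("V", "C")) else list("H")
  }
  pps1 <- estimate_progression_proportions(t1)
  pps2 <- estimate_progression_proportions(t2)
  stepwise <- lapply(functionals, function(f)
    stepwise_replacement(pps1, pps2, functional = f, order = order))
  names(stepwise) <- vapply(functionals, function(f)
    if (identical(f, "H")) "H" else paste0("H_", paste(f, collapse = "+")),
    character(1))
  structure(list(cohort1 = measure_report(t1), cohort2 = measure_report(t2),
                 form1 = form1_decompose(t1, t2),
                 pps1 = pps1, pps2 = pps2, stepwise = stepwise,
                 path_test = compare_path_distributions(
                   t1, t2, min_expected = min_expected)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Cohort 1 ==\n"); print(x$cohort1)
  cat("== Cohort 2 ==\n"); print(x$cohort2)
  cat("== Treated-proportion decomposition ==\n"); print(x$form1)
  for (nm in names(x$stepwise)) {
    cat("== Stepwise decomposition:", nm, "==\n")
    print(x$stepwise[[nm]])
  }
  cat("== Path distributions ==\n"); print(x$path_test)
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' Full float precision (rounding happens only in printed renderings);
#' [read_report_json()] parses the file back.
#'
#' @param report A [run_compare()] result.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_report_json <- function(report, file) {
  obj <- list(
    cohort1 = unclass(report$cohort1),
    cohort2 = unclass(report$cohort2),
    form1 = unclass(report$form1),
    pps1 = list(pp = as.list(report$pps1$p),
                denominators = as.list(report$pps1$denominators)),
    pps2 = list(pp = as.list(report$pps2$p),
                denominators = as.list(report$pps2$denominators)),
    stepwise = lapply(report$stepwise, function(s)
      list(functional = s$functional, order = s$order,
           values = as.list(s$values),
           differences = as.list(s$differences),
           contributions = as.list(s$contributions))),
    path_test = list(statistic = report$path_test$statistic,
                     df = report$path_test$df,
                     p.value = report$path_test$p.value,
                     categories = report$path_test$categories,
                     pooling_log = report$path_test$pooling_log))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(file)
}

#' Read a comparison report written by [write_report_json()]
#'
#' @param file Path to the JSON file.
#' @return The parsed report as a list (numbers at full precision).
#' @export
read_report_json <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
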