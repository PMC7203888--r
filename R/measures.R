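#' Overall treatment ratio and iatrogenic labour index
#'
#' The simplest measures of intervention intensity in a cohort of `N` women
#' who received `E` treatments in total: the overall treatment ratio
#' (OTR) `H = E/N`, the average number of treatments per woman (untreated
#' women included), ranging from 0 (nobody treated) to `n` (everyone
#' receives every treatment); and the iatrogenic labour index
#' `ILI = H/n` in `[0, 1]`, which normalises the total intervention burden
#' by the maximum hypothetically administrable (`n` treatments to each of
#' `N` women).
#'
#' Ratios are formed from the exact integer numerator and denominator,
#' which are retained in the result.
#'
#' @param table A [path_count_table()] with `N > 0`.
#' @return A list of class `measure_set` with elements `E`, `N`, `H`,
#'   `ILI` and `n`.
#' @examples
#' tab <- load_fixture("bcm_paths")
#' overall_treatment_ratio(tab)
#' @export
overall_treatment_ratio <- function(table) {
  stop_if_degenerate(table)
  treatments <- as.integer(rowSums(table$paths))
  E <- sum(treatments * table$counts)
  structure(list(E = E, N = table$N, H = E / table$N,
                 ILI = E / (table$N * table$protocol$n),
                 n = table$protocol$n),
            class = "measure_set")
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf("E = %d treatments over N = %d women\nH (OTR) = %.3f  ILI = %.3f\n",
              x$E, x$N, x$H, x$ILI))
  invisible(x)
}

#' Multiplicative split of the OTR: treated proportion and intensity
#'
#' Writes `H = S * H_T` where `S = (N - N0)/N` is the proportion of women
#' who received at least one treatment (`N0` = untreated count) and
#' `H_T = E/(N - N0)` is the mean number of treatments among treated
#' women.  `H_T` is reported as `NA` when no woman was treated.
#'
#' @inheritParams overall_treatment_ratio
#' @return A list of class `form1_components` with elements `N0`, `S` and
#'   `H_T`.
#' @export
form1_components <- function(table) {
  stop_if_degenerate(table)
  treatments <- rowSums(table$paths)
  N0 <- sum(table$counts[treatments == 0])
  treated <- table$N - N0
  E <- sum(treatments * table$counts)
  structure(list(N0 = N0, S = treated / table$N,
                 H_T = if (treated > 0) E / treated else NA_real_),
            class = "form1_components")
}

#' @export
print.form1_components <- function(x, ...) {
  cat(sprintf("Treated proportion S = %.3f; mean treatments among treated H_T = %s\n",
              x$S, if (is.na(x$H_T)) "undefined (nobody treated)"
                   else sprintf("%.3f", x$H_T)))
  invisible(x)
}

#' Type-specific treatment ratios
#'
#' The OTR does not distinguish intervention types: the same `H` can arise
#' from many augmentations or from many caesareans.  The type-specific
#' treatment ratio (STR) for intervention `j` is `H_j = E_j/N`, the
#' proportion of women who received `j`; the STRs sum to `H`.
#'
#' @inheritParams overall_treatment_ratio
#' @return A list of class `type_specific_ratios` with named vectors `E_j`
#'   and `H_j` (one entry per protocol label) plus `N`.
#' @export
type_specific_ratios <- function(table) {
  stop_if_degenerate(table)
  E_j <- as.integer(colSums(table$paths * table$counts))
  names(E_j) <- table$protocol$labels
  structure(list(E_j = E_j, H_j = E_j / table$N, N = table$N),
            class = "type_specific_ratios")
}

#' @export
print.type_specific_ratios <- function(x, ...) {
  d <- data.frame(E = x$E_j, H = round(x$H_j, 4))
  print(d)
  invisible(x)
}

#' Aggregate treatment ratio over a subset of interventions
#'
#' Sum of the type-specific ratios over a subset of the protocol, e.g.
#' `H_V + H_C` as the overall intensity of operative delivery.  With the
#' full protocol as subset this is the OTR itself.
#'
#' @inheritParams overall_treatment_ratio
#' @param subset Character vector of protocol labels.
#' @return The aggregate ratio (a single number).
#' @examples
#' aggregate_ratio(load_fixture("bcm_paths"), c("V", "C"))
#' @export
aggregate_ratio <- function(table, subset) {
  stop_if_degenerate(table)
  unknown <- setdiff(subset, table$protocol$labels)
  if (length(unknown))
    stop("unknown intervention label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tsr <- type_specific_ratios(table)
  sum(tsr$H_j[subset])
}

#' Distribution of the number of treatments and of the paths
#'
#' `H` is also the mean of the distribution of the number of treatments
#' received: with `f_i = N_i/N` the proportion of women with `i`
#' treatments, `H = sum(i * f_i)`; and equivalently the path-weighted mean
#' `H = sum((x+y+z) * f(x,y,z))` over the path proportions
#' `f(path) = N(path)/N`.  Aggregating paths with the same number of
#' treatments collapses the path form into the count form.
#'
#' @inheritParams overall_treatment_ratio
#' @return A list of class `treatment_count_distribution` with `N_i`,
#'   `f_i` (indexed `0..n`), `f_path` (canonical path order) and `mean`.
#' @export
treatment_count_distribution <- function(table) {
  stop_if_degenerate(table)
  treatments <- rowSums(table$paths)
  n <- table$protocol$n
  N_i <- vapply(0:n, function(i) sum(table$counts[treatments == i]), numeric(1))
  names(N_i) <- as.character(0:n)
  f_i <- N_i / table$N
  f_path <- table$counts / table$N
  structure(list(N_i = N_i, f_i = f_i, f_path = f_path,
                 mean = sum((0:n) * f_i)),
            class = "treatment_count_distribution")
}

#' @export
print.treatment_count_distribution <- function(x, ...) {
  cat("Treatments received:\n")
  print(data.frame(i = names(x$N_i), N_i = as.integer(x$N_i),
                   f_i = round(x$f_i, 4), row.names = NULL))
  cat(sprintf("mean (= H): %.4f\n", x$mean))
  invisible(x)
}

#' Full measure report for one cohort
#'
#' Bundles the OTR/ILI, the treated-proportion split, the type-specific
#' ratios and the treatment-count distribution for a single cohort, with a
#' JSON serialisation and a plain-text rendering.
#'
#' @inheritParams overall_treatment_ratio
#' @return A list of class `measure_report`.
#' @export
measure_report <- function(table) {
  ms <- overall_treatment_ratio(table)
  f1 <- form1_components(table)
  tsr <- type_specific_ratios(table)
  dist <- treatment_count_distribution(table)
  structure(list(N = ms$N, E = ms$E, H = ms$H, ILI = ms$ILI,
                 N0 = f1$N0, S = f1$S, H_T = f1$H_T,
                 E_j = as.list(tsr$E_j), H_j = as.list(tsr$H_j),
                 f_i = as.list(dist$f_i), f_path = as.list(dist$f_path),
                 stratum = table$stratum),
            class = "measure_report")
}

#' Write a measure report as JSON
#'
#' @param report A [measure_report()].
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_measure_report <- function(report, file) {
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(file)
}

#' @export
print.measure_report <- function(x, ...) {
  cat(sprintf("N = %d women, E = %d treatments\n", x$N, x$E))
  cat(sprintf("H (OTR) = %.3f   ILI = %.3f   S = %.3f   H_T = %s\n",
              x$H, x$ILI, x$S,
              if (is.na(x$H_T)) "undefined" else sprintf("%.3f", x$H_T)))
  cat("Type-specific ratios:\n")
  print(data.frame(E = unlist(x$E_j), H = round(unlist(x$H_j), 4)))
  invisible(x)
}
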