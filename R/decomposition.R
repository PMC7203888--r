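#' Multiplicative decomposition of an OTR difference
#'
#' Under the split `H = S * H_T` (treated proportion times intensity among
#' the treated), the relative difference between two cohorts decomposes
#' exactly as
#' `(H2 - H1)/H1 = relS + relHT + relS * relHT`,
#' the relative change in `S`, plus the relative change in `H_T`, plus the
#' interaction of the two.  This answers whether a change in overall
#' intervention intensity came mainly from treating fewer (more) women or
#' from treating each treated woman less (more).
#'
#' @param table1,table2 Baseline and comparison [path_count_table()]s on
#'   the same protocol, both with `N > 0` and with `S > 0` in cohort 1.
#' @return A list of class `form1_decomposition` with `rel_S`, `rel_HT`,
#'   `interaction` and `total` (all relative to cohort 1).
#' @examples
#' form1_decompose(load_fixture("bcm_paths"), load_fixture("acm_paths"))
#' @export
form1_decompose <- function(table1, table2) {
  f1 <- form1_components(table1)
  f2 <- form1_components(table2)
  if (f1$S == 0)
    stop("cohort 1 has no treated women: relative changes undefined",
         call. = FALSE)
  H1 <- overall_treatment_ratio(table1)$H
  H2 <- overall_treatment_ratio(table2)$H
  rel_S <- (f2$S - f1$S) / f1$S
  HT2 <- if (is.na(f2$H_T)) 0 else f2$H_T    # S2 = 0 implies H2 = 0
  rel_HT <- (HT2 - f1$H_T) / f1$H_T
  structure(list(rel_S = rel_S, rel_HT = rel_HT,
                 interaction = rel_S * rel_HT,
                 total = (H2 - H1) / H1,
                 H1 = H1, H2 = H2),
            class = "form1_decomposition")
}

#' @export
print.form1_decomposition <- function(x, ...) {
  cat(sprintf("Relative difference (H2 - H1)/H1 = %.4f\n", x$total))
  cat(sprintf("  change in treated proportion S: %+.4f\n", x$rel_S))
  cat(sprintf("  change in intensity H_T:        %+.4f\n", x$rel_HT))
  cat(sprintf("  interaction:                    %+.4f\n", x$interaction))
  invisible(x)
}

# evaluate a treatment-ratio functional on a named pp vector
evaluate_functional <- function(p, protocol, functional) {
  v <- stats::setNames(numeric(protocol$n), protocol$labels)
  for (j in seq_len(protocol$n)) {
    v[j] <- p[paste0("O->", protocol$labels[j])]
    if (j > 1)
      for (i in seq_len(j - 1))
        v[j] <- v[j] + v[i] * p[paste0(protocol$labels[i], "->",
                                       protocol$labels[j])]
  }
  if (identical(functional, "H")) return(sum(v))
  unknown <- setdiff(functional, protocol$labels)
  if (length(unknown))
    stop("functional must be \"H\" or a subset of the protocol labels; ",
         "unknown: ", paste(unknown, collapse = ", "), call. = FALSE)
  sum(v[functional])
}

#' Stepwise-replacement decomposition of a functional difference
#'
#' Attributes the difference in a treatment-ratio functional between two
#' cohorts to the individual progression proportions.  Starting from the
#' cohort-1 PPs, each PP is replaced in turn by its cohort-2 value; after
#' step `i` the functional takes an intermediate value `H*_i`, with
#' `H*_0 = H_1` and, after the last replacement, `H*_k = H_2`.  The partial
#' differences `delta_i = H*_i - H*_(i-1)` sum exactly to `H_2 - H_1` and
#' quantify the contribution of each PP under the chosen order.  Scaled
#' contributions express every step relative to the magnitude of the first
#' one (`100 * delta_i / |delta_1|`, so the first step is +-100).
#'
#' The default order replaces PPs leading to less invasive treatments
#' first: source state ascending, then target ascending
#' (`O->A, O->V, O->C, A->V, A->C, V->C` for the default protocol).  The
#' endpoints never depend on the order; the attribution in between does —
#' see [order_sensitivity()].
#'
#' @param pps1,pps2 `progression_proportions` on the same protocol
#'   (cohort 1 and cohort 2).
#' @param functional `"H"` for the OTR, a single protocol label for one
#'   type-specific ratio, or a character vector of labels for an aggregate
#'   (e.g. `c("V", "C")` for operative delivery).
#' @param order Permutation of [pp_labels()]; default the natural order
#'   above.
#' @return A list of class `stepwise_decomposition` with `order`,
#'   `values` (`H*_0 .. H*_k`), `differences` (`delta_i`), and
#'   `contributions` (scaled; all `NA` when `delta_1 = 0`).
#' @examples
#' p1 <- estimate_progression_proportions(load_fixture("bcm_paths"))
#' p2 <- estimate_progression_proportions(load_fixture("acm_paths"))
#' stepwise_replacement(p1, p2, functional = "H")
#' @export
stepwise_replacement <- function(pps1, pps2, functional = "H", order = NULL) {
  stopifnot(inherits(pps1, "progression_proportions"),
            inherits(pps2, "progression_proportions"))
  if (!identical(pps1$protocol$labels, pps2$protocol$labels))
    stop("the two PP sets are on different protocols", call. = FALSE)
  protocol <- pps1$protocol
  labels <- pp_labels(protocol)
  if (is.null(order)) order <- labels
  if (!identical(sort(order), sort(labels)))
    stop("order must be a permutation of the PP labels", call. = FALSE)
  p1 <- pp_vector(pps1)
  p2 <- pp_vector(pps2)

  values <- numeric(length(order) + 1L)
  p <- p1
  values[1] <- evaluate_functional(p, protocol, functional)
  for (i in seq_along(order)) {
    p[order[i]] <- p2[order[i]]
    values[i + 1] <- evaluate_functional(p, protocol, functional)
  }
  names(values) <- c("start", order)
  differences <- stats::setNames(diff(values), order)
  contributions <- if (differences[1] == 0)
    stats::setNames(rep(NA_real_, length(order)), order)
  else 100 * differences / abs(differences[1])
  structure(list(functional = functional, order = order, values = values,
                 differences = differences, contributions = contributions),
            class = "stepwise_decomposition")
}

#' @export
print.stepwise_decomposition <- function(x, ...) {
  fname <- if (identical(x$functional, "H")) "H"
           else paste0("H_", paste(x$functional, collapse = "+"))
  cat("Stepwise replacement decomposition of", fname, "\n")
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("total difference: %.4f\n", sum(x$differences)))
  invisible(x)
}

#' @export
as.data.frame.stepwise_decomposition <- function(x, ...) {
  data.frame(step = c("start", x$order),
             value = as.numeric(x$values),
             difference = c(NA, as.numeric(x$differences)),
             contribution = c(NA, as.numeric(x$contributions)))
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Order sensitivity of the stepwise decomposition
#'
#' The stepwise attribution depends on the replacement order (only the
#' endpoints are order-free).  This runs [stepwise_replacement()] for every
#' permutation of the PP labels (or a seeded random sample of permutations
#' when the factorial count exceeds `cap`) and summarises, per PP, the
#' spread of its partial difference across orders.  The mean over all
#' orders is the Shapley attribution of that PP.
#'
#' @inheritParams stepwise_replacement
#' @param cap Maximum number of permutations enumerated exhaustively
#'   (default `5040 = 7!`).
#' @param sample_size When the factorial count exceeds `cap`, the number of
#'   random orders to draw; an error if left `NULL` in that case.
#' @param seed Seed for the permutation sample (only used when sampling).
#' @return A list of class `order_sensitivity` with the per-order matrix of
#'   partial differences (`differences`, orders in rows) and a `summary`
#'   data frame (per PP: min, mean, max of the partial difference).
#' @export
order_sensitivity <- function(pps1, pps2, functional = "H", cap = 5040,
                              sample_size = NULL, seed = 1L) {
  labels <- pp_labels(pps1$protocol)
  k <- length(labels)
  n_orders <- factorial(k)
  if (n_orders <= cap) {
    orders <- all_permutations(labels)
    exhaustive <- TRUE
  } else {
    if (is.null(sample_size))
      stop("factorial(", k, ") = ", n_orders, " orders exceed the cap of ",
           cap, "; give sample_size to sample orders instead", call. = FALSE)
    set.seed(seed)
    orders <- replicate(sample_size, sample(labels), simplify = FALSE)
    exhaustive <- FALSE
  }
  diffs <- t(vapply(orders, function(ord) {
    d <- stepwise_replacement(pps1, pps2, functional, order = ord)$differences
    d[labels]
  }, numeric(k)))
  colnames(diffs) <- labels
  summary <- data.frame(pp = labels,
                        min = apply(diffs, 2, min),
                        mean = colMeans(diffs),
                        max = apply(diffs, 2, max),
                        row.names = NULL)
  structure(list(differences = diffs, summary = summary,
                 exhaustive = exhaustive, functional = functional),
            class = "order_sensitivity")
}

#' @export
print.order_sensitivity <- function(x, ...) {
  cat(if (x$exhaustive) "Exhaustive" else "Sampled",
      "order sensitivity over", nrow(x$differences), "replacement orders\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Render a stepwise decomposition as a grid
#'
#' A wide grid in the layout used for reporting replacement algorithms:
#' one row per PP showing its value at every step (the replaced entries
#' switching from cohort 1 to cohort 2), then the functional value per
#' step, the partial differences and the scaled contributions.
#'
#' @param decomposition A [stepwise_replacement()] result.
#' @param pps1,pps2 The PP sets that produced it.
#' @param file Optional path; when given, the grid is written as CSV.
#' @param digits Rounding for display (default 3).
#' @return The grid as a data frame (invisibly when `file` is given).
#' @export
decomposition_grid <- function(decomposition, pps1, pps2, file = NULL,
                               digits = 3) {
  labels <- decomposition$order
  p1 <- pp_vector(pps1, warn = FALSE)
  p2 <- pp_vector(pps2, warn = FALSE)
  k <- length(labels)
  grid <- matrix(NA_real_, nrow = k + 3, ncol = k + 2,
                 dimnames = list(c(labels, "functional", "difference",
                                   "contribution"),
                                 c("cohort1", labels, "cohort2")))
  for (i in seq_len(k)) {
    lab <- labels[i]
    grid[lab, ] <- c(p1[lab],
                     ifelse(seq_len(k) >= i, p2[lab], p1[lab]),
                     p2[lab])
  }
  grid["functional", ] <- c(decomposition$values,
                            decomposition$values[k + 1])
  grid["difference", 2:(k + 1)] <- decomposition$differences
  grid["contribution", 2:(k + 1)] <- decomposition$contributions
  out <- as.data.frame(round(grid, digits))
  out <- cbind(row = rownames(grid), out)
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
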