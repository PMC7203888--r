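#' Progression-proportion labels of a protocol
#'
#' Labour is represented as an absorbing forward chain over the states
#' onset `O`, the protocol's treatments, and birth `B`.  The free
#' parameters are the progression proportions (PPs) `p[s->t]`: the
#' proportion of women in state `s` whose next treatment is `t` (a strictly
#' later state); the remainder `1 - sum_t p[s->t]` exits directly to birth.
#' Labels are ordered source-ascending then target-ascending — for the
#' default protocol `O->A, O->V, O->C, A->V, A->C, V->C` — which is also
#' the default replacement order in [stepwise_replacement()].
#'
#' @param protocol An [intervention_protocol()].
#' @return Character vector of PP labels, e.g. `"O->A"`.
#' @export
pp_labels <- function(protocol = intervention_protocol()) {
  protocol <- as_protocol(protocol)
  sources <- c("O", protocol$labels[-protocol$n])
  unlist(lapply(seq_along(sources), function(i) {
    targets <- protocol$labels[seq(i, protocol$n)]
    paste0(sources[i], "->", targets)
  }))
}

new_progression_proportions <- function(p, denominators, protocol) {
  structure(list(protocol = protocol, p = p, denominators = denominators,
                 defined = !is.na(p)),
            class = "progression_proportions")
}

#' Construct a progression-proportion set from values
#'
#' @param p Named numeric vector with one entry per label of
#'   [pp_labels()]; values in `[0, 1]`, with per-source sums at most 1.
#' @param protocol An [intervention_protocol()].
#' @param denominators Optional named vector of the numbers of women at
#'   risk behind each estimate.
#' @return An object of class `progression_proportions`.
#' @examples
#' progression_proportions(c("O->A" = .3, "O->V" = .02, "O->C" = .04,
#'                           "A->V" = .08, "A->C" = .18, "V->C" = .07))
#' @export
progression_proportions <- function(p, protocol = intervention_protocol(),
                                    denominators = NULL) {
  protocol <- as_protocol(protocol)
  labels <- pp_labels(protocol)
  if (is.null(names(p)) && length(p) == length(labels)) names(p) <- labels
  missing_lab <- setdiff(labels, names(p))
  if (length(missing_lab))
    stop("missing progression proportion(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  p <- p[labels]
  validate_pp_values(p, protocol)
  if (is.null(denominators))
    denominators <- stats::setNames(rep(NA_real_, length(p)), labels)
  new_progression_proportions(p, denominators[labels], protocol)
}

validate_pp_values <- function(p, protocol) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok))
    stop("progression proportions must lie in [0, 1]; offending: ",
         paste(names(p)[!ok], collapse = ", "), call. = FALSE)
  src <- sub("->.*", "", names(p))
  sums <- tapply(ifelse(is.na(p), 0, p), src, sum)
  if (any(sums > 1 + 1e-12))
    stop("progression proportions from state(s) ",
         paste(names(sums)[sums > 1 + 1e-12], collapse = ", "),
         " sum to more than 1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.progression_proportions <- function(x, ...) {
  d <- data.frame(transition = names(x$p), p = round(x$p, 4),
                  at_risk = x$denominators, row.names = NULL)
  print(d)
  if (any(!x$defined))
    cat("undefined (state never reached):",
        paste(names(x$p)[!x$defined], collapse = ", "), "\n")
  invisible(x)
}

#' Estimate progression proportions from a path-count table
#'
#' History-pooled maximum-likelihood estimates: `p[s->t]` is the number of
#' women whose first treatment after state `s` is `t` (the next 1-flag in
#' protocol order), divided by the number of women who reach `s` (every
#' woman reaches `O`; a treatment state is reached iff its flag is 1).
#' Women arriving at `s` by different routes are pooled — e.g. `p[V->C]`
#' pools women who reached ventouse directly and via augmentation — which
#' makes the visit-probability identity `N * v_j = E_j` exact (see
#' [visit_probabilities()]).
#'
#' States never reached give undefined entries (`NA`), flagged in the
#' result; downstream functionals treat them as zero with a warning.
#'
#' @param table A [path_count_table()] with `N > 0`.
#' @return An object of class `progression_proportions`.
#' @examples
#' estimate_progression_proportions(load_fixture("bcm_paths"))
#' @export
estimate_progression_proportions <- function(table) {
  stop_if_degenerate(table)
  protocol <- table$protocol
  n <- protocol$n
  paths <- table$paths
  counts <- table$counts
  labels <- pp_labels(protocol)
  p <- stats::setNames(rep(NA_real_, length(labels)), labels)
  denom <- stats::setNames(rep(0, length(labels)), labels)

  for (i in 0:(n - 1)) {                       # source: O (0) or treatment i
    at_risk <- if (i == 0) rep(TRUE, nrow(paths)) else paths[, i] == 1
    d <- sum(counts[at_risk])
    src <- if (i == 0) "O" else protocol$labels[i]
    for (j in (i + 1):n) {                     # target treatment j
      between <- if (j > i + 1) (i + 1):(j - 1) else integer(0)
      next_is_j <- at_risk & paths[, j] == 1
      for (b in between) next_is_j <- next_is_j & paths[, b] == 0
      lab <- paste0(src, "->", protocol$labels[j])
      denom[lab] <- d
      p[lab] <- if (d > 0) sum(counts[next_is_j]) / d else NA_real_
    }
  }
  new_progression_proportions(p, denom, protocol)
}

# extract a fully-defined pp vector, zero-filling undefined entries
pp_vector <- function(pps, warn = TRUE) {
  stopifnot(inherits(pps, "progression_proportions"))
  p <- pps$p
  if (any(!pps$defined)) {
    if (warn)
      warning("undefined progression proportion(s) treated as 0: ",
              paste(names(p)[!pps$defined], collapse = ", "), call. = FALSE)
    p[!pps$defined] <- 0
  }
  validate_pp_values(p, pps$protocol)
  p
}

#' Visit probabilities of each treatment state
#'
#' The probability that a woman visits treatment `j` — which equals the
#' type-specific ratio `H_j` when the PPs are estimated from the same
#' cohort — computed by forward recursion over the protocol order:
#' `v_j = p[O->j] + sum over i < j of v_i * p[i->j]`.
#' For the default three-intervention protocol this expands to
#' `H_A = p_OA`, `H_V = p_OV + p_OA p_AV`,
#' `H_C = p_OC + p_OA p_AC + p_OV p_VC + p_OA p_AV p_VC`.
#'
#' @param pps A `progression_proportions` object (undefined entries are
#'   treated as zero with a warning).
#' @return Named numeric vector `v`, one entry per protocol label.
#' @export
visit_probabilities <- function(pps) {
  p <- pp_vector(pps)
  protocol <- pps$protocol
  n <- protocol$n
  v <- stats::setNames(numeric(n), protocol$labels)
  for (j in seq_len(n)) {
    v[j] <- p[paste0("O->", protocol$labels[j])]
    if (j > 1)
      for (i in seq_len(j - 1))
        v[j] <- v[j] + v[i] * p[paste0(protocol$labels[i], "->",
                                       protocol$labels[j])]
  }
  v
}

#' Overall treatment ratio as a functional of the progression proportions
#'
#' The OTR equals the sum of the visit probabilities,
#' `H = sum_j v_j(p)` — the expected number of states visited in the
#' forward chain.  When the PPs are estimated from a table this equals the
#' count-based `H` of [overall_treatment_ratio()] exactly.
#'
#' @inheritParams visit_probabilities
#' @return The OTR (single number).
#' @export
otr_from_pps <- function(pps) {
  sum(visit_probabilities(pps))
}

#' Path distribution implied by the Markov assumption
#'
#' Under the Markov (route-independence) assumption the probability of a
#' path visiting treatments `s1 < s2 < ... < sk` is
#' `p[O->s1] * p[s1->s2] * ... * p[s(k-1)->sk] * (1 - sum of exits from sk)`,
#' with the empty path taking `1 - sum of exits from O`.  The implied
#' distribution sums to one and reproduces the visit probabilities, but
#' matches the empirical path frequencies only when history-specific
#' progression behaviour coincides with the pooled one — comparing the two
#' is the basis of [markov_property_test()].
#'
#' @inheritParams visit_probabilities
#' @return Named numeric vector of path probabilities in canonical order.
#' @export
reconstruct_path_distribution <- function(pps) {
  p <- pp_vector(pps)
  protocol <- pps$protocol
  paths <- enumerate_paths(protocol)
  states <- protocol$labels
  exit_prob <- function(state_idx) {        # 0 = O
    src <- if (state_idx == 0) "O" else states[state_idx]
    later <- if (state_idx < protocol$n)
      paste0(src, "->", states[(state_idx + 1):protocol$n]) else character(0)
    1 - sum(p[later])
  }
  probs <- apply(paths, 1L, function(flags) {
    visited <- which(flags == 1)
    pr <- 1
    prev <- 0
    for (s in visited) {
      src <- if (prev == 0) "O" else states[prev]
      pr <- pr * p[paste0(src, "->", states[s])]
      prev <- s
    }
    pr * exit_prob(prev)
  })
  stats::setNames(as.numeric(probs), rownames(paths))
}

#' Test the Markov (route-independence) assumption
#'
#' The Markov representation assumes that the decision to progress from a
#' treatment state depends only on the current state, not on the route by
#' which it was reached.  In real labour-ward data this is an empirical
#' hypothesis.  For every treatment state `s` reachable by at least two
#' distinct histories (subsets of earlier treatments) and every later
#' target `t`, women who reached `s` are cross-classified as history
#' versus whether their next treatment was `t`, and the resulting `k x 2`
#' table is tested with Fisher's exact test — chosen because the
#' history-specific cell counts in cohorts of this size are typically far
#' below chi-square validity thresholds.
#'
#' @param table A [path_count_table()] for a protocol with `n >= 2`.
#' @param adjust Multiplicity adjustment across the reported tests:
#'   `"none"` (default) or `"bonferroni"`.
#' @return An object of class `markov_property_test`: a list with a
#'   data-frame `tests` (state, target, number of histories, counts,
#'   p-value, adjusted p-value), a list `tables` of the underlying
#'   contingency tables, and `skipped` notes for states with fewer than
#'   two observed histories.
#' @examples
#' markov_property_test(load_fixture("bcm_paths"))
#' @export
markov_property_test <- function(table, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stop_if_degenerate(table)
  protocol <- table$protocol
  if (protocol$n < 2)
    stop("the Markov property needs at least two interventions to test",
         call. = FALSE)
  paths <- table$paths
  counts <- table$counts
  rows <- list()
  tables <- list()
  skipped <- character(0)

  for (s in 2:protocol$n) {                 # states reachable by >1 route
    at_s <- paths[, s] == 1
    if (!sum(counts[at_s])) {
      skipped <- c(skipped, sprintf("state %s never reached",
                                    protocol$labels[s]))
      next
    }
    hist_id <- apply(paths[, seq_len(s - 1), drop = FALSE], 1L, paste,
                     collapse = "")
    observed <- unique(hist_id[at_s & counts > 0])
    if (length(observed) < 2) {
      skipped <- c(skipped, sprintf("state %s reached via a single history",
                                    protocol$labels[s]))
      next
    }
    if (s == protocol$n) targets <- integer(0) else targets <- (s + 1):protocol$n
    for (t in targets) {
      between <- if (t > s + 1) (s + 1):(t - 1) else integer(0)
      next_is_t <- at_s & paths[, t] == 1
      for (b in between) next_is_t <- next_is_t & paths[, b] == 0
      m <- t(vapply(observed, function(h) {
        in_h <- at_s & hist_id == h
        c(progressed = sum(counts[in_h & next_is_t]),
          other = sum(counts[in_h & !next_is_t]))
      }, numeric(2)))
      pv <- stats::fisher.test(m)$p.value
      key <- sprintf("%s->%s", protocol$labels[s], protocol$labels[t])
      tables[[key]] <- m
      rows[[length(rows) + 1L]] <- data.frame(
        state = protocol$labels[s], target = protocol$labels[t],
        histories = nrow(m), at_risk = sum(m), p.value = pv,
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(state = character(0), target = character(0),
               histories = integer(0), at_risk = numeric(0),
               p.value = numeric(0))
  tests$p.adjusted <- if (adjust == "bonferroni")
    stats::p.adjust(tests$p.value, "bonferroni") else tests$p.value
  structure(list(tests = tests, tables = tables, skipped = skipped,
                 adjust = adjust),
            class = "markov_property_test")
}

#' @export
print.markov_property_test <- function(x, ...) {
  cat("Markov property test (Fisher exact per state/target",
      if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted"), ")\n",
      sep = "")
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  else cat("no testable states\n")
  for (note in x$skipped) cat("skipped:", note, "\n")
  invisible(x)
}

#' Serialize progression proportions to JSON
#'
#' @param pps A `progression_proportions` object.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_pp_json <- function(pps, file) {
  stopifnot(inherits(pps, "progression_proportions"))
  obj <- list(states = c("O", pps$protocol$labels, "B"),
              protocol = pps$protocol$labels,
              pp = as.list(pps$p),
              denominators = as.list(pps$denominators))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(file)
}

#' Read progression proportions from JSON
#'
#' @param file Path to a JSON file written by [write_pp_json()] (or
#'   hand-authored with the same fields).
#' @return A `progression_proportions` object.
#' @export
read_pp_json <- function(file) {
  obj <- jsonlite::read_json(file)
  protocol <- intervention_protocol(unlist(obj$protocol))
  p <- vapply(obj$pp, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
              numeric(1))
  denom <- if (!is.null(obj$denominators))
    vapply(obj$denominators, function(v)
      if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  progression_proportions(p, protocol, denominators = denom)
}
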