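#' Define a sequential intervention protocol
#'
#' A protocol is an ordered set of interventions, from least to most
#' invasive, that a woman may receive between labour onset (state `O`) and
#' birth (state `B`).  The ordering encodes the sequential-protocol
#' assumption: when a woman receives several interventions, the less
#' invasive ones come first (emergencies appear as direct transitions that
#' skip intermediate states, e.g. straight from onset to caesarean).
#'
#' The default protocol is the three-intervention one used throughout the
#' package documentation: augmentation (`A`, amniotomy and/or synthetic
#' oxytocin after labour onset), ventouse (`V`) and caesarean section (`C`).
#'
#' @param labels Character vector of unique, non-empty intervention names,
#'   ordered least to most invasive.
#' @return An object of class `intervention_protocol`: a list with elements
#'   `labels` and `n` (the number of interventions).
#' @examples
#' intervention_protocol()            # augmentation, ventouse, caesarean
#' intervention_protocol(c("I", "A", "V", "C"))
#' @export
intervention_protocol <- function(labels = c("A", "V", "C")) {
  labels <- as.character(labels)
  if (length(labels) < 1L)
    stop("a protocol needs at least one intervention", call. = FALSE)
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("intervention labels must be non-empty", call. = FALSE)
  if (anyDuplicated(labels))
    stop("intervention labels must be unique", call. = FALSE)
  structure(list(labels = labels, n = length(labels)),
            class = "intervention_protocol")
}

as_protocol <- function(x) {
  if (inherits(x, "intervention_protocol")) return(x)
  intervention_protocol(x)
}

#' @export
print.intervention_protocol <- function(x, ...) {
  cat("Sequential intervention protocol (", x$n, " interventions): ",
      paste(x$labels, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Enumerate all intervention paths of a protocol
#'
#' With `n` sequential interventions a woman can follow any of `2^n`
#' mutually exclusive, exhaustive binary paths: each intervention is either
#' received (1) or not (0).  Paths are returned in canonical binary
#' ascending order with the first (least invasive) intervention as the most
#' significant bit: for the default protocol
#' `(0,0,0), (0,0,1), (0,1,0), (0,1,1), (1,0,0), ...`.
#'
#' Paths combining ventouse and caesarean (e.g. `(0,1,1)`) are legal: they
#' record a failed ventouse followed by caesarean section.
#'
#' @param protocol An [intervention_protocol()] (or a character vector of
#'   labels, which is promoted to one).
#' @return An integer matrix with `2^n` rows and `n` columns named by the
#'   protocol labels; row names are the concatenated binary flags.  The
#'   number of interventions on each path is `rowSums()` of the matrix.
#' @examples
#' enumerate_paths(intervention_protocol())
#' @export
enumerate_paths <- function(protocol = intervention_protocol()) {
  protocol <- as_protocol(protocol)
  n <- protocol$n
  idx <- 0:(2^n - 1L)
  # bit j (from the left) of the row index
  m <- sapply(seq_len(n), function(j) bitwAnd(idx %/% 2^(n - j), 1L))
  m <- matrix(as.integer(m), nrow = 2^n, ncol = n,
              dimnames = list(apply_path_id(idx, n), protocol$labels))
  m
}

apply_path_id <- function(idx, n) {
  vapply(idx, function(i) {
    bits <- as.integer(bitwAnd(i %/% 2^((n - 1):0), 1L))
    paste(bits, collapse = "")
  }, character(1))
}

path_id <- function(flags) {
  if (is.matrix(flags)) apply(flags, 1L, paste, collapse = "")
  else paste(flags, collapse = "")
}
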