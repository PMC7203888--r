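#' Configure a synthetic cohort simulation
#'
#' The generative model is the forward absorbing chain of the Markov
#' representation: every woman starts at labour onset `O`; from her current
#' state she progresses to a later treatment `t` with probability
#' `p[s->t]`, or exits to birth with the remaining probability.  Optional
#' history modifiers break the Markov property in a controlled way: a
#' modifier multiplies the odds of one transition for women whose earlier
#' treatment flags match a specified history (the result is clipped to
#' `[0, 1]`, keeping extreme settings valid).
#'
#' @param pps A `progression_proportions` object (the generative truth).
#' @param N Cohort size.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @param modifiers Optional list of history modifiers, each a list with
#'   elements `state` (source treatment label), `target` (later treatment
#'   label), `history` (named 0/1 vector over earlier treatments that a
#'   woman must match) and `odds_multiplier` (> 0).
#' @return A list of class `simulation_config`.
#' @examples
#' pps <- estimate_progression_proportions(load_fixture("bcm_paths"))
#' simulation_config(pps, N = 1000, seed = 42)
#' @export
simulation_config <- function(pps, N, seed = 1L, modifiers = NULL) {
  stopifnot(inherits(pps, "progression_proportions"))
  if (N < 1 || N != round(N)) stop("N must be a positive integer", call. = FALSE)
  p <- pps$p
  p[is.na(p)] <- 0
  validate_pp_values(p, pps$protocol)
  config <- structure(list(protocol = pps$protocol, p = p, N = as.integer(N),
                           seed = as.integer(seed), modifiers = modifiers),
                      class = "simulation_config")
  validate_modifiers(config)
  config
}

modified_prob <- function(p, multiplier) {
  if (p <= 0 || p >= 1) return(min(max(p, 0), 1))
  odds <- p / (1 - p) * multiplier
  min(max(odds / (1 + odds), 0), 1)
}

# check every effective transition distribution over all possible histories
validate_modifiers <- function(config) {
  protocol <- config$protocol
  if (!is.null(config$modifiers)) {
    for (m in config$modifiers) {
      if (!all(c("state", "target", "history", "odds_multiplier") %in% names(m)))
        stop("each modifier needs state, target, history, odds_multiplier",
             call. = FALSE)
      if (!m$state %in% protocol$labels || !m$target %in% protocol$labels ||
          match(m$target, protocol$labels) <= match(m$state, protocol$labels))
        stop("modifier must act on a forward transition between protocol states",
             call. = FALSE)
      if (m$odds_multiplier < 0)
        stop("odds_multiplier must be nonnegative", call. = FALSE)
      earlier <- protocol$labels[seq_len(match(m$state, protocol$labels) - 1)]
      if (!all(names(m$history) %in% earlier))
        stop("modifier history may only involve treatments earlier than its state",
             call. = FALSE)
    }
  }
  for (i in seq_len(protocol$n - 1)) {       # treatment sources with targets
    earlier <- protocol$labels[seq_len(i - 1)]
    hists <- if (length(earlier))
      as.matrix(expand.grid(rep(list(0:1), length(earlier))))
    else matrix(0, nrow = 1, ncol = 0)
    colnames(hists) <- earlier
    for (h in seq_len(nrow(hists))) {
      probs <- effective_probs(config, i, hists[h, , drop = TRUE])
      if (any(probs < 0 | probs > 1) || sum(probs) > 1 + 1e-12)
        stop("modified transition probabilities from state ",
             protocol$labels[i], " invalid for history ",
             paste(hists[h, ], collapse = ""), call. = FALSE)
    }
  }
  invisible(config)
}

# transition probabilities out of source state i (1-based treatment index;
# 0 = onset) for a woman with the given earlier-treatment flags
effective_probs <- function(config, i, history_flags) {
  protocol <- config$protocol
  src <- if (i == 0) "O" else protocol$labels[i]
  targets <- protocol$labels[seq(i + 1, protocol$n)]
  probs <- config$p[paste0(src, "->", targets)]
  names(probs) <- targets
  if (i > 0 && !is.null(config$modifiers)) {
    for (m in config$modifiers) {
      if (m$state != src) next
      if (length(m$history) &&
          !all(history_flags[names(m$history)] == m$history)) next
      probs[m$target] <- modified_prob(probs[m$target], m$odds_multiplier)
    }
  }
  probs
}

#' Simulate a cohort of intervention paths
#'
#' Draws `N` women through the forward chain of a [simulation_config()]
#' and aggregates their paths.  Sampling is vectorised by source state, in
#' protocol order, with one uniform draw per state visit, so a fixed seed
#' reproduces the cohort exactly.
#'
#' @param config A [simulation_config()].
#' @return A [path_count_table()] on the config's protocol.
#' @examples
#' pps <- estimate_progression_proportions(load_fixture("bcm_paths"))
#' simulate_cohort(simulation_config(pps, N = 500, seed = 7))
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  protocol <- config$protocol
  n <- protocol$n
  set.seed(config$seed)
  flags <- matrix(0L, nrow = config$N, ncol = n,
                  dimnames = list(NULL, protocol$labels))
  state <- integer(config$N)            # 0 = onset; -1 = birth (absorbed)

  for (i in 0:(n - 1)) {
    here <- which(state == i)
    if (!length(here)) next
    u <- stats::runif(length(here))
    if (i == 0 || is.null(config$modifiers)) {
      probs <- effective_probs(config, i, NULL)
      cuts <- cumsum(probs)
      nxt <- rep(-1L, length(here))
      for (j in rev(seq_along(cuts))) nxt[u < cuts[j]] <- i + j
    } else {
      # modifiers may act here: group women by their history
      hist_ids <- apply(flags[here, seq_len(i), drop = FALSE], 1L, paste,
                        collapse = "")
      nxt <- rep(-1L, length(here))
      for (h in unique(hist_ids)) {
        sel <- hist_ids == h
        hv <- as.integer(strsplit(h, "")[[1]])
        names(hv) <- protocol$labels[seq_len(i)]
        cuts <- cumsum(effective_probs(config, i, hv))
        for (j in rev(seq_along(cuts))) {
          hit <- sel & u < cuts[j]
          nxt[hit] <- i + j
        }
      }
    }
    moved <- nxt > 0
    state[here] <- nxt
    if (any(moved))
      flags[cbind(here[moved], nxt[moved])] <- 1L
  }

  ids <- path_id(flags)
  tab <- table(factor(ids, levels = rownames(enumerate_paths(protocol))))
  path_count_table(stats::setNames(as.integer(tab), names(tab)), protocol)
}

#' Parameter-recovery experiment for the PP estimator
#'
#' Simulates `replicates` cohorts from a config (with per-replicate seeds
#' derived from the config seed), re-estimates the progression proportions
#' from each, and reports per-PP bias and root-mean-square error, together
#' with how often each PP was undefined (its source state never reached).
#'
#' @param config A [simulation_config()].
#' @param replicates Number of replicate cohorts (at least 2).
#' @return A list of class `recovery_experiment` with a `summary` data
#'   frame (per PP: truth, mean estimate, bias, RMSE, times undefined) and
#'   the raw estimate matrix.
#' @export
recovery_experiment <- function(config, replicates) {
  if (replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  labels <- pp_labels(config$protocol)
  est <- matrix(NA_real_, nrow = replicates, ncol = length(labels),
                dimnames = list(NULL, labels))
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    tab <- simulate_cohort(cfg)
    est[r, ] <- estimate_progression_proportions(tab)$p
  }
  truth <- config$p[labels]
  defined <- !is.na(est)
  mean_est <- colMeans(est, na.rm = TRUE)
  bias <- mean_est - truth
  rmse <- sqrt(colMeans((est - matrix(truth, nrow = replicates,
                                      ncol = length(labels),
                                      byrow = TRUE))^2, na.rm = TRUE))
  structure(list(summary = data.frame(pp = labels, truth = truth,
                                      mean = mean_est, bias = bias,
                                      rmse = rmse,
                                      n_undefined = colSums(!defined),
                                      row.names = NULL),
                 estimates = est, replicates = replicates,
                 seed = config$seed),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("PP recovery over", x$replicates, "replicates (seed", x$seed, ")\n")
  s <- x$summary
  s[, c("truth", "mean", "bias", "rmse")] <-
    round(s[, c("truth", "mean", "bias", "rmse")], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Read a simulation config from JSON
#'
#' Expects fields `protocol` (labels), `pp` (named object of progression
#' proportions), `N`, `seed`, and optionally `modifiers`.
#'
#' @param file Path to the JSON file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(file) {
  obj <- jsonlite::read_json(file)
  protocol <- intervention_protocol(unlist(obj$protocol))
  p <- vapply(obj$pp, as.numeric, numeric(1))
  mods <- if (!is.null(obj$modifiers))
    lapply(obj$modifiers, function(m)
      list(state = m$state, target = m$target,
           history = unlist(m$history),
           odds_multiplier = as.numeric(m$odds_multiplier)))
  simulation_config(progression_proportions(p, protocol),
                    N = as.integer(obj$N), seed = as.integer(obj$seed),
                    modifiers = mods)
}
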