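# Shared fixtures and independent oracles for the test suite.

bcm <- load_fixture("bcm_paths")
acm <- load_fixture("acm_paths")

# a random valid path-count table on a random protocol
random_table <- function(n = sample(1:4, 1), max_count = 200) {
  protocol <- intervention_protocol(paste0("T", seq_len(n)))
  counts <- rpois(2^n, lambda = runif(1, 1, max_count / 4))
  counts[1] <- counts[1] + 1L  # keep N > 0
  path_count_table(stats::setNames(as.integer(counts),
                                   rownames(enumerate_paths(protocol))),
                   protocol)
}

# random valid progression proportions on a protocol
random_pps <- function(protocol) {
  labels <- pp_labels(protocol)
  src <- sub("->.*", "", labels)
  p <- numeric(length(labels))
  for (s in unique(src)) {
    idx <- which(src == s)
    raw <- runif(length(idx))
    p[idx] <- raw / sum(raw) * runif(1, 0, 0.95)
  }
  progression_proportions(stats::setNames(p, labels), protocol)
}

# brute-force oracle: visit probabilities and path distribution by
# exhaustive enumeration of all 2^n paths (independent of the forward
# recursion in the package)
brute_force_paths <- function(pps) {
  protocol <- pps$protocol
  p <- pps$p
  p[is.na(p)] <- 0
  paths <- enumerate_paths(protocol)
  states <- protocol$labels
  probs <- apply(paths, 1, function(flags) {
    visited <- which(flags == 1)
    pr <- 1
    prev <- "O"
    for (s in visited) {
      pr <- pr * p[paste0(prev, "->", states[s])]
      prev <- states[s]
    }
    last_idx <- if (length(visited)) max(visited) else 0
    later <- if (last_idx < protocol$n)
      paste0(prev, "->", states[(last_idx + 1):protocol$n]) else character(0)
    pr * (1 - sum(p[later]))
  })
  stats::setNames(as.numeric(probs), rownames(paths))
}

brute_force_visits <- function(pps) {
  f <- brute_force_paths(pps)
  paths <- enumerate_paths(pps$protocol)
  stats::setNames(as.numeric(colSums(paths * f)), pps$protocol$labels)
}
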