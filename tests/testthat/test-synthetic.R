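test_that("simulation is seed-deterministic and respects degenerate chains", {
  pps <- estimate_progression_proportions(bcm)
  cfg <- simulation_config(pps, N = 2000, seed = 77)
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1$counts, t2$counts)
  expect_equal(t1$N, 2000)

  zero <- progression_proportions(stats::setNames(rep(0, 6), pp_labels()))
  tz <- simulate_cohort(simulation_config(zero, N = 100, seed = 1))
  expect_equal(unname(tz$counts["000"]), 100L)

  chain <- progression_proportions(c("O->A" = 1, "O->V" = 0, "O->C" = 0,
                                     "A->V" = 1, "A->C" = 0, "V->C" = 1))
  tc <- simulate_cohort(simulation_config(chain, N = 100, seed = 1))
  expect_equal(unname(tc$counts["111"]), 100L)
  expect_equal(overall_treatment_ratio(tc)$H, 3)
})

test_that("estimates from a large simulated cohort recover the truth", {
  pps <- estimate_progression_proportions(bcm)
  tab <- simulate_cohort(simulation_config(pps, N = 1e5, seed = 2024))
  est <- estimate_progression_proportions(tab)
  for (lab in pp_labels()) {
    denom <- est$denominators[lab]
    se <- sqrt(pps$p[lab] * (1 - pps$p[lab]) / denom)
    expect_lt(abs(est$p[lab] - pps$p[lab]), 3 * se + 1e-12)
  }
  # path frequencies converge to the Markov reconstruction
  f_pred <- reconstruct_path_distribution(pps)
  f_emp <- tab$counts / tab$N
  bound <- 4 * sqrt(pmax(f_pred * (1 - f_pred), 1e-12) / tab$N)
  expect_true(all(abs(f_emp - f_pred) < pmax(bound, 1e-3)))
})

test_that("the recovery experiment reports small bias and its undefined entries", {
  pps <- estimate_progression_proportions(bcm)
  rec <- recovery_experiment(simulation_config(pps, N = 10000, seed = 42),
                             replicates = 100)
  s <- rec$summary
  for (i in seq_len(nrow(s))) {
    denom <- switch(substr(s$pp[i], 1, 1),
                    "O" = 10000,
                    "A" = 10000 * pps$p["O->A"],
                    "V" = 10000 * (pps$p["O->V"] +
                                   pps$p["O->A"] * pps$p["A->V"]))
    se_mean <- sqrt(s$truth[i] * (1 - s$truth[i]) / denom) / sqrt(100)
    expect_lt(abs(s$bias[i]), max(3 * se_mean, 5e-4))
  }
  expect_true(all(s$n_undefined == 0))

  # one-woman cohorts: most treatment-source denominators are zero
  tiny <- recovery_experiment(simulation_config(pps, N = 1, seed = 9),
                              replicates = 50)
  expect_gt(sum(tiny$summary$n_undefined), 0)
  expect_error(recovery_experiment(simulation_config(pps, N = 10, seed = 1),
                                   replicates = 1), "at least 2")
})

test_that("history modifiers break the Markov property detectably", {
  pps <- estimate_progression_proportions(bcm)
  mod <- list(list(state = "V", target = "C", history = c(A = 1),
                   odds_multiplier = 4))
  hits <- 0
  replicates <- 200
  for (r in seq_len(replicates)) {
    tab <- simulate_cohort(simulation_config(pps, N = 5000, seed = 3000 + r,
                                             modifiers = mod))
    mt <- markov_property_test(tab)
    hits <- hits + (mt$tests$p.value[mt$tests$state == "V"] < 0.05)
  }
  expect_gt(hits / replicates, 0.8)
})

test_that("modifier configs are validated before sampling", {
  pps <- estimate_progression_proportions(bcm)
  expect_error(simulation_config(pps, N = 10, seed = 1,
                                 modifiers = list(list(state = "C",
                                                       target = "V",
                                                       history = c(A = 1),
                                                       odds_multiplier = 2))),
               "forward transition")
  expect_error(simulation_config(pps, N = 10, seed = 1,
                                 modifiers = list(list(state = "A",
                                                       target = "C",
                                                       history = c(V = 1),
                                                       odds_multiplier = 2))),
               "earlier than its state")
  expect_error(simulation_config(pps, N = 0, seed = 1), "positive integer")

  # extreme multipliers stay valid through odds clipping
  big <- simulation_config(pps, N = 100, seed = 1,
                           modifiers = list(list(state = "V", target = "C",
                                                 history = c(A = 1),
                                                 odds_multiplier = 1e9)))
  tab <- simulate_cohort(big)
  expect_equal(tab$N, 100)
})

test_that("simulation configs round-trip through JSON", {
  pps <- estimate_progression_proportions(bcm)
  f <- withr::local_tempfile(fileext = ".json")
  obj <- list(protocol = list("A", "V", "C"),
              pp = as.list(pps$p), N = 500, seed = 12,
              modifiers = list(list(state = "V", target = "C",
                                    history = list(A = 1),
                                    odds_multiplier = 2)))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = I(17))
  cfg <- read_simulation_config(f)
  expect_equal(cfg$N, 500L)
  expect_equal(cfg$p, pps$p, tolerance = 0)
  expect_equal(cfg$modifiers[[1]]$odds_multiplier, 2)
  tab <- simulate_cohort(cfg)
  expect_equal(tab$N, 500)
})
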