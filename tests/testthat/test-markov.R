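test_that("estimated progression proportions match the published values", {
  p1 <- estimate_progression_proportions(bcm)
  expect_equal(unname(round(p1$p, 3)),
               c(0.338, 0.016, 0.039, 0.079, 0.177, 0.074))
  expect_equal(unname(p1$p), c(215 / 637, 10 / 637, 25 / 637,
                               17 / 215, 38 / 215, 2 / 27))
  expect_equal(unname(p1$denominators), c(637, 637, 637, 215, 215, 27))

  p2 <- estimate_progression_proportions(acm)
  expect_equal(unname(round(p2$p, 3)),
               c(0.231, 0.028, 0.037, 0.088, 0.139, 0.045))
})

test_that("unreached states give undefined PPs that propagate as zeros", {
  tab <- path_count_table(c("000" = 10))
  pps <- estimate_progression_proportions(tab)
  expect_equal(unname(pps$p[c("O->A", "O->V", "O->C")]), c(0, 0, 0))
  expect_true(all(is.na(pps$p[c("A->V", "A->C", "V->C")])))
  expect_warning(v <- visit_probabilities(pps), "treated as 0")
  expect_equal(unname(v), c(0, 0, 0))
  expect_warning(expect_equal(otr_from_pps(pps), 0))
})

test_that("visit probabilities reproduce the type-specific ratios exactly", {
  for (tab in list(bcm, acm)) {
    pps <- estimate_progression_proportions(tab)
    v <- visit_probabilities(pps)
    E_j <- type_specific_ratios(tab)$E_j
    # N * v_j recovers the integer treatment totals
    expect_equal(unname(round(tab$N * v)), as.numeric(E_j), tolerance = 1e-9)
    expect_equal(unname(v), unname(E_j / tab$N), tolerance = 1e-12)
    expect_equal(otr_from_pps(pps), overall_treatment_ratio(tab)$H,
                 tolerance = 1e-12)
  }
  # and on random tables, for protocols beyond n = 3
  set.seed(13)
  for (i in 1:25) {
    tab <- random_table()
    pps <- estimate_progression_proportions(tab)
    v <- suppressWarnings(visit_probabilities(pps))
    E_j <- type_specific_ratios(tab)$E_j
    expect_equal(unname(round(tab$N * v)), as.numeric(E_j), tolerance = 1e-9)
  }
})

test_that("the forward recursion agrees with exhaustive path enumeration", {
  set.seed(31)
  for (n in c(2, 3, 5, 8)) {
    protocol <- intervention_protocol(paste0("T", 1:n))
    pps <- random_pps(protocol)
    expect_equal(visit_probabilities(pps), brute_force_visits(pps),
                 tolerance = 1e-12)
    expect_equal(otr_from_pps(pps), sum(brute_force_visits(pps)),
                 tolerance = 1e-12)
  }
})

test_that("reconstructed path distributions are proper and self-consistent", {
  p1 <- estimate_progression_proportions(bcm)
  f <- reconstruct_path_distribution(p1)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # predicted count for the ventouse-then-caesarean path: 10 * (2/27)
  expect_equal(637 * f[["011"]], 10 * 2 / 27, tolerance = 1e-12)
  # mean treatments of the reconstruction equals the PP-based OTR
  paths <- enumerate_paths(p1$protocol)
  expect_equal(sum(rowSums(paths) * f), otr_from_pps(p1), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:10) {
    protocol <- intervention_protocol(paste0("T", 1:sample(2:5, 1)))
    pps <- random_pps(protocol)
    f <- reconstruct_path_distribution(pps)
    expect_equal(f, brute_force_paths(pps), tolerance = 1e-12)
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("a Markov-consistent cohort is a fixed point of reconstruction", {
  # counts generated exactly from a product chain: reconstruction of the
  # estimated PPs must reproduce the empirical frequencies
  p <- c("O->A" = 0.4, "O->V" = 0.1, "O->C" = 0.1,
         "A->V" = 0.25, "A->C" = 0.25, "V->C" = 0.5)
  pps <- progression_proportions(p)
  f <- reconstruct_path_distribution(pps)
  counts <- round(f * 8000)   # all frequencies are exact multiples
  tab <- path_count_table(stats::setNames(as.integer(counts), names(f)))
  est <- estimate_progression_proportions(tab)
  expect_equal(est$p, p, tolerance = 1e-12)
  expect_equal(reconstruct_path_distribution(est), tab$counts / tab$N,
               tolerance = 1e-12)
})

test_that("the Markov property test matches hand-computed Fisher results", {
  mt <- markov_property_test(bcm)
  expect_equal(nrow(mt$tests), 1)
  expect_equal(mt$tests$state, "V")
  expect_equal(mt$tests$target, "C")
  # direct arrivals: 1 of 10 progressed; via augmentation: 1 of 17
  expect_equal(unname(mt$tables[["V->C"]][, "progressed"] +
                      mt$tables[["V->C"]][, "other"]), c(10, 17))
  expect_equal(mt$tests$p.value, 1.0, tolerance = 1e-12)
  expect_equal(mt$tests$p.value,
               fisher.test(matrix(c(1, 9, 1, 16), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("a gross Markov violation is detected at extreme significance", {
  # 50 direct ventouse arrivals never progress; 50 via-A arrivals always do
  tab <- path_count_table(c("010" = 50, "111" = 50))
  mt <- markov_property_test(tab)
  expect_lt(mt$tests$p.value, 1e-10)
  # oracle: the two extreme tables of the hypergeometric with these margins
  expect_equal(mt$tests$p.value, 2 / choose(100, 50), tolerance = 1e-9)
})

test_that("states with a single observed history are skipped with a note", {
  tab <- path_count_table(c("000" = 5, "110" = 5))  # V only via A
  mt <- markov_property_test(tab)
  expect_equal(nrow(mt$tests), 0)
  expect_true(any(grepl("single history", mt$skipped)))
  expect_error(markov_property_test(path_count_table(c("0" = 1, "1" = 1),
                                                     intervention_protocol("A"))),
               "at least two")
})

test_that("progression proportions round-trip through JSON", {
  pps <- estimate_progression_proportions(bcm)
  f <- withr::local_tempfile(fileext = ".json")
  write_pp_json(pps, f)
  back <- read_pp_json(f)
  expect_equal(back$p, pps$p, tolerance = 0)
  expect_equal(back$protocol$labels, pps$protocol$labels)
})

test_that("invalid PP vectors are rejected", {
  expect_error(progression_proportions(c("O->A" = 1.2, "O->V" = 0,
                                         "O->C" = 0, "A->V" = 0,
                                         "A->C" = 0, "V->C" = 0)),
               "\\[0, 1\\]")
  expect_error(progression_proportions(c("O->A" = 0.6, "O->V" = 0.3,
                                         "O->C" = 0.2, "A->V" = 0,
                                         "A->C" = 0, "V->C" = 0)),
               "sum to more than 1")
})
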