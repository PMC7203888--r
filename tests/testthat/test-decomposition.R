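test_that("the treated-proportion decomposition reproduces the published split", {
  d <- form1_decompose(bcm, acm)
  expect_equal(round(d$rel_S, 4), -0.2476)
  expect_equal(round(d$rel_HT, 4), -0.0352)
  expect_equal(round(d$total, 4), -0.2742)
  expect_equal(round(100 * d$rel_S), -25)       # S fell by about 25%
  # exact additivity of the multiplicative split
  expect_equal(d$total, d$rel_S + d$rel_HT + d$interaction,
               tolerance = 1e-12)
})

test_that("treated-proportion decomposition handles edge constructions", {
  expect_equal(form1_decompose(bcm, bcm)$total, 0, tolerance = 1e-15)
  expect_equal(form1_decompose(bcm, bcm)$rel_S, 0, tolerance = 1e-15)

  # cohort 2 = cohort 1 with enough untreated women added to halve S
  # (H_T unchanged), so the relative change in H is -0.5 + relHT * 0
  counts2 <- bcm$counts
  counts2["000"] <- counts2["000"] + 637L   # N doubles, treated unchanged
  half <- path_count_table(counts2)
  d <- form1_decompose(bcm, half)
  expect_equal(d$rel_HT, 0, tolerance = 1e-12)
  expect_equal(d$rel_S, -0.5, tolerance = 1e-12)
  expect_equal(d$total, -0.5, tolerance = 1e-12)

  untreated <- path_count_table(c("000" = 10))
  expect_error(form1_decompose(untreated, bcm), "no treated women")
})

test_that("stepwise replacement reproduces the published decomposition grid", {
  p1 <- estimate_progression_proportions(bcm)
  p2 <- estimate_progression_proportions(acm)

  sH <- stepwise_replacement(p1, p2, functional = "H")
  expect_equal(unname(round(sH$values, 3)),
               c(0.482, 0.347, 0.360, 0.358, 0.360, 0.351, 0.350))
  expect_equal(unname(round(sH$contributions, 2)),
               c(-100.00, 9.50, -1.60, 1.70, -6.48, -1.02))
  expect_equal(unname(round(sH$differences, 3)),
               c(-0.135, 0.013, -0.002, 0.002, -0.009, -0.001))

  sC <- stepwise_replacement(p1, p2, functional = "C")
  expect_equal(unname(round(sC$values, 3)),
               c(0.102, 0.083, 0.083, 0.081, 0.081, 0.073, 0.071))
  expect_equal(unname(round(sC$contributions, 1)),
               c(-100.0, 4.5, -11.0, 0.8, -44.8, -7.0))

  sVC <- stepwise_replacement(p1, p2, functional = c("V", "C"))
  expect_equal(unname(round(sVC$values, 3)),
               c(0.144, 0.116, 0.129, 0.127, 0.129, 0.121, 0.119))
  expect_equal(unname(round(sVC$contributions, 1)),
               c(-100.0, 45.8, -7.7, 8.2, -31.3, -4.9))
})

test_that("stepwise endpoints and additivity are exact for any order", {
  p1 <- estimate_progression_proportions(bcm)
  p2 <- estimate_progression_proportions(acm)
  H1 <- overall_treatment_ratio(bcm)$H
  H2 <- overall_treatment_ratio(acm)$H

  set.seed(5)
  for (i in 1:10) {
    ord <- sample(pp_labels(p1$protocol))
    s <- stepwise_replacement(p1, p2, "H", order = ord)
    expect_equal(unname(s$values[1]), H1, tolerance = 1e-12)
    expect_equal(unname(s$values[7]), H2, tolerance = 1e-12)
    expect_equal(sum(s$differences), H2 - H1, tolerance = 1e-12)
    expect_equal(abs(unname(s$contributions[1])), 100, tolerance = 1e-12)
  }
})

test_that("degenerate stepwise inputs behave as documented", {
  p1 <- estimate_progression_proportions(bcm)
  s <- stepwise_replacement(p1, p1, "H")
  expect_equal(unname(s$differences), rep(0, 6), tolerance = 1e-15)
  expect_true(all(is.na(s$contributions)))   # delta_1 = 0
  expect_equal(unname(s$values[7]), unname(s$values[1]))

  p2 <- estimate_progression_proportions(acm)
  expect_error(stepwise_replacement(p1, p2, "H",
                                    order = rep("O->A", 6)),
               "permutation")
  expect_error(stepwise_replacement(p1, p2, functional = "Z"),
               "unknown")
})

test_that("every replacement order yields the same total difference", {
  p1 <- estimate_progression_proportions(bcm)
  p2 <- estimate_progression_proportions(acm)
  os <- order_sensitivity(p1, p2, functional = "H")
  expect_true(os$exhaustive)
  expect_equal(nrow(os$differences), factorial(6))
  totals <- rowSums(os$differences)
  expect_equal(max(abs(totals - (481 / 1375 - 307 / 637))), 0,
               tolerance = 1e-12)
  # the augmentation entry dominates the Shapley (mean-over-orders) split
  means <- abs(os$summary$mean)
  expect_equal(os$summary$pp[which.max(means)], "O->A")
})

test_that("a PP that alone differs gets an order-invariant contribution", {
  p <- c("O->A" = 0.3, "O->V" = 0.05, "O->C" = 0.05,
         "A->V" = 0.1, "A->C" = 0.2, "V->C" = 0.1)
  q <- p; q["O->C"] <- 0.15
  pp1 <- progression_proportions(p)
  pp2 <- progression_proportions(q)
  os <- order_sensitivity(pp1, pp2, "H")
  occ <- os$differences[, "O->C"]
  expect_equal(max(occ) - min(occ), 0, tolerance = 1e-15)
  others <- os$differences[, colnames(os$differences) != "O->C"]
  expect_equal(max(abs(others)), 0, tolerance = 1e-15)
})

test_that("order sensitivity samples when the factorial count exceeds the cap", {
  protocol <- intervention_protocol(paste0("T", 1:4))  # 10 PPs, 10! orders
  set.seed(2)
  pp1 <- random_pps(protocol)
  pp2 <- random_pps(protocol)
  expect_error(order_sensitivity(pp1, pp2, "H"), "sample_size")
  os <- order_sensitivity(pp1, pp2, "H", sample_size = 50, seed = 3)
  expect_false(os$exhaustive)
  expect_equal(nrow(os$differences), 50)
  total <- otr_from_pps(pp2) - otr_from_pps(pp1)
  expect_equal(max(abs(rowSums(os$differences) - total)), 0,
               tolerance = 1e-12)
})

test_that("the decomposition grid renders and exports the full layout", {
  p1 <- estimate_progression_proportions(bcm)
  p2 <- estimate_progression_proportions(acm)
  s <- stepwise_replacement(p1, p2, "H")
  g <- decomposition_grid(s, p1, p2)
  expect_equal(nrow(g), 9)            # 6 PPs + functional/difference/contribution
  expect_equal(g$cohort1[g$row == "functional"], 0.482)
  expect_equal(g$cohort2[g$row == "functional"], 0.350)
  f <- withr::local_tempfile(fileext = ".csv")
  decomposition_grid(s, p1, p2, file = f)
  expect_true(file.exists(f))
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$cohort1[back$row == "O->A"], 0.338, tolerance = 1e-6)
})
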