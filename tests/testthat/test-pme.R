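test_that("examiner averaging matches a cell-by-cell oracle", {
  sc <- data.frame(patient_id = rep("P1", 4),
                   antigen = rep(c("A", "B"), each = 2),
                   examiner = rep(1:2, 2),
                   raw_score = c(3, 4, 0, 0))
  m <- average_examiners(sc)
  expect_equal(m$mean_score[m$antigen == "A"], 3.5)
  expect_equal(m$mean_score[m$antigen == "B"], 0)

  ihc <- generate_ihc(ihc_sim_config(n_patients = 12, seed = 5))
  m <- average_examiners(ihc)
  for (i in sample(nrow(m), 25)) {
    cell <- ihc$scores[ihc$scores$patient_id == m$patient_id[i] &
                         ihc$scores$antigen == m$antigen[i], ]
    expect_equal(m$mean_score[i], sum(cell$raw_score) / nrow(cell))
  }

  expect_error(average_examiners(sc[-1, ]), "missing score cells")
})

test_that("PME scores are bounded sums, invariant to row order", {
  ihc <- generate_ihc(ihc_sim_config(seed = 7))
  m <- average_examiners(ihc)
  pme <- compute_pme(m)
  expect_true(all(pme$pme >= 0 & pme$pme <= 40))
  scrambled <- compute_pme(m[sample(nrow(m)), ])
  expect_equal(scrambled, pme)

  hi <- data.frame(patient_id = "P1", antigen = letters[1:10], mean_score = 4)
  expect_equal(compute_pme(hi)$pme, 40)
  lo <- transform(hi, mean_score = 0)
  expect_equal(compute_pme(lo)$pme, 0)
  two <- rbind(hi, transform(hi, patient_id = "P2"))
  expect_error(compute_pme(two[-1, ]), "missing antigen")
})

test_that("the marginal-resampling null matches exhaustive enumeration", {
  m <- data.frame(patient_id = rep(c("p1", "p2", "p3"), 2),
                  antigen = rep(c("A", "B"), each = 3),
                  mean_score = c(0, 0.5, 3, 0, 1, 5))
  null <- simulate_null(m, n_perm = 50000, seed = 4)
  exact <- outer(c(0, 0.5, 3), c(0, 1, 5), `+`)
  exact_tab <- table(factor(exact, levels = sort(unique(c(exact)))))
  emp_tab <- table(factor(null$samples, levels = names(exact_tab)))
  expect_equal(sum(is.na(match(null$samples, as.numeric(names(exact_tab))))), 0)
  tv <- 0.5 * sum(abs(emp_tab / length(null$samples) - exact_tab / 9))
  expect_lt(tv, 0.02)

  # analytic mean: sum of the antigen marginal means
  se <- stats::sd(null$samples) / sqrt(null$n_perm)
  expect_lt(abs(mean(null$samples) - (mean(c(0, 0.5, 3)) + mean(c(0, 1, 5)))),
            3 * se)
})

test_that("null cutoffs are nested and degenerate nulls refuse tail tests", {
  ihc <- generate_ihc(ihc_sim_config(seed = 3))
  null <- simulate_null(average_examiners(ihc), n_perm = 5000, seed = 1)
  expect_lte(null$cutoff_1[["lower"]], null$cutoff_5[["lower"]])
  expect_gte(null$cutoff_1[["upper"]], null$cutoff_5[["upper"]])
  expect_lte(null$cutoff_5[["lower"]], null$cutoff_5[["upper"]])

  const <- data.frame(patient_id = rep(c("p1", "p2"), 2),
                      antigen = rep(c("A", "B"), each = 2),
                      mean_score = c(2, 2, 3, 3))
  pm <- suppressWarnings(simulate_null(const, n_perm = 500, seed = 1))
  expect_true(all(pm$samples == 5))
  expect_error(tail_chi2(c(5, 5), pm), "degenerate")
  expect_warning(simulate_null(const, n_perm = 500, seed = 1), "unstable")
})

test_that("tail counting uses strict inequality and both chi-square layouts", {
  ihc <- generate_ihc(ihc_sim_config(n_patients = 40, seed = 11))
  m <- average_examiners(ihc)
  null <- simulate_null(m, n_perm = 20000, seed = 2)
  # values exactly at the cutoffs are not in the tails
  at_cut <- c(null$cutoff_5[["lower"]], null$cutoff_5[["upper"]])
  res <- tail_chi2(c(at_cut, rep(mean(null$samples), 38)), null, 0.05)
  expect_equal(res$observed_in_tail, 0)

  # a perfectly alpha-occupied sample gives chi2 = 0 in the pooled layout
  inside <- rep(mean(null$samples), 38)
  beyond <- c(null$cutoff_5[["lower"]] - 1, null$cutoff_5[["upper"]] + 1)
  perfect <- tail_chi2(c(inside, beyond), null, 0.05)
  expect_equal(perfect$observed_in_tail, 2)
  expect_equal(perfect$chi2, 0, tolerance = 1e-12)
  expect_equal(perfect$p_value, 1, tolerance = 1e-12)

  split3 <- tail_chi2(c(inside, beyond), null, 0.05, cells = "split")
  expect_equal(split3$df, 2)
  expect_equal(split3$observed_in_tail, 2)
})

test_that("recurrence groups are compared by rank-sum with exact small-n behavior", {
  pme_same <- data.frame(patient_id = sprintf("P%02d", 1:6),
                         pme = rep(c(10, 20, 30), 2))
  meta <- data.frame(patient_id = sprintf("P%02d", 1:6),
                     recurrence = rep(c(TRUE, FALSE), each = 3),
                     endocrine_therapy = TRUE)
  same <- compare_groups(pme_same, meta)
  expect_gt(same$p_value, 0.99)

  pme_sep <- data.frame(patient_id = sprintf("P%02d", 1:6),
                        pme = c(1, 2, 3, 30, 31, 32))
  sep <- compare_groups(pme_sep, meta)
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)
  expect_lt(sep$medians[["recurrent"]], sep$medians[["nonrecurrent"]])

  expect_error(compare_groups(pme_same, transform(meta, recurrence = TRUE)),
               "non-empty")
})

test_that("linked recurrence lowers PME in the recurrent group", {
  lower <- vapply(1:60, function(i) {
    ihc <- generate_ihc(ihc_sim_config(n_patients = 200, sync_rho = 0.6,
                                       recurrence_link = 1.5, seed = 500 + i))
    pme <- compute_pme(average_examiners(ihc))
    g <- compare_groups(pme, ihc)
    g$medians[["recurrent"]] < g$medians[["nonrecurrent"]]
  }, logical(1))
  expect_gt(mean(lower), 0.95)
})
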