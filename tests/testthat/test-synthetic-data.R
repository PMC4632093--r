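test_that("generators are pure functions of config and seed", {
  s1 <- generate_screen(screen_sim_config(5, seed = 11))
  s2 <- generate_screen(screen_sim_config(5, seed = 11))
  expect_identical(s1, s2)
  n1 <- generate_network(network_sim_config(30, seed = 4))
  n2 <- generate_network(network_sim_config(30, seed = 4))
  expect_identical(igraph::as_data_frame(n1$catalog$graph),
                   igraph::as_data_frame(n2$catalog$graph))
  expect_identical(n1$truth, n2$truth)
  expect_identical(generate_ihc(ihc_sim_config(seed = 9)),
                   generate_ihc(ihc_sim_config(seed = 9)))
  expect_identical(generate_cohort(cohort_sim_config(20, seed = 2)),
                   generate_cohort(cohort_sim_config(20, seed = 2)))
  # and they do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_screen(screen_sim_config(3, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("screen tables have the configured shape and sane values", {
  cfg <- screen_sim_config(4, clones_per_target = 5, replicates = 3, seed = 1)
  tab <- generate_screen(cfg)
  expect_true(all(tab$viability >= 0))
  per_target <- tapply(tab$clone_id, tab$target_id,
                       function(x) length(unique(x)))
  expect_true(all(per_target[setdiff(names(per_target), "pLKO.1")] == 5))
  # one row per (target, clone, arm, replicate)
  expect_equal(nrow(tab), 4 * 5 * 2 * 3 + 2 * 3)
  expect_true("pLKO.1" %in% tab$target_id)
  expect_error(screen_sim_config(0), "n_targets")
  expect_error(screen_sim_config(5, clones_per_target = 1), "clones_per_target")
})

test_that("noiseless screens with a real effect make every hit clone positive", {
  cfg <- screen_sim_config(3, true_hits = c("T0001", "T0003"),
                           effect_size = 0.5, noise_sd = 0, seed = 1)
  calls <- call_hits(generate_screen(cfg))
  hits <- calls$targets
  expect_true(all(hits$is_hit[hits$target_id %in% c("T0001", "T0003")]))
  expect_equal(hits$n_positive_clones[hits$target_id == "T0001"], 5)
  expect_false(hits$is_hit[hits$target_id == "T0002"])
})

test_that("planted network respects size, connectivity and degenerate configs", {
  net <- generate_network(network_sim_config(50, mean_degree = 1.5,
                                             planted_subnetwork_size = 8,
                                             primary_seed_count = 3, seed = 6))
  expect_length(net$truth, 8)
  expect_true(all(net$seeds %in% net$truth))
  sub <- igraph::induced_subgraph(net$catalog$graph, net$truth)
  expect_true(igraph::is_connected(sub))

  single <- generate_network(network_sim_config(20, mean_degree = 0,
                                                planted_subnetwork_size = 1,
                                                primary_seed_count = 1, seed = 3))
  expect_length(single$truth, 1)
  expect_identical(single$seeds, single$truth)
  expect_equal(igraph::ecount(single$catalog$graph), 0)
  expect_error(network_sim_config(5, planted_subnetwork_size = 9),
               "planted_subnetwork_size")
})

test_that("IHC scores stay on the 0-4 scale with the default 18 x 10 x 2 shape", {
  ihc <- generate_ihc(ihc_sim_config(seed = 2))
  expect_equal(nrow(ihc$scores), 18 * 10 * 2)
  expect_equal(length(unique(ihc$scores$patient_id)), 18)
  expect_equal(length(unique(ihc$scores$antigen)), 10)
  expect_equal(sort(unique(ihc$scores$examiner)), 1:2)
  expect_true(all(ihc$scores$raw_score %in% 0:4))
  expect_true(all(c("recurrence", "endocrine_therapy") %in%
                    names(ihc$patients)))
})

test_that("sync_rho controls inter-antigen correlation", {
  # independent antigens: mean pairwise Spearman correlation near zero
  ihc0 <- generate_ihc(ihc_sim_config(n_patients = 500, sync_rho = 0,
                                      examiner_sd = 0, seed = 8))
  m0 <- with(average_examiners(ihc0),
             tapply(mean_score, list(patient_id, antigen), mean))
  cors <- stats::cor(m0, method = "spearman")
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.1)

  # perfect synchronization with no rater noise: identical ranks per patient
  ihc1 <- generate_ihc(ihc_sim_config(n_patients = 30, sync_rho = 1,
                                      examiner_sd = 0, seed = 8))
  m1 <- with(average_examiners(ihc1),
             tapply(mean_score, list(patient_id, antigen), mean))
  expect_true(all(apply(m1, 1, function(r) length(unique(r)) == 1L)))
})

test_that("cohorts link expression to hazard and honor the censor rate", {
  co <- generate_cohort(cohort_sim_config(300, n_genes = 5,
                                          prognostic_genes = c(gene_001 = 0.3),
                                          censor_rate = 0.2, seed = 4))
  expect_equal(ncol(co$expression), 300)
  expect_true(all(co$survival$time >= 0))
  high <- co$expression["gene_001", ] > median(co$expression["gene_001", ])
  ev <- co$survival$event == 1
  # protective gene: high expressers survive longer among events
  expect_gt(median(co$survival$time[high & ev]),
            median(co$survival$time[!high & ev]))

  all_cens <- generate_cohort(cohort_sim_config(30, censor_rate = 1, seed = 1))
  expect_equal(sum(all_cens$survival$event), 0)
  expect_error(survival_screen(all_cens, "gene_001"), "degenerate")
})

test_that("tables round-trip through their TSV formats", {
  tmp <- withr::local_tempdir()
  tab <- generate_screen(screen_sim_config(3, seed = 1))
  f <- file.path(tmp, "screen.tsv")
  write_viability_table(tab, f)
  expect_equal(read_viability_table(f)$viability, tab$viability)

  ihc <- generate_ihc(ihc_sim_config(seed = 1))
  write_ihc_table(ihc, file.path(tmp, "ihc"))
  back <- read_ihc_table(file.path(tmp, "ihc"))
  expect_equal(back$scores$raw_score, ihc$scores$raw_score)

  co <- generate_cohort(cohort_sim_config(10, n_genes = 4, seed = 1))
  write_cohort(co, file.path(tmp, "coh"))
  back <- read_cohort(file.path(tmp, "coh"))
  expect_equal(unname(back$expression), unname(co$expression), tolerance = 1e-8)
  expect_equal(back$survival$time, co$survival$time, tolerance = 1e-8)
})
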