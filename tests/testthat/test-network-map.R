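test_that("candidate proposal deduplicates, tracks sources, and warns on unknowns", {
  cat <- interaction_catalog(data.frame(from = c("A", "B", "A"),
                                        to = c("X", "X", "Y")))
  cand <- propose_candidates(cat, c("A", "B"))
  expect_setequal(cand$gene, c("X", "Y"))
  expect_setequal(cand$sources[[which(cand$gene == "X")]], c("A", "B"))
  expect_identical(cand$sources[[which(cand$gene == "Y")]], "A")

  lonely <- interaction_catalog(data.frame(from = "A", to = "B"),
                                genes = "Z")
  expect_equal(nrow(propose_candidates(lonely, "Z")), 0)
  expect_warning(propose_candidates(lonely, c("A", "NOPE")), "NOPE")
})

test_that("replaying the shipped campaign ledger reproduces the published map", {
  map <- fulvestrant_map()
  expect_equal(nrow(map$nodes), 19)
  expect_equal(sum(map$nodes$status == "predicted_only"), 3)
  gen <- split(map$nodes$label, map$nodes$generation)
  expect_setequal(gen[["1"]], c("BIK", "ERBB4", "DAPK3", "MAP2K2"))
  expect_setequal(gen[["2"]], c("DAPK1", "DAPK2", "ROCK1", "TP53",
                                "Myosin light chains"))
  expect_setequal(gen[["3"]], c("MYLK3", "MAPK9", "CAMK1D", "CAMK4"))
  expect_setequal(gen[["4"]], c("CALM1", "MAP2K7", "PAG1", "STAT3", "STAT5A"))
  expect_setequal(gen[["5"]], "CSK")
  expect_setequal(
    map$nodes$label[map$nodes$status == "predicted_only"],
    c("Myosin light chains", "STAT3", "STAT5A"))
  expect_true(igraph::is_connected(map$graph))
  # STAT5B is a survival-screen gene, not a map node
  expect_false("STAT5B" %in% map$nodes$label)
})

test_that("every non-primary node connects to a strictly lower generation", {
  map <- fulvestrant_map()
  g <- map$graph
  for (v in igraph::V(g)$name) {
    gen <- map$nodes$generation[map$nodes$label == v]
    if (gen == 1L) next
    nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
    nb_gen <- map$nodes$generation[match(nb, map$nodes$label)]
    expect_true(any(nb_gen < gen), label = paste("provenance for", v))
  }
})

test_that("ledger replay is order-invariant and validates source references", {
  led <- fulvestrant_ledger()
  shuffled <- led$records[sample(nrow(led$records)), ]
  map <- assemble_from_ledger(shuffled, catalog = fulvestrant_catalog(),
                              aliases = led$aliases)
  ref <- fulvestrant_map()
  expect_equal(nrow(map$nodes), nrow(ref$nodes))
  expect_setequal(map$nodes$label, ref$nodes$label)

  bad <- rbind(led$records,
               validation_record("NEW1", round = 3, source_nodes = "GHOST"))
  expect_error(assemble_from_ledger(bad, aliases = led$aliases),
               "GHOST")
})

test_that("a primary-only ledger yields isolated generation-1 nodes", {
  led <- fulvestrant_ledger()
  primaries <- led$records[led$records$round == 1, ]
  map <- assemble_from_ledger(primaries)
  expect_equal(nrow(map$nodes), 4)
  expect_true(all(map$nodes$generation == 1))
  expect_equal(nrow(map$edges), 0)
})

test_that("untestable candidates are admitted only by downstream validation or corroboration", {
  rec <- rbind(
    validation_record("S", 1),
    validation_record("TOX_USED", 2, "S", outcome = "untestable_toxic"),
    validation_record("TOX_ORPHAN", 2, "S", outcome = "untestable_toxic"),
    validation_record("COR", 2, "S", outcome = "untestable_failed",
                      corroboration = TRUE),
    validation_record("CHILD", 3, "TOX_USED", outcome = "validated"),
    validation_record("NEG", 2, "S", outcome = "negative"))
  map <- assemble_from_ledger(rec)
  expect_setequal(map$nodes$label, c("S", "TOX_USED", "COR", "CHILD"))
  expect_false("TOX_ORPHAN" %in% map$nodes$label)
  expect_false("NEG" %in% map$nodes$label)
  expect_identical(map$nodes$status[map$nodes$label == "TOX_USED"],
                   "predicted_only")
})

test_that("saturation is declared after k validation-free rounds", {
  expect_true(check_saturation(c(4, 4, 3, 0, 0), k = 2))
  expect_false(check_saturation(c(4, 0, 3), k = 2))
  expect_false(check_saturation(c(0), k = 2))
  expect_error(check_saturation(c(1, 0), k = 0), "k")
  expect_error(check_saturation(integer(0)), "non-empty")
})

test_that("maps round-trip through graphml, json and sif", {
  map <- fulvestrant_map()
  tmp <- withr::local_tempdir()

  gml <- file.path(tmp, "map.graphml")
  export_map(map, gml)
  expect_equal(length(grep("<node ", readLines(gml))), 19)
  back <- import_map(gml)
  expect_setequal(back$nodes$label, map$nodes$label)
  expect_equal(back$nodes$generation[match(map$nodes$label, back$nodes$label)],
               map$nodes$generation)
  expect_true(igraph::isomorphic(back$graph, map$graph))

  js <- file.path(tmp, "map.json")
  export_map(map, js)
  back2 <- import_map(js)
  expect_equal(back2$nodes, map$nodes)
  expect_equal(back2$edges, map$edges)
  expect_equal(nrow(back2$ledger), nrow(map$ledger))

  sif <- file.path(tmp, "map.sif")
  export_map(map, sif)
  back3 <- import_map(sif)
  expect_setequal(back3$nodes$label, map$nodes$label)
  expect_equal(nrow(back3$edges), nrow(map$edges))

  expect_error(export_map(map, file.path(tmp, "map.xlsx")), "unknown format")

  empty <- assemble_from_ledger(validation_record("A", 1))
  ef <- file.path(tmp, "one.json")
  export_map(empty, ef)
  expect_equal(nrow(import_map(ef)$nodes), 1)
})

test_that("noiseless campaigns recover all reachable planted genes at saturation", {
  for (seed in c(2, 5, 9)) {
    net <- generate_network(network_sim_config(
      50, mean_degree = 1.5, planted_subnetwork_size = 8,
      primary_seed_count = 2, seed = seed))
    camp <- run_campaign(net, effect_size = 0.5, noise_sd = 0, seed = seed)
    expect_true(camp$saturated)
    expect_equal(camp$recall, 1)
  }
})

test_that("the kinome screen summary fixture is consistent with the map", {
  tab <- kinome_screen_summary()
  expect_true(all(tab$n_positive_clones >= 2))
  expect_identical(tab$gene[tab$n_positive_clones == 4], "CSK")
  map_genes <- unlist(strsplit(fulvestrant_map()$nodes$members, ";"))
  expect_true(all(tab$gene[tab$in_map] %in% map_genes))
})
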