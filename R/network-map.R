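#' Candidate-interaction catalog
#'
#' An undirected catalog of known or predicted gene-gene interactions
#' (physical or functional), the substrate for the seed-and-expand
#' prediction step. Self-loops are dropped and duplicate edges merged.
#' Alias groups let one displayed map node cover several gene symbols
#' (e.g. a "Myosin light chains" node covering MYL2 and MYL9).
#'
#' @param edges `data.frame` with columns `from`, `to` (gene symbols) and
#'   optionally `annotation` (`"physical"`/`"functional"`).
#' @param genes optional character vector of isolated genes to include.
#' @param aliases named list: alias label -> character vector of member
#'   gene symbols.
#' @return an object of class `interaction_catalog`.
#' @export
interaction_catalog <- function(edges, genes = NULL, aliases = list()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) && (!all(c("from", "to") %in% names(edges)))) {
    stop("`edges` must have columns `from` and `to`", call. = FALSE)
  }
  verts <- unique(c(as.character(edges$from), as.character(edges$to), genes))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  structure(list(graph = g, aliases = aliases), class = "interaction_catalog")
}

#' @rdname interaction_catalog
#' @param x an `interaction_catalog`.
#' @param ... unused.
#' @export
print.interaction_catalog <- function(x, ...) {
  cat(sprintf("interaction catalog: %d genes, %d edges, %d alias group(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$aliases)))
  invisible(x)
}

#' Read / write a catalog as SIF or two-column edge-list TSV
#'
#' SIF rows are `source<TAB>relation<TAB>target`; edge-list rows are
#' `from<TAB>to` with a header.
#'
#' @param path file path; format inferred from the `.sif` extension unless
#'   given.
#' @param format `"sif"` or `"tsv"`.
#' @param aliases passed through to [interaction_catalog()].
#' @return an `interaction_catalog` (for `read_catalog`).
#' @export
read_catalog <- function(path, format = NULL, aliases = list()) {
  if (is.null(format)) {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    edges <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) >= 3L) {
        data.frame(from = p[1L], to = p[3L], annotation = p[2L],
                   stringsAsFactors = FALSE)
      } else {
        # a single-column SIF row declares an isolated node
        data.frame(from = character(), to = character(),
                   annotation = character())
      }
    }))
    iso <- unlist(lapply(parts, function(p) if (length(p) == 1L) p else NULL))
    interaction_catalog(edges, genes = iso, aliases = aliases)
  } else {
    edges <- read.delim(path, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("from", "to")
    interaction_catalog(edges, aliases = aliases)
  }
}

#' @rdname read_catalog
#' @param catalog the catalog to write.
#' @export
write_catalog <- function(catalog, path, format = NULL) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  if (is.null(format)) {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  ed <- igraph::as_data_frame(catalog$graph, what = "edges")
  if (format == "sif") {
    rel <- if ("annotation" %in% names(ed)) ed$annotation else
      rep("interacts", nrow(ed))
    rel[is.na(rel)] <- "interacts"
    writeLines(paste(ed$from, rel, ed$to, sep = "\t"), path)
  } else {
    write.table(ed[, c("from", "to")], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Propose new candidate genes from the current frontier
#'
#' The in-silico prediction step of one iteration: all catalog neighbors of
#' the frontier genes that are not already in the map, deduplicated, each
#' carrying the set of frontier genes (source nodes) whose neighborhood
#' produced it.
#'
#' @param catalog an [interaction_catalog()].
#' @param frontier character vector of frontier gene symbols (typically the
#'   genes validated in the previous round).
#' @param exclude genes already in the map (or otherwise ineligible).
#' @return a `data.frame` with columns `gene` and `sources` (a list column
#'   of character vectors).
#' @export
propose_candidates <- function(catalog, frontier, exclude = character()) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  if (length(frontier) == 0L) {
    stop("`frontier` must be non-empty", call. = FALSE)
  }
  known <- igraph::V(catalog$graph)$name
  missing <- setdiff(frontier, known)
  if (length(missing)) {
    warning("frontier gene(s) absent from catalog: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  frontier <- intersect(frontier, known)
  hits <- list()
  for (f in frontier) {
    nb <- igraph::V(catalog$graph)$name[
      igraph::neighbors(catalog$graph, f)]
    nb <- setdiff(nb, c(exclude, frontier))
    for (g in nb) hits[[g]] <- c(hits[[g]], f)
  }
  if (length(hits) == 0L) {
    return(data.frame(gene = character(),
                      sources = I(list()), stringsAsFactors = FALSE))
  }
  data.frame(gene = names(hits),
             sources = I(unname(lapply(hits, unique))),
             stringsAsFactors = FALSE)
}

#' Validation ledger records
#'
#' One record per candidate gene per screening round: the genes whose
#' prediction produced it, and the experimental outcome of its RNAi
#' validation (`validated`, `negative`, `untestable_toxic` for nonspecific
#' cell damage, `untestable_failed` for a failed knockdown).
#'
#' @param gene gene symbol.
#' @param round iteration index (primaries have round 1).
#' @param source_nodes character vector of source genes (empty for
#'   primaries).
#' @param outcome one of `"validated"`, `"negative"`, `"untestable_toxic"`,
#'   `"untestable_failed"`.
#' @param corroboration external-evidence flag allowing a predicted-only
#'   node without downstream validation.
#' @return a one-row ledger `data.frame`.
#' @export
validation_record <- function(gene, round, source_nodes = character(),
                              outcome = "validated", corroboration = FALSE) {
  outcome <- match.arg(outcome, c("validated", "negative",
                                  "untestable_toxic", "untestable_failed"))
  round <- check_count(round, "round")
  if (round == 1L && length(source_nodes)) {
    stop("primary records (round 1) must have empty source_nodes",
         call. = FALSE)
  }
  data.frame(gene = gene, round = round,
             sources = paste(source_nodes, collapse = ";"),
             outcome = outcome, corroboration = isTRUE(corroboration),
             stringsAsFactors = FALSE)
}

ledger_sources <- function(ledger) {
  strsplit(ifelse(is.na(ledger$sources) | !nzchar(ledger$sources),
                  "", ledger$sources), ";", fixed = TRUE)
}

#' Read / write a validation ledger
#'
#' JSON ledgers are objects with an optional `aliases` map and a `records`
#' array; TSV ledgers are flat tables with `;`-separated `sources`.
#'
#' @param path file path (`.json` or `.tsv`).
#' @return for `read_ledger`, a list with `records` (`data.frame`) and
#'   `aliases` (named list).
#' @export
read_ledger <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    rec <- obj$records
    rec$corroboration <- isTRUE_vec(rec$corroboration)
    aliases <- as.list(obj$aliases)
    aliases <- lapply(aliases, unlist)
    list(records = rec, aliases = aliases)
  } else {
    rec <- read.delim(path, stringsAsFactors = FALSE)
    rec$corroboration <- isTRUE_vec(rec$corroboration)
    list(records = rec, aliases = list())
  }
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(logical(0))
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' @rdname read_ledger
#' @param records ledger `data.frame`.
#' @param aliases named list of alias groups.
#' @export
write_ledger <- function(records, path, aliases = list()) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(aliases = aliases, records = records), path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Assemble an interaction map by replaying a validation ledger
#'
#' Deterministically replays a recorded screening campaign:
#' * validated candidates become map nodes with generation = their round;
#' * negative candidates stay in the provenance ledger only;
#' * untestable candidates (toxic knockdown or failed knockdown) are
#'   admitted at finalization as *predicted-only* nodes iff a
#'   later-validated node was discovered via them, or their external
#'   corroboration flag is set;
#' * alias groups collapse several gene symbols into one displayed node
#'   (generation = earliest member round; validated if any member was).
#'
#' Map edges are the candidate-source pairs of admitted records plus any
#' catalog edges whose both endpoints are admitted.
#'
#' @param records ledger `data.frame` (see [validation_record()]), or the
#'   list returned by [read_ledger()].
#' @param catalog optional [interaction_catalog()] supplying extra edges
#'   between admitted nodes.
#' @param aliases named list of alias groups (overrides any carried by
#'   `records`).
#' @return an object of class `interaction_map`: list with `nodes`
#'   (`label`, `generation`, `status`, `members`), `edges` (`from`, `to`),
#'   `graph` (igraph with node attributes) and `ledger`.
#' @export
assemble_from_ledger <- function(records, catalog = NULL, aliases = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    if (is.null(aliases)) aliases <- records$aliases
    records <- records$records
  }
  if (is.null(aliases)) aliases <- list()
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  records$round <- as.integer(records$round)
  src <- ledger_sources(records)

  # internal consistency: every source must be recorded at an earlier or
  # equal round (campaigns may chain a validation through a pending
  # untestable candidate predicted in the same round)
  for (i in seq_len(nrow(records))) {
    for (s in src[[i]]) {
      j <- which(records$gene == s)
      if (length(j) == 0L || min(records$round[j]) > records$round[i]) {
        stop(sprintf(
          "record for '%s' (round %d) references source '%s' not recorded at an earlier round",
          records$gene[i], records$round[i], s), call. = FALSE)
      }
    }
  }

  validated <- records[records$outcome == "validated", , drop = FALSE]
  untestable <- records[records$outcome %in%
                          c("untestable_toxic", "untestable_failed"), ,
                        drop = FALSE]
  validated_sources <- unique(unlist(src[records$outcome == "validated"]))

  admit_untestable <- vapply(seq_len(nrow(untestable)), function(i) {
    untestable$gene[i] %in% validated_sources || untestable$corroboration[i]
  }, logical(1L))
  admitted <- rbind(validated, untestable[admit_untestable, , drop = FALSE])

  # earliest record wins if a gene was re-predicted
  admitted <- admitted[order(admitted$round), , drop = FALSE]
  admitted <- admitted[!duplicated(admitted$gene), , drop = FALSE]

  alias_of <- function(gene) {
    for (lab in names(aliases)) {
      if (gene %in% aliases[[lab]]) return(lab)
    }
    gene
  }
  admitted$label <- vapply(admitted$gene, alias_of, "")

  nodes <- do.call(rbind, lapply(split(admitted, admitted$label), function(d) {
    data.frame(label = d$label[1L],
               generation = min(d$round),
               status = if (any(d$outcome == "validated")) "validated"
                        else "predicted_only",
               members = paste(sort(unique(d$gene)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(nodes$generation, nodes$label), , drop = FALSE]
  rownames(nodes) <- NULL

  gene2label <- structure(admitted$label, names = admitted$gene)
  adm_src <- ledger_sources(admitted)
  edge_pairs <- list()
  for (i in seq_len(nrow(admitted))) {
    for (s in adm_src[[i]]) {
      if (s %in% names(gene2label)) {
        edge_pairs[[length(edge_pairs) + 1L]] <-
          c(admitted$label[i], unname(gene2label[s]))
      }
    }
  }
  if (!is.null(catalog)) {
    ed <- igraph::as_data_frame(catalog$graph, what = "edges")
    keep <- ed$from %in% names(gene2label) & ed$to %in% names(gene2label)
    for (k in which(keep)) {
      edge_pairs[[length(edge_pairs) + 1L]] <-
        unname(c(gene2label[ed$from[k]], gene2label[ed$to[k]]))
    }
  }
  edges <- if (length(edge_pairs)) {
    em <- unique(t(vapply(edge_pairs, function(p) sort(p), character(2L))))
    em <- em[em[, 1L] != em[, 2L], , drop = FALSE]
    data.frame(from = em[, 1L], to = em[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character())
  }

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$label, generation = nodes$generation,
                          status = nodes$status, members = nodes$members))
  structure(list(nodes = nodes, edges = edges, graph = g, ledger = records,
                 aliases = aliases),
            class = "interaction_map")
}

#' @rdname assemble_from_ledger
#' @param x an `interaction_map`.
#' @param ... unused.
#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf(
    "interaction map: %d nodes (%d validated, %d predicted-only), %d edges, %d generation(s)\n",
    nrow(x$nodes), sum(x$nodes$status == "validated"),
    sum(x$nodes$status == "predicted_only"), nrow(x$edges),
    max(x$nodes$generation)))
  print(x$nodes[, c("label", "generation", "status")], row.names = FALSE)
  invisible(x)
}

#' Detect screening saturation
#'
#' The campaign is saturating when newly predicted genes are no longer
#' experimentally validated over several consecutive rounds.
#'
#' @param history integer vector of newly validated node counts per round.
#' @param k number of trailing zero-validation rounds required (default 2).
#' @return `TRUE` iff the last `k` rounds each validated zero new nodes.
#' @export
check_saturation <- function(history, k = 2L) {
  k <- check_count(k, "k")
  if (length(history) == 0L) stop("`history` must be non-empty", call. = FALSE)
  length(history) >= k && all(tail(history, k) == 0)
}

#' Export / import an interaction map
#'
#' `"sif"` writes edges (plus a sidecar `<path>.nodes.tsv` attribute
#' table); `"graphml"` stores nodes, edges and attributes; `"json"`
#' additionally carries the full provenance ledger and alias groups and
#' round-trips the map losslessly.
#'
#' @param map an [assemble_from_ledger()] result.
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"json"` (default: from the file
#'   extension).
#' @return the path, invisibly (`export_map`); an `interaction_map`
#'   (`import_map`).
#' @export
export_map <- function(map, path, format = NULL) {
  stopifnot(inherits(map, "interaction_map"))
  format <- map_format(path, format)
  switch(format,
    sif = {
      writeLines(paste(map$edges$from, "interacts", map$edges$to, sep = "\t"),
                 path)
      write.table(map$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    },
    graphml = igraph::write_graph(map$graph, path, format = "graphml"),
    json = jsonlite::write_json(
      list(nodes = map$nodes, edges = map$edges, ledger = map$ledger,
           aliases = map$aliases),
      path, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    stop("unknown format: ", format, call. = FALSE))
  invisible(path)
}

map_format <- function(path, format) {
  if (!is.null(format)) {
    if (!format %in% c("sif", "graphml", "json")) {
      stop("unknown format: ", format, call. = FALSE)
    }
    return(format)
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("sif", "graphml", "json")) {
    stop("unknown format: ", ext, call. = FALSE)
  }
  ext
}

#' @rdname export_map
#' @export
import_map <- function(path, format = NULL) {
  format <- map_format(path, format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    edges <- if (length(obj$edges)) {
      as.data.frame(obj$edges, stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character())
    }
    ledger <- as.data.frame(obj$ledger, stringsAsFactors = FALSE)
    aliases <- lapply(as.list(obj$aliases), unlist)
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = nodes$label, generation = nodes$generation,
                            status = nodes$status, members = nodes$members))
    structure(list(nodes = nodes, edges = edges, graph = g, ledger = ledger,
                   aliases = aliases), class = "interaction_map")
  } else if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(label = igraph::V(g)$name,
                        generation = as.integer(igraph::V(g)$generation),
                        status = igraph::V(g)$status,
                        members = igraph::V(g)$members,
                        stringsAsFactors = FALSE)
    edges <- igraph::as_data_frame(g, what = "edges")[, c("from", "to")]
    structure(list(nodes = nodes, edges = edges, graph = g,
                   ledger = NULL, aliases = list()),
              class = "interaction_map")
  } else {
    edges <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("from", "rel", "to"))[, c("from", "to")]
    nodes <- read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = nodes$label, generation = nodes$generation,
                            status = nodes$status, members = nodes$members))
    structure(list(nodes = nodes, edges = edges, graph = g,
                   ledger = NULL, aliases = list()),
              class = "interaction_map")
  }
}

#' Run a simulated nodes-and-connections campaign
#'
#' Couples the prediction step ([propose_candidates()]) with per-candidate
#' simulated viability screening ([generate_screen()] + [call_hits()]) and
#' iterates until saturation: candidates whose knockdown confers drug
#' resistance (genes in the planted required set) are validated and become
#' the next frontier.
#'
#' @param network a [generate_network()] result (or a
#'   [network_sim_config()], which is generated first).
#' @param effect_size drug-arm viability uplift for required genes.
#' @param noise_sd assay noise (0 gives the noiseless oracle regime).
#' @param replicates replicates per clone per arm.
#' @param clones_per_target shRNA clones per candidate.
#' @param alpha per-clone significance level.
#' @param min_positive positive-clone rule.
#' @param saturation_k trailing zero rounds declaring saturation.
#' @param max_rounds hard iteration cap.
#' @param seed RNG seed for the simulated assays.
#' @return a list with `map` (the final `interaction_map`), `history`
#'   (validated counts per expansion round), `truth`, `seeds`, `recall`
#'   (recovered fraction of planted genes reachable from the seeds) and
#'   `saturated`.
#' @export
run_campaign <- function(network, effect_size = 0.5, noise_sd = 0.1,
                         replicates = 3L, clones_per_target = 5L,
                         alpha = 0.05, min_positive = 2L,
                         saturation_k = 2L, max_rounds = 20L, seed = 1L) {
  if (inherits(network, "network_sim_config")) network <- generate_network(network)
  catalog <- network$catalog
  truth <- network$truth
  seeds <- network$seeds
  records <- do.call(rbind, lapply(seeds, function(s) {
    validation_record(s, round = 1L, outcome = "validated")
  }))
  in_map <- seeds
  frontier <- seeds
  proposed <- seeds
  history <- integer(0)
  round_i <- 1L
  sim_seed <- seed
  while (round_i < max_rounds) {
    round_i <- round_i + 1L
    # after a zero-validation round the frontier is empty; keep predicting
    # from the whole map (without retesting negatives) so saturation can be
    # observed rather than inferred
    src <- if (length(frontier)) frontier else in_map
    cand <- propose_candidates(catalog, src, exclude = proposed)
    if (nrow(cand) == 0L) {
      history <- c(history, 0L)
      if (check_saturation(history, k = saturation_k)) break
      next
    }
    proposed <- c(proposed, cand$gene)
    sim_seed <- sim_seed + 1L
    ids <- sprintf("T%04d", seq_len(nrow(cand)))
    cfg <- screen_sim_config(
      n_targets = nrow(cand), clones_per_target = clones_per_target,
      replicates = replicates, true_hits = ids[cand$gene %in% truth],
      effect_size = effect_size, noise_sd = noise_sd, seed = sim_seed)
    tab <- generate_screen(cfg)
    renamed <- match(tab$target_id, ids)
    tab$target_id[!is.na(renamed)] <- cand$gene[renamed[!is.na(renamed)]]
    calls <- call_hits(tab, alpha = alpha, min_positive = min_positive,
                       control_id = cfg$control_id)
    validated <- calls$targets$target_id[
      !is.na(calls$targets$is_hit) & calls$targets$is_hit]
    validated <- intersect(cand$gene, validated)
    for (i in seq_len(nrow(cand))) {
      g <- cand$gene[i]
      records <- rbind(records, validation_record(
        g, round = round_i, source_nodes = cand$sources[[i]],
        outcome = if (g %in% validated) "validated" else "negative"))
    }
    history <- c(history, length(validated))
    in_map <- c(in_map, validated)
    frontier <- validated
    if (check_saturation(history, k = saturation_k)) break
  }
  reachable <- reachable_truth(catalog, seeds, truth)
  recall <- if (length(reachable)) {
    length(intersect(in_map, reachable)) / length(reachable)
  } else {
    NA_real_
  }
  map <- assemble_from_ledger(records, catalog = catalog)
  list(map = map, history = history, truth = truth, seeds = seeds,
       recall = recall, saturated = check_saturation(history, k = saturation_k))
}

# planted genes reachable from the seeds through catalog paths that stay
# within the planted set (a campaign can only validate along such paths)
reachable_truth <- function(catalog, seeds, truth) {
  sub <- igraph::induced_subgraph(
    catalog$graph, intersect(igraph::V(catalog$graph)$name, truth))
  comp <- igraph::components(sub)
  keep <- unique(comp$membership[intersect(seeds, names(comp$membership))])
  names(comp$membership)[comp$membership %in% keep]
}

#' The shipped fulvestrant-apoptosis screening fixture
#'
#' Loads the packaged candidate-interaction catalog and validation ledger
#' for the fulvestrant-induced MCF-7 apoptosis campaign: four primary
#' nodes (BIK, ERBB4, DAPK3, MAP2K2) expanded over five generations into a
#' 19-node map with three predicted-only nodes (Myosin light chains,
#' STAT3, STAT5A).
#'
#' @return `fulvestrant_catalog()`: an [interaction_catalog()];
#'   `fulvestrant_ledger()`: a list with `records` and `aliases` as from
#'   [read_ledger()]; `fulvestrant_map()`: the assembled
#'   `interaction_map`.
#' @export
fulvestrant_catalog <- function() {
  read_catalog(system.file("extdata", "fulvestrant_catalog.sif",
                           package = "nodeconnect", mustWork = TRUE))
}

#' @rdname fulvestrant_catalog
#' @export
fulvestrant_ledger <- function() {
  read_ledger(system.file("extdata", "fulvestrant_ledger.json",
                          package = "nodeconnect", mustWork = TRUE))
}

#' @rdname fulvestrant_catalog
#' @export
fulvestrant_map <- function() {
  assemble_from_ledger(fulvestrant_ledger(), catalog = fulvestrant_catalog())
}

#' Kinome-screen positive-hit summary fixture
#'
#' The packaged summary of the arrayed kinome screen: each positive-hit
#' gene with its number of positive shRNA clones and whether it entered
#' the interaction map.
#'
#' @return a `data.frame` with columns `gene`, `n_positive_clones`,
#'   `in_map`.
#' @export
kinome_screen_summary <- function() {
  read.delim(system.file("extdata", "kinome_screen_summary.tsv",
                         package = "nodeconnect", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
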