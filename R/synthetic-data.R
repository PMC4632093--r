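#' Configure a synthetic RNAi viability screen
#'
#' Describes one arrayed shRNA knockdown screen of cultured cells under a
#' cytotoxic drug (e.g. fulvestrant) versus vehicle. Each target gene is
#' covered by several independent shRNA clones; each clone is assayed in
#' replicate in both arms. Knockdown of a *true hit* protects cells from the
#' drug (viability uplift in the drug arm); knockdown of a *toxic* target
#' kills cells regardless of treatment (vehicle-arm depression), emulating
#' genes such as the myosin light chains whose silencing damages the cells
#' nonspecifically.
#'
#' Viability is modeled as normal noise around arm means, with the
#' drug-arm mean of control-infected cells normalized to 1.0 (the
#' drug-killed baseline); resistance appears as an uplift above it.
#'
#' @param n_targets number of target genes in the library.
#' @param clones_per_target distinct shRNA clones per target (>= 2).
#' @param replicates replicate wells per clone per arm (>= 2; >= 3 advised).
#' @param true_hits character vector of target IDs whose knockdown confers
#'   drug resistance.
#' @param effect_size mean drug-arm viability uplift for true hits, as a
#'   fraction of the drug-killed baseline (0 = null screen).
#' @param toxic_targets character vector of targets whose knockdown reduces
#'   viability in both arms.
#' @param toxic_factor multiplicative viability factor for toxic-target
#'   clones (default 0.3, i.e. a strong nonspecific kill).
#' @param noise_sd standard deviation of the assay noise (>= 0; 0 gives the
#'   noiseless limit used by simulation oracles).
#' @param control_id label of the empty-vector control (default "pLKO.1").
#' @param control_replicates replicate wells for the control arm rows
#'   (default: same as `replicates`).
#' @param seed integer RNG seed.
#' @return an object of class `screen_sim_config`.
#' @seealso [generate_screen()]
#' @export
screen_sim_config <- function(n_targets,
                              clones_per_target = 5L,
                              replicates = 3L,
                              true_hits = character(),
                              effect_size = 0.5,
                              toxic_targets = character(),
                              toxic_factor = 0.3,
                              noise_sd = 0.1,
                              control_id = "pLKO.1",
                              control_replicates = NULL,
                              seed = 1L) {
  n_targets <- check_count(n_targets, "n_targets")
  clones_per_target <- check_count(clones_per_target, "clones_per_target", min = 2L)
  replicates <- check_count(replicates, "replicates", min = 2L)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    stop("`effect_size` must be >= 0", call. = FALSE)
  }
  check_fraction(toxic_factor, "toxic_factor")
  if (is.null(control_replicates)) control_replicates <- replicates
  control_replicates <- check_count(control_replicates, "control_replicates", min = 2L)
  structure(
    list(n_targets = n_targets, clones_per_target = clones_per_target,
         replicates = replicates, true_hits = as.character(true_hits),
         effect_size = as.numeric(effect_size),
         toxic_targets = as.character(toxic_targets),
         toxic_factor = as.numeric(toxic_factor),
         noise_sd = as.numeric(noise_sd), control_id = control_id,
         control_replicates = control_replicates, seed = as.integer(seed)),
    class = "screen_sim_config")
}

#' Simulate a clone-level viability table
#'
#' Generates one row per (target, clone, arm, replicate) plus control rows
#' labeled with the control-vector ID. True-hit targets have elevated
#' drug-arm means; toxic targets have depressed means in both arms (a target
#' may be both). Viabilities are truncated at zero.
#'
#' @param config a [screen_sim_config()].
#' @return a `data.frame` with columns `target_id`, `clone_id`, `arm`
#'   (`"drug"` or `"vehicle"`), `replicate`, `viability`.
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    targets <- sprintf("T%04d", seq_len(config$n_targets))
    if (length(config$true_hits)) {
      # allow symbolic hit IDs: anything not matching a generated ID is kept
      # as-is so callers can plant named genes
      extra <- setdiff(config$true_hits, targets)
      targets <- unique(c(targets, extra))
    }
    extra_tox <- setdiff(config$toxic_targets, targets)
    targets <- unique(c(targets, extra_tox))

    rows <- vector("list", length(targets) + 1L)
    clone_counter <- 0L
    for (i in seq_along(targets)) {
      tg <- targets[i]
      is_hit <- tg %in% config$true_hits
      is_tox <- tg %in% config$toxic_targets
      drug_mean <- (1 + if (is_hit) config$effect_size else 0) *
        (if (is_tox) config$toxic_factor else 1)
      veh_mean <- 1 * (if (is_tox) config$toxic_factor else 1)
      clone_ids <- sprintf("TRCN%07d", clone_counter + seq_len(config$clones_per_target))
      clone_counter <- clone_counter + config$clones_per_target
      n <- config$replicates
      rows[[i]] <- data.frame(
        target_id = tg,
        clone_id = rep(clone_ids, each = 2L * n),
        arm = rep(rep(c("drug", "vehicle"), each = n), config$clones_per_target),
        replicate = rep(seq_len(n), 2L * config$clones_per_target),
        mu = rep(rep(c(drug_mean, veh_mean), each = n), config$clones_per_target),
        stringsAsFactors = FALSE)
    }
    nc <- config$control_replicates
    rows[[length(targets) + 1L]] <- data.frame(
      target_id = config$control_id, clone_id = config$control_id,
      arm = rep(c("drug", "vehicle"), each = nc),
      replicate = rep(seq_len(nc), 2L),
      mu = 1, stringsAsFactors = FALSE)
    tab <- do.call(rbind, rows)
    tab$viability <- pmax(0, tab$mu + rnorm(nrow(tab), sd = config$noise_sd))
    tab$mu <- NULL
    rownames(tab) <- NULL
    tab
  })
}

#' Configure a synthetic candidate-interaction network
#'
#' Builds a random undirected gene graph with a planted connected
#' subnetwork representing the true required-gene set, so that the recall
#' and precision of the iterative seed-and-expand screen can be measured
#' against known ground truth.
#'
#' @param n_genes genes in the catalog.
#' @param mean_degree expected background degree (Erdos-Renyi edges).
#' @param planted_subnetwork_size size of the planted required-gene set
#'   (<= `n_genes`); connected via a random spanning tree when >= 2.
#' @param primary_seed_count number of primary seed genes, drawn from the
#'   planted subnetwork.
#' @param seed integer RNG seed.
#' @return an object of class `network_sim_config`.
#' @export
network_sim_config <- function(n_genes, mean_degree = 2,
                               planted_subnetwork_size = 5L,
                               primary_seed_count = 2L, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  planted_subnetwork_size <- check_count(planted_subnetwork_size,
                                         "planted_subnetwork_size")
  if (planted_subnetwork_size > n_genes) {
    stop("`planted_subnetwork_size` must be <= `n_genes`", call. = FALSE)
  }
  primary_seed_count <- check_count(primary_seed_count, "primary_seed_count")
  if (primary_seed_count > planted_subnetwork_size) {
    stop("`primary_seed_count` must be <= `planted_subnetwork_size`",
         call. = FALSE)
  }
  if (!is.numeric(mean_degree) || mean_degree < 0) {
    stop("`mean_degree` must be >= 0", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, mean_degree = as.numeric(mean_degree),
         planted_subnetwork_size = planted_subnetwork_size,
         primary_seed_count = primary_seed_count, seed = as.integer(seed)),
    class = "network_sim_config")
}

#' Simulate a candidate-interaction catalog with a planted subnetwork
#'
#' @param config a [network_sim_config()].
#' @return a list with elements `catalog` (an [interaction_catalog()]),
#'   `truth` (the planted required-gene set) and `seeds` (the primary seed
#'   genes, a subset of `truth`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    truth <- sample(genes, config$planted_subnetwork_size)
    edges <- matrix(character(0), ncol = 2L)
    if (length(truth) >= 2L) {
      # random recursive tree keeps the planted subnetwork connected
      tree_to <- vapply(2:length(truth),
                        function(i) truth[sample.int(i - 1L, 1L)], "")
      edges <- rbind(edges, cbind(truth[-1L], tree_to))
    }
    p_edge <- min(1, config$mean_degree / max(1L, config$n_genes - 1L))
    if (p_edge > 0 && config$n_genes >= 2L) {
      pairs <- utils::combn(genes, 2L)
      keep <- runif(ncol(pairs)) < p_edge
      if (any(keep)) edges <- rbind(edges, t(pairs[, keep, drop = FALSE]))
    }
    ed <- if (nrow(edges)) {
      data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character())
    }
    catalog <- interaction_catalog(ed, genes = genes)
    seeds <- sample(truth, config$primary_seed_count)
    list(catalog = catalog, truth = sort(truth), seeds = sort(seeds))
  })
}

# The 10 antigens scored in the immunohistochemistry panel.
ihc_default_antigens <- c("calmodulin", "CSK", "DAPK1", "DAPK3", "ERBB4",
                          "JNK2", "MEK2", "MYLK", "STAT3", "STAT5")

#' Configure a synthetic immunohistochemistry scoring experiment
#'
#' Emulates two-examiner ordinal intensity scoring (0-4) of a panel of
#' antigens over a set of tumor sections, with a latent per-patient
#' synchronization factor: when `sync_rho` is high, antigens rise and fall
#' together across patients (the "synchronized expression" structure), and
#' the same latent factor lowers the probability of recurrence-free status
#' through `recurrence_link`.
#'
#' @param n_patients number of patients (default 18).
#' @param n_antigens antigens in the panel (default 10).
#' @param n_examiners independent scorers (default 2).
#' @param sync_rho latent-factor loading in `[0, 1]`; 0 makes antigens
#'   mutually independent, 1 makes them perfectly rank-synchronized.
#' @param recurrence_link log-odds effect of the latent factor on
#'   recurrence (positive: high-scoring patients recur less).
#' @param examiner_sd standard deviation of inter-rater noise on the
#'   ordinal scale (0 = both examiners agree exactly).
#' @param endocrine_frac fraction of patients receiving endocrine therapy.
#' @param seed integer RNG seed.
#' @return an object of class `ihc_sim_config`.
#' @export
ihc_sim_config <- function(n_patients = 18L, n_antigens = 10L,
                           n_examiners = 2L, sync_rho = 0.6,
                           recurrence_link = 1, examiner_sd = 0.5,
                           endocrine_frac = 0.5, seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 2L)
  n_antigens <- check_count(n_antigens, "n_antigens")
  n_examiners <- check_count(n_examiners, "n_examiners")
  check_fraction(sync_rho, "sync_rho")
  check_fraction(endocrine_frac, "endocrine_frac")
  if (!is.numeric(examiner_sd) || examiner_sd < 0) {
    stop("`examiner_sd` must be >= 0", call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, n_antigens = n_antigens,
         n_examiners = n_examiners, sync_rho = as.numeric(sync_rho),
         recurrence_link = as.numeric(recurrence_link),
         examiner_sd = as.numeric(examiner_sd),
         endocrine_frac = as.numeric(endocrine_frac), seed = as.integer(seed)),
    class = "ihc_sim_config")
}

#' Simulate a two-examiner ordinal IHC score table
#'
#' A standard-normal latent factor per patient drives all antigens with
#' loading `sync_rho`; per-antigen latent values are discretized to the
#' `{0..4}` scale by fixed standard-normal quintile bins, and each
#' examiner's raw score adds rounded rating noise, clipped to the scale.
#'
#' @param config an [ihc_sim_config()].
#' @return a list of class `ihc_table` with elements `scores` (long
#'   `data.frame`: `patient_id`, `antigen`, `examiner`, `raw_score`) and
#'   `patients` (`patient_id`, `recurrence`, `endocrine_therapy`, plus
#'   T/N/M and clinical stage labels).
#' @export
generate_ihc <- function(config) {
  stopifnot(inherits(config, "ihc_sim_config"))
  with_seed(config$seed, {
    np <- config$n_patients
    na_ <- config$n_antigens
    antigens <- if (na_ == length(ihc_default_antigens)) {
      ihc_default_antigens
    } else {
      sprintf("antigen_%02d", seq_len(na_))
    }
    pid <- sprintf("P%03d", seq_len(np))
    f <- rnorm(np)
    rho <- config$sync_rho
    z <- rho * f + sqrt(1 - rho^2) * matrix(rnorm(np * na_), np, na_)
    bins <- qnorm(c(0.2, 0.4, 0.6, 0.8))  # fixed quintile bins -> {0..4}
    base_score <- matrix(findInterval(z, bins), np, na_)
    scores <- expand.grid(patient_id = pid, antigen = antigens,
                          examiner = seq_len(config$n_examiners),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idx <- cbind(match(scores$patient_id, pid), match(scores$antigen, antigens))
    noise <- if (config$examiner_sd > 0) {
      round(rnorm(nrow(scores), sd = config$examiner_sd))
    } else {
      0
    }
    scores$raw_score <- pmin(4L, pmax(0L, base_score[idx] + noise))
    p_rec <- plogis(-0.4 - config$recurrence_link * f)
    patients <- data.frame(
      patient_id = pid,
      recurrence = runif(np) < p_rec,
      endocrine_therapy = runif(np) < config$endocrine_frac,
      t_stage = sample(1:4, np, replace = TRUE),
      n_stage = sample(0:2, np, replace = TRUE),
      m_stage = 0L,
      stringsAsFactors = FALSE)
    patients$clinical_stage <- c("I", "II", "IIIa", "IIIb")[patients$t_stage]
    structure(list(scores = scores, patients = patients, config = config),
              class = "ihc_table")
  })
}

#' Configure a synthetic expression-plus-survival cohort
#'
#' Emulates a breast-cancer cohort with a gene-by-patient expression matrix
#' and recurrence-free survival records, under a proportional-hazards model
#' acting through median-split expression groups: above-median expressers of
#' a prognostic gene have their hazard multiplied by that gene's hazard
#' ratio (ratios < 1 mean high expression is protective).
#'
#' @param n_patients cohort size.
#' @param n_genes genes in the expression matrix.
#' @param prognostic_genes named numeric vector of hazard ratios (> 0),
#'   names giving gene IDs; may be empty for a null cohort.
#' @param baseline_hazard exponential event rate for the reference group.
#' @param censor_rate fraction of patients independently censored (their
#'   follow-up ends uniformly before the event).
#' @param cohort_id label carried through to results.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients, n_genes = 20L,
                              prognostic_genes = numeric(),
                              baseline_hazard = 0.1, censor_rate = 0.2,
                              cohort_id = "synthetic_cohort", seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 4L)
  n_genes <- check_count(n_genes, "n_genes")
  if (length(prognostic_genes)) {
    if (is.null(names(prognostic_genes)) || any(!nzchar(names(prognostic_genes)))) {
      stop("`prognostic_genes` must be a named vector of hazard ratios",
           call. = FALSE)
    }
    if (any(prognostic_genes <= 0)) {
      stop("hazard ratios must be > 0", call. = FALSE)
    }
  }
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    stop("`baseline_hazard` must be > 0", call. = FALSE)
  }
  check_fraction(censor_rate, "censor_rate")
  structure(
    list(n_patients = n_patients, n_genes = n_genes,
         prognostic_genes = prognostic_genes,
         baseline_hazard = as.numeric(baseline_hazard),
         censor_rate = as.numeric(censor_rate), cohort_id = cohort_id,
         seed = as.integer(seed)),
    class = "cohort_sim_config")
}

#' Simulate an expression matrix with linked survival
#'
#' Event times are exponential with per-patient hazard
#' `baseline * prod(HR^(expression > median))` over prognostic genes.
#' Censoring is independent of covariates: each patient is censored with
#' probability `censor_rate`, at a time uniform on `(0, T)`.
#'
#' @param config a [cohort_sim_config()].
#' @return a list of class `cohort_dataset` with `cohort_id`, `expression`
#'   (genes x patients matrix) and `survival` (`patient_id`, `time`,
#'   `event`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    np <- config$n_patients
    genes <- sprintf("gene_%03d", seq_len(config$n_genes))
    pg <- names(config$prognostic_genes)
    genes <- unique(c(genes, pg))
    expr <- matrix(rnorm(length(genes) * np), nrow = length(genes),
                   dimnames = list(genes, sprintf("S%04d", seq_len(np))))
    hazard <- rep(config$baseline_hazard, np)
    for (g in pg) {
      high <- expr[g, ] > median(expr[g, ])
      hazard <- hazard * ifelse(high, config$prognostic_genes[[g]], 1)
    }
    t_event <- rexp(np, rate = hazard)
    censored <- runif(np) < config$censor_rate
    time <- ifelse(censored, runif(np) * t_event, t_event)
    surv <- data.frame(patient_id = colnames(expr), time = time,
                       event = as.integer(!censored),
                       stringsAsFactors = FALSE)
    structure(list(cohort_id = config$cohort_id, expression = expr,
                   survival = surv, config = config),
              class = "cohort_dataset")
  })
}

#' Write simulated tables to plain-text files
#'
#' Writers for the pipeline's tab-separated interchange formats.
#'
#' @param x the object to write.
#' @param path output file (for `write_ihc_table`, a stem producing
#'   `<stem>_scores.tsv` and `<stem>_patients.tsv`; for
#'   `write_cohort`, `<stem>_expression.tsv` and `<stem>_survival.tsv`).
#' @return the path(s) written, invisibly.
#' @export
write_viability_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_viability_table
#' @export
read_viability_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_id", "clone_id", "arm", "replicate", "viability")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("viability table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' @rdname write_viability_table
#' @export
write_ihc_table <- function(x, path) {
  stopifnot(inherits(x, "ihc_table"))
  paths <- paste0(path, c("_scores.tsv", "_patients.tsv"))
  write.table(x$scores, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$patients, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_viability_table
#' @export
read_ihc_table <- function(path) {
  paths <- paste0(path, c("_scores.tsv", "_patients.tsv"))
  structure(list(scores = read.delim(paths[1L], stringsAsFactors = FALSE),
                 patients = read.delim(paths[2L], stringsAsFactors = FALSE)),
            class = "ihc_table")
}

#' @rdname write_viability_table
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort_dataset"))
  paths <- paste0(path, c("_expression.tsv", "_survival.tsv"))
  expr <- data.frame(gene = rownames(x$expression), x$expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write.table(expr, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$survival, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_viability_table
#' @param cohort_id cohort label for `read_cohort`.
#' @export
read_cohort <- function(path, cohort_id = basename(path)) {
  paths <- paste0(path, c("_expression.tsv", "_survival.tsv"))
  expr_df <- read.delim(paths[1L], check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(expr_df[, -1L, drop = FALSE])
  rownames(expr) <- expr_df[[1L]]
  surv <- read.delim(paths[2L], stringsAsFactors = FALSE)
  structure(list(cohort_id = cohort_id, expression = expr, survival = surv),
            class = "cohort_dataset")
}
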