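#' Per-clone resistance test (one-way ANOVA versus control)
#'
#' Tests whether one shRNA clone's drug-arm viability differs from the
#' empty-vector control's drug-arm viability by a two-group one-way ANOVA
#' (F test), and gates the *positive* call on the resistant direction: a
#' clone is positive only if the test is significant **and** its mean
#' viability under drug lies strictly above the control mean. The F test
#' alone is direction-blind, so a significant drop (a sensitizing clone)
#' is never a positive.
#'
#' @param clone_viability numeric vector: drug-arm viabilities for the clone.
#' @param control_viability numeric vector: drug-arm viabilities for the
#'   control-infected cells.
#' @param alpha significance level for the positive call (default 0.05).
#' @param target_id,clone_id optional labels carried into the result.
#' @return a one-row `data.frame` with `target_id`, `clone_id`, `F_stat`,
#'   `p_value`, `direction` (`"resistant"`, `"sensitizing"` or `"none"`)
#'   and `positive`.
#' @export
test_clone <- function(clone_viability, control_viability, alpha = 0.05,
                       target_id = NA_character_, clone_id = NA_character_) {
  clone_viability <- as.numeric(clone_viability)
  control_viability <- as.numeric(control_viability)
  if (length(clone_viability) < 2L || length(control_viability) < 2L) {
    stop("insufficient data: need >= 2 replicates per group in the drug arm",
         call. = FALSE)
  }
  if (any(!is.finite(clone_viability)) || any(!is.finite(control_viability))) {
    stop("viabilities must be finite", call. = FALSE)
  }
  check_fraction(alpha, "alpha")
  m_clone <- mean(clone_viability)
  m_ctrl <- mean(control_viability)
  ss_within <- sum((clone_viability - m_clone)^2) +
    sum((control_viability - m_ctrl)^2)
  if (ss_within == 0) {
    if (m_clone == m_ctrl) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
    }
  } else {
    fit <- oneway.test(v ~ g, data = data.frame(
      v = c(clone_viability, control_viability),
      g = rep(c("clone", "control"),
              c(length(clone_viability), length(control_viability)))),
      var.equal = TRUE)
    f <- unname(fit$statistic)
    p <- unname(fit$p.value)
  }
  direction <- if (m_clone > m_ctrl) "resistant"
               else if (m_clone < m_ctrl) "sensitizing"
               else "none"
  data.frame(target_id = target_id, clone_id = clone_id, F_stat = f,
             p_value = p, direction = direction,
             positive = (p < alpha && direction == "resistant"),
             stringsAsFactors = FALSE)
}

#' Call a positive-hit target from its clone results
#'
#' A target is a *positive hit* when at least `min_positive` distinct shRNA
#' clones each induce statistically significant drug resistance (the
#' two-clone rule filters out clone-specific off-target effects). A target
#' flagged toxic is reported untestable (`is_hit = NA`) rather than
#' negative, feeding the predicted-only logic of the map assembly.
#'
#' @param clone_results `data.frame` of [test_clone()] rows for one target.
#' @param min_positive minimum number of positive clones (default 2).
#' @param toxicity_flag `TRUE`, `FALSE` or `NA` (indeterminate) from
#'   [flag_toxicity()].
#' @return a one-row `data.frame` with `target_id`, `n_positive_clones`,
#'   `n_clones_tested`, `is_hit` (logical; `NA` = untestable because toxic)
#'   and `toxicity_flag`.
#' @export
call_target <- function(clone_results, min_positive = 2L,
                        toxicity_flag = FALSE) {
  if (is.null(clone_results) || nrow(clone_results) == 0L) {
    stop("`clone_results` must contain at least one clone", call. = FALSE)
  }
  min_positive <- check_count(min_positive, "min_positive")
  n_pos <- sum(clone_results$positive)
  hit <- n_pos >= min_positive
  if (isTRUE(toxicity_flag)) hit <- NA
  data.frame(target_id = clone_results$target_id[1L],
             n_positive_clones = n_pos,
             n_clones_tested = nrow(clone_results),
             is_hit = hit,
             toxicity_flag = toxicity_flag,
             stringsAsFactors = FALSE)
}

#' Flag nonspecifically toxic knockdowns from vehicle-arm viability
#'
#' A clone whose vehicle-arm mean viability falls below
#' `threshold * control vehicle-arm mean` kills cells even without drug,
#' so its requirement for drug-induced death cannot be assayed.
#'
#' @param vehicle_clone numeric vector of vehicle-arm viabilities for the
#'   clone (or all clones of a target pooled).
#' @param vehicle_control numeric vector of vehicle-arm control viabilities.
#' @param threshold fraction of the control mean below which the knockdown
#'   is toxic (default 0.5).
#' @return `TRUE`, `FALSE`, or `NA` when either vehicle arm is absent
#'   (indeterminate, distinct from "not toxic").
#' @export
flag_toxicity <- function(vehicle_clone, vehicle_control, threshold = 0.5) {
  check_fraction(threshold, "threshold", lo = 0, hi = Inf)
  if (length(vehicle_clone) == 0L || length(vehicle_control) == 0L) {
    return(NA)
  }
  mean(vehicle_clone) < threshold * mean(vehicle_control)
}

#' Call hits across a whole clone-level viability table
#'
#' Runs [test_clone()] for every clone of every target against the control
#' (drug arm), [flag_toxicity()] per target (vehicle arm, all clones
#' pooled), and [call_target()] per target.
#'
#' @param table a clone-level viability `data.frame` (see
#'   [generate_screen()] for the schema).
#' @param alpha per-clone ANOVA significance level.
#' @param min_positive minimum positive clones for a hit.
#' @param toxicity_threshold vehicle-arm viability fraction below which a
#'   target is toxic.
#' @param control_id `target_id` of the empty-vector control rows.
#' @return a list with `clones` (per-clone test results) and `targets`
#'   (per-target hit calls).
#' @export
call_hits <- function(table, alpha = 0.05, min_positive = 2L,
                      toxicity_threshold = 0.5, control_id = "pLKO.1") {
  stopifnot(is.data.frame(table))
  if (!control_id %in% table$target_id) {
    stop(sprintf("control target '%s' not found in table", control_id),
         call. = FALSE)
  }
  ctrl <- table[table$target_id == control_id, ]
  ctrl_drug <- ctrl$viability[ctrl$arm == "drug"]
  ctrl_veh <- ctrl$viability[ctrl$arm == "vehicle"]
  targets <- setdiff(unique(table$target_id), control_id)
  clone_res <- vector("list", 0L)
  target_res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[i]
    sub <- table[table$target_id == tg, ]
    res <- lapply(split(sub, sub$clone_id), function(cl) {
      test_clone(cl$viability[cl$arm == "drug"], ctrl_drug, alpha = alpha,
                 target_id = tg, clone_id = cl$clone_id[1L])
    })
    res <- do.call(rbind, res)
    rownames(res) <- NULL
    tox <- flag_toxicity(sub$viability[sub$arm == "vehicle"], ctrl_veh,
                         threshold = toxicity_threshold)
    clone_res[[length(clone_res) + 1L]] <- res
    target_res[[i]] <- call_target(res, min_positive = min_positive,
                                   toxicity_flag = tox)
  }
  clones <- do.call(rbind, clone_res)
  targets_df <- do.call(rbind, target_res)
  rownames(clones) <- rownames(targets_df) <- NULL
  list(clones = clones, targets = targets_df)
}
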