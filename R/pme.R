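#' Average the two examiners' raw scores
#'
#' Immunohistochemistry signal intensities are scored independently by the
#' examiners on an ordinal 0-4 scale; the arithmetic mean of the raw
#' scores per (patient, antigen) cell is used for all downstream analysis
#' (steps of 0.5 for two examiners).
#'
#' @param scores long `data.frame` with columns `patient_id`, `antigen`,
#'   `examiner`, `raw_score`, or an `ihc_table` (its `$scores` is used).
#' @return `data.frame` with columns `patient_id`, `antigen`,
#'   `mean_score`.
#' @export
average_examiners <- function(scores) {
  if (inherits(scores, "ihc_table")) scores <- scores$scores
  stopifnot(is.data.frame(scores))
  need <- c("patient_id", "antigen", "examiner", "raw_score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    stop("score table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  full <- expand.grid(patient_id = unique(scores$patient_id),
                      antigen = unique(scores$antigen),
                      examiner = unique(scores$examiner),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$patient_id, d$antigen, d$examiner, sep = "\r")
  absent <- !(key(full) %in% key(scores))
  if (any(absent)) {
    cells <- with(full[absent, , drop = FALSE],
                  paste0("(", patient_id, ", ", antigen, ", examiner ",
                         examiner, ")"))
    stop("missing score cells: ", paste(head(cells, 10L), collapse = ", "),
         if (sum(absent) > 10L) sprintf(" and %d more", sum(absent) - 10L),
         call. = FALSE)
  }
  out <- aggregate(raw_score ~ patient_id + antigen, data = scores, FUN = mean)
  names(out)[names(out) == "raw_score"] <- "mean_score"
  out[order(out$patient_id, out$antigen), ]
}

#' Compute per-patient Prognosis Marker Expression (PME) scores
#'
#' The PME score of a tumor is the sum over the antigen panel of the
#' examiner-averaged intensity scores, so it ranges from 0 to
#' `4 * n_antigens` (0-40 for the 10-antigen panel).
#'
#' @param mean_scores output of [average_examiners()].
#' @return `data.frame` with columns `patient_id`, `pme`, ordered by
#'   patient.
#' @export
compute_pme <- function(mean_scores) {
  stopifnot(is.data.frame(mean_scores),
            all(c("patient_id", "antigen", "mean_score") %in%
                  names(mean_scores)))
  antigens <- unique(mean_scores$antigen)
  counts <- table(mean_scores$patient_id)
  if (any(counts != length(antigens))) {
    bad <- names(counts)[counts != length(antigens)]
    stop("patients missing antigen scores: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- aggregate(mean_score ~ patient_id, data = mean_scores, FUN = sum)
  names(out)[names(out) == "mean_score"] <- "pme"
  out[order(out$patient_id), ]
}

#' Marginal-resampling permutation null for the PME score
#'
#' Builds the theoretical PME distribution under the hypothesis that the
#' antigens are expressed mutually independently: each simulated score
#' draws, independently per antigen and with replacement, one value from
#' that antigen's observed per-patient mean scores and sums over the
#' panel. The two-tail 5% and 1% cutoffs are the empirical 2.5/97.5 and
#' 0.5/99.5 percentiles (linear interpolation).
#'
#' @param mean_scores output of [average_examiners()].
#' @param n_perm number of simulated PME scores (default 50000).
#' @param seed integer RNG seed.
#' @return an object of class `permutation_null`: list with `samples`,
#'   `cutoff_5` (`lower`, `upper`), `cutoff_1`, `n_perm`, `seed`.
#' @export
simulate_null <- function(mean_scores, n_perm = 50000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 1000L) {
    warning("n_perm < 1000: tail cutoffs will be unstable", call. = FALSE)
  }
  mat <- score_matrix(mean_scores)
  if (nrow(mat) < 2L) {
    stop("need >= 2 distinct patients to resample marginals", call. = FALSE)
  }
  with_seed(seed, {
    sums <- rowSums(vapply(seq_len(ncol(mat)), function(j) {
      sample(mat[, j], n_perm, replace = TRUE)
    }, numeric(n_perm)))
    structure(list(
      samples = sums,
      cutoff_5 = c(lower = unname(quantile(sums, 0.025)),
                   upper = unname(quantile(sums, 0.975))),
      cutoff_1 = c(lower = unname(quantile(sums, 0.005)),
                   upper = unname(quantile(sums, 0.995))),
      n_perm = n_perm, seed = seed), class = "permutation_null")
  })
}

score_matrix <- function(mean_scores) {
  stopifnot(is.data.frame(mean_scores))
  pts <- unique(mean_scores$patient_id)
  ags <- unique(mean_scores$antigen)
  mat <- matrix(NA_real_, length(pts), length(ags),
                dimnames = list(pts, ags))
  mat[cbind(match(mean_scores$patient_id, pts),
            match(mean_scores$antigen, ags))] <- mean_scores$mean_score
  if (anyNA(mat)) stop("incomplete patient x antigen score grid", call. = FALSE)
  mat
}

#' @rdname simulate_null
#' @param x a `permutation_null`.
#' @param ... unused.
#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation null: %d samples, mean %.2f; 5%% tails (%.2f, %.2f); 1%% tails (%.2f, %.2f)\n",
    x$n_perm, mean(x$samples), x$cutoff_5["lower"], x$cutoff_5["upper"],
    x$cutoff_1["lower"], x$cutoff_1["upper"]))
  invisible(x)
}

#' Tail-occupancy chi-square test of synchronized expression
#'
#' If antigen expression were mutually independent, the observed PME
#' scores would follow the marginal-resampling null and a fraction
#' `alpha_level` of patients would fall strictly beyond its two-tail
#' cutoffs. Over-occupancy of the tails (many extreme tumors, all-high or
#' all-low) indicates synchronized expression. A Pearson chi-square
#' compares tail counts with expectation; because the expected tail
#' counts are small at n = 18 (0.9 at the 5% tails), an exact binomial
#' p-value is reported alongside.
#'
#' @param pme `data.frame` from [compute_pme()], or a numeric vector of
#'   observed PME scores.
#' @param null a [simulate_null()] result.
#' @param alpha_level tail probability, 0.05 or 0.01 (any value in (0,1)
#'   is accepted).
#' @param cells `"pooled"` (one in-tail cell versus out-of-tail, 1 df) or
#'   `"split"` (lower tail / middle / upper tail, 2 df).
#' @return a list of class `tail_chi2` with `alpha_level`,
#'   `observed_in_tail`, `expected_in_tail`, `chi2`, `df`, `p_value`,
#'   `p_binomial`, `cutoffs`.
#' @export
tail_chi2 <- function(pme, null, alpha_level = 0.05,
                      cells = c("pooled", "split")) {
  cells <- match.arg(cells)
  stopifnot(inherits(null, "permutation_null"))
  x <- if (is.data.frame(pme)) pme$pme else as.numeric(pme)
  n <- length(x)
  if (n == 0L) stop("no observed PME scores", call. = FALSE)
  check_fraction(alpha_level, "alpha_level")
  cuts <- if (alpha_level <= 0.01) null$cutoff_1 else null$cutoff_5
  if (cuts["lower"] == cuts["upper"] &&
      diff(range(null$samples)) == 0 && n * alpha_level > 0) {
    stop("degenerate point-mass null: tail expectations are undefined",
         call. = FALSE)
  }
  in_lower <- x < cuts["lower"]
  in_upper <- x > cuts["upper"]
  obs <- sum(in_lower | in_upper)
  exp_tail <- n * alpha_level
  if (cells == "pooled") {
    observed <- c(obs, n - obs)
    expected <- c(exp_tail, n - exp_tail)
    df <- 1L
  } else {
    observed <- c(sum(in_lower), n - obs, sum(in_upper))
    expected <- c(exp_tail / 2, n - exp_tail, exp_tail / 2)
    df <- 2L
  }
  chi2 <- sum((observed - expected)^2 / expected)
  structure(list(
    alpha_level = alpha_level, observed_in_tail = obs,
    expected_in_tail = exp_tail, chi2 = chi2, df = df,
    p_value = pchisq(chi2, df = df, lower.tail = FALSE),
    p_binomial = binom.test(obs, n, p = alpha_level)$p.value,
    cutoffs = cuts, cells = cells, n = n), class = "tail_chi2")
}

#' @rdname tail_chi2
#' @param x a `tail_chi2` result.
#' @param ... unused.
#' @export
print.tail_chi2 <- function(x, ...) {
  cat(sprintf(
    "tail chi-square (%s, %g%% two-tail): %d/%d in tail (expected %.2f), chi2 = %.4f (df %d), p = %.3g; exact binomial p = %.3g\n",
    x$cells, 100 * x$alpha_level, x$observed_in_tail, x$n,
    x$expected_in_tail, x$chi2, x$df, x$p_value, x$p_binomial))
  invisible(x)
}

#' Compare PME scores between recurrence groups
#'
#' Two-sided Wilcoxon rank-sum test of PME by recurrence status, with a
#' Welch t-test reported alongside, optionally restricted to the patients
#' who did (or did not) receive endocrine therapy.
#'
#' @param pme `data.frame` from [compute_pme()].
#' @param patients patient metadata with `patient_id`, `recurrence` and
#'   (for subgrouping) `endocrine_therapy`; an `ihc_table` is also
#'   accepted.
#' @param subgroup `"all"`, `"endocrine_only"` or `"no_endocrine"`.
#' @return a list with `subgroup`, `n`, group `medians`, `statistic`,
#'   `p_value` (Wilcoxon) and `p_t` (Welch).
#' @export
compare_groups <- function(pme, patients,
                           subgroup = c("all", "endocrine_only",
                                        "no_endocrine")) {
  subgroup <- match.arg(subgroup)
  if (inherits(patients, "ihc_table")) patients <- patients$patients
  d <- merge(pme, patients, by = "patient_id")
  if (subgroup == "endocrine_only") d <- d[isTRUE_vec(d$endocrine_therapy), ]
  if (subgroup == "no_endocrine") d <- d[!isTRUE_vec(d$endocrine_therapy), ]
  rec <- isTRUE_vec(d$recurrence)
  if (!any(rec) || all(rec)) {
    stop("both recurrence groups must be non-empty in subgroup '",
         subgroup, "'", call. = FALSE)
  }
  w <- suppressWarnings(wilcox.test(d$pme[rec], d$pme[!rec],
                                    alternative = "two.sided"))
  tt <- t.test(d$pme[rec], d$pme[!rec])
  list(subgroup = subgroup,
       n = c(recurrent = sum(rec), nonrecurrent = sum(!rec)),
       medians = c(recurrent = median(d$pme[rec]),
                   nonrecurrent = median(d$pme[!rec])),
       statistic = unname(w$statistic), p_value = w$p.value,
       p_t = tt$p.value)
}
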