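#' Median split of an expression vector
#'
#' Divides patients into high expressers (strictly above the sample
#' median) and low expressers (at or below it). Ties at the median go to
#' the low group, so every non-tied high-group value exceeds every
#' low-group value.
#'
#' @param x numeric expression vector (>= 4 patients).
#' @return a factor with levels `"low"`, `"high"` aligned to `x`.
#' @export
median_split <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("need >= 4 patients to split", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("all expression values identical: no median split possible",
         call. = FALSE)
  }
  factor(ifelse(x > median(x), "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier recurrence-free survival curve
#'
#' Product-limit estimate of the survival function; censored subjects
#' leave the risk set without contributing an event.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1/TRUE = recurrence observed).
#' @return a `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, one row per distinct observed time.
#' @export
km_curve <- function(times, events) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative follow-up times", call. = FALSE)
  if (length(times) < 1L) stop("need >= 1 subject", call. = FALSE)
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' One-sided log-rank test, "high expressers fare better"
#'
#' Standard log-rank statistic with the hypergeometric variance; the
#' one-sided p-value is `pnorm(z)` where `z` carries the sign of
#' (observed - expected) events in the high-expression group, so fewer
#' events than expected among high expressers (better survival) gives
#' p < 0.5.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators.
#' @param groups a factor from [median_split()] (levels `low`, `high`), or
#'   anything coercible to one.
#' @return the one-sided p-value.
#' @export
logrank_one_sided <- function(times, events, groups) {
  groups <- factor(groups, levels = c("low", "high"))
  if (anyNA(groups)) stop("groups must be 'low'/'high'", call. = FALSE)
  if (!all(table(groups) >= 1L)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  events <- as.integer(as.logical(events))
  if (sum(events) == 0L) {
    stop("degenerate input: no events observed", call. = FALSE)
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  i_high <- grep("high", names(sd_$n))[1L]
  obs_high <- sd_$obs[i_high]
  exp_high <- sd_$exp[i_high]
  var_high <- if (is.matrix(sd_$var)) sd_$var[i_high, i_high]
              else sd_$var[i_high]
  if (var_high <= 0) return(0.5)
  z <- (obs_high - exp_high) / sqrt(var_high)
  pnorm(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return the BH-adjusted values (estimated false discovery rates).
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Median-split prognostic screen across cohorts
#'
#' For every (gene, cohort) pair: split the cohort at the gene's median
#' expression, run the one-sided log-rank test against the alternative
#' that high expressers have better recurrence-free survival, then adjust
#' all p-values jointly by Benjamini-Hochberg and call significance at
#' the chosen false-discovery-rate threshold. Genes absent from a
#' cohort's matrix are recorded as skipped and excluded from the BH
#' family.
#'
#' @param cohorts a `cohort_dataset` or list of them (see
#'   [generate_cohort()] / [read_cohort()]).
#' @param genes character vector of genes to test.
#' @param fdr significance threshold on the adjusted values (default
#'   0.25).
#' @return a `data.frame` with one row per (gene, cohort):
#'   `gene`, `cohort_id`, `p_one_sided`, `fdr`, `significant`, `n_high`,
#'   `n_low`, `skipped`.
#' @export
survival_screen <- function(cohorts, genes, fdr = 0.25) {
  if (inherits(cohorts, "cohort_dataset")) cohorts <- list(cohorts)
  check_fraction(fdr, "fdr")
  rows <- list()
  for (co in cohorts) {
    stopifnot(inherits(co, "cohort_dataset"))
    if (sum(co$survival$event) == 0L) {
      stop(sprintf("cohort '%s' has no events: survival screen is degenerate",
                   co$cohort_id), call. = FALSE)
    }
    for (g in genes) {
      if (!g %in% rownames(co$expression)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, cohort_id = co$cohort_id, p_one_sided = NA_real_,
          fdr = NA_real_, significant = NA, n_high = NA_integer_,
          n_low = NA_integer_, skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      grp <- median_split(co$expression[g, ])
      p <- logrank_one_sided(co$survival$time, co$survival$event, grp)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cohort_id = co$cohort_id, p_one_sided = p, fdr = NA_real_,
        significant = NA, n_high = sum(grp == "high"),
        n_low = sum(grp == "low"), skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L || all(vapply(rows, function(r) r$skipped, TRUE))) {
    stop("no testable (gene, cohort) pairs", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  tested <- !res$skipped
  res$fdr[tested] <- bh_adjust(res$p_one_sided[tested])
  res$significant[tested] <- res$fdr[tested] < fdr
  res
}
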