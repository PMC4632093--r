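#' Classify a gene's transcriptional response to a treatment
#'
#' Works on normalized relative expression (vehicle mean defined as 1.00):
#' an omnibus one-way ANOVA across vehicle plus all treatment conditions
#' decides significance; if significant, the call follows the sign of the
#' most extreme condition mean relative to 1.00 (`induced` above,
#' `suppressed` below). For a dose series, every individually significant
#' dose must deviate on the same side of 1.00, otherwise the gene is
#' reported `unchanged` with a warning (inconsistent direction).
#'
#' @param dataset `data.frame` with columns `gene`, `condition`,
#'   `replicate`, `relative_expression`; the vehicle condition must be
#'   present. Values are renormalized so the vehicle mean is exactly 1.
#' @param gene gene to classify (default: the only gene present).
#' @param treatment character vector naming the treatment condition(s)
#'   (e.g. `"drug"`, or the dose levels of an agonist series). Defaults
#'   to every non-vehicle condition in the table.
#' @param alpha significance level (default 0.05).
#' @param vehicle label of the vehicle condition (default `"vehicle"`).
#' @return a list of class `response_call` with `gene`, `treatment`,
#'   `call` (`"induced"`, `"suppressed"`, `"unchanged"`), `p_value`
#'   (omnibus), `condition_means` and `per_dose` (per-condition p-values
#'   and directions).
#' @export
classify_response <- function(dataset, gene = NULL, treatment = NULL,
                              alpha = 0.05, vehicle = "vehicle") {
  stopifnot(is.data.frame(dataset))
  need <- c("gene", "condition", "replicate", "relative_expression")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) {
    stop("dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(gene)) {
    gene <- unique(dataset$gene)
    if (length(gene) != 1L) {
      stop("several genes present; specify `gene`", call. = FALSE)
    }
  }
  d <- dataset[dataset$gene == gene, , drop = FALSE]
  if (!vehicle %in% d$condition) {
    stop(sprintf("vehicle condition '%s' missing for gene %s", vehicle, gene),
         call. = FALSE)
  }
  if (is.null(treatment)) treatment <- setdiff(unique(d$condition), vehicle)
  d <- d[d$condition %in% c(vehicle, treatment), , drop = FALSE]
  reps <- table(d$condition)
  if (any(reps < 3L)) {
    stop("need >= 3 replicates per condition; short: ",
         paste(names(reps)[reps < 3L], collapse = ", "), call. = FALSE)
  }
  # renormalize so the vehicle mean is exactly 1.00 (scale invariance)
  v_mean <- mean(d$relative_expression[d$condition == vehicle])
  if (v_mean <= 0) stop("vehicle mean must be positive", call. = FALSE)
  d$relative_expression <- d$relative_expression / v_mean

  d$condition <- factor(d$condition, levels = c(vehicle, treatment))
  cond_means <- tapply(d$relative_expression, d$condition, mean)
  ss_within <- sum(tapply(d$relative_expression, d$condition,
                          function(v) sum((v - mean(v))^2)))
  if (ss_within == 0 && length(unique(round(cond_means, 12))) == 1L) {
    p_omni <- 1
  } else if (ss_within == 0) {
    p_omni <- 0
  } else {
    p_omni <- oneway.test(relative_expression ~ condition, data = d,
                          var.equal = TRUE)$p.value
  }

  per_dose <- do.call(rbind, lapply(treatment, function(tr) {
    vi <- d$relative_expression[d$condition == vehicle]
    ti <- d$relative_expression[d$condition == tr]
    ssw <- sum((vi - mean(vi))^2) + sum((ti - mean(ti))^2)
    p <- if (ssw == 0) {
      if (mean(ti) == mean(vi)) 1 else 0
    } else {
      oneway.test(v ~ g,
                  data = data.frame(v = c(vi, ti),
                                    g = rep(c("v", "t"),
                                            c(length(vi), length(ti)))),
                  var.equal = TRUE)$p.value
    }
    data.frame(condition = tr, mean = mean(ti), p_value = p,
               direction = ifelse(mean(ti) > 1, "up",
                                  ifelse(mean(ti) < 1, "down", "flat")),
               stringsAsFactors = FALSE)
  }))

  call <- "unchanged"
  if (p_omni < alpha) {
    sig <- per_dose[per_dose$p_value < alpha & per_dose$direction != "flat", ,
                    drop = FALSE]
    if (nrow(sig) == 0L) {
      # omnibus significant but no single dose separates: fall back on the
      # extreme-condition direction
      extreme <- per_dose$mean[which.max(abs(per_dose$mean - 1))]
      call <- if (extreme > 1) "induced" else "suppressed"
    } else if (all(sig$direction == "up")) {
      call <- "induced"
    } else if (all(sig$direction == "down")) {
      call <- "suppressed"
    } else {
      warning(sprintf(
        "gene %s: significant doses deviate in inconsistent directions; reporting unchanged",
        gene), call. = FALSE)
      call <- "unchanged"
    }
  }
  structure(list(gene = gene, treatment = treatment, call = call,
                 p_value = p_omni,
                 condition_means = cond_means, per_dose = per_dose,
                 alpha = alpha), class = "response_call")
}

#' @rdname classify_response
#' @param x a `response_call`.
#' @param ... unused.
#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("%s: %s (omnibus ANOVA p = %.3g across %d condition(s))\n",
              x$gene, x$call, x$p_value, length(x$treatment)))
  invisible(x)
}
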