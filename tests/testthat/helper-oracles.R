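# Independent oracles coded from first principles, used to cross-check the
# package's statistical routines. These deliberately avoid the code paths
# (and where possible the library calls) they verify.

# One-way two-group ANOVA from sums of squares.
anova_oracle <- function(x, y) {
  grand <- mean(c(x, y))
  ss_between <- length(x) * (mean(x) - grand)^2 +
    length(y) * (mean(y) - grand)^2
  ss_within <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  df1 <- 1
  df2 <- length(x) + length(y) - 2
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Log-rank z for the "high" group, looped over event times with the
# hypergeometric expectation and variance.
logrank_z_oracle <- function(times, events, high) {
  ut <- sort(unique(times[events == 1]))
  o <- e <- v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & high)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e) / sqrt(v)
}

# Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# A deterministic, strongly synchronized 18-patient two-examiner score
# table (synthetic stand-in for a deposited raw-score table): per-patient
# target PME scores are spread across the 10 antigens in half-point steps.
# Patient 2765 carries the maximum (36), patient 1363 the minimum (2.5).
make_synthetic_extreme_ihc <- function() {
  targets <- c("1363" = 2.5, L1 = 3, L2 = 3.5, L3 = 4, L4 = 5,
               M1 = 14, M2 = 16, M3 = 18, M4 = 19, M5 = 20, M6 = 21,
               M7 = 22, M8 = 24,
               H1 = 33, H2 = 34, H3 = 35, H4 = 35.5, "2765" = 36)
  antigens <- sprintf("antigen_%02d", 1:10)
  rows <- list()
  for (pid in names(targets)) {
    p <- targets[[pid]]
    base <- floor(p / 10 / 0.5) * 0.5
    k <- round((p - 10 * base) / 0.5)
    means <- rep(base, 10)
    if (k > 0) means[seq_len(k)] <- base + 0.5
    for (a in 1:10) {
      m <- means[a]
      pair <- if (abs(m - round(m)) < 1e-9) c(m, m) else c(floor(m), ceiling(m))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, antigen = antigens[a], examiner = 1:2,
        raw_score = pair, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
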