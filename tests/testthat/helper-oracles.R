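# Independent oracles, written from the defining formulas and kept free of
# any oncorank internals so they can cross-check the package's routes.

# Welch unequal-variance t-test, two-sided, from the textbook formulas.
oracle_welch_p <- function(a, b) {
  m1 <- mean(a); m2 <- mean(b)
  v1 <- var(a); v2 <- var(b)
  n1 <- length(a); n2 <- length(b)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t_stat), df)
}

# Product-limit estimator applied by hand: S(t) multiplies (1 - d/n) over
# event times up to t.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    n_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  data.frame(time = ut, survival = out)
}

# Log-rank by explicit risk tables: observed minus expected events in group
# A at each distinct event time, hypergeometric variance for ties.
oracle_logrank <- function(times, events, in_a) {
  ut <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (s in ut) {
    at <- times >= s
    n <- sum(at)
    n1 <- sum(at & in_a)
    d <- sum(times == s & events == 1)
    d1 <- sum(times == s & events == 1 & in_a)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(list(chisq = 0, p = 1))
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Cox beta for a binary covariate by direct maximization of the written-out
# Breslow partial likelihood.
oracle_cox_beta <- function(times, events, z) {
  nll <- function(b) {
    s <- 0
    for (i in which(events == 1)) {
      risk <- which(times >= times[i])
      s <- s - (b * z[i] - log(sum(exp(b * z[risk]))))
    }
    s
  }
  optimize(nll, c(-10, 10), tol = 1e-12)$minimum
}

# Exhaustive best-cutoff search: admissible cutoffs enumerated from the
# definition, each evaluated with oracle_logrank, minimum p wins, ties to
# the smaller cutoff.
oracle_best_cutoff <- function(expression, times, events,
                               q_lo = 0.1, q_hi = 0.9, min_group = NULL) {
  ok <- !is.na(expression)
  expression <- expression[ok]; times <- times[ok]; events <- events[ok]
  n <- length(expression)
  if (is.null(min_group)) min_group <- max(5L, ceiling(0.1 * n))
  qs <- quantile(expression, c(q_lo, q_hi), names = FALSE, type = 7)
  cand <- sort(unique(expression))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  rows <- lapply(cand, function(cc) {
    high <- expression > cc
    if (sum(high) < min_group || sum(!high) < min_group) return(NULL)
    lr <- oracle_logrank(times, events, high)
    data.frame(cutoff = cc, n_high = sum(high), chisq = lr$chisq, p = lr$p)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(NULL)
  rows[which.min(rows$p), ]
}

# Borda-style consensus: unweighted mean of the component ranks.
oracle_mean_rank <- function(rank_tbl) {
  agg <- aggregate(rank ~ symbol, data = as.data.frame(rank_tbl), FUN = mean)
  agg[order(agg$rank, agg$symbol), ]
}

# Small fixture: quantification dataset built in code.
make_toy_dataset <- function(abund = NULL, id = "toy") {
  abund <- abund %||% tibble::tibble(
    accession = c("P1", "P2", "P3"),
    symbol = c("CD44", "PLXNB2", "ALB"),
    length_aa = c(742L, 1838L, 609L),
    t1 = c(10, 3, 50), t2 = c(12, 5, 60),
    n1 = c(2, 1, 55), n2 = c(3, NA, 45)
  )
  quant_dataset(
    abund,
    sample_info = tibble::tibble(
      sample_id = c("t1", "t2", "n1", "n2"),
      condition = c("tumor", "tumor", "normal", "normal")
    ),
    dataset_id = id
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Compare tabular content only: drop class and auxiliary attributes.
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  x
}
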