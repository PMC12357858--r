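# Clinical-association machinery: Kaplan-Meier curves, the Cox-Mantel
# (log-rank) test, Cox hazard ratios for a binary high/low split, and the
# best-cutoff scan that dichotomizes expression at the most significant
# split.

#' Kaplan-Meier curve
#'
#' Product-limit survival estimates. Censored observations shrink the risk
#' set without contributing events, so the estimate steps down only at event
#' times.
#'
#' @param times Positive follow-up times.
#' @param events 0 (censored) / 1 (event) per patient.
#' @return Tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` at every distinct observed time, plus the
#'   implicit `S(0) = 1`.
#' @export
km_curve <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

check_surv_input <- function(times, events) {
  if (!length(times)) {
    abort("empty survival input", class = "oncorank_input_error")
  }
  if (anyNA(times) || any(times <= 0)) {
    abort("times must be > 0", class = "oncorank_input_error")
  }
  if (!all(events %in% c(0, 1))) {
    abort("events must be 0 or 1", class = "oncorank_input_error")
  }
  invisible(TRUE)
}

# Mantel-Haenszel machinery shared by logrank_test() and the cutoff scan.
# `high` is an n x C logical matrix: one column per candidate split, TRUE =
# member of the "high" group. Returns per column the observed and expected
# event counts in the high group, the hypergeometric variance, chi-square
# and p. Exact hypergeometric moments handle tied event times.
logrank_core <- function(high, times, events) {
  high <- as.matrix(high)
  n <- length(times)
  o <- order(times)
  tt <- times[o]
  ee <- events[o]
  hh <- high[o, , drop = FALSE]
  storage.mode(hh) <- "double"

  first <- which(!duplicated(tt))          # first index of each distinct time
  ut <- tt[first]
  grp <- rep.int(seq_along(first), diff(c(first, n + 1L)))
  d <- rowsum(ee, grp, reorder = FALSE)[, 1]          # events per distinct time
  n_risk <- n - first + 1

  ev <- which(d > 0)
  if (!length(ev)) {
    z <- rep(0, ncol(hh))
    return(tibble(observed = z, expected = z, variance = z,
                  chisq = z, p = rep(1, ncol(hh))))
  }

  # at-risk count in the high group at each distinct time: reverse cumsum
  rc <- apply(hh, 2, function(col) rev(cumsum(rev(col))))
  rc <- matrix(rc, nrow = n)
  n1 <- rc[first, , drop = FALSE]           # distinct-times x C
  d1 <- rowsum(hh * ee, grp, reorder = FALSE)

  dj <- d[ev]
  nj <- n_risk[ev]
  n1j <- n1[ev, , drop = FALSE]
  d1j <- d1[ev, , drop = FALSE]
  pj <- n1j / nj
  Ej <- dj * pj
  denom <- pmax(nj - 1, 1)
  Vj <- dj * pj * (1 - pj) * (nj - dj) / denom

  observed <- colSums(d1j)
  expected <- colSums(Ej)
  variance <- colSums(Vj)
  chisq <- ifelse(variance > 0, (observed - expected)^2 / variance, 0)
  p <- ifelse(variance > 0, pchisq(chisq, df = 1, lower.tail = FALSE), 1)
  tibble(observed = observed, expected = expected, variance = variance,
         chisq = chisq, p = p)
}

#' Cox-Mantel (log-rank) test for two groups
#'
#' Sums observed-minus-expected events in group A over the risk table at
#' each distinct event time, with exact hypergeometric variance for ties;
#' the statistic is chi-square with 1 df. With zero events overall the
#' curves carry no information and `chisq = 0`, `p = 1` is returned with a
#' message.
#'
#' @param times_a,events_a Follow-up times and 0/1 event indicators, group A.
#' @param times_b,events_b Same for group B.
#' @return One-row tibble: `chisq`, `p`, `observed_a`, `expected_a`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  check_surv_input(times_a, events_a)
  check_surv_input(times_b, events_b)
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  if (sum(events) == 0) {
    inform("zero events overall; log-rank is uninformative (p = 1)")
  }
  in_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  res <- logrank_core(matrix(in_a, ncol = 1), times, events)
  tibble(chisq = res$chisq, p = res$p,
         observed_a = res$observed, expected_a = res$expected)
}

#' Cox hazard ratio for a binary split
#'
#' Fits a Cox proportional-hazards model with the single binary covariate
#' "high group" (Breslow tie handling, convergence tolerance 1e-9 on the
#' coefficient) and returns `exp(beta)`, the high-versus-low hazard ratio.
#' A monotone partial likelihood (one group's events all precede the
#' other's, so beta diverges) is flagged non-estimable and the hazard ratio
#' returned as `NA`.
#'
#' @param group_high Logical or 0/1 per patient: member of the high group.
#' @param times,events Follow-up times and event indicators.
#' @return One-row tibble: `hazard_ratio`, `log_hr`, `se_log_hr`,
#'   `estimable`.
#' @export
cox_hazard_ratio <- function(group_high, times, events) {
  check_surv_input(times, events)
  g <- as.numeric(group_high)
  if (length(unique(g)) < 2) {
    abort("both groups must be non-empty", class = "oncorank_input_error")
  }
  infinite <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(times, events) ~ g,
      ties = "breslow",
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)
    ),
    warning = function(w) {
      if (grepl("infinite", conditionMessage(w))) infinite <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(fit$coefficients[[1]])
  se <- sqrt(unname(fit$var[1, 1]))
  if (infinite || !is.finite(beta) || abs(beta) > 15) {
    return(tibble(hazard_ratio = NA_real_, log_hr = NA_real_,
                  se_log_hr = NA_real_, estimable = FALSE))
  }
  tibble(hazard_ratio = exp(beta), log_hr = beta, se_log_hr = se,
         estimable = TRUE)
}

default_min_group <- function(n) max(5L, ceiling(0.1 * n))

#' Best-cutoff survival association for one protein
#'
#' Scans every admissible dichotomization of an expression vector and
#' returns the split with the smallest log-rank p-value, together with the
#' Cox hazard ratio of the high group at that split. Candidate cutoffs are
#' the distinct observed expression values lying within the `[q_lo, q_hi]`
#' expression quantiles whose induced split ("high" is strictly greater
#' than the cutoff) leaves both groups with at least `min_group` patients.
#' Ties on the p-value break toward the smaller cutoff.
#'
#' The scan maximizes significance over many candidate splits, so the
#' returned p-value is not calibrated as a single pre-specified test; it is
#' a screening statistic, mirroring the "best cutoff" practice of online
#' Kaplan-Meier tools, and no multiplicity correction is applied.
#'
#' @param expression Per-patient expression (`NA` allowed; such patients are
#'   dropped for this protein).
#' @param times,events Follow-up times and 0/1 event indicators, aligned
#'   with `expression`.
#' @param q_lo,q_hi Quantile bounds of the cutoff search window.
#' @param min_group Minimum patients per group; default
#'   `max(5, ceiling(0.1 * n))`.
#' @return One-row tibble of class `cutoff_scan`: `cutoff`, `chisq`,
#'   `p_logrank`, `hazard_ratio`, `log_hr`, `n_high`, `n_low`,
#'   `direction_consistent` (`TRUE` iff the hazard ratio exceeds 1, i.e.
#'   high expression is adverse). The full per-cutoff scan table is attached
#'   as attribute `"scan"` and available via `tidy()`.
#' @export
best_cutoff_scan <- function(expression, times, events,
                             q_lo = 0.1, q_hi = 0.9, min_group = NULL) {
  ok <- !is.na(expression)
  expression <- expression[ok]
  times <- times[ok]
  events <- events[ok]
  check_surv_input(times, events)
  n <- length(expression)
  min_group <- min_group %||% default_min_group(n)
  values <- sort(unique(expression))
  if (length(values) < 2) {
    abort("no valid cutoff: constant expression",
          class = "oncorank_no_valid_cutoff")
  }
  qs <- quantile(expression, c(q_lo, q_hi), names = FALSE, type = 7)
  cand <- values[values >= qs[1] & values <= qs[2]]
  if (length(cand)) {
    n_high <- vapply(cand, function(cc) sum(expression > cc), 0L)
    keep <- n_high >= min_group & (n - n_high) >= min_group
    cand <- cand[keep]
    n_high <- n_high[keep]
  }
  if (!length(cand)) {
    abort("no valid cutoff: every split violates the group-size bounds",
          class = "oncorank_no_valid_cutoff")
  }

  high <- outer(expression, cand, `>`)
  res <- logrank_core(high, times, events)
  scan <- tibble(cutoff = cand, n_high = n_high, n_low = n - n_high,
                 chisq = res$chisq, p = res$p)
  best <- which.min(scan$p)      # first minimum = smallest cutoff on ties
  cut_best <- scan$cutoff[[best]]
  cox <- cox_hazard_ratio(expression > cut_best, times, events)
  out <- tibble(
    cutoff = cut_best,
    chisq = scan$chisq[[best]],
    p_logrank = scan$p[[best]],
    hazard_ratio = cox$hazard_ratio,
    log_hr = cox$log_hr,
    n_high = scan$n_high[[best]],
    n_low = scan$n_low[[best]],
    direction_consistent = isTRUE(cox$hazard_ratio > 1)
  )
  structure(out, scan = scan, class = c("cutoff_scan", class(out)))
}

#' Survival-association components of a cohort
#'
#' Runs [best_cutoff_scan()] for every protein and turns the results into
#' the two clinical-association ranking components: the best-split log-rank
#' p-value (lower is better) and the Cox hazard ratio (higher is better).
#'
#' Oncogenic-direction handling: a protein whose best-split hazard ratio is
#' at most 1 (or non-estimable) cannot show the adverse high-expression
#' association being ranked; it is retained in the result table but is
#' assigned the worst possible component values (`p = 1`, `hazard ratio =
#' 0`) so it falls to the bottom of the ranking instead of disappearing.
#' Proteins with all-missing expression or no valid cutoff are excluded and
#' flagged in the `status` column.
#'
#' @param cohort A [survival_cohort()].
#' @param proteins Symbols to score; default every expression column.
#' @param q_lo,q_hi,min_group Passed to [best_cutoff_scan()].
#' @return List with `results` (one row per protein: scan outcome plus
#'   `status`) and `components` (two [component_score()] tables bound by
#'   row).
#' @export
cohort_association <- function(cohort, proteins = NULL,
                               q_lo = 0.1, q_hi = 0.9, min_group = NULL) {
  proteins <- proteins %||% cohort_proteins(cohort)
  missing_p <- setdiff(proteins, cohort_proteins(cohort))
  if (length(missing_p)) {
    abort(paste0("protein(s) not in cohort: ",
                 paste(head(missing_p, 5), collapse = ", ")),
          class = "oncorank_input_error")
  }
  empty_row <- tibble(
    cutoff = NA_real_, chisq = NA_real_, p_logrank = NA_real_,
    hazard_ratio = NA_real_, log_hr = NA_real_,
    n_high = NA_integer_, n_low = NA_integer_,
    direction_consistent = FALSE
  )
  results <- purrr::map_dfr(proteins, function(sym) {
    expr <- cohort[[sym]]
    if (all(is.na(expr))) {
      return(dplyr::bind_cols(tibble(symbol = sym), empty_row,
                              tibble(status = "all_missing")))
    }
    scan <- tryCatch(
      best_cutoff_scan(expr, cohort$time, cohort$event,
                       q_lo = q_lo, q_hi = q_hi, min_group = min_group),
      oncorank_no_valid_cutoff = function(e) NULL
    )
    if (is.null(scan)) {
      return(dplyr::bind_cols(tibble(symbol = sym), empty_row,
                              tibble(status = "no_valid_cutoff")))
    }
    status <- if (is.na(scan$hazard_ratio)) {
      "hr_nonestimable"
    } else if (!scan$direction_consistent) {
      "hr_not_adverse"
    } else {
      "ok"
    }
    dplyr::bind_cols(tibble(symbol = sym), as_tibble(scan),
                     tibble(status = status))
  })
  excluded <- sum(results$status %in% c("all_missing", "no_valid_cutoff"))
  if (excluded) {
    inform(paste0("cohort '", attr(cohort, "cohort_id"), "': ", excluded,
                  " protein(s) not estimable, excluded from ranking"))
  }
  scored <- dplyr::filter(results,
                          !.data$status %in% c("all_missing",
                                               "no_valid_cutoff"))
  # rank-penalize non-adverse / non-estimable proteins to the bottom
  p_vals <- ifelse(scored$status == "ok", scored$p_logrank, 1)
  hr_vals <- ifelse(scored$status == "ok", scored$hazard_ratio, 0)
  cid <- attr(cohort, "cohort_id")
  components <- dplyr::bind_rows(
    component_score(paste0("p_logrank_", cid), cid, "p_logrank",
                    setNames(p_vals, scored$symbol)),
    component_score(paste0("hazard_ratio_", cid), cid, "hazard_ratio",
                    setNames(hr_vals, scored$symbol))
  )
  list(results = results, components = components)
}
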