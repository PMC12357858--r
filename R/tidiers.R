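# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a best-cutoff scan
#'
#' Returns the full per-cutoff scan table (one row per admissible cutoff,
#' with group sizes, chi-square and p), not just the selected optimum.
#'
#' @param x A `cutoff_scan` from [best_cutoff_scan()].
#' @param ... Unused.
#' @return Tibble: `cutoff`, `n_high`, `n_low`, `chisq`, `p`.
#' @method tidy cutoff_scan
#' @export
tidy.cutoff_scan <- function(x, ...) {
  attr(x, "scan")
}

#' One-row summary of a best-cutoff scan
#'
#' @param x A `cutoff_scan`.
#' @param ... Unused.
#' @return One-row tibble with the selected cutoff, log-rank statistic,
#'   hazard ratio, group sizes and the number of cutoffs scanned.
#' @method glance cutoff_scan
#' @export
glance.cutoff_scan <- function(x, ...) {
  out <- as_tibble(x)
  out$n_cutoffs_scanned <- nrow(attr(x, "scan"))
  out
}

#' Tidy a candidate report
#'
#' Long format: one row per protein and component with its rank, suitable
#' for faceting or further aggregation.
#'
#' @param x A `candidate_report`.
#' @param ... Unused.
#' @return Tibble: `final_rank`, `symbol`, `rscore`, `component_id`,
#'   `rank`.
#' @method tidy candidate_report
#' @export
tidy.candidate_report <- function(x, ...) {
  rank_cols <- grep("^rank_", names(x), value = TRUE)
  if (!length(rank_cols)) {
    return(dplyr::select(as_tibble(x), "final_rank", "symbol", "rscore"))
  }
  tidyr::pivot_longer(
    dplyr::select(as_tibble(x), "final_rank", "symbol", "rscore",
                  dplyr::all_of(rank_cols)),
    cols = dplyr::all_of(rank_cols),
    names_to = "component_id", names_prefix = "rank_",
    values_to = "rank"
  )
}

#' One-row summary of a candidate report
#'
#' @param x A `candidate_report`.
#' @param ... Unused.
#' @return One-row tibble: number of candidates, number of components, best
#'   protein and its Rscore.
#' @method glance candidate_report
#' @export
glance.candidate_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_components = sum(grepl("^rank_", names(x))),
    top_symbol = if (nrow(x)) x$symbol[[1]] else NA_character_,
    top_rscore = if (nrow(x)) x$rscore[[1]] else NA_real_
  )
}
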