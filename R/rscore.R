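# Weighted rank aggregation: direction-aware ranking of component scores,
# candidate intersection across datasets, and the integrated Rscore
# (sum of weighted ranks divided by the number of components; smaller is
# better).

#' Rank a component score with its direction
#'
#' Converts metric values into ranks 1..x where rank 1 is the best value in
#' the metric's declared direction: descending for higher-is-better metrics
#' (abundance, fold change, absolute change, hazard ratio), ascending for
#' lower-is-better ones (p-values). Ties receive the average of the covered
#' positions, so every rank vector sums to `x (x + 1) / 2`. Proteins with
#' missing values are absent from the vector.
#'
#' @param score A [component_score()] for a single component.
#' @return Tibble of class `rank_vector`: `component_id`, `symbol`, `rank`,
#'   `x` (number of ranked proteins).
#' @examples
#' sc <- component_score("ab", "d1", "abundance", c(A = 5, B = 2, C = 9))
#' rank_with_direction(sc)
#' @export
rank_with_direction <- function(score) {
  if (!nrow(score)) {
    abort("all values missing; nothing to rank",
          class = "oncorank_input_error")
  }
  if (length(unique(score$component_id)) != 1L) {
    abort("rank_with_direction expects a single component",
          class = "oncorank_input_error")
  }
  keyed <- if (score$direction[[1]] == "higher_is_better") {
    -score$value
  } else {
    score$value
  }
  out <- tibble(
    component_id = score$component_id,
    symbol = score$symbol,
    rank = rank(keyed, ties.method = "average"),
    x = nrow(score)
  )
  class(out) <- c("rank_vector", class(out))
  out
}

#' Intersect candidate protein sets
#'
#' The proteins detected in every dataset, as in a Venn-diagram overlap of
#' per-dataset detection lists. Output is sorted for determinism; an empty
#' intersection is legal and yields an empty candidate list, not an error.
#'
#' @param protein_sets List of character vectors of symbols.
#' @return Sorted character vector.
#' @export
intersect_candidates <- function(protein_sets) {
  if (!length(protein_sets)) {
    abort("need at least one protein set", class = "oncorank_input_error")
  }
  sort(purrr::reduce(lapply(protein_sets, as.character), intersect))
}

#' Rscore configuration
#'
#' Component weights and aggregation policy for [compute_rscore()].
#'
#' @param components Tibble (or data frame) with columns `component_id` and
#'   `weight` (>= 0); `NULL` means "all components seen, weight 1".
#'   Components with weight 0 are dropped and do not count toward `n`.
#' @param missing_policy `"intersection"` (default: only proteins present in
#'   every weighted component are scored, `n` = number of weighted
#'   components) or `"adjusted_n"` (every protein seen anywhere is scored,
#'   `n` = its per-protein count of available components).
#' @param rank_scale `"absolute"` (default: raw ranks 1..x) or
#'   `"percentile"` (each rank divided by its component's x before
#'   weighting, making components from datasets of different sizes
#'   commensurable).
#' @param collapse_specificity If `TRUE`, the three tumor-specificity
#'   components of a dataset (p-value, ratio, absolute change) are averaged
#'   into one rank before aggregation.
#' @param seed Integer recorded in report provenance.
#' @return List of class `rscore_config`.
#' @export
rscore_config <- function(components = NULL,
                          missing_policy = c("intersection", "adjusted_n"),
                          rank_scale = c("absolute", "percentile"),
                          collapse_specificity = FALSE,
                          seed = NA_integer_) {
  missing_policy <- match.arg(missing_policy)
  rank_scale <- match.arg(rank_scale)
  if (!is.null(components)) {
    components <- as_tibble(components)
    stopifnot(all(c("component_id", "weight") %in% names(components)))
    if (any(components$weight < 0)) {
      abort("weights must be >= 0", class = "oncorank_input_error")
    }
    if (!any(components$weight > 0)) {
      abort("at least one component must have weight > 0",
            class = "oncorank_input_error")
    }
  }
  structure(
    list(components = components, missing_policy = missing_policy,
         rank_scale = rank_scale,
         collapse_specificity = collapse_specificity,
         seed = as.integer(seed)),
    class = "rscore_config"
  )
}

#' @export
print.rscore_config <- function(x, ...) {
  cat("<rscore_config> policy=", x$missing_policy,
      ", scale=", x$rank_scale, "\n", sep = "")
  if (is.null(x$components)) {
    cat("  components: all observed, weight 1\n")
  } else {
    cat("  components:",
        paste0(x$components$component_id, "=", x$components$weight,
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Integrated Rscore
#'
#' Aggregates component rank vectors into one score per protein:
#' `Rscore = sum_i rank_i * weight_i / n`, where `n` is the number of
#' integrated components (see `missing_policy`). Smaller Rscores are
#' better; the top candidates have the smallest weighted rank sums. With
#' `rank_scale = "percentile"` each rank is first divided by its
#' component's size x.
#'
#' If the weighted components have sizes differing by more than 2-fold and
#' `rank_scale = "absolute"`, a warning notes that raw ranks from datasets
#' of very different sizes are not commensurable.
#'
#' @param rank_vectors A tibble of rank vectors (rows from
#'   [rank_with_direction()], bound together), or a list of them.
#' @param config An [rscore_config()].
#' @return Tibble: `symbol`, `rscore`, `n_used`, sorted ascending by
#'   `rscore`.
#' @export
compute_rscore <- function(rank_vectors, config = rscore_config()) {
  ranks <- if (is.data.frame(rank_vectors)) {
    as_tibble(rank_vectors)
  } else {
    dplyr::bind_rows(rank_vectors)
  }
  if (!nrow(ranks)) {
    abort("no rank vectors supplied", class = "oncorank_input_error")
  }
  weights <- config$components %||%
    tibble(component_id = unique(ranks$component_id), weight = 1)
  weights <- dplyr::filter(weights, .data$weight > 0)
  ranks <- dplyr::inner_join(ranks, weights, by = "component_id")
  if (!nrow(ranks)) {
    abort("no proteins remain after applying the component weights",
          class = "oncorank_input_error")
  }
  sizes <- dplyr::distinct(ranks, .data$component_id, .data$x)
  if (config$rank_scale == "absolute" &&
      max(sizes$x) > 2 * min(sizes$x)) {
    warn(paste0("component sizes differ by more than 2x (",
                min(sizes$x), "-", max(sizes$x), "); absolute ranks are ",
                "not commensurable - consider rank_scale = \"percentile\""))
  }
  if (config$rank_scale == "percentile") {
    ranks$rank <- ranks$rank / ranks$x
  }
  n_components <- nrow(weights)
  scored <- ranks |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(
      weighted_sum = sum(.data$rank * .data$weight),
      n_used = dplyr::n(),
      .groups = "drop"
    )
  if (config$missing_policy == "intersection") {
    scored <- dplyr::filter(scored, .data$n_used == n_components)
    if (!nrow(scored)) {
      abort("no protein is present in every weighted component",
            class = "oncorank_input_error")
    }
    scored$rscore <- scored$weighted_sum / n_components
  } else {
    scored$rscore <- scored$weighted_sum / scored$n_used
  }
  dplyr::arrange(
    dplyr::select(scored, "symbol", "rscore", "n_used"),
    .data$rscore
  )
}

#' Final candidate ranking
#'
#' Orders proteins by ascending Rscore (smallest = best), breaks ties
#' deterministically by lexicographic accession (falling back to symbol
#' when no accession map is given), and assigns `final_rank` 1..K.
#'
#' @param rscores Tibble from [compute_rscore()].
#' @param accessions Optional named character vector symbol -> accession
#'   carried for provenance.
#' @param provenance Optional list recorded on the report (config echo,
#'   seed, dataset ids).
#' @return Tibble of class `candidate_report`: `final_rank`, `symbol`,
#'   `accession`, `rscore`, `n_used`.
#' @export
final_ranking <- function(rscores, accessions = NULL, provenance = list()) {
  if (!nrow(rscores)) {
    abort("empty Rscore table", class = "oncorank_input_error")
  }
  acc <- if (is.null(accessions)) {
    rscores$symbol
  } else {
    unname(accessions[rscores$symbol])
  }
  out <- rscores
  out$accession <- ifelse(is.na(acc), out$symbol, acc)
  out <- dplyr::arrange(out, .data$rscore, .data$accession)
  out$final_rank <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "final_rank", "symbol", "accession", "rscore",
                         "n_used")
  structure(out, provenance = provenance,
            class = c("candidate_report", class(tibble())))
}
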