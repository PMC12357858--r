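# End-to-end orchestration: load -> gene-set filter -> abundance components
# -> tumor-specificity components -> cross-dataset candidate intersection
# -> survival components -> Rscore -> final report.

#' Rank candidate driver proteins across datasets
#'
#' The in-memory pipeline core. Each quantification dataset is restricted
#' to the gene set and contributes one length-normalized abundance
#' component; datasets with at least two tumor and two normal samples also
#' contribute the three tumor-specificity components; the survival cohort
#' contributes the best-cutoff log-rank p and hazard-ratio components.
#' Candidates are the proteins detected in every dataset (Venn
#' intersection); components are ranked within the candidates and
#' aggregated into the Rscore. The survival scan runs after the
#' intersection, on candidates only, since under the default intersection
#' policy no other protein can be scored.
#'
#' @param datasets Named list of [quant_dataset()]s.
#' @param cohort A [survival_cohort()], or `NULL` to skip the
#'   clinical-association components.
#' @param set A [gene_set()] (or character vector), or `NULL` to rank all
#'   proteins.
#' @param config An [rscore_config()].
#' @param q_lo,q_hi,min_group Cutoff-scan settings, see
#'   [best_cutoff_scan()].
#' @param pseudocount Specificity pseudocount; default per dataset, see
#'   [default_pseudocount()].
#' @return A `candidate_report` tibble (possibly 0 rows when the
#'   intersection is empty) with per-component rank and metric columns and
#'   a provenance attribute. The survival scan table is attached as
#'   attribute `"association"`.
#' @export
rank_candidates <- function(datasets, cohort = NULL, set = NULL,
                            config = rscore_config(),
                            q_lo = 0.1, q_hi = 0.9, min_group = NULL,
                            pseudocount = NULL) {
  stopifnot(length(datasets) >= 1)
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, dataset_id, "")
  }
  if (!is.null(set)) {
    datasets <- purrr::map(datasets, filter_to_gene_set, set = set)
  }
  if (any(!vapply(datasets, nrow, 0L))) {
    return(empty_report(config, datasets,
                        reason = "a dataset has no gene-set proteins"))
  }

  counts <- purrr::map(datasets, summarize_counts)
  components <- purrr::imap(datasets, function(ds, nm) {
    normalize_abundance(counts[[nm]],
                        component_id = paste0("abundance_", nm),
                        dataset_id = nm)
  })
  spec_stats <- list()
  for (nm in names(datasets)) {
    info <- sample_conditions(datasets[[nm]])
    if (sum(info$condition == "tumor") >= 2 &&
        sum(info$condition == "normal") >= 2) {
      spec <- dataset_specificity(datasets[[nm]], pseudocount = pseudocount)
      spec_stats[[nm]] <- spec$stats
      components[[paste0("specificity_", nm)]] <- spec$components
    }
  }

  candidates <- intersect_candidates(purrr::map(counts, "symbol"))
  if (!length(candidates)) {
    inform("empty cross-dataset intersection: zero candidates")
    return(empty_report(config, datasets, reason = "empty intersection"))
  }

  association <- NULL
  if (!is.null(cohort)) {
    scorable <- intersect(candidates, cohort_proteins(cohort))
    if (length(scorable)) {
      assoc <- cohort_association(cohort, proteins = scorable,
                                  q_lo = q_lo, q_hi = q_hi,
                                  min_group = min_group)
      association <- assoc$results
      components[["survival"]] <- assoc$components
    } else {
      inform("no candidate has expression in the cohort; survival components skipped")
    }
  }

  scores <- dplyr::bind_rows(components)
  scores <- dplyr::filter(scores, .data$symbol %in% candidates)
  ranks <- scores |>
    dplyr::group_split(.data$component_id) |>
    purrr::map(rank_with_direction) |>
    dplyr::bind_rows()
  if (isTRUE(config$collapse_specificity)) {
    ranks <- collapse_specificity_ranks(ranks)
  }

  rscores <- compute_rscore(ranks, config)
  accession_map <- accessions_of(datasets)
  provenance <- list(
    tool = paste0("oncorank ", packageVersion("oncorank")),
    datasets = names(datasets),
    cohort = if (is.null(cohort)) "none" else attr(cohort, "cohort_id"),
    gene_set = if (is.null(set)) "none" else attr(set, "name") %||% "custom",
    n_candidates = length(candidates),
    components = paste(sort(unique(ranks$component_id)), collapse = ","),
    missing_policy = config$missing_policy,
    rank_scale = config$rank_scale,
    seed = config$seed
  )
  report <- final_ranking(rscores, accessions = accession_map,
                          provenance = provenance)
  report <- attach_component_columns(report, ranks, scores)
  attr(report, "association") <- association
  attr(report, "specificity") <- spec_stats
  report
}

empty_report <- function(config, datasets, reason) {
  structure(
    tibble(final_rank = integer(), symbol = character(),
           accession = character(), rscore = numeric(),
           n_used = integer()),
    provenance = list(
      tool = paste0("oncorank ", packageVersion("oncorank")),
      datasets = names(datasets), reason = reason, seed = config$seed
    ),
    class = c("candidate_report", class(tibble()))
  )
}

accessions_of <- function(datasets) {
  tab <- dplyr::distinct(
    dplyr::bind_rows(purrr::map(datasets, ~ as_tibble(.x)[c("symbol", "accession")])),
    .data$symbol, .keep_all = TRUE
  )
  setNames(tab$accession, tab$symbol)
}

# Average the three specificity ranks of each dataset into one component,
# then re-rank so the averaged vector again satisfies the rank-sum
# invariant.
collapse_specificity_ranks <- function(ranks) {
  is_spec <- grepl("^(p_diff|ratio|abs_change)_", ranks$component_id)
  if (!any(is_spec)) return(ranks)
  spec <- ranks[is_spec, ]
  spec$dataset <- sub("^(p_diff|ratio|abs_change)_", "", spec$component_id)
  merged <- spec |>
    dplyr::group_by(.data$dataset, .data$symbol) |>
    dplyr::summarise(mean_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::group_split(.data$dataset) |>
    purrr::map(function(g) {
      tibble(component_id = paste0("specificity_", g$dataset[[1]]),
             symbol = g$symbol,
             rank = rank(g$mean_rank, ties.method = "average"),
             x = nrow(g))
    }) |>
    dplyr::bind_rows()
  dplyr::bind_rows(ranks[!is_spec, ], merged)
}

# Wide per-component rank/metric columns for the report TSV.
attach_component_columns <- function(report, ranks, scores) {
  rank_wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(ranks), "component_id", "symbol", "rank"),
    names_from = "component_id", values_from = "rank",
    names_prefix = "rank_"
  )
  metric_wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(scores), "component_id", "symbol", "value"),
    names_from = "component_id", values_from = "value",
    names_prefix = "metric_"
  )
  out <- dplyr::left_join(as_tibble(report), rank_wide, by = "symbol")
  out <- dplyr::left_join(out, metric_wide, by = "symbol")
  structure(out, provenance = attr(report, "provenance"),
            class = c("candidate_report", class(tibble())))
}

#' Pipeline configuration
#'
#' File-level configuration for [run_pipeline()], round-trippable through
#' YAML ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param datasets Named list; each element a list with `quant` and
#'   `samples` TSV paths.
#' @param gene_set Path to a GMT file, or `NULL`.
#' @param cohort Path to a survival TSV, or `NULL`.
#' @param out_dir Output directory for the report and association table.
#' @param weights Optional named numeric vector component_id -> weight.
#' @param missing_policy,rank_scale,collapse_specificity See
#'   [rscore_config()].
#' @param q_lo,q_hi,min_group See [best_cutoff_scan()].
#' @param seed Integer seed recorded in provenance (the ranking itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets, gene_set = NULL, cohort = NULL,
                            out_dir = ".", weights = NULL,
                            missing_policy = "intersection",
                            rank_scale = "absolute",
                            collapse_specificity = FALSE,
                            q_lo = 0.1, q_hi = 0.9, min_group = NULL,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   `write_pipeline_config()` returns the config invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "weights")])
  if (!is.null(raw$weights)) cfg$weights <- unlist(raw$weights)
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$weights)) out$weights <- as.list(out$weights)
  yaml::write_yaml(out, path)
  invisible(config)
}

#' Run the full ranking pipeline from files
#'
#' Loads the quantification datasets, gene set and survival cohort named in
#' the configuration, runs [rank_candidates()], and writes
#' `candidate_report.tsv` (with provenance header) plus
#' `survival_association.tsv` into the output directory. An empty
#' intersection produces an empty report and a message, not an error.
#'
#' @param config A [pipeline_config()] or path to its YAML file.
#' @return The `candidate_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  datasets <- purrr::imap(config$datasets, function(d, nm) {
    read_quant_table(d$quant, d$samples, dataset_id = nm)
  })
  set <- if (!is.null(config$gene_set)) read_gene_set(config$gene_set)
  cohort <- if (!is.null(config$cohort)) read_survival_table(config$cohort)
  weights_tbl <- if (!is.null(config$weights)) {
    tibble(component_id = names(config$weights),
           weight = unname(config$weights))
  }
  rcfg <- rscore_config(components = weights_tbl,
                        missing_policy = config$missing_policy,
                        rank_scale = config$rank_scale,
                        collapse_specificity = config$collapse_specificity,
                        seed = config$seed)
  report <- rank_candidates(datasets, cohort = cohort, set = set,
                            config = rcfg, q_lo = config$q_lo,
                            q_hi = config$q_hi,
                            min_group = config$min_group)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_candidate_report(report,
                         file.path(config$out_dir, "candidate_report.tsv"))
  assoc <- attr(report, "association")
  if (!is.null(assoc)) {
    readr::write_tsv(assoc,
                     file.path(config$out_dir, "survival_association.tsv"),
                     na = "NA")
  }
  invisible(report)
}
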