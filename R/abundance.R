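#' Per-protein total spectral counts
#'
#' Sums the present abundance values of each protein over the samples whose
#' condition is included. Proteins missing (`NA`) in every included sample
#' were never detected in those samples and are excluded (a message reports
#' how many), so they do not enter the abundance component.
#'
#' @param dataset A [quant_dataset()].
#' @param conditions Conditions to include; default all conditions present.
#' @return Tibble with columns `symbol`, `length_aa`, `count`.
#' @export
summarize_counts <- function(dataset, conditions = NULL) {
  info <- sample_conditions(dataset)
  conditions <- conditions %||% unique(info$condition)
  keep_samples <- info$sample_id[info$condition %in% conditions]
  if (!length(keep_samples)) {
    abort("no samples with an included condition",
          class = "oncorank_input_error")
  }
  vals <- as.matrix(as_tibble(dataset)[keep_samples])
  detected <- rowSums(!is.na(vals)) > 0
  if (any(!detected)) {
    inform(paste0("dataset '", dataset_id(dataset), "': ", sum(!detected),
                  " protein(s) undetected in all included samples, excluded"))
  }
  tibble(
    symbol = dataset$symbol[detected],
    length_aa = dataset$length_aa[detected],
    count = rowSums(vals[detected, , drop = FALSE], na.rm = TRUE)
  )
}

#' Length-normalized relative abundance
#'
#' Divides each protein's total spectral count by the ratio of its length to
#' the median length of the proteins present in the dataset:
#' `count / (length_aa / median(length_aa))`. Long proteins contribute more
#' spectra per copy, so the division makes abundances comparable across
#' proteins; a protein of exactly median length keeps its raw count.
#'
#' @param counts Tibble with columns `symbol`, `length_aa`, `count`
#'   (as from [summarize_counts()]).
#' @param component_id Component identifier for the resulting score.
#' @param dataset_id Dataset identifier recorded on the score.
#' @return A [component_score()] with `metric_name = "abundance"`
#'   (higher is better).
#' @export
normalize_abundance <- function(counts, component_id = "abundance",
                                dataset_id = component_id) {
  if (!nrow(counts)) {
    abort("empty protein set", class = "oncorank_input_error")
  }
  if (any(counts$count < 0) || any(counts$length_aa < 1)) {
    abort("counts must be >= 0 and lengths >= 1",
          class = "oncorank_input_error")
  }
  med <- median(counts$length_aa)
  vals <- counts$count / (counts$length_aa / med)
  component_score(component_id, dataset_id, "abundance",
                  setNames(vals, counts$symbol))
}

#' Abundance component of one dataset
#'
#' Convenience wrapper: [summarize_counts()] then [normalize_abundance()].
#'
#' @inheritParams summarize_counts
#' @param component_id Component identifier; defaults to
#'   `"abundance_<dataset id>"`.
#' @return A [component_score()].
#' @export
abundance_component <- function(dataset, conditions = NULL,
                                component_id = NULL) {
  component_id <- component_id %||% paste0("abundance_", dataset_id(dataset))
  normalize_abundance(summarize_counts(dataset, conditions),
                      component_id = component_id,
                      dataset_id = dataset_id(dataset))
}
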