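# Tumor-vs-normal differential statistics feeding the significant-change
# ranking components (p-value, fold change, absolute change).

#' Differential statistics for one protein
#'
#' Compares tumor against normal abundances for a single protein:
#' `abs_change` is the difference of group means, `ratio` the
#' pseudocount-stabilized fold change `(mean_t + eps) / (mean_n + eps)`, and
#' `p_diff` a two-sided Welch unequal-variance t-test on `log2(value + eps)`
#' — the standard treatment for MS intensities, whose errors are roughly
#' log-normal. When both groups are the same constant the t statistic is 0
#' and `p_diff = 1`.
#'
#' @param tumor_values,normal_values Numeric per-sample abundances; `NA`s
#'   are dropped. The p-value needs at least 2 present values per group
#'   (otherwise `p_diff` is `NA`); ratio and absolute change need 1.
#' @param pseudocount Positive stabilizer `eps` for the ratio and the log
#'   transform.
#' @return One-row tibble: `p_diff`, `ratio`, `abs_change`, `n_tumor`,
#'   `n_normal`.
#' @examples
#' differential_stats(c(4, 5, 6), c(1, 2, 3), pseudocount = 0.5)
#' @export
differential_stats <- function(tumor_values, normal_values, pseudocount) {
  stopifnot(is.numeric(pseudocount), pseudocount > 0)
  tv <- tumor_values[!is.na(tumor_values)]
  nv <- normal_values[!is.na(normal_values)]
  if (!length(tv) || !length(nv)) {
    abort("a group is entirely missing", class = "oncorank_input_error")
  }
  abs_change <- mean(tv) - mean(nv)
  ratio <- (mean(tv) + pseudocount) / (mean(nv) + pseudocount)
  p_diff <- NA_real_
  if (length(tv) >= 2 && length(nv) >= 2) {
    lt <- log2(tv + pseudocount)
    ln <- log2(nv + pseudocount)
    if (var(lt) == 0 && var(ln) == 0) {
      # degenerate: Welch t is 0/0 when means agree, +-Inf otherwise
      p_diff <- if (mean(lt) == mean(ln)) 1 else .Machine$double.xmin
    } else {
      p_diff <- t.test(lt, ln, var.equal = FALSE)$p.value
    }
  }
  tibble(p_diff = p_diff, ratio = ratio, abs_change = abs_change,
         n_tumor = length(tv), n_normal = length(nv))
}

#' Default pseudocount for a dataset
#'
#' Half the smallest nonzero abundance observed, so zero handling is on the
#' scale of the data.
#'
#' @param dataset A [quant_dataset()].
#' @return A positive scalar.
#' @export
default_pseudocount <- function(dataset) {
  info <- sample_conditions(dataset)
  vals <- as.matrix(as_tibble(dataset)[info$sample_id])
  nz <- vals[!is.na(vals) & vals > 0]
  if (!length(nz)) return(0.5)
  min(nz) / 2
}

#' Tumor-specificity components of a dataset
#'
#' Computes per-protein differential statistics between the dataset's tumor
#' and normal samples and expresses them as three ranking components:
#' `p_diff` (lower is better), `ratio` and `abs_change` (higher is better).
#' Raw p-values are ranked; no multiple-testing adjustment enters the
#' ranking (BH q-values are reported in `stats` for information only).
#'
#' Proteins without at least 2 present values in each group get `p_diff =
#' NA` and are absent from the p component but retained, pseudocount-
#' stabilized, for ratio and absolute change. A protein detected in only
#' one group was never observed in the other, so that group's abundance is
#' taken as 0 (the pseudocount keeps the ratio finite); proteins missing in
#' every tumor and normal sample are excluded (and counted in a message).
#'
#' @param dataset A [quant_dataset()] with >= 2 tumor and >= 2 normal
#'   samples.
#' @param pseudocount Positive stabilizer; default [default_pseudocount()].
#' @return List with `stats` (per-protein tibble: `symbol`, `p_diff`,
#'   `q_diff`, `ratio`, `abs_change`, `n_tumor`, `n_normal`) and
#'   `components` (the three [component_score()] tables bound by row).
#' @export
dataset_specificity <- function(dataset, pseudocount = NULL) {
  info <- sample_conditions(dataset)
  t_samples <- info$sample_id[info$condition == "tumor"]
  n_samples <- info$sample_id[info$condition == "normal"]
  if (length(t_samples) < 2 || length(n_samples) < 2) {
    abort("dataset needs >= 2 tumor and >= 2 normal samples",
          class = "oncorank_input_error")
  }
  pseudocount <- pseudocount %||% default_pseudocount(dataset)
  tab <- as_tibble(dataset)
  tmat <- as.matrix(tab[t_samples])
  nmat <- as.matrix(tab[n_samples])
  ok <- rowSums(!is.na(tmat)) >= 1 | rowSums(!is.na(nmat)) >= 1
  if (any(!ok)) {
    inform(paste0("dataset '", dataset_id(dataset), "': ", sum(!ok),
                  " protein(s) missing in every tumor and normal sample, ",
                  "excluded from specificity"))
  }
  stats <- purrr::map_dfr(which(ok), function(i) {
    tv <- tmat[i, ]
    nv <- nmat[i, ]
    if (all(is.na(tv))) tv <- 0   # undetected in tumors: zero abundance
    if (all(is.na(nv))) nv <- 0
    differential_stats(tv, nv, pseudocount)
  })
  stats <- dplyr::bind_cols(tibble(symbol = tab$symbol[ok]), stats)
  stats$q_diff <- stats::p.adjust(stats$p_diff, method = "BH")
  did <- dataset_id(dataset)
  components <- dplyr::bind_rows(
    component_score(paste0("p_diff_", did), did, "p_diff",
                    setNames(stats$p_diff, stats$symbol)),
    component_score(paste0("ratio_", did), did, "ratio",
                    setNames(stats$ratio, stats$symbol)),
    component_score(paste0("abs_change_", did), did, "abs_change",
                    setNames(stats$abs_change, stats$symbol))
  )
  list(stats = dplyr::relocate(stats, "q_diff", .after = "p_diff"),
       components = components)
}
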