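#' Construct a quantification dataset
#'
#' A quantification dataset couples a proteins-by-samples abundance table
#' (spectral counts, PSM counts or intensities) with protein lengths and
#' per-sample condition labels. Missing cells (protein not quantified in a
#' sample) are `NA`; a zero is a genuine zero count.
#'
#' Duplicate gene symbols are collapsed to the row with the highest total
#' abundance (a warning reports how many rows were dropped), so every symbol
#' is ranked once.
#'
#' @param data A data frame with columns `accession`, `symbol`, `length_aa`
#'   followed by one numeric column per sample.
#' @param sample_info A data frame with columns `sample_id` and `condition`
#'   (`tumor`, `normal`, `cell_line` or `ctc`) covering every sample column.
#' @param dataset_id Identifier string for the dataset.
#' @return A tibble of class `quant_dataset`; the sample sheet and id travel
#'   as attributes `sample_info` and `dataset_id`.
#' @examples
#' qd <- quant_dataset(
#'   tibble::tibble(
#'     accession = c("P1", "P2"), symbol = c("CD44", "PLXNB2"),
#'     length_aa = c(742L, 1838L), s1 = c(10, 3), s2 = c(12, NA)
#'   ),
#'   sample_info = tibble::tibble(
#'     sample_id = c("s1", "s2"), condition = c("tumor", "normal")
#'   ),
#'   dataset_id = "toy"
#' )
#' sample_conditions(qd)
#' @export
quant_dataset <- function(data, sample_info, dataset_id) {
  data <- as_tibble(data)
  sample_info <- as_tibble(sample_info)
  required <- c("accession", "symbol", "length_aa")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "oncorank_input_error")
  }
  if (!all(c("sample_id", "condition") %in% names(sample_info))) {
    abort("sample sheet needs columns sample_id and condition",
          class = "oncorank_input_error")
  }
  sample_cols <- setdiff(names(data), required)
  if (length(sample_cols) < 1L) {
    abort("dataset needs at least one sample column",
          class = "oncorank_input_error")
  }
  absent <- setdiff(sample_cols, sample_info$sample_id)
  if (length(absent)) {
    abort(paste0("sample '", absent[[1]], "' absent from sheet"),
          class = "oncorank_input_error")
  }
  bad_cond <- setdiff(unique(sample_info$condition), QUANT_CONDITIONS)
  if (length(bad_cond)) {
    abort(paste0("unknown condition: ", paste(bad_cond, collapse = ", ")),
          class = "oncorank_input_error")
  }
  sample_info <- dplyr::filter(sample_info, .data$sample_id %in% sample_cols)

  if (anyNA(data$accession) || any(!nzchar(data$accession))) {
    abort("accession must be non-empty", class = "oncorank_input_error")
  }
  if (anyDuplicated(data$accession)) {
    abort("accession must be unique within a dataset",
          class = "oncorank_input_error")
  }
  if (anyNA(data$length_aa) || any(data$length_aa != as.integer(data$length_aa)) ||
      any(data$length_aa < 1)) {
    abort("length_aa must be integer and >= 1", class = "oncorank_input_error")
  }
  data$length_aa <- as.integer(data$length_aa)
  abund <- as.matrix(data[sample_cols])
  if (!is.numeric(abund)) {
    abort("abundance columns must be numeric", class = "oncorank_input_error")
  }
  if (any(abund < 0, na.rm = TRUE)) {
    abort("negative abundance", class = "oncorank_input_error")
  }

  if (anyDuplicated(data$symbol)) {
    totals <- rowSums(abund, na.rm = TRUE)
    keep <- order(totals, decreasing = TRUE)
    keep <- keep[!duplicated(data$symbol[keep])]
    n_drop <- nrow(data) - length(keep)
    warn(paste0("collapsed ", n_drop, " duplicate-symbol row(s), keeping the ",
                "highest-abundance entry per symbol"))
    data <- data[sort(keep), , drop = FALSE]
  }

  structure(
    data,
    sample_info = sample_info,
    dataset_id = dataset_id,
    class = c("quant_dataset", class(tibble()))
  )
}

#' @export
print.quant_dataset <- function(x, ...) {
  cat("<quant_dataset> ", attr(x, "dataset_id"), ": ", nrow(x), " proteins x ",
      nrow(attr(x, "sample_info")), " samples\n", sep = "")
  NextMethod()
}

#' Sample conditions of a quantification dataset
#'
#' @param dataset A [quant_dataset()].
#' @return Tibble with columns `sample_id`, `condition`.
#' @export
sample_conditions <- function(dataset) {
  attr(dataset, "sample_info")
}

#' Dataset identifier
#' @param dataset A [quant_dataset()].
#' @return The dataset id string.
#' @export
dataset_id <- function(dataset) {
  attr(dataset, "dataset_id")
}

#' Construct a gene set
#'
#' A named collection of unique gene symbols, as read from one line of a GMT
#' file. Stands in for curated candidate universes such as the cell-adhesion
#' molecule sets of MSigDB.
#'
#' @param name Set name.
#' @param members Character vector of gene symbols; duplicates are removed
#'   with a message.
#' @return An object of class `gene_set` (a character vector of members with
#'   a `name` attribute).
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  members <- members[nzchar(members)]
  if (!length(members)) {
    abort("gene set must have at least one member",
          class = "oncorank_input_error")
  }
  n_dup <- sum(duplicated(members))
  if (n_dup > 0) {
    inform(paste0("gene set '", name, "': removed ", n_dup,
                  " duplicate symbol(s)"))
    members <- unique(members)
  }
  structure(members, name = name, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", attr(x, "name"), ": ", length(x), " symbols\n", sep = "")
  print(unclass(head(x, 10)))
  invisible(x)
}

#' Restrict a dataset to a gene set
#'
#' Keeps exactly the proteins whose symbol is in the gene set, preserving the
#' original row order. An empty result is legal (a message is emitted), so a
#' disjoint gene set does not abort a pipeline.
#'
#' @param dataset A [quant_dataset()].
#' @param set A [gene_set()] or character vector of symbols.
#' @return A `quant_dataset` with the subset of rows.
#' @export
filter_to_gene_set <- function(dataset, set) {
  keep <- dataset$symbol %in% as.character(set)
  if (!any(keep)) {
    inform(paste0("dataset '", dataset_id(dataset),
                  "': no proteins in gene set"))
  }
  out <- dataset[keep, , drop = FALSE]
  attributes(out) <- utils::modifyList(
    attributes(out),
    list(sample_info = attr(dataset, "sample_info"),
         dataset_id = attr(dataset, "dataset_id"),
         class = class(dataset))
  )
  out
}

#' Construct a survival cohort
#'
#' Patient-level time-to-event records with per-protein expression, used for
#' the clinical-association ranking component (overall survival or distant
#' metastasis-free survival endpoints).
#'
#' @param data Data frame with columns `patient_id`, `time` (> 0), `event`
#'   (0 censored / 1 event), then one numeric expression column per protein.
#' @param cohort_id Cohort identifier.
#' @param endpoint `"OS"` or `"DMFS"`.
#' @return Tibble of class `survival_cohort` with attributes `cohort_id`
#'   and `endpoint`.
#' @export
survival_cohort <- function(data, cohort_id, endpoint = c("OS", "DMFS")) {
  endpoint <- match.arg(endpoint)
  data <- as_tibble(data)
  required <- c("patient_id", "time", "event")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "oncorank_input_error")
  }
  if (anyDuplicated(data$patient_id)) {
    abort("duplicate patient_id", class = "oncorank_input_error")
  }
  if (anyNA(data$time) || any(data$time <= 0)) {
    abort("time must be > 0", class = "oncorank_input_error")
  }
  if (!all(data$event %in% c(0, 1))) {
    abort("event must be 0 or 1", class = "oncorank_input_error")
  }
  expr_cols <- setdiff(names(data), required)
  if (length(expr_cols)) {
    vals <- as.matrix(data[expr_cols])
    if (!is.numeric(vals)) {
      abort("expression columns must be numeric",
            class = "oncorank_input_error")
    }
    if (any(vals < 0, na.rm = TRUE)) {
      abort("expression must be non-negative", class = "oncorank_input_error")
    }
  }
  structure(
    data,
    cohort_id = cohort_id,
    endpoint = endpoint,
    class = c("survival_cohort", class(tibble()))
  )
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat("<survival_cohort> ", attr(x, "cohort_id"), " (", attr(x, "endpoint"),
      "): ", nrow(x), " patients, ", sum(x$event), " events\n", sep = "")
  NextMethod()
}

#' Expression column names of a survival cohort
#' @param cohort A [survival_cohort()].
#' @return Character vector of protein symbols with expression columns.
#' @export
cohort_proteins <- function(cohort) {
  setdiff(names(cohort), c("patient_id", "time", "event"))
}
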