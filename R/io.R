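# Readers/writers for the plain-text formats the pipeline touches.
# Dialect everywhere: tab-separated, UTF-8, "." decimal separator, literal
# "NA" for missing cells.

read_tsv_strict <- function(path, ...) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE,
                  ...)
}

#' Read a protein quantification matrix
#'
#' The main file is a tab-separated matrix with columns `accession`,
#' `symbol`, `length_aa`, then one numeric column per sample; the sample
#' sheet maps `sample_id` to `condition` (tumor / normal / cell_line / ctc).
#' Missing cells are the literal `NA` and are preserved as missing.
#'
#' @param path Path to the quantification TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @param dataset_id Dataset identifier; defaults to the file name without
#'   extension.
#' @return A validated [quant_dataset()].
#' @export
read_quant_table <- function(path, sample_sheet_path,
                             dataset_id = NULL) {
  dataset_id <- dataset_id %||%
    sub("\\.[^.]*$", "", basename(path))
  data <- read_tsv_strict(path)
  sheet <- read_tsv_strict(
    sample_sheet_path,
    col_types = readr::cols(.default = readr::col_character())
  )
  quant_dataset(data, sample_info = sheet, dataset_id = dataset_id)
}

#' Write a quantification dataset and its sample sheet
#'
#' @param dataset A [quant_dataset()].
#' @param path Output TSV path for the matrix.
#' @param sample_sheet_path Output TSV path for the sample sheet.
#' @return The dataset, invisibly.
#' @export
write_quant_table <- function(dataset, path, sample_sheet_path) {
  readr::write_tsv(as_tibble(dataset), path, na = "NA")
  readr::write_tsv(sample_conditions(dataset), sample_sheet_path, na = "NA")
  invisible(dataset)
}

#' Read a gene set from a GMT file
#'
#' GMT lines are `name<TAB>description<TAB>member1<TAB>member2...`. One set
#' is returned; by default the first line, otherwise the line whose name
#' matches `set`.
#'
#' @param path Path to the GMT file.
#' @param set Optional set name to select.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, set = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    abort("empty GMT file", class = "oncorank_input_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names(fields) <- vapply(fields, function(f) f[[1]] %||% "", "")
  pick <- if (is.null(set)) 1L else match(set, names(fields))
  if (is.na(pick)) {
    abort(paste0("gene set '", set, "' not found in ", path),
          class = "oncorank_input_error")
  }
  f <- fields[[pick]]
  if (length(f) < 3L) {
    abort("GMT line needs at least 3 tab-separated fields (name, description, members)",
          class = "oncorank_input_error")
  }
  gene_set(name = f[[1]], members = f[-(1:2)])
}

#' Write a gene set as a one-line GMT file
#'
#' @param set A [gene_set()].
#' @param path Output path.
#' @param description Free-text description field.
#' @return The set, invisibly.
#' @export
write_gene_set <- function(set, path, description = "") {
  line <- paste(c(attr(set, "name"), description, as.character(set)),
                collapse = "\t")
  writeLines(line, path, useBytes = TRUE)
  invisible(set)
}

#' Read a survival cohort table
#'
#' Tab-separated columns `patient_id`, `time`, `event`, then one expression
#' column per protein.
#'
#' @param path Path to the survival TSV.
#' @param cohort_id Cohort identifier; defaults to the file name.
#' @param endpoint `"OS"` or `"DMFS"`.
#' @return A validated [survival_cohort()].
#' @export
read_survival_table <- function(path, cohort_id = NULL, endpoint = "OS") {
  cohort_id <- cohort_id %||% sub("\\.[^.]*$", "", basename(path))
  data <- read_tsv_strict(path)
  survival_cohort(data, cohort_id = cohort_id, endpoint = endpoint)
}

#' Write a survival cohort table
#'
#' @param cohort A [survival_cohort()].
#' @param path Output TSV path.
#' @return The cohort, invisibly.
#' @export
write_survival_table <- function(cohort, path) {
  readr::write_tsv(as_tibble(cohort), path, na = "NA")
  invisible(cohort)
}

#' Write a candidate report
#'
#' Writes the final ranking table as TSV with a `#`-prefixed provenance
#' header (config echo, seed, dataset ids, package version). Reports must be
#' fully computed: a missing or non-finite Rscore is an error.
#'
#' @param report A `candidate_report` (see [final_ranking()]).
#' @param path Output path.
#' @return The report, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  if (anyNA(report$rscore) || any(!is.finite(report$rscore))) {
    abort("report contains missing Rscore values; reports must be fully computed",
          class = "oncorank_input_error")
  }
  prov <- attr(report, "provenance") %||% list()
  header <- vapply(
    names(prov),
    function(k) paste0("# ", k, ": ",
                       paste(as.character(prov[[k]]), collapse = ",")),
    ""
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  body <- readr::format_tsv(as_tibble(report), na = "NA")
  writeLines(sub("\n$", "", body), con)
  invisible(report)
}

#' Read back a candidate report
#'
#' Provenance lines (`#`-prefixed) are parsed into the `provenance`
#' attribute; rows come back equal to what [write_candidate_report()] wrote.
#'
#' @param path Report path.
#' @return A `candidate_report` tibble.
#' @export
read_candidate_report <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_prov <- startsWith(lines, "#")
  prov <- list()
  if (any(is_prov)) {
    kv <- sub("^# ", "", lines[is_prov])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: ", "", kv)
    prov <- as.list(setNames(vals, keys))
  }
  body <- paste(lines[!is_prov], collapse = "\n")
  out <- readr::read_tsv(I(body), na = "NA", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  structure(as_tibble(out), provenance = prov,
            class = c("candidate_report", class(tibble())))
}
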