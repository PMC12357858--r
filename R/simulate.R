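# Synthetic multi-dataset proteomic studies with planted driver proteins.
# The generator emulates the statistical structure the ranking consumes:
# spectral-count abundance with a protein-length effect, tumor-vs-normal
# differential expression, cross-dataset detection dropout, and a survival
# cohort where driver expression carries a hazard.

#' Parameters of a synthetic study
#'
#' Defaults describe a mid-sized label-free proteomic study: 500 proteins
#' with log-normal lengths centred on 400 aa, log-normal base abundances,
#' negative-binomial spectral counts whose mean scales with protein length
#' (longer proteins yield more spectra per copy) and with per-sample
#' sequencing depth, logistic detection dropout centred on the 20th
#' abundance percentile, and a 200-patient survival cohort.
#'
#' Planted drivers carry three signals, each individually switchable:
#' a high base abundance (re-drawn above `driver_abundance_quantile`;
#' `NA` disables the planting), a tumor fold change
#' (`tumor_fold_change = 1` disables), and an expression-dependent hazard
#' (`hr_true = 1` disables). [null_params()] switches all three off.
#'
#' @param n_proteins Total proteins simulated.
#' @param n_gene_set Size of the candidate gene set (subset of proteins).
#' @param n_drivers Number of planted drivers (subset of the gene set).
#' @param length_meanlog,length_sdlog,length_floor Log-normal protein-length
#'   model, floored (aa).
#' @param abundance_meanlog,abundance_sdlog Log-normal base abundance.
#' @param nb_dispersion Negative-binomial dispersion of counts
#'   (`size = 1/dispersion`).
#' @param depth_sdlog Log-normal spread of per-sample depth factors
#'   (meanlog 0).
#' @param tumor_fold_change Driver mean multiplier in tumor samples.
#' @param driver_abundance_quantile Drivers' base abundance is re-drawn
#'   uniformly between this quantile and 0.95 of the abundance
#'   distribution; `NA` leaves driver abundance unplanted.
#' @param dropout_midpoint_quantile Abundance quantile at which detection
#'   probability is 0.5.
#' @param dropout_slope Slope of the logistic detection model in log
#'   abundance.
#' @param n_patients Survival cohort size.
#' @param hr_true Hazard ratio applied when a driver's expression exceeds
#'   its cohort median.
#' @param baseline_hazard Exponential baseline hazard per time unit.
#' @param censor_horizon Uniform censoring horizon (time units).
#' @param expression_sdlog Log-normal spread of patient expression around a
#'   protein's base abundance.
#' @return List of class `synthetic_params`.
#' @export
synthetic_params <- function(n_proteins = 500L,
                             n_gene_set = 150L,
                             n_drivers = 3L,
                             length_meanlog = log(400),
                             length_sdlog = 0.5,
                             length_floor = 50L,
                             abundance_meanlog = log(10),
                             abundance_sdlog = 1,
                             nb_dispersion = 0.2,
                             depth_sdlog = 0.25,
                             tumor_fold_change = 4,
                             driver_abundance_quantile = 0.75,
                             dropout_midpoint_quantile = 0.2,
                             dropout_slope = 2,
                             n_patients = 200L,
                             hr_true = 2.5,
                             baseline_hazard = 0.02,
                             censor_horizon = 60,
                             expression_sdlog = 0.5) {
  p <- as.list(environment())
  if (p$n_drivers > p$n_gene_set || p$n_gene_set > p$n_proteins) {
    abort("need drivers <= gene set <= proteins",
          class = "oncorank_input_error")
  }
  stopifnot(p$nb_dispersion > 0, p$tumor_fold_change > 0, p$hr_true > 0,
            p$baseline_hazard > 0, p$censor_horizon > 0)
  structure(p, class = "synthetic_params")
}

#' Null-signal study parameters
#'
#' All three planted driver signals off: no abundance planting, tumor fold
#' change 1, hazard ratio 1. Drivers remain labelled in the truth table
#' but are statistically exchangeable with non-drivers, so recovery of
#' "drivers" can only happen at the chance rate.
#'
#' @param ... Overrides passed to [synthetic_params()].
#' @return A `synthetic_params` object.
#' @export
null_params <- function(...) {
  synthetic_params(tumor_fold_change = 1, hr_true = 1,
                   driver_abundance_quantile = NA_real_, ...)
}

# Layout of the generated datasets: one LCM-style tumor/normal tissue
# dataset, two cell-line datasets, one CTC dataset.
study_layout <- function() {
  list(
    tumor_tissue = c(rep("tumor", 3), rep("normal", 3)),
    cell_line_a  = rep("cell_line", 3),
    cell_line_b  = rep("cell_line", 3),
    ctc          = rep("ctc", 4)
  )
}

# One global seed fans out to independent per-block streams so adding a
# dataset does not perturb the others.
fan_out_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Generate a synthetic multi-dataset study
#'
#' Produces four quantification datasets (tumor/normal tissue, two cell
#' lines, CTCs), a survival cohort over the gene-set proteins, the gene
#' set, and a truth table of planted parameters. Drivers are exempt from
#' detection dropout (the ranking only scores proteins detected in every
#' dataset, so recoverability requires drivers to be scoreable); all other
#' proteins drop out independently per dataset with probability following a
#' logistic curve in log abundance.
#'
#' In the survival cohort each patient's hazard is the baseline multiplied
#' by `hr_true` for every driver whose expression in that patient exceeds
#' the driver's cohort median; non-driver expression has no hazard link.
#'
#' @param params A [synthetic_params()].
#' @param seed Integer seed; the same seed reproduces the study exactly.
#' @return List of class `synthetic_study`: `datasets` (named list of
#'   [quant_dataset()]), `cohort`, `gene_set`, `truth` (tibble `symbol`,
#'   `is_driver`, planted parameters), `params`, `seed`.
#' @export
generate_study <- function(params = synthetic_params(), seed = 1L) {
  layout <- study_layout()
  seeds <- fan_out_seeds(seed, 2L + length(layout))

  # --- global stream: proteins, gene set, drivers, base abundance ---------
  set.seed(seeds[[1]])
  n <- params$n_proteins
  symbols <- sprintf("PROT%04d", seq_len(n))
  accessions <- sprintf("SYN%05d", seq_len(n))
  lengths <- pmax(params$length_floor,
                  as.integer(round(rlnorm(n, params$length_meanlog,
                                          params$length_sdlog))))
  in_set <- sample(symbols, params$n_gene_set)
  drivers <- sample(in_set, params$n_drivers)
  abundance <- rlnorm(n, params$abundance_meanlog, params$abundance_sdlog)
  if (!is.na(params$driver_abundance_quantile)) {
    qd <- runif(params$n_drivers, params$driver_abundance_quantile, 0.95)
    abundance[match(drivers, symbols)] <-
      quantile(abundance, qd, names = FALSE)
  }
  detect_mid <- quantile(abundance, params$dropout_midpoint_quantile,
                         names = FALSE)
  p_detect <- plogis(params$dropout_slope * (log(abundance) -
                                               log(detect_mid)))
  is_driver <- symbols %in% drivers

  proteins <- tibble(accession = accessions, symbol = symbols,
                     length_aa = lengths)
  med_len <- median(lengths)

  # --- per-dataset streams ------------------------------------------------
  datasets <- purrr::imap(layout, function(conditions, ds_name) {
    set.seed(seeds[[2L + match(ds_name, names(layout))]])
    n_samples <- length(conditions)
    sample_ids <- paste0(ds_name, "_s", seq_len(n_samples))
    depth <- rlnorm(n_samples, 0, params$depth_sdlog)
    detected <- rbinom(n, 1, p_detect) == 1 | is_driver
    counts <- matrix(NA_real_, n, n_samples,
                     dimnames = list(NULL, sample_ids))
    for (s in seq_len(n_samples)) {
      mu <- abundance * (lengths / med_len) * depth[[s]]
      # base abundance is the normal-tissue baseline; cancer-derived
      # material (tumor voxels, cancer cell lines, CTCs) expresses the
      # planted drivers at the tumor fold change
      if (conditions[[s]] %in% c("tumor", "cell_line", "ctc")) {
        mu[is_driver] <- mu[is_driver] * params$tumor_fold_change
      }
      counts[, s] <- rnbinom(n, mu = mu, size = 1 / params$nb_dispersion)
    }
    counts[!detected, ] <- NA_real_
    qd <- quant_dataset(
      dplyr::bind_cols(proteins, as_tibble(counts)),
      sample_info = tibble(sample_id = sample_ids, condition = conditions),
      dataset_id = ds_name
    )
    # per-sample depth factors kept for verification of the count model
    attr(qd, "sim_depth") <- setNames(depth, sample_ids)
    qd
  })

  # --- cohort stream ------------------------------------------------------
  set.seed(seeds[[2]])
  cohort <- simulate_study_cohort(params, in_set, drivers,
                                  abundance[match(in_set, symbols)])

  truth <- tibble(
    symbol = symbols,
    accession = accessions,
    is_driver = is_driver,
    base_abundance = abundance,
    tumor_fold_change = ifelse(is_driver, params$tumor_fold_change, 1),
    hr_true = ifelse(is_driver, params$hr_true, 1)
  )

  structure(
    list(datasets = datasets,
         cohort = cohort,
         gene_set = gene_set("SYNTHETIC_CANDIDATES", sort(in_set)),
         truth = truth,
         params = params,
         seed = seed),
    class = "synthetic_study"
  )
}

# Patient expression is log-normal around each protein's base abundance;
# each driver above its cohort median multiplies the patient's hazard by
# hr_true (multiplicative across drivers, i.e. a linear predictor of
# indicator covariates).
simulate_study_cohort <- function(params, set_symbols, drivers,
                                  set_abundance) {
  np <- params$n_patients
  expr <- vapply(seq_along(set_symbols), function(j) {
    rlnorm(np, log(set_abundance[[j]]), params$expression_sdlog)
  }, numeric(np))
  colnames(expr) <- set_symbols
  log_rr <- rep(0, np)
  for (d in drivers) {
    high <- expr[, d] > median(expr[, d])
    log_rr <- log_rr + log(params$hr_true) * high
  }
  hazard <- params$baseline_hazard * exp(log_rr)
  event_time <- rexp(np, rate = hazard)
  censor_time <- runif(np, 0, params$censor_horizon)
  time <- pmin(event_time, censor_time)
  event <- as.numeric(event_time <= censor_time)
  survival_cohort(
    dplyr::bind_cols(
      tibble(patient_id = sprintf("PT%04d", seq_len(np)),
             time = time, event = event),
      as_tibble(expr)
    ),
    cohort_id = "synthetic_cohort", endpoint = "OS"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> seed ", x$seed, ": ",
      length(x$datasets), " datasets, ",
      nrow(x$cohort), " patients, ",
      sum(x$truth$is_driver), " planted drivers (",
      paste(x$truth$symbol[x$truth$is_driver], collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Simulate a single-protein survival cohort
#'
#' A minimal cohort for calibration and power studies: expression is
#' log-normal, patients above the `split_quantile` expression quantile have
#' their exponential hazard multiplied by `hr_true`, and censoring time is
#' uniform on `(0, censor_horizon)`.
#'
#' @param n Number of patients (>= 10).
#' @param hr_true True high-vs-low hazard ratio (> 0); 1 gives a null
#'   cohort.
#' @param split_quantile Expression quantile defining the high group.
#' @param baseline_hazard Exponential hazard of the low group per time
#'   unit.
#' @param censor_horizon Upper bound of the uniform censoring time (> 0);
#'   as it approaches 0 every record is censored and downstream tests flag
#'   zero events.
#' @param seed Integer seed.
#' @param protein Name of the expression column.
#' @return A [survival_cohort()] with one expression column.
#' @export
simulate_survival_cohort <- function(n = 200L, hr_true = 1,
                                     split_quantile = 0.5,
                                     baseline_hazard = 0.02,
                                     censor_horizon = 60,
                                     seed = 1L,
                                     protein = "SIM1") {
  if (n < 10) abort("n must be >= 10", class = "oncorank_input_error")
  if (hr_true <= 0 || baseline_hazard <= 0 || censor_horizon <= 0) {
    abort("hr_true, baseline_hazard and censor_horizon must be > 0",
          class = "oncorank_input_error")
  }
  set.seed(seed)
  expr <- rlnorm(n, log(10), 0.5)
  high <- expr > quantile(expr, split_quantile, names = FALSE)
  hazard <- baseline_hazard * ifelse(high, hr_true, 1)
  event_time <- rexp(n, rate = hazard)
  censor_time <- runif(n, 0, censor_horizon)
  cohort <- tibble(
    patient_id = sprintf("PT%04d", seq_len(n)),
    time = pmin(event_time, censor_time),
    event = as.numeric(event_time <= censor_time)
  )
  cohort[[protein]] <- expr
  survival_cohort(cohort, cohort_id = paste0("sim_hr", hr_true),
                  endpoint = "OS")
}

#' Write a synthetic study to a directory
#'
#' Writes each dataset's quantification TSV and sample sheet, the gene set
#' (GMT), the survival table and the truth table, in the same dialect the
#' readers accept, so a written study round-trips through
#' [read_quant_table()] and friends.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (ds_name in names(study$datasets)) {
    qp <- file.path(dir, paste0(ds_name, ".tsv"))
    sp <- file.path(dir, paste0(ds_name, "_samples.tsv"))
    write_quant_table(study$datasets[[ds_name]], qp, sp)
    paths[paste0(ds_name, "_quant")] <- qp
    paths[paste0(ds_name, "_samples")] <- sp
  }
  gp <- file.path(dir, "gene_set.gmt")
  write_gene_set(study$gene_set, gp, description = "synthetic candidates")
  paths["gene_set"] <- gp
  cp <- file.path(dir, "cohort.tsv")
  write_survival_table(study$cohort, cp)
  paths["cohort"] <- cp
  tp <- file.path(dir, "truth.tsv")
  readr::write_tsv(study$truth, tp, na = "NA")
  paths["truth"] <- tp
  invisible(paths)
}
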