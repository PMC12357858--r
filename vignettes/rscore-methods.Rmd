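---
title: "Integrated rank aggregation for driver-protein prioritization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated rank aggregation for driver-protein prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(oncorank)
```

## The problem

A recurring task in cancer proteomics is to pick a handful of candidate
driver proteins out of hundreds detected across heterogeneous
mass-spectrometry (MS) datasets — patient tumor tissue, cancer cell lines,
circulating tumor cells (CTCs) — where no single dataset or statistic is
trustworthy on its own. oncorank implements an integrated, weighted
rank-aggregation score (the *Rscore*) that combines three families of
evidence per protein:

1. **Relative abundance**, length-normalized, in each MS dataset;
2. **Tumor specificity**: differential statistics between tumor and
   normal-adjacent samples (p-value, fold change, absolute change);
3. **Clinical association**: best-cutoff log-rank p-value and Cox hazard
   ratio against a survival cohort (overall survival or distant
   metastasis-free survival).

Each statistic becomes a rank vector over the candidate proteins, and the
aggregate is

$$ R_{score}(p) \;=\; \frac{\sum_{i=1}^{n} r_i(p)\, c_i}{n}, $$

where $r_i(p)$ is protein $p$'s rank in component $i$ (rank 1 = best),
$c_i \ge 0$ the component's weight, and $n$ the number of integrated
components. **Smaller Rscores are better.** With all $c_i = 1$ this is a
Borda-style mean rank, which the test suite verifies against an
independent mean-rank oracle.

## Ranking components

### Length-normalized abundance

Spectral counting over-counts long proteins (more peptides per copy), so
a dataset's per-protein total count $C_p$ is divided by the protein's
length relative to the dataset median:

$$ A_p = \frac{C_p}{L_p / \mathrm{median}(L)} . $$

A protein of exactly median length keeps its raw count; scaling all
lengths by a common factor changes nothing; scaling counts scales the
output linearly. Counts are summed over all included samples of a dataset
(replicate-level modelling is out of scope), and a protein missing in
every sample of a dataset is treated as *undetected* there rather than as
zero. The median of an even-sized length list is the usual midpoint of
the two central values. PSM-count datasets (cell lines) are handled
identically to spectral-count datasets.

### Tumor specificity

For each protein with tumor and normal samples, three statistics enter the
ranking with their own directions:

* `abs_change` $= \bar{x}_T - \bar{x}_N$ (higher is better),
* `ratio` $= (\bar{x}_T + \varepsilon)/(\bar{x}_N + \varepsilon)$ (higher
  is better),
* `p_diff`: two-sided Welch unequal-variance t-test on
  $\log_2(x + \varepsilon)$ (lower is better).

Welch-on-logs is the standard treatment for MS intensities, whose errors
are approximately log-normal; the suite checks that the p-value is
calibrated (5% rejections at $\alpha = 0.05$) when both groups are drawn
from one log-normal. The pseudocount $\varepsilon$ defaults to half the
smallest nonzero value in the dataset, a scale-aware zero guard. Raw
p-values are ranked — Benjamini–Hochberg q-values are reported for
information but deliberately never ranked, since the aggregation consumes
relative ordering, which monotone adjustment preserves anyway. A protein
detected in only one group contributes ratio and absolute change (the
undetected group's abundance is 0) but no p-value; when both groups are
an identical constant the t statistic is 0 and $p = 1$.

### Clinical association

For each protein the cohort is dichotomized at the **best cutoff**: every
distinct observed expression value within the 10th–90th expression
percentiles whose split leaves at least `min_group` patients
(`max(5, 10%)` by default) on each side is a candidate; "high" means
strictly greater than the cutoff; the cutoff minimizing the Cox–Mantel
(log-rank) p-value wins, ties breaking toward the smaller cutoff. The
log-rank statistic uses exact hypergeometric moments at tied event times.
At the selected split a Cox proportional-hazards model with the single
binary covariate (Breslow tie handling, convergence tolerance $10^{-9}$
on $\beta$) yields the hazard ratio $e^{\hat\beta}$ of high versus low.

Two caveats are intrinsic and documented rather than corrected:

* **Scan optimism.** Minimizing p over many splits inflates type-I error;
  the returned p is a screening statistic, mirroring the "best cutoff"
  practice of public Kaplan–Meier portals, and no multiplicity correction
  is applied across the scan. Calibration is asserted in the tests only
  for a *fixed* median split, where the 5% level holds.
* **Direction handling.** The ranking targets oncogenic candidates (high
  expression adverse, HR > 1). A protein whose best split gives HR ≤ 1,
  or whose likelihood is monotone (one group's events all precede the
  other's; $\beta$ diverges and is flagged non-estimable), is kept in the
  output table but assigned the worst possible component values (p = 1,
  HR = 0) so rank vectors stay complete without rewarding a protective or
  unstable association.

The implementation evaluates all cutoffs of the scan in one vectorized
risk-table pass; the tests require exact agreement with an exhaustive
per-cutoff brute force and with `survival::survdiff`, and the Cox fit is
checked against direct maximization of the written-out partial
likelihood.

## Aggregation policies

* **Weights** default to $c_i = 1$ for every component and are fully
  configurable; no published weighting exists to reproduce, so defaults
  are explicit and echoed in the report provenance.
* **Missing data**: `intersection` (default) scores only proteins present
  in every weighted component with $n$ = number of components, matching
  the workflow of first intersecting detected proteins across datasets
  (Venn overlap); `adjusted_n` scores every protein with its per-protein
  component count.
* **Rank scale**: `absolute` ranks (default) are faithful to the score's
  definition; `percentile` divides each rank by its component size
  $x_i$, useful when dataset sizes differ by more than about 2-fold
  (the package warns in that case), since absolute ranks from differently
  sized datasets are not commensurable.
* The three specificity statistics enter as three separately weighted
  components by default; `collapse_specificity = TRUE` averages their
  ranks into one component (re-ranked so the triangular-sum invariant is
  preserved) for users who consider them one line of evidence.
* Ties within a component receive average ranks, so every rank vector
  sums to $x(x+1)/2$ — an invariant the tests enforce everywhere. Final
  Rscore ties break lexicographically by accession for deterministic
  output.

Protein identity across datasets is the gene symbol; accessions are
carried for provenance only. Duplicate symbols within a dataset collapse
to the highest-total-abundance row with a warning, since each protein is
ranked once.

## The synthetic study generator

`generate_study()` builds a complete multi-dataset study with known truth
so every stage is testable without patient data: an LCM-style tissue
dataset (3 tumor + 3 normal samples), two cancer cell-line datasets (3
samples each), a CTC dataset (4 samples), a 200-patient survival cohort
over the gene-set proteins, and a 150-member candidate gene set drawn
from 500 simulated proteins, 3 of which are planted drivers.

The count model is negative binomial with dispersion 0.2 and mean

$$ \mu_{ps} = a_p \cdot \frac{L_p}{\mathrm{median}(L)} \cdot d_s , $$

with log-normal base abundance $a_p$ (meanlog $\log 10$, sdlog 1),
log-normal protein lengths (meanlog $\log 400$ aa, sdlog 0.5, floored at
50 aa) and log-normal sample depths (sdlog 0.25). The length factor makes
counts rise with protein length, so the length normalization is exercised
non-trivially: an abundant long protein must not outrank a shorter driver
after normalization. Detection dropout is Bernoulli per protein and
dataset with logistic probability in log abundance, midpoint at the 20th
abundance percentile (slope 2); dropped proteins are missing in all of
that dataset's samples, which produces realistic partial cross-dataset
overlap.

Planted drivers carry three signals, each independently switchable:

* base abundance re-drawn between the 75th and 95th percentile of the
  abundance distribution (`driver_abundance_quantile`, `NA` disables);
* a fold change $f = 4$ applied to the driver's count mean in
  cancer-derived material — tumor voxels, cell lines and CTCs alike,
  since the base abundance represents the normal-tissue baseline and an
  overexpressed oncoprotein is overexpressed in every cancer context, not
  only in the tissue comparison (`tumor_fold_change = 1` disables);
* an expression-dependent hazard in the cohort: each driver above its
  cohort median multiplies the patient's exponential hazard (baseline
  0.02 per time unit) by $HR_{true} = 2.5$, with uniform censoring on
  $(0, 60)$ time units (`hr_true = 1` disables).

Drivers are exempt from dropout: the ranking only scores proteins
detected everywhere, so recoverability requires scoreable drivers; this
mirrors the practice of ranking only the cross-dataset overlap.
`null_params()` switches all three signals off at once. This is the
appropriate null for recovery experiments: leaving any planted signal on
(for example the abundance planting) would make "drivers" identifiable
for reasons unrelated to the effect sizes being nulled, so the null
configuration defines drivers as fully exchangeable with non-drivers.

One global seed fans out to independent per-dataset streams, so adding a
dataset leaves the others bit-identical. The generator emulates the
*statistical structure* the ranking consumes — count overdispersion,
length confounding, detection overlap, expression-linked hazards — and
deliberately not peptide-level realism, retention times, batch effects,
isoform ambiguity, or correlated protein modules. Passing recovery tests
therefore demonstrate internal consistency of the pipeline under its own
assumptions, not performance on real cohorts.

## Numerical and testing choices

* Log-rank variance uses $d_j \frac{n_{1j}}{n_j}(1-\frac{n_{1j}}{n_j})
  \frac{n_j-d_j}{n_j-1}$ per distinct event time; a degenerate scan
  column with zero variance returns $\chi^2 = 0$, $p = 1$. Zero events
  overall is reported as uninformative ($p = 1$) with a message, never an
  error, so heavily censored cohorts degrade gracefully.
* Cox: Breslow ties, $|\beta| > 15$ or a divergence warning marks the fit
  non-estimable (monotone likelihood).
* Constant expression or splits that cannot satisfy the group-size bound
  raise a typed `NoValidCutoff` condition that the cohort-level driver
  catches and records as a status flag.
* Times are only compared, never differenced: all survival statistics are
  invariant to a common positive rescaling of time, which the suite
  checks.
* Test problem sizes were chosen to make the checks sharp but quick: the
  null calibrations use 2,000 replicates at cohort size 200 (binomial
  standard error ≈ 0.5%), hazard-ratio recovery uses 200 cohorts of
  1,000 patients, scan-vs-brute-force equivalence uses 100 random
  instances, and end-to-end recovery uses 100 default studies plus 100
  null studies.

## A worked run

```{r example, eval = FALSE}
study <- generate_study(synthetic_params(), seed = 1)
report <- rank_candidates(study$datasets, study$cohort, study$gene_set,
                          config = rscore_config(seed = 1))
head(report[, 1:5])
study$truth$symbol[study$truth$is_driver]
autoplot(report)                 # Rscore lollipop
plot_component_ranks(report)     # which signal drives each candidate
```

With the default configuration the three planted drivers occupy three of
the top five rows in the large majority of seeds; under `null_params()`
they scatter uniformly. The `scripts/acceptance.R` script in the source
repository recomputes these rates, the log-rank null size, and the Cox
recovery from scratch for any seed.

## Limitations

* The score aggregates ranks, not effect sizes: a protein that is
  mediocre everywhere can outrank one that is exceptional in a single
  component. This is by design (robustness to incommensurable scales) but
  means weights $c_i$ matter, and no principled weighting is estimated
  here.
* The best-cutoff p-values are optimistically biased and should be used
  for ordering, not inference.
* Symbol-level collapsing hides isoform-specific behavior.
* Absolute ranks from datasets of very different sizes are not
  commensurable; use `rank_scale = "percentile"` when mixing them.
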