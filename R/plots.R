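# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate, with censoring marks.
#'
#' @param object A `km_curve` from [km_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, survival = 1, n_censor = 0),
    as_tibble(object)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$n_censor > 0),
                        shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
  p
}

#' Plot two Kaplan-Meier curves for a dichotomized protein
#'
#' Convenience display of a best-cutoff split: survival of the high- and
#' low-expression groups.
#'
#' @param cohort A [survival_cohort()].
#' @param protein Symbol of the expression column.
#' @param cutoff Expression cutoff; "high" is strictly greater.
#' @return A ggplot.
#' @export
plot_km_split <- function(cohort, protein, cutoff) {
  expr <- cohort[[protein]]
  ok <- !is.na(expr)
  groups <- list(high = ok & expr > cutoff, low = ok & expr <= cutoff)
  df <- purrr::imap_dfr(groups, function(idx, nm) {
    crv <- km_curve(cohort$time[idx], cohort$event[idx])
    dplyr::bind_rows(tibble(time = 0, survival = 1, n_censor = 0),
                     as_tibble(crv)) |>
      dplyr::mutate(group = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = paste0(protein, " (cutoff ", signif(cutoff, 3), ")"),
                  x = "Time", y = "Survival probability",
                  color = "Expression") +
    ggplot2::theme_minimal()
}

#' Plot the cutoff scan profile
#'
#' -log10 log-rank p against candidate cutoff, with the selected optimum
#' marked.
#'
#' @param object A `cutoff_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cutoff_scan
#' @export
autoplot.cutoff_scan <- function(object, ...) {
  scan <- attr(object, "scan")
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$cutoff,
                                     y = -log10(.data$p))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(scan,
                                             .data$cutoff == object$cutoff),
                        color = "red", size = 2) +
    ggplot2::labs(x = "Expression cutoff",
                  y = expression(-log[10] ~ "log-rank p")) +
    ggplot2::theme_minimal()
}

#' Plot the top of a candidate report
#'
#' Lollipop chart of the smallest (best) Rscores.
#'
#' @param object A `candidate_report`.
#' @param top Number of proteins to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot candidate_report
#' @export
autoplot.candidate_report <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  df$symbol <- factor(df$symbol, levels = rev(df$symbol))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rscore, y = .data$symbol)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$rscore,
                                       yend = .data$symbol),
                          color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Rscore (smaller is better)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-component rank heatmap of the top candidates
#'
#' Shows where each top protein sits in every ranking component, making
#' visible which signal (abundance, specificity, survival) drives its
#' aggregate position.
#'
#' @param report A `candidate_report`.
#' @param top Number of proteins to show.
#' @return A ggplot.
#' @export
plot_component_ranks <- function(report, top = 20) {
  df <- tidy(report)
  df <- dplyr::filter(df, .data$final_rank <= top)
  df$symbol <- factor(df$symbol,
                      levels = rev(unique(df$symbol[order(df$final_rank)])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component_id, y = .data$symbol,
                                   fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Rank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
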