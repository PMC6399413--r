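# End-to-end report over a simulated or measured experiment, plus ggplot2
# figure builders for each result type.

#' Run the full tabular pipeline and collect summary artifacts
#'
#' Takes the three input tables (as produced by [simulate_experiment()] or
#' read from CSV), runs the budget, PLFA-SIP and CFE stages, and returns
#' the standard summary artifacts: a budget table in the whole-system
#' layout (per-pool excess masses and percent of total label, with
#' aggregate rows), a CFE microbial/dissolved-pool summary, the per-group
#' PLFA panel, and the underlying fitted objects. Writing the tables with
#' [write_pipeline_csv()] is byte-deterministic given identical inputs.
#'
#' @param pools Pool table (absolute atom%, `is_control` column).
#' @param plfa Long-format PLFA peak table with labeled and control rows.
#' @param cfe Extract-pair table with labeled and control rows.
#' @param config Pipeline configuration ([load_pipeline_config()]).
#' @return List with `budget` (a `label_budget`), `budget_table`,
#'   `plfa_groups`, `cfe_table`.
#' @export
pipeline_report <- function(pools, plfa, cfe,
                            config = load_pipeline_config()) {
  if (!all(c("atom_pct_13c", "atom_pct_15n") %in% names(pools))) {
    abort("Pipeline stage 'budget' input is missing: pool table with atom%% columns required.")
  }
  labeled <- dplyr::filter(pools, !.data$is_control)
  controls <- dplyr::filter(pools, .data$is_control)
  if (nrow(controls) == 0L) {
    abort("Pipeline stage 'budget' requires unlabeled control boxes.")
  }
  budget <- labeled |>
    pool_excess_from_controls(controls) |>
    build_budget()

  plfa_out <- plfa_sip_summary(plfa,
                               istd_amount_ug = config$istd_amount_ug,
                               methanol_atom_pct =
                                 config$methanol_atom_pct_13c)

  cfe_labeled <- dplyr::filter(cfe, .data$treatment == "labeled")
  cfe_controls <- dplyr::filter(cfe, .data$treatment == "control")
  if (nrow(cfe_controls) == 0L) {
    abort("Pipeline stage 'cfe' requires unlabeled control extracts.")
  }
  cfe_table <- cfe_summary(cfe_labeled, cfe_controls)

  list(budget = budget,
       budget_table = tidy(budget),
       plfa_groups = plfa_out$groups,
       cfe_table = cfe_table)
}

#' Figure builders for pipeline results
#'
#' `plot_budget()` shows each compartment's percent of total label per
#' tracer; `plot_group_enrichment()` the per-group atom% excess 13C by
#' pool; `plot_group_biomass()` PLFA-C biomass by pool and box side (the
#' view in which an N-addition decline is visible);
#' `plot_roi_composition()` per-ROI isotope content with 1-sigma counting
#' error bars; `plot_ca()` a correspondence-analysis biplot with
#' variance-explained axis labels.
#'
#' @param budget A `label_budget` from [build_budget()].
#' @return A ggplot object.
#' @export
plot_budget <- function(budget) {
  stopifnot(inherits(budget, "label_budget"))
  tab <- budget$summary |>
    dplyr::filter(.data$pool %in% POOL_LEVELS) |>
    dplyr::select("pool", `13C` = "pct_13c", `15N` = "pct_15n") |>
    tidyr::pivot_longer(-"pool", names_to = "tracer",
                        values_to = "percent")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pool, y = .data$percent,
                                    fill = .data$tracer)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of total recovered label",
                  fill = "tracer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_budget
#' @param groups Per-group PLFA summary (`$groups` of
#'   [plfa_sip_summary()]).
#' @export
plot_group_enrichment <- function(groups) {
  ggplot2::ggplot(groups,
                  ggplot2::aes(x = .data$group, y = .data$ape_13c,
                               fill = .data$pool)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "atom% excess 13C (abundance-weighted)",
                  fill = "pool") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_budget
#' @export
plot_group_biomass <- function(groups) {
  ggplot2::ggplot(groups,
                  ggplot2::aes(x = .data$group,
                               y = .data$biomass_ugC_per_g,
                               fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pool)) +
    ggplot2::labs(x = NULL, y = "PLFA biomass (ug C / g dw)",
                  fill = "box side") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_budget
#' @param rois ROI table from [roi_composition()].
#' @param isotope `"13c"` (dimer estimator) or `"15n"`.
#' @export
plot_roi_composition <- function(rois, isotope = c("13c", "15n")) {
  isotope <- match.arg(isotope)
  if (isotope == "13c") {
    y <- "atom_pct_13c_dimer"; s <- "sigma_13c_dimer"
    lab <- "atom% 13C"
  } else {
    y <- "atom_pct_15n"; s <- "sigma_15n"
    lab <- "atom% 15N"
  }
  ggplot2::ggplot(rois, ggplot2::aes(x = factor(.data$roi_id),
                                     y = .data[[y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[y]] - .data[[s]],
                                        ymax = .data[[y]] + .data[[s]]),
                           width = 0.2) +
    ggplot2::labs(x = "ROI", y = lab) +
    ggplot2::theme_minimal()
}

#' @rdname plot_budget
#' @param ca_fit A `ca_fit` from [correspondence_analysis()].
#' @export
plot_ca <- function(ca_fit) {
  stopifnot(inherits(ca_fit, "ca_fit"))
  scores <- tidy(ca_fit) |>
    tidyr::pivot_wider(names_from = "axis", values_from = "score")
  pct <- 100 * ca_fit$inertia_fraction
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$CA1, y = .data$CA2,
                                       colour = .data$type,
                                       label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("CA1 (%.1f%%)", pct[1]),
                  y = sprintf("CA2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ca_fit <- function(object, ...) plot_ca(object)

#' @exportS3Method ggplot2::autoplot
autoplot.label_budget <- function(object, ...) plot_budget(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
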