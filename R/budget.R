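# Whole-system 13C / 15N label budgets across plant, soil and litter pools.

POOL_LEVELS <- c("leaves", "stem", "roots",
                 "rhizosphere_soil", "bulk_soil", "litter")
PLANT_POOLS <- c("leaves", "stem", "roots")
SOIL_LITTER_POOLS <- c("rhizosphere_soil", "bulk_soil", "litter")
SIDE_LEVELS <- c("N_treated", "untreated", "whole_plant")

validate_pool_table <- function(pools) {
  required <- c("box_id", "side", "pool", "c_mass_g", "n_mass_g",
                "ape_13c", "ape_15n")
  missing <- setdiff(required, names(pools))
  if (length(missing)) {
    abort(paste0("Pool table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad_pool <- setdiff(unique(pools$pool), POOL_LEVELS)
  if (length(bad_pool)) {
    abort(paste0("Unknown pool(s): ", paste(bad_pool, collapse = ", ")))
  }
  bad_side <- setdiff(unique(pools$side), SIDE_LEVELS)
  if (length(bad_side)) {
    abort(paste0("Unknown side(s): ", paste(bad_side, collapse = ", ")))
  }
  wp <- pools$side == "whole_plant" & !pools$pool %in% c("leaves", "stem")
  if (any(wp)) {
    abort("side = 'whole_plant' is only valid for leaves and stem.")
  }
  if (any(pools$c_mass_g < 0) || any(pools$n_mass_g < 0)) {
    abort("Pool C and N masses must be >= 0.")
  }
  dup <- duplicated(pools[c("box_id", "side", "pool")])
  if (any(dup)) {
    abort("Duplicate (box_id, side, pool) keys in pool table.")
  }
  invisible(pools)
}

#' Atom percent excess of labeled pools against unlabeled controls
#'
#' Joins a labeled pool table (absolute atom% columns) to per-pool control
#' means and converts the isotope columns to atom percent excess, the form
#' consumed by [build_budget()].
#'
#' @param labeled Tibble with columns `box_id`, `side`, `pool`, `c_mass_g`,
#'   `n_mass_g`, `atom_pct_13c`, `atom_pct_15n` for labeled boxes.
#' @param controls Same layout for unlabeled control boxes; baselines are
#'   per-pool means over all control rows.
#'
#' @return The labeled table with `ape_13c` and `ape_15n` columns replacing
#'   the absolute atom% columns.
#' @export
pool_excess_from_controls <- function(labeled, controls) {
  for (tab in list(labeled, controls)) {
    miss <- setdiff(c("pool", "atom_pct_13c", "atom_pct_15n"), names(tab))
    if (length(miss)) {
      abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
    }
  }
  baseline <- controls |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(ctrl_13c = mean(.data$atom_pct_13c),
                     ctrl_15n = mean(.data$atom_pct_15n),
                     .groups = "drop")
  out <- labeled |>
    dplyr::inner_join(baseline, by = "pool") |>
    dplyr::mutate(
      ape_13c = atom_percent_excess(.data$atom_pct_13c, .data$ctrl_13c),
      ape_15n = atom_percent_excess(.data$atom_pct_15n, .data$ctrl_15n)
    ) |>
    dplyr::select(-dplyr::any_of(c("atom_pct_13c", "atom_pct_15n",
                                   "ctrl_13c", "ctrl_15n")))
  if (nrow(out) < nrow(labeled)) {
    warn("Some labeled pools had no matching control pool and were dropped.")
  }
  out
}

#' Build a whole-system label budget
#'
#' Computes, per replicate box, the excess tracer mass of every compartment
#' (mg 13C from the C mass and atom% excess 13C; ug 15N from the N mass and
#' atom% excess 15N), expresses each compartment as a percentage of the
#' box's total recovered label, and aggregates plant biomass
#' (leaves + stem + roots) and soil + litter
#' (rhizosphere + bulk soil + litter). Rows belonging to the same
#' (box, pool) on different box sides are summed before percentages are
#' formed.
#'
#' Across replicate boxes the summary reports the mean of per-box
#' percentages (mean of ratios) with standard errors; the ratio of mean
#' excess masses is reported alongside as `pct_13c_pooled` / `pct_15n_pooled`
#' for comparison, since the two differ when allocation varies between boxes.
#'
#' @param pools Pool table with columns `box_id`, `side`, `pool`,
#'   `c_mass_g`, `n_mass_g`, `ape_13c`, `ape_15n`. See
#'   [pool_excess_from_controls()] to derive the APE columns from absolute
#'   atom% measurements.
#'
#' @return An object of class `label_budget`: a list with tibbles
#'   `per_box` (one row per box x pool, with excess masses and per-box
#'   percentages) and `summary` (one row per pool plus the aggregate rows
#'   `plant_biomass`, `soil_litter` and `total`). `tidy()` returns the
#'   summary; `glance()` returns one row of totals.
#'
#' @examples
#' pools <- tibble::tibble(
#'   box_id = 1, side = "whole_plant", pool = c("leaves", "stem"),
#'   c_mass_g = c(0.5, 2.0), n_mass_g = c(0.03, 0.03),
#'   ape_13c = c(0.9, 0.36), ape_15n = c(0.001, 0.01)
#' )
#' build_budget(pools)
#' @export
build_budget <- function(pools) {
  if (!is.data.frame(pools) || nrow(pools) == 0L) {
    abort("`pools` must be a non-empty data frame.")
  }
  pools <- tibble::as_tibble(pools)
  validate_pool_table(pools)

  per_box <- pools |>
    dplyr::mutate(
      excess_13c_mg = label_mass_excess(.data$c_mass_g, .data$ape_13c),
      excess_15n_ug = label_mass_excess(.data$n_mass_g, .data$ape_15n) * 1000
    ) |>
    dplyr::group_by(.data$box_id, .data$pool) |>
    dplyr::summarise(
      c_mass_g = sum(.data$c_mass_g),
      n_mass_g = sum(.data$n_mass_g),
      excess_13c_mg = sum(.data$excess_13c_mg),
      excess_15n_ug = sum(.data$excess_15n_ug),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      total_13c_mg = sum(.data$excess_13c_mg),
      total_15n_ug = sum(.data$excess_15n_ug)
    ) |>
    dplyr::ungroup()

  if (any(per_box$total_13c_mg <= 0) || any(per_box$total_15n_ug <= 0)) {
    abort("Total excess label must be > 0 in every box to form percentages.")
  }
  per_box <- per_box |>
    dplyr::mutate(
      pct_13c = 100 * .data$excess_13c_mg / .data$total_13c_mg,
      pct_15n = 100 * .data$excess_15n_ug / .data$total_15n_ug
    ) |>
    dplyr::select(-dplyr::all_of(c("total_13c_mg", "total_15n_ug")))

  aggregate_rows <- function(tab, pool_set, label) {
    tab |>
      dplyr::filter(.data$pool %in% pool_set) |>
      dplyr::group_by(.data$box_id) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(c("c_mass_g", "n_mass_g", "excess_13c_mg",
                        "excess_15n_ug", "pct_13c", "pct_15n")), sum),
        .groups = "drop") |>
      dplyr::mutate(pool = label)
  }
  with_aggregates <- dplyr::bind_rows(
    per_box,
    aggregate_rows(per_box, PLANT_POOLS, "plant_biomass"),
    aggregate_rows(per_box, SOIL_LITTER_POOLS, "soil_litter"),
    aggregate_rows(per_box, POOL_LEVELS, "total")
  )

  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  summary <- with_aggregates |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(
      n_boxes = dplyr::n(),
      dplyr::across(dplyr::all_of(c("c_mass_g", "n_mass_g", "excess_13c_mg",
                                    "excess_15n_ug", "pct_13c", "pct_15n")),
                    list(mean = mean, se = se),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~ sub("_mean$", "", .x)) |>
    dplyr::mutate(pool = factor(.data$pool,
                                levels = c(POOL_LEVELS, "plant_biomass",
                                           "soil_litter", "total"))) |>
    dplyr::arrange(.data$pool)

  # ratio-of-means alternative: percent of summed mean excess masses
  pooled <- summary |>
    dplyr::filter(.data$pool %in% POOL_LEVELS)
  summary <- summary |>
    dplyr::mutate(
      pct_13c_pooled = 100 * .data$excess_13c_mg / sum(pooled$excess_13c_mg),
      pct_15n_pooled = 100 * .data$excess_15n_ug / sum(pooled$excess_15n_ug)
    )

  structure(list(per_box = per_box, summary = summary),
            class = "label_budget")
}

#' @export
print.label_budget <- function(x, ...) {
  cat(sprintf("<label_budget> %d box(es)\n",
              length(unique(x$per_box$box_id))))
  print(dplyr::select(x$summary, "pool", "excess_13c_mg", "pct_13c",
                      "excess_15n_ug", "pct_15n"), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.label_budget <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.label_budget <- function(x, ...) {
  tot <- dplyr::filter(x$summary, .data$pool == "total")
  tibble::tibble(
    n_boxes = tot$n_boxes,
    total_13c_excess_mg = tot$excess_13c_mg,
    total_15n_excess_ug = tot$excess_15n_ug
  )
}

#' Share of a budget fraction within a larger fraction
#'
#' Expresses one percentage of the total label as a share of another, e.g.
#' the litter compartment's share of all 13C allocated below ground.
#'
#' @param part_percent,whole_percent Percentages of total label with
#'   `0 <= part <= whole` and `whole > 0`.
#'
#' @return `100 * part_percent / whole_percent`.
#'
#' @examples
#' budget_ratio(0.36, 11.74)  # litter share of belowground 13C, ~3%
#' @export
budget_ratio <- function(part_percent, whole_percent) {
  check_finite_numeric(part_percent, "part_percent")
  check_finite_numeric(whole_percent, "whole_percent")
  if (any(whole_percent <= 0)) abort("`whole_percent` must be > 0.")
  if (any(part_percent < 0)) abort("`part_percent` must be >= 0.")
  if (any(part_percent > whole_percent)) {
    abort("`part_percent` cannot exceed `whole_percent`.")
  }
  100 * part_percent / whole_percent
}
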