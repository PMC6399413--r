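# PLFA quantification, methanolysis correction, biomarker group assignment
# and abundance-weighted 13C enrichment.

#' Canonical PLFA biomarker names
#'
#' Normalises omega notation so that "18:2w6,9" and "18:2ω6,9" compare
#' equal; cis/trans prefixes and methyl-branch prefixes are preserved.
#' Whitespace is stripped.
#'
#' @param name Character vector of biomarker names.
#' @return Canonicalised names (ASCII `w` form).
#' @examples
#' canonical_biomarker(c("18:2ω6,9", "cy19:0", " i15:0"))
#' @export
canonical_biomarker <- function(name) {
  out <- gsub("ω", "w", name, fixed = TRUE)
  gsub("[[:space:]]", "", out)
}

#' Default biomarker-to-group assignment table
#'
#' The standard diagnostic assignment for soil PLFA profiling:
#' i15:0, a15:0, i16:0, i17:0, a17:0 indicate Gram-positive bacteria;
#' 10Me17:0 indicates Actinobacteria; 16:1w5, 16:1w7, cy17:0 and cy19:0
#' indicate Gram-negative bacteria (16:1w5 can also derive from arbuscular
#' mycorrhizal fungi but is treated as Gram-negative in host systems that do
#' not form AM symbioses, such as beech); 17:0 belongs to the general
#' bacterial pool; cis18:1w9, trans18:1w9 and 18:2w6,9 are fungal and are
#' kept as two separate fungal groups because the two fatty acids vary
#' independently between fungal taxa; 16:0 and 18:0 are general biomarkers.
#' The union of the three diagnostic bacterial groups plus 17:0 constitutes
#' `bacteria_general`.
#'
#' @return Tibble with columns `biomarker` and `group`.
#' @export
default_biomarker_groups <- function() {
  tibble::tribble(
    ~biomarker,    ~group,
    "i15:0",       "gram_positive",
    "a15:0",       "gram_positive",
    "i16:0",       "gram_positive",
    "i17:0",       "gram_positive",
    "a17:0",       "gram_positive",
    "10Me17:0",    "actinobacteria",
    "16:1w5",      "gram_negative",
    "16:1w7",      "gram_negative",
    "cy17:0",      "gram_negative",
    "cy19:0",      "gram_negative",
    "17:0",        "bacteria_general",
    "cis18:1w9",   "fungi_18_1w9",
    "trans18:1w9", "fungi_18_1w9",
    "18:2w6,9",    "fungi_18_2w69",
    "16:0",        "general",
    "18:0",        "general"
  )
}

BACTERIAL_GROUPS <- c("gram_positive", "actinobacteria", "gram_negative",
                      "bacteria_general")

#' Default acyl carbon counts per biomarker
#'
#' Carbon atoms in the fatty-acid (acyl) chain of each biomarker, counting
#' methyl branches; the FAME derivative carries one additional carbon from
#' methanol. Used by [methanolysis_correction()]. Override entries by
#' passing a modified table where chromatographic assignments differ.
#'
#' @return Tibble with columns `biomarker` and `acyl_carbons`.
#' @export
default_acyl_carbons <- function() {
  tibble::tribble(
    ~biomarker,    ~acyl_carbons,
    "i15:0",       15L,
    "a15:0",       15L,
    "i16:0",       16L,
    "i17:0",       17L,
    "a17:0",       17L,
    "10Me17:0",    18L,
    "16:1w5",      16L,
    "16:1w7",      16L,
    "cy17:0",      17L,
    "cy19:0",      19L,
    "17:0",        17L,
    "cis18:1w9",   18L,
    "trans18:1w9", 18L,
    "18:2w6,9",    18L,
    "16:0",        16L,
    "18:0",        18L
  )
}

#' Quantify a PLFA from the internal standard peak
#'
#' Single-point internal-standard quantification: the analyte concentration
#' is the area ratio to the internal standard (nonadecanoic acid methyl
#' ester, FAME 19:0, added before methylation) scaled by the standard amount
#' and normalised to soil dry weight. A relative response factor of 1 is
#' assumed by default.
#'
#' @param peak_area Analyte peak area, `>= 0` (arbitrary units).
#' @param istd_area Internal-standard peak area, `> 0` (same units).
#' @param istd_amount_ug Amount of internal standard added, ug.
#' @param soil_dw_g Soil dry weight extracted, g, `> 0`.
#' @param response_factor Relative response factor analyte/standard.
#'
#' @return Concentration in ug per g dry soil.
#' @examples
#' quantify_from_internal_standard(500, 1000, 10, 2)
#' @export
quantify_from_internal_standard <- function(peak_area, istd_area,
                                            istd_amount_ug, soil_dw_g,
                                            response_factor = 1) {
  check_finite_numeric(peak_area, "peak_area")
  check_finite_numeric(istd_area, "istd_area")
  if (any(istd_area <= 0)) abort("`istd_area` must be > 0.")
  if (any(soil_dw_g <= 0)) abort("`soil_dw_g` must be > 0.")
  if (any(peak_area < 0)) abort("`peak_area` must be >= 0.")
  peak_area / istd_area / response_factor * istd_amount_ug / soil_dw_g
}

#' Correct FAME atom percent for the methanol-derived methyl carbon
#'
#' Methanolysis adds one methyl carbon from methanol to each fatty acid, so
#' the measured FAME isotope signature is a mixture of n acyl carbons and
#' one methanol carbon. The underlying PLFA atom% is recovered by the mass
#' balance `((n + 1) * fame - methanol) / n`. Results that fall outside
#' `[0, 100]` (possible with noisy inputs near the natural-abundance
#' baseline) are returned as computed together with a `flagged` attribute —
#' they are never silently clamped.
#'
#' @param fame_atom_pct Measured FAME atom% 13C, in `[0, 100]`.
#' @param acyl_carbons Acyl carbon count n, `>= 2`.
#' @param methanol_atom_pct atom% 13C of the methanol used for
#'   derivatization; defaults to natural-abundance carbon on the VPDB scale.
#'
#' @return Numeric vector of PLFA atom% 13C with attribute `flagged`
#'   (logical vector marking out-of-range results).
#' @examples
#' methanolysis_correction(2.0, 16, 1.08)
#' @export
methanolysis_correction <- function(fame_atom_pct, acyl_carbons,
                                    methanol_atom_pct =
                                      ratio_to_atom_percent(std_vpdb()$ratio)) {
  check_finite_numeric(fame_atom_pct, "fame_atom_pct")
  check_finite_numeric(methanol_atom_pct, "methanol_atom_pct")
  if (any(acyl_carbons < 2)) abort("`acyl_carbons` must be >= 2.")
  if (any(fame_atom_pct < 0 | fame_atom_pct > 100) ||
      any(methanol_atom_pct < 0 | methanol_atom_pct > 100)) {
    abort("atom%% inputs must lie in [0, 100].")
  }
  n <- acyl_carbons
  out <- ((n + 1) * fame_atom_pct - methanol_atom_pct) / n
  flagged <- out < 0 | out > 100
  if (any(flagged)) {
    warn(sprintf(
      "%d methanolysis-corrected atom%% value(s) fall outside [0, 100]; flagged.",
      sum(flagged)))
  }
  attr(out, "flagged") <- flagged
  out
}

#' Assign PLFA records to microbial groups
#'
#' Tags each record with its diagnostic microbial group after
#' canonicalising biomarker names. Unknown biomarkers are tagged
#' `"unassigned"` with a warning. Records in the three diagnostic bacterial
#' groups also belong to the composite `bacteria_general` pool (see
#' [group_members()]).
#'
#' @param records Tibble with at least a `biomarker` column.
#' @param assignment Assignment table as from [default_biomarker_groups()].
#'
#' @return `records` with canonical `biomarker` names and a `group` column.
#' @export
assign_groups <- function(records, assignment = default_biomarker_groups()) {
  if (!"biomarker" %in% names(records)) {
    abort("`records` must have a `biomarker` column.")
  }
  if (anyDuplicated(canonical_biomarker(assignment$biomarker))) {
    abort("Assignment table maps a biomarker to more than one group.")
  }
  assignment <- dplyr::mutate(
    assignment, biomarker = canonical_biomarker(.data$biomarker))
  out <- records |>
    dplyr::mutate(biomarker = canonical_biomarker(.data$biomarker)) |>
    dplyr::left_join(assignment, by = "biomarker")
  if (anyNA(out$group)) {
    unknown <- unique(out$biomarker[is.na(out$group)])
    warn(paste0("Unassigned biomarker(s): ", paste(unknown, collapse = ", ")))
    out$group[is.na(out$group)] <- "unassigned"
  }
  out
}

#' Expand a grouped record set for a composite group
#'
#' `bacteria_general` is the union of the Gram-positive, Actinobacteria and
#' Gram-negative diagnostic groups plus 17:0; all other groups are their own
#' members.
#'
#' @param records Output of [assign_groups()].
#' @param group Group name.
#' @return The member records of `group`.
#' @export
group_members <- function(records, group) {
  if (group == "bacteria_general") {
    dplyr::filter(records, .data$group %in% BACTERIAL_GROUPS)
  } else {
    dplyr::filter(records, .data$group == !!group)
  }
}

#' Abundance-weighted group-level 13C enrichment
#'
#' The enrichment of a microbial group is the mean of its member PLFAs'
#' atom% excess 13C weighted by their abundance (ug PLFA-C per g dry soil),
#' so that abundant biomarkers dominate the group signal.
#'
#' @param ape Atom percent excess per biomarker.
#' @param weight Abundance weight per biomarker, `>= 0`, at least one `> 0`.
#'
#' @return Weighted mean atom% excess (scalar).
#' @examples
#' weighted_group_enrichment(c(0.2, 0.4), c(1, 1))
#' @export
weighted_group_enrichment <- function(ape, weight) {
  check_finite_numeric(ape, "ape")
  check_finite_numeric(weight, "weight")
  if (length(ape) != length(weight)) {
    abort("`ape` and `weight` must have equal length.")
  }
  if (any(weight < 0)) abort("Weights must be >= 0.")
  if (sum(weight) <= 0) abort("At least one weight must be > 0.")
  sum(ape * weight) / sum(weight)
}

#' Excess 13C mass bound in a group's PLFAs
#'
#' Sums, over the member biomarkers, concentration times atom% excess /100:
#' the mass of tracer-derived 13C held in the group's membrane lipids per
#' gram of dry soil.
#'
#' @param ape Atom percent excess per biomarker.
#' @param conc Concentration per biomarker, ug PLFA-C per g dry soil.
#'
#' @return ug excess 13C per g dry weight (scalar).
#' @export
group_13c_mass <- function(ape, conc) {
  check_finite_numeric(ape, "ape")
  check_finite_numeric(conc, "conc")
  if (length(ape) != length(conc)) {
    abort("`ape` and `conc` must have equal length.")
  }
  if (any(conc < 0)) abort("Concentrations must be >= 0.")
  sum(conc * ape / 100)
}

#' Full PLFA stable-isotope-probing summary
#'
#' Runs the complete PLFA workflow on a long-format peak table: internal
#' standard quantification, methanolysis correction, atom% excess against
#' per-biomarker x per-pool control baselines, group assignment, and
#' per-group abundance-weighted enrichment and excess-13C mass.
#'
#' @param plfa Tibble with columns `sample_id`, `box_id`, `side`, `pool`,
#'   `treatment` (`"labeled"` or `"control"`), `biomarker`, `peak_area`,
#'   `istd_area`, `soil_dw_g`, `fame_atom_pct_13c`.
#' @param istd_amount_ug Internal standard amount per sample, ug.
#' @param methanol_atom_pct atom% 13C of the derivatization methanol.
#' @param assignment Biomarker-group table ([default_biomarker_groups()]).
#' @param acyl_carbons Acyl carbon table ([default_acyl_carbons()]).
#' @param weight_by `"pool_mean"` (default) weights group enrichment by the
#'   per-pool mean biomarker abundance across replicates; `"sample"` weights
#'   by each sample's own abundances.
#'
#' @return List with tibbles `records` (per sample x biomarker:
#'   concentration, corrected atom%, APE, group) and `groups` (per
#'   pool x side x group: total biomass ug C/g, weighted APE, excess 13C
#'   ug/g).
#' @export
plfa_sip_summary <- function(plfa,
                             istd_amount_ug,
                             methanol_atom_pct =
                               ratio_to_atom_percent(std_vpdb()$ratio),
                             assignment = default_biomarker_groups(),
                             acyl_carbons = default_acyl_carbons(),
                             weight_by = c("pool_mean", "sample")) {
  weight_by <- match.arg(weight_by)
  required <- c("sample_id", "box_id", "side", "pool", "treatment",
                "biomarker", "peak_area", "istd_area", "soil_dw_g",
                "fame_atom_pct_13c")
  missing <- setdiff(required, names(plfa))
  if (length(missing)) {
    abort(paste0("PLFA table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  acyl_carbons <- dplyr::mutate(
    acyl_carbons, biomarker = canonical_biomarker(.data$biomarker))

  records <- plfa |>
    assign_groups(assignment) |>
    dplyr::left_join(acyl_carbons, by = "biomarker") |>
    dplyr::mutate(
      conc_ugC_per_g = quantify_from_internal_standard(
        .data$peak_area, .data$istd_area, istd_amount_ug, .data$soil_dw_g),
      plfa_atom_pct_13c = as.numeric(methanolysis_correction(
        .data$fame_atom_pct_13c,
        dplyr::coalesce(.data$acyl_carbons, 16L),
        methanol_atom_pct))
    )

  baseline <- records |>
    dplyr::filter(.data$treatment == "control") |>
    dplyr::group_by(.data$biomarker, .data$pool) |>
    dplyr::summarise(control_atom_pct = mean(.data$plfa_atom_pct_13c),
                     .groups = "drop")
  if (nrow(baseline) == 0L) {
    abort("No control samples found to establish natural-abundance baselines.")
  }

  records <- records |>
    dplyr::left_join(baseline, by = c("biomarker", "pool")) |>
    dplyr::mutate(ape_13c = .data$plfa_atom_pct_13c - .data$control_atom_pct)

  labeled <- dplyr::filter(records, .data$treatment == "labeled")
  pool_weights <- labeled |>
    dplyr::group_by(.data$pool, .data$biomarker) |>
    dplyr::summarise(pool_mean_conc = mean(.data$conc_ugC_per_g),
                     .groups = "drop")
  labeled <- dplyr::left_join(labeled, pool_weights,
                              by = c("pool", "biomarker"))

  summarise_group <- function(tab, group_name) {
    members <- group_members(tab, group_name)
    if (nrow(members) == 0L) return(NULL)
    w <- if (weight_by == "pool_mean") members$pool_mean_conc else
      members$conc_ugC_per_g
    tibble::tibble(
      group = group_name,
      n_biomarkers = dplyr::n_distinct(members$biomarker),
      biomass_ugC_per_g = sum(members$conc_ugC_per_g) /
        dplyr::n_distinct(members$sample_id),
      ape_13c = weighted_group_enrichment(members$ape_13c, w),
      excess_13c_ug_per_g = group_13c_mass(members$ape_13c,
                                           members$conc_ugC_per_g) /
        dplyr::n_distinct(members$sample_id)
    )
  }

  all_groups <- c(setdiff(unique(labeled$group), "unassigned"),
                  "bacteria_general")
  all_groups <- unique(all_groups)
  groups <- labeled |>
    dplyr::group_by(.data$pool, .data$side) |>
    dplyr::group_modify(function(tab, key) {
      tab$sample_id <- as.character(tab$sample_id)
      dplyr::bind_rows(lapply(all_groups, function(g) summarise_group(tab, g)))
    }) |>
    dplyr::ungroup()

  list(records = records, groups = groups)
}
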