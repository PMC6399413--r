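# Validated CSV readers/writers and YAML pipeline configuration.
#
# CSV dialect: UTF-8, comma separator, "." decimal, mandatory header row;
# units are encoded in column names (c_mass_g, conc ug/g in *_ugC_per_g).

read_validated_csv <- function(path, col_types, numeric_cols,
                               enum_cols = list()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(names(col_types), names(tab))
  if (length(missing)) {
    abort(paste0(basename(path), " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  problems <- character(0)
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(parsed) & !is.na(tab[[col]]))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "non-numeric value in column '%s', row(s) %s", col,
        paste(head(bad, 5), collapse = ", ")))
    }
    tab[[col]] <- parsed
  }
  for (col in names(enum_cols)) {
    bad <- which(!tab[[col]] %in% enum_cols[[col]] & !is.na(tab[[col]]))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "invalid value in column '%s', row(s) %s (allowed: %s)", col,
        paste(head(bad, 5), collapse = ", "),
        paste(enum_cols[[col]], collapse = "/")))
    }
  }
  if (length(problems)) {
    abort(paste0("Validation of ", basename(path), " failed:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  tab
}

#' Read the pipeline's tabular inputs
#'
#' Schema-validated CSV readers: every numeric column must parse, enum
#' columns (pool, side) must use the documented levels, and violations are
#' reported with row numbers. `read_pool_table()` reads per-compartment C/N
#' masses with absolute atom% values and a logical `is_control` column;
#' `read_plfa_table()` reads the long-format PLFA peak table;
#' `read_extract_table()` reads paired fumigated/unfumigated extract
#' measurements.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_pool_table <- function(path) {
  tab <- read_validated_csv(
    path,
    col_types = setNames(rep("c", 8),
                         c("box_id", "side", "pool", "c_mass_g", "n_mass_g",
                           "atom_pct_13c", "atom_pct_15n", "is_control")),
    numeric_cols = c("c_mass_g", "n_mass_g", "atom_pct_13c", "atom_pct_15n"),
    enum_cols = list(pool = POOL_LEVELS, side = SIDE_LEVELS)
  )
  tab$is_control <- tab$is_control %in% c("TRUE", "true", "1", "yes")
  tab
}

#' @rdname read_pool_table
#' @export
read_plfa_table <- function(path) {
  read_validated_csv(
    path,
    col_types = setNames(rep("c", 10),
                         c("sample_id", "box_id", "side", "pool", "treatment",
                           "biomarker", "peak_area", "istd_area", "soil_dw_g",
                           "fame_atom_pct_13c")),
    numeric_cols = c("peak_area", "istd_area", "soil_dw_g",
                     "fame_atom_pct_13c"),
    enum_cols = list(pool = POOL_LEVELS,
                     treatment = c("labeled", "control"))
  )
}

#' @rdname read_pool_table
#' @export
read_extract_table <- function(path) {
  read_validated_csv(
    path,
    col_types = setNames(rep("c", 11),
                         c("sample_id", "box_id", "side", "pool", "treatment",
                           "doc_unfumigated", "doc_fumigated",
                           "tdn_unfumigated", "tdn_fumigated",
                           "atom_pct_13c_unfumigated",
                           "atom_pct_13c_fumigated")),
    numeric_cols = c("doc_unfumigated", "doc_fumigated", "tdn_unfumigated",
                     "tdn_fumigated", "atom_pct_13c_unfumigated",
                     "atom_pct_13c_fumigated"),
    enum_cols = list(pool = POOL_LEVELS,
                     treatment = c("labeled", "control"))
  )
}

#' Write a pipeline table to CSV
#'
#' @param tab A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(tab, path) {
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    isotope_standards = list(
      vpdb = list(name = "VPDB", ratio = 0.0111802),
      air = list(name = "AIR-N2", ratio = 0.0036765)
    ),
    istd_amount_ug = 10,
    methanol_atom_pct_13c = NATURAL_13C_ATOM_PCT,
    n_molar_mass = 14.003,
    significance_level = 0.05,
    enrichment_significance_level = 0.001,
    anosim_permutations = 999,
    seed = 1L
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML configuration and merges it over the documented defaults
#' (isotope standard ratios, internal-standard amount, methanol atom% 13C,
#' nitrogen molar mass, significance levels, permutation count, seed).
#' Unknown keys are rejected with a message naming them, so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Named list of configuration values.
#' @export
load_pipeline_config <- function(path = NULL) {
  defaults <- default_pipeline_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, user)
}

#' Published whole-system budget means used as a numeric fixture
#'
#' Pool-level means (with standard errors) of compartment C and N masses,
#' excess 13C (mg) and 15N (ug), percent-of-total-label allocation and C/N
#' ratios from the dual-labeling study whose conditions the synthetic
#' generator emulates. These printed summary values serve as inputs for
#' budget-aggregation checks and as the default allocation structure of
#' [experiment_config()].
#'
#' @return Tibble with one row per pool plus the aggregate rows
#'   `plant_biomass`, `soil_litter` and `total`.
#' @export
reference_budget_means <- function() {
  path <- system.file("extdata", "reference_pool_budget.csv",
                      package = "mycotrace", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    pool = readr::col_character(), .default = readr::col_double()),
    na = "NA", progress = FALSE)
}
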