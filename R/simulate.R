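# Synthetic experiment generator: pool tables, PLFA peak tables and CFE
# extract pairs with known ground truth, at the scale and allocation
# structure of a dual 13C-CO2 / 15N split-root pulse-chase study.

NATURAL_13C_ATOM_PCT <- 1.10566   # VPDB-scale natural abundance
NATURAL_15N_ATOM_PCT <- 0.36630   # AIR-scale natural abundance

#' Configuration of a synthetic dual-label experiment
#'
#' Defaults describe the study conditions the generator emulates: seven
#' replicate split-root boxes; compartment C and N masses on the scale of a
#' young beech mesocosm; 13C allocation dominated by plant biomass
#' (~88% of recovered label: leaves ~21%, stem ~36%, roots ~31%) with ~12%
#' below ground, and 15N allocation dominated by the litter compartment
#' that received the tracer (~78%); total recovered excess of 20.93 mg 13C
#' and 319.62 ug 15N per box; an N-addition effect that reduces
#' Gram-positive and actinobacterial PLFA abundance on the N-treated side
#' (multiplier `n_decline_factor`); and multiplicative lognormal noise on
#' concentrations (`noise_cv`) with additive Gaussian noise on atom%
#' values (`noise_sd_atom_pct`).
#'
#' @param n_boxes Labeled replicate boxes.
#' @param n_control Unlabeled control boxes.
#' @param noise_cv Coefficient of variation of lognormal multiplicative
#'   noise on masses and concentrations; 0 disables noise.
#' @param noise_sd_delta SD of additive isotope-measurement noise,
#'   expressed as delta-scale precision in permil (typical EA/GC-IRMS:
#'   ~0.2 permil) and converted to atom% per isotope against its standard
#'   ratio, so the same instrument precision implies far smaller atom%
#'   noise for 15N than for 13C.
#' @param n_decline_factor Multiplier on Gram-positive and actinobacterial
#'   PLFA abundance in N-treated compartments (`< 1` = decline).
#' @param allocation_13c,allocation_15n Named fractions of total excess
#'   label per pool; each must sum to 1.
#' @param total_13c_excess_mg,total_15n_excess_ug Recovered label per box.
#'
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n_boxes = 7,
                              n_control = 3,
                              noise_cv = 0.15,
                              noise_sd_delta = 0.2,
                              n_decline_factor = 0.6,
                              allocation_13c = c(
                                leaves = 0.2086, stem = 0.3592,
                                roots = 0.3147, rhizosphere_soil = 0.0435,
                                bulk_soil = 0.0704, litter = 0.0036),
                              allocation_15n = c(
                                leaves = 0.0010, stem = 0.0121,
                                roots = 0.0571, rhizosphere_soil = 0.0425,
                                bulk_soil = 0.1025, litter = 0.7848),
                              total_13c_excess_mg = 20.93,
                              total_15n_excess_ug = 319.62) {
  for (alloc in list(allocation_13c, allocation_15n)) {
    if (!setequal(names(alloc), POOL_LEVELS)) {
      abort("Allocation fractions must name every pool.")
    }
    if (abs(sum(alloc) - 1) > 1e-6) {
      abort("Allocation fractions must sum to 1 within 1e-6.")
    }
    if (any(alloc < 0)) abort("Allocation fractions must be >= 0.")
  }
  if (noise_cv < 0 || noise_sd_delta < 0) {
    abort("Noise parameters must be >= 0.")
  }
  structure(list(
    n_boxes = n_boxes, n_control = n_control,
    noise_cv = noise_cv, noise_sd_delta = noise_sd_delta,
    n_decline_factor = n_decline_factor,
    allocation_13c = allocation_13c[POOL_LEVELS],
    allocation_15n = allocation_15n[POOL_LEVELS],
    total_13c_excess_mg = total_13c_excess_mg,
    total_15n_excess_ug = total_15n_excess_ug,
    # mean compartment element masses (g per box)
    pool_masses = tibble::tibble(
      pool = POOL_LEVELS,
      c_mass_g = c(0.49, 2.07, 0.88, 6.70, 25.64, 6.23),
      n_mass_g = c(0.03, 0.03, 0.02, 0.53, 2.05, 0.24)
    ),
    # per-pool true PLFA group enrichment (atom% excess 13C) and biomass
    plfa_truth = tibble::tibble(
      pool = rep(c("rhizosphere_soil", "bulk_soil", "litter"), each = 5),
      group = rep(c("gram_positive", "actinobacteria", "gram_negative",
                    "fungi_18_1w9", "fungi_18_2w69"), times = 3),
      true_ape = c(0.30, 0.20, 0.28, 0.35, 0.40,
                   0.06, 0.02, 0.03, 0.30, 0.20,
                   0.20, 0.12, 0.18, 0.32, 0.08),
      conc_per_biomarker = c(6, 3, 5, 8, 7,
                             5, 2.5, 4, 6, 5,
                             14, 7, 12, 20, 16)
    ),
    # CFE truth per pool (ug per g dw; atom% excess)
    cfe_truth = tibble::tibble(
      pool = c("rhizosphere_soil", "bulk_soil", "litter"),
      cmic = c(610, 655, 1726),
      nmic = c(142, 126, 286),
      doc = c(155, 145, 2868),
      tdn = c(28, 26, 812),
      ape_13c_mic = c(0.47, 0.20, 0.10),
      ape_13c_doc = c(0.17, 0.03, 0.01)
    ),
    istd_amount_ug = 10,
    soil_dw_g = 2,
    istd_area = 1e5
  ), class = "experiment_config")
}

lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

addnoise <- function(x, sd) if (sd == 0) x else x + rnorm(length(x), 0, sd)

# atom% noise equivalent to a delta-scale (permil) measurement precision,
# evaluated at natural abundance: d(atom%)/d(delta) = 100 R0 / (1000 (1+R0)^2)
delta_sd_to_atom_sd <- function(sd_delta, standard) {
  r0 <- standard$ratio
  sd_delta * 100 * r0 / (1000 * (1 + r0)^2)
}

#' Simulate a complete dual-label experiment
#'
#' Draws, under a fixed seed, the three tables consumed by the downstream
#' pipeline — a pool table (with labeled and control boxes, absolute atom%
#' values), a long-format PLFA peak table, and CFE extract pairs — plus a
#' `truth` record of every generating parameter for recovery testing.
#' Identical seeds give identical tables.
#'
#' Belowground compartments are split over the two box sides (the litter
#' of one side receives the N addition); leaves and stem connect to both
#' sides and appear as `whole_plant` rows. With `noise_cv = 0` and
#' `noise_sd_delta = 0` the generated tables recover the allocation
#' fractions exactly.
#'
#' @param config An [experiment_config()].
#' @param seed Integer RNG seed.
#' @return List with tibbles `pools`, `plfa`, `cfe` and list `truth`.
#' @export
simulate_experiment <- function(config = experiment_config(), seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  cv <- config$noise_cv
  asd13 <- delta_sd_to_atom_sd(config$noise_sd_delta, std_vpdb())
  asd15 <- delta_sd_to_atom_sd(config$noise_sd_delta, std_air())

  pool_rows <- function(box, is_control) {
    tab <- config$pool_masses
    excess_13c <- config$allocation_13c * config$total_13c_excess_mg *
      lognoise(6, cv)
    excess_15n <- config$allocation_15n * config$total_15n_excess_ug *
      lognoise(6, cv)
    c_mass <- tab$c_mass_g * lognoise(6, cv)
    n_mass <- tab$n_mass_g * lognoise(6, cv)
    ape_13c <- if (is_control) rep(0, 6) else
      unname(excess_13c / (10 * c_mass))
    ape_15n <- if (is_control) rep(0, 6) else
      unname((excess_15n / 1000) / (10 * n_mass))
    base <- tibble::tibble(
      box_id = box, pool = tab$pool, c_mass_g = c_mass, n_mass_g = n_mass,
      atom_pct_13c = addnoise(NATURAL_13C_ATOM_PCT + ape_13c, asd13),
      atom_pct_15n = addnoise(NATURAL_15N_ATOM_PCT + ape_15n, asd15),
      is_control = is_control
    )
    # split belowground pools across sides; aboveground is whole-plant
    above <- base |>
      dplyr::filter(.data$pool %in% c("leaves", "stem")) |>
      dplyr::mutate(side = "whole_plant")
    below <- base |>
      dplyr::filter(!.data$pool %in% c("leaves", "stem"))
    dplyr::bind_rows(
      above,
      below |> dplyr::mutate(side = "N_treated",
                             c_mass_g = .data$c_mass_g / 2,
                             n_mass_g = .data$n_mass_g / 2),
      below |> dplyr::mutate(side = "untreated",
                             c_mass_g = .data$c_mass_g / 2,
                             n_mass_g = .data$n_mass_g / 2)
    )
  }

  pools <- dplyr::bind_rows(
    lapply(seq_len(config$n_boxes),
           function(b) pool_rows(paste0("L", b), FALSE)),
    lapply(seq_len(config$n_control),
           function(b) pool_rows(paste0("C", b), TRUE))
  )

  # ---- PLFA peak table -------------------------------------------------
  members <- default_biomarker_groups() |>
    dplyr::filter(!.data$group %in% c("general", "bacteria_general"))
  plfa_truth <- config$plfa_truth |>
    dplyr::inner_join(members, by = "group", relationship = "many-to-many")
  acyl <- default_acyl_carbons()

  plfa_sample <- function(box, side, treatment) {
    decline <- plfa_truth$group %in% c("gram_positive", "actinobacteria") &
      side == "N_treated"
    conc <- plfa_truth$conc_per_biomarker *
      ifelse(decline, config$n_decline_factor, 1) *
      lognoise(nrow(plfa_truth), cv)
    ape <- if (treatment == "labeled") plfa_truth$true_ape else 0
    plfa_atom <- addnoise(NATURAL_13C_ATOM_PCT + ape, asd13)
    n_acyl <- acyl$acyl_carbons[match(plfa_truth$biomarker, acyl$biomarker)]
    fame_atom <- (n_acyl * plfa_atom + NATURAL_13C_ATOM_PCT) / (n_acyl + 1)
    tibble::tibble(
      sample_id = paste(box, side, plfa_truth$pool, sep = "_"),
      box_id = box, side = side, pool = plfa_truth$pool,
      treatment = treatment,
      biomarker = plfa_truth$biomarker,
      peak_area = conc * config$soil_dw_g / config$istd_amount_ug *
        config$istd_area,
      istd_area = config$istd_area,
      soil_dw_g = config$soil_dw_g,
      fame_atom_pct_13c = fame_atom
    )
  }

  plfa <- dplyr::bind_rows(
    lapply(seq_len(config$n_boxes), function(b) dplyr::bind_rows(
      plfa_sample(paste0("L", b), "N_treated", "labeled"),
      plfa_sample(paste0("L", b), "untreated", "labeled"))),
    lapply(seq_len(config$n_control), function(b) dplyr::bind_rows(
      plfa_sample(paste0("C", b), "N_treated", "control"),
      plfa_sample(paste0("C", b), "untreated", "control")))
  )

  # ---- CFE extract pairs ----------------------------------------------
  cfe_sample <- function(box, side, treatment) {
    tr <- config$cfe_truth
    labeled <- treatment == "labeled"
    doc_u <- tr$doc * lognoise(3, cv)
    cmic <- tr$cmic * lognoise(3, cv)
    tdn_u <- tr$tdn * lognoise(3, cv)
    nmic <- tr$nmic * lognoise(3, cv)
    ape_doc <- if (labeled) tr$ape_13c_doc else 0
    ape_mic <- if (labeled) tr$ape_13c_mic else 0
    atom_u <- addnoise(NATURAL_13C_ATOM_PCT + ape_doc, asd13)
    tibble::tibble(
      sample_id = paste(box, side, tr$pool, sep = "_"),
      box_id = box, side = side, pool = tr$pool, treatment = treatment,
      doc_unfumigated = doc_u, doc_fumigated = doc_u + cmic,
      tdn_unfumigated = tdn_u, tdn_fumigated = tdn_u + nmic,
      atom_pct_13c_unfumigated = atom_u,
      atom_pct_13c_fumigated = addnoise(atom_u + ape_mic, asd13)
    )
  }

  cfe <- dplyr::bind_rows(
    lapply(seq_len(config$n_boxes), function(b) dplyr::bind_rows(
      cfe_sample(paste0("L", b), "N_treated", "labeled"),
      cfe_sample(paste0("L", b), "untreated", "labeled"))),
    lapply(seq_len(config$n_control), function(b) dplyr::bind_rows(
      cfe_sample(paste0("C", b), "N_treated", "control"),
      cfe_sample(paste0("C", b), "untreated", "control")))
  )

  truth <- list(
    seed = seed,
    allocation_13c = config$allocation_13c,
    allocation_15n = config$allocation_15n,
    total_13c_excess_mg = config$total_13c_excess_mg,
    total_15n_excess_ug = config$total_15n_excess_ug,
    plfa_truth = config$plfa_truth,
    cfe_truth = config$cfe_truth,
    n_decline_factor = config$n_decline_factor,
    natural_13c = NATURAL_13C_ATOM_PCT,
    natural_15n = NATURAL_15N_ATOM_PCT
  )
  list(pools = pools, plfa = plfa, cfe = cfe, truth = truth)
}
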