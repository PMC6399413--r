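# Synthetic NanoSIMS scenes: a hypha with surface-attached microbial cells,
# rendered as per-pixel, per-cycle Poisson ion counts with known ground
# truth.

#' Specification of a synthetic ion-count scene
#'
#' Describes a simple hypha-plus-cells geometry: a horizontal tube (the
#' hypha) across the raster, elliptical cells on its surface, and a sparse
#' background. Each region carries a true atom% 13C and 15N, a total
#' carbon-ion count rate, and relative N/C and P/C levels; counts are drawn
#' per pixel per cycle as independent Poisson variates. Defaults reflect a
#' labeled-hypha scene: lumen at 2.0 atom% 13C / 0.50 atom% 15N, attached
#' cells at 1.3 atom% 13C / 0.44 atom% 15N, background at natural
#' abundance, with cells showing elevated N/C and P/C (the biomass
#' signature used to delineate cell ROIs).
#'
#' @param raster Image edge length in pixels (square raster).
#' @param n_cycles Number of scan cycles.
#' @param dwell_time_s Dwell time per pixel per cycle, seconds.
#' @param raster_um Physical raster size, micrometres.
#' @param hypha_atom_pct_13c,hypha_atom_pct_15n True hypha composition.
#' @param cell_atom_pct_13c,cell_atom_pct_15n True attached-cell
#'   composition.
#' @param background_atom_pct_13c,background_atom_pct_15n Background
#'   (natural abundance by default).
#' @param c_rate_hypha,c_rate_cell,c_rate_background Total carbon-ion
#'   counts per pixel per cycle by region.
#' @param dimer_rate_factor C2 dimer event rate as a fraction of the atomic
#'   carbon rate.
#' @param nc_rel_hypha,nc_rel_cell,nc_rel_background Relative N/C level
#'   (CN-ion rate = level x carbon rate).
#' @param pc_rel_hypha,pc_rel_cell,pc_rel_background Relative P/C level.
#' @param n_cells Number of attached cells.
#'
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(raster = 64,
                       n_cycles = 19,
                       dwell_time_s = 0.02,
                       raster_um = 40,
                       hypha_atom_pct_13c = 2.0,
                       hypha_atom_pct_15n = 0.50,
                       cell_atom_pct_13c = 1.3,
                       cell_atom_pct_15n = 0.44,
                       background_atom_pct_13c = NATURAL_13C_ATOM_PCT,
                       background_atom_pct_15n = NATURAL_15N_ATOM_PCT,
                       c_rate_hypha = 60,
                       c_rate_cell = 80,
                       c_rate_background = 4,
                       dimer_rate_factor = 0.5,
                       nc_rel_hypha = 0.4,
                       nc_rel_cell = 1.0,
                       nc_rel_background = 0.1,
                       pc_rel_hypha = 0.05,
                       pc_rel_cell = 0.25,
                       pc_rel_background = 0.01,
                       n_cells = 3) {
  spec <- mget(names(formals()))
  aps <- c(hypha_atom_pct_13c, hypha_atom_pct_15n, cell_atom_pct_13c,
           cell_atom_pct_15n, background_atom_pct_13c,
           background_atom_pct_15n)
  if (any(aps < 0 | aps > 100)) abort("Region atom%% must lie in [0, 100].")
  rates <- c(c_rate_hypha, c_rate_cell, c_rate_background,
             dimer_rate_factor, nc_rel_hypha, nc_rel_cell,
             nc_rel_background, pc_rel_hypha, pc_rel_cell,
             pc_rel_background)
  if (any(rates < 0)) abort("Count rates must be >= 0.")
  structure(spec, class = "scene_spec")
}

scene_region_masks <- function(spec) {
  n <- spec$raster
  region <- matrix(0L, n, n)  # 0 background
  # hypha: horizontal tube through the middle, ~1/4 of the raster high
  half_w <- max(2L, round(n / 8))
  mid <- round(n / 2)
  region[(mid - half_w):(mid + half_w), ] <- 1L
  # cells: ellipses sitting on the upper tube surface
  centres_x <- round(seq(0.2, 0.8, length.out = spec$n_cells) * n)
  cell_ry <- max(2L, round(n / 16))
  cell_rx <- max(2L, round(n / 12))
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (k in seq_len(spec$n_cells)) {
    cy <- mid - half_w - cell_ry + 1L
    inside <- ((rows - cy) / cell_ry)^2 + ((cols - centres_x[k]) / cell_rx)^2 <= 1
    region[inside] <- 1L + k
  }
  region
}

#' Simulate a NanoSIMS ion-count stack from a scene specification
#'
#' Renders the scene geometry, then draws each channel's per-pixel,
#' per-cycle counts as independent Poisson variates whose means follow the
#' region composition: for true 13C atom fraction f and carbon rate r,
#' the 13C- rate is `f r` and the 12C- rate `(1 - f) r`; C2 dimer species
#' follow binomial pairing of two carbon atoms, `(1 - f)^2` and
#' `2 f (1 - f)` of the dimer event rate — which makes the dimer ratio
#' `x / (2a + x)` an unbiased estimator of f and lets the monomer and dimer
#' estimators cross-validate. CN species follow the 15N fraction at the
#' region's relative N/C level, and 31P the relative P/C level.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer RNG seed.
#' @return List: `stack` (an [ion_count_stack()]), `region_mask` (integer
#'   matrix; 0 background, 1 hypha, 2+ cells), `regions` (tibble of true
#'   per-region compositions and rates).
#' @export
simulate_ion_stack <- function(spec = scene_spec(), seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  region <- scene_region_masks(spec)
  n <- spec$raster

  region_tab <- tibble::tibble(
    region_id = c(0L, 1L, seq_len(spec$n_cells) + 1L),
    name = c("background", "hypha", paste0("cell_", seq_len(spec$n_cells))),
    atom_pct_13c = c(spec$background_atom_pct_13c, spec$hypha_atom_pct_13c,
                     rep(spec$cell_atom_pct_13c, spec$n_cells)),
    atom_pct_15n = c(spec$background_atom_pct_15n, spec$hypha_atom_pct_15n,
                     rep(spec$cell_atom_pct_15n, spec$n_cells)),
    c_rate = c(spec$c_rate_background, spec$c_rate_hypha,
               rep(spec$c_rate_cell, spec$n_cells)),
    nc_rel = c(spec$nc_rel_background, spec$nc_rel_hypha,
               rep(spec$nc_rel_cell, spec$n_cells)),
    pc_rel = c(spec$pc_rel_background, spec$pc_rel_hypha,
               rep(spec$pc_rel_cell, spec$n_cells))
  )

  idx <- match(as.vector(region), region_tab$region_id)
  f13 <- region_tab$atom_pct_13c[idx] / 100
  f15 <- region_tab$atom_pct_15n[idx] / 100
  c_rate <- region_tab$c_rate[idx]
  cn_rate <- c_rate * region_tab$nc_rel[idx]
  p_rate <- c_rate * region_tab$pc_rel[idx]
  dimer_rate <- c_rate * spec$dimer_rate_factor

  rates <- list(
    C12 = (1 - f13) * c_rate,
    C13 = f13 * c_rate,
    C12C12 = (1 - f13)^2 * dimer_rate,
    C12C13 = 2 * f13 * (1 - f13) * dimer_rate,
    C12N14 = (1 - f15) * cn_rate,
    C12N15 = f15 * cn_rate,
    P31 = p_rate
  )
  channels <- lapply(rates, function(mu) {
    draws <- rpois(n * n * spec$n_cycles, rep(mu, spec$n_cycles))
    array(as.integer(draws), dim = c(n, n, spec$n_cycles))
  })

  stack <- ion_count_stack(channels, dwell_time_s = spec$dwell_time_s,
                           raster_um = spec$raster_um)
  list(stack = stack, region_mask = region, regions = region_tab)
}
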