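test_that("the experiment generator is seed-deterministic", {
  cfg <- experiment_config(n_boxes = 2, n_control = 1)
  a <- simulate_experiment(cfg, seed = 42)
  b <- simulate_experiment(cfg, seed = 42)
  c <- simulate_experiment(cfg, seed = 43)
  expect_identical(a$pools, b$pools)
  expect_identical(a$plfa, b$plfa)
  expect_identical(a$cfe, b$cfe)
  expect_false(identical(a$pools$atom_pct_13c, c$pools$atom_pct_13c))
})

test_that("noise-free simulation recovers the allocation fractions exactly", {
  cfg <- experiment_config(noise_cv = 0, noise_sd_delta = 0,
                           n_boxes = 3, n_control = 2)
  sim <- simulate_experiment(cfg, seed = 1)
  rep <- pipeline_report(sim$pools, sim$plfa, sim$cfe)
  tab <- rep$budget_table
  by_pool <- setNames(tab$pct_13c, as.character(tab$pool))
  expect_equal(by_pool[names(cfg$allocation_13c)] / 100,
               cfg$allocation_13c, tolerance = 1e-9)
  by_pool_n <- setNames(tab$pct_15n, as.character(tab$pool))
  expect_equal(by_pool_n[names(cfg$allocation_15n)] / 100,
               cfg$allocation_15n, tolerance = 1e-9)
})

test_that("the N-addition decline appears in the programmed groups", {
  cfg <- experiment_config(noise_cv = 0.05, n_boxes = 6)
  sim <- simulate_experiment(cfg, seed = 3)
  groups <- plfa_sip_summary(sim$plfa,
                             istd_amount_ug = cfg$istd_amount_ug)$groups
  wide <- groups |>
    dplyr::filter(group %in% c("gram_positive", "actinobacteria")) |>
    tidyr::pivot_wider(id_cols = c("pool", "group"),
                       names_from = "side",
                       values_from = "biomass_ugC_per_g")
  expect_true(all(wide$N_treated < wide$untreated))
})

test_that("ion scenes draw integer Poisson counts at the programmed rates", {
  spec <- scene_spec(raster = 40, n_cycles = 30)
  sc <- simulate_ion_stack(spec, seed = 6)
  for (arr in sc$stack$channels) {
    expect_true(all(arr >= 0))
    expect_type(arr, "integer")
  }
  # channel means converge to the specified rates within Poisson error
  hypha <- sc$region_mask == 1L
  c_tot <- (accumulate(sc$stack)$C12 + accumulate(sc$stack)$C13) /
    sc$stack$n_cycles
  expect_equal(mean(c_tot[hypha]), spec$c_rate_hypha, tolerance = 0.02)
  bg <- sc$region_mask == 0L
  expect_equal(mean(c_tot[bg]), spec$c_rate_background, tolerance = 0.05)

  # identical seeds give identical stacks
  sc2 <- simulate_ion_stack(spec, seed = 6)
  expect_identical(sc$stack$channels, sc2$stack$channels)
})

test_that("a zero-13C scene yields identically zero carbon fraction maps", {
  spec <- scene_spec(raster = 24, n_cycles = 3, hypha_atom_pct_13c = 0,
                     cell_atom_pct_13c = 0, background_atom_pct_13c = 0)
  sc <- simulate_ion_stack(spec, seed = 8)
  acc <- accumulate(sc$stack)
  cf <- carbon_fraction_map_monomer(acc$C12, acc$C13)
  expect_true(all(cf[!is.na(cf)] == 0))
})

test_that("scene ROI estimates recover the generating composition", {
  spec <- scene_spec(raster = 48, n_cycles = 10)
  sc <- simulate_ion_stack(spec, seed = 10)
  rois <- roi_composition(sc$stack, sc$region_mask)
  hypha <- rois[rois$roi_id == 1L, ]
  expect_equal(hypha$atom_pct_13c_dimer, spec$hypha_atom_pct_13c,
               tolerance = 3 * hypha$sigma_13c_dimer /
                 spec$hypha_atom_pct_13c)
  expect_equal(hypha$atom_pct_15n, spec$hypha_atom_pct_15n,
               tolerance = 3 * hypha$sigma_15n / spec$hypha_atom_pct_15n)
  # monomer and dimer estimators agree within combined uncertainty
  expect_lt(abs(hypha$atom_pct_13c_monomer - hypha$atom_pct_13c_dimer),
            3 * sqrt(hypha$sigma_13c_monomer^2 + hypha$sigma_13c_dimer^2))
  # cells show elevated N/C and P/C relative to the hypha surface
  acc <- accumulate(sc$stack)
  nc <- relative_ratio_map(acc$C12N14 + acc$C12N15,
                           list(acc$C12, acc$C13))
  expect_gt(mean(nc[sc$region_mask == 2L], na.rm = TRUE),
            mean(nc[sc$region_mask == 1L], na.rm = TRUE))
})

test_that("invalid configurations are rejected", {
  expect_error(experiment_config(allocation_13c = c(leaves = 1)),
               "every pool")
  bad <- c(leaves = 0.5, stem = 0.2, roots = 0.2, rhizosphere_soil = 0.2,
           bulk_soil = 0.05, litter = 0.05)
  expect_error(experiment_config(allocation_13c = bad), "sum to 1")
  expect_error(experiment_config(noise_cv = -1), ">= 0")
  expect_error(scene_spec(hypha_atom_pct_13c = 101), "\\[0, 100\\]")
  expect_error(scene_spec(c_rate_hypha = -5), ">= 0")
})
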