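test_that("dose arithmetic reproduces the labeling protocol numbers", {
  dims <- c(1350, 545, 320)
  expect_identical(chamber_mixing_ratio(0, dims), 0)
  expect_equal(chamber_mixing_ratio(60, dims), 254.8, tolerance = 1e-3)
  expect_equal(chamber_mixing_ratio(235.44, dims), 1000, tolerance = 1e-6)
  expect_error(chamber_mixing_ratio(60, c(-1, 545, 320)), "> 0")

  expect_identical(dose_nitrogen_mass(0, 1), 0)
  expect_equal(dose_nitrogen_mass(12, 1), 0.168, tolerance = 1e-3)
  expect_equal(dose_nitrogen_mass(12, 2), 2 * dose_nitrogen_mass(12, 1))

  expect_equal(molar_n_concentration(54.5, 54.49), 1.00, tolerance = 1e-3)
  expect_equal(molar_n_concentration(140, 140), 1.0)
  expect_identical(molar_n_concentration(0, 99), 0)
  expect_error(molar_n_concentration(1, 0), "> 0")
})

test_that("a single labeled pool holds 100% of the budget", {
  pools <- tibble::tibble(
    box_id = "b", side = "untreated", pool = "litter",
    c_mass_g = 2, n_mass_g = 0.2, ape_13c = 0.5, ape_15n = 3
  )
  b <- build_budget(pools)
  litter <- dplyr::filter(b$summary, pool == "litter")
  expect_equal(litter$pct_13c, 100)
  expect_equal(litter$pct_15n, 100)
})

test_that("budget percentages conserve mass and are invariant to order and scale", {
  set.seed(21)
  excess_c <- runif(6, 0.1, 8)
  excess_n <- runif(6, 1, 250)
  pools <- pool_table_with_excess(excess_c, excess_n)

  b <- build_budget(pools)
  plant <- dplyr::filter(b$summary, pool == "plant_biomass")
  soil <- dplyr::filter(b$summary, pool == "soil_litter")
  expect_equal(plant$pct_13c + soil$pct_13c, 100, tolerance = 1e-9)
  expect_equal(plant$pct_15n + soil$pct_15n, 100, tolerance = 1e-9)

  shuffled <- build_budget(pools[sample(nrow(pools)), ])
  expect_equal(shuffled$summary, b$summary)

  doubled <- pools
  doubled$ape_13c <- doubled$ape_13c * 2
  doubled$ape_15n <- doubled$ape_15n * 2
  b2 <- build_budget(doubled)
  expect_equal(b2$summary$pct_13c, b$summary$pct_13c)
  expect_equal(b2$summary$pct_15n, b$summary$pct_15n)
})

test_that("multi-box summaries average per-box percentages (mean of ratios)", {
  p1 <- pool_table_with_excess(c(4, 7, 6, 1, 1.5, 0.1),
                               c(0.3, 4, 16, 13, 36, 250), box_id = "b1")
  p2 <- pool_table_with_excess(c(5, 8, 7, 0.8, 1.2, 0.05),
                               c(0.4, 3, 18, 12, 30, 260), box_id = "b2")
  b <- build_budget(dplyr::bind_rows(p1, p2))
  per_box_leaf_pct <- c(4 / sum(c(4, 7, 6, 1, 1.5, 0.1)),
                        5 / sum(c(5, 8, 7, 0.8, 1.2, 0.05))) * 100
  leaf <- dplyr::filter(b$summary, pool == "leaves")
  expect_equal(leaf$pct_13c, mean(per_box_leaf_pct))
  # ratio-of-means column differs from mean-of-ratios in general
  expect_false(isTRUE(all.equal(leaf$pct_13c, leaf$pct_13c_pooled)))
  expect_equal(dplyr::filter(b$summary, pool == "total")$pct_13c_pooled, 100)
})

test_that("pool table validation rejects malformed input", {
  pools <- pool_table_with_excess(rep(1, 6), rep(10, 6))
  expect_error(build_budget(pools[0, ]), "non-empty")
  expect_error(build_budget(dplyr::bind_rows(pools, pools[1, ])),
               "Duplicate")
  bad_side <- pools
  bad_side$side[3] <- "whole_plant"   # roots cannot span both sides
  expect_error(build_budget(bad_side), "whole_plant")
  zero <- pools
  zero$ape_13c <- 0
  expect_error(build_budget(zero), "> 0")
})

test_that("control subtraction converts absolute atom% to excess", {
  labeled <- tibble::tibble(
    box_id = "L1", side = "untreated", pool = c("litter", "bulk_soil"),
    c_mass_g = 1, n_mass_g = 1,
    atom_pct_13c = c(1.5, 1.2), atom_pct_15n = c(0.9, 0.4)
  )
  controls <- tibble::tibble(
    box_id = c("C1", "C2"), side = "untreated",
    pool = rep(c("litter", "bulk_soil"), each = 1),
    c_mass_g = 1, n_mass_g = 1,
    atom_pct_13c = c(1.1, 1.1), atom_pct_15n = c(0.37, 0.37)
  )
  out <- pool_excess_from_controls(labeled, controls)
  expect_equal(out$ape_13c, c(1.5 - 1.1, 1.2 - 1.1))
  expect_equal(out$ape_15n, c(0.9 - 0.37, 0.4 - 0.37))
})

test_that("budget_ratio expresses a sub-fraction as a share", {
  expect_equal(budget_ratio(5, 5), 100)
  expect_identical(budget_ratio(0, 4), 0)
  # litter share of all belowground 13C
  expect_equal(budget_ratio(0.36, 11.74), 3.07, tolerance = 1e-2)
  expect_error(budget_ratio(5, 4), "exceed")
  expect_error(budget_ratio(1, 0), "> 0")
})
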