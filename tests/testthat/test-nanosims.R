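test_that("accumulation sums cycles and is associative over chunks", {
  set.seed(51)
  stack <- random_small_stack(cycles = 1)
  expect_equal(accumulate(stack)$C12, stack$channels$C12[, , 1])

  zero <- ion_count_stack(list(C12 = array(0L, c(3, 3, 4))),
                          dwell_time_s = 0.02)
  expect_true(all(accumulate(zero)$C12 == 0))

  stack <- random_small_stack(cycles = 6)
  acc <- accumulate(stack)
  for (ch in names(stack$channels)) {
    oracle <- matrix(0L, 6, 5)
    arr <- stack$channels[[ch]]
    for (i in 1:6) for (j in 1:5) for (k in 1:6) {
      oracle[i, j] <- oracle[i, j] + arr[i, j, k]
    }
    expect_equal(acc[[ch]], oracle)
  }
  # chunked accumulation agrees with the full range
  chunked <- accumulate(stack, 1:3)$C13 + accumulate(stack, 4:6)$C13
  expect_equal(chunked, acc$C13)
  expect_error(accumulate(stack, integer(0)), "Empty")
  expect_error(accumulate(stack, 7), "\\[1, 6\\]")
})

test_that("isotope fraction maps implement the per-pixel count ratios", {
  c12 <- matrix(c(9889, 50, 0, 10), 2)
  c13 <- matrix(c(111, 50, 0, 0), 2)
  m <- carbon_fraction_map_monomer(c12, c13)
  expect_equal(m[1, 1], 100 * 111 / (9889 + 111), tolerance = 1e-9)
  expect_equal(round(m[1, 1], 2), 1.11)
  expect_equal(m[2, 1], 50)
  expect_true(is.na(m[1, 2]))      # zero total carbon is masked
  expect_equal(m[2, 2], 0)

  a <- matrix(c(9779, 7, 0), 1); x <- matrix(c(219, 7, 0), 1)
  d <- carbon_fraction_map_dimer(a, x)
  expect_equal(d[1, 1], 100 * 219 / (2 * 9779 + 219), tolerance = 1e-9)
  expect_equal(round(d[1, 1], 3), 1.107)
  expect_equal(d[1, 2], 100 / 3, tolerance = 1e-9)  # a = x
  expect_true(is.na(d[1, 3]))

  n14 <- matrix(9963); n15 <- matrix(37)
  expect_equal(nitrogen_fraction_map(n14, n15)[1, 1], 0.37,
               tolerance = 1e-9)
  expect_error(carbon_fraction_map_monomer(matrix(1, 2, 2), matrix(1, 3, 3)),
               "shape")
})

test_that("relative elemental ratio maps normalise by the reference signal", {
  num <- matrix(runif(12, 0, 40), 3)
  ref1 <- matrix(runif(12, 1, 60), 3); ref2 <- matrix(runif(12, 1, 60), 3)
  r <- relative_ratio_map(num, list(ref1, ref2))
  expect_equal(r, num / (ref1 + ref2))
  expect_equal(relative_ratio_map(ref1, ref1), matrix(1, 3, 4))
  z <- relative_ratio_map(matrix(0, 2, 2), matrix(c(0, 1, 2, 3), 2))
  expect_true(is.na(z[1, 1]))
  expect_equal(z[2, 1], 0)
})

test_that("intensity thresholds use count rates with >= at the boundary", {
  plane <- matrix(c(22L, 23L, 0L, 100L), 2)
  mask <- intensity_threshold_mask(plane, 60, dwell_time_s = 0.02,
                                   n_cycles = 19)
  # 60 counts/(sec*pixel) x 0.02 s x 19 cycles = 22.8 accumulated counts
  expect_false(mask[1, 1])
  expect_true(mask[2, 1])
  expect_true(all(intensity_threshold_mask(plane, 0, 0.02, 19)))
  # exact boundary passes
  exact <- matrix(10L)
  expect_true(intensity_threshold_mask(exact, 50, 0.02, 10)[1, 1])
  expect_error(intensity_threshold_mask(plane, 60, 0, 19), "> 0")

  # masking never alters the surviving pixels' values
  vals <- carbon_fraction_map_monomer(plane, plane)
  masked_vals <- vals
  masked_vals[!mask] <- NA
  expect_equal(masked_vals[mask], vals[mask])
})

test_that("ROI composition equals brute-force pixel/cycle summation", {
  set.seed(52)
  for (rep in 1:5) {
    stack <- random_small_stack(nrow = 7, ncol = 6, cycles = 4)
    mask <- random_roi_mask(7, 6, n_rois = 3)
    rois <- roi_composition(stack, mask)
    for (id in rois$roi_id) {
      oracle <- brute_force_roi(stack, mask, id)
      row <- rois[rois$roi_id == id, ]
      for (ch in names(stack$channels)) {
        expect_identical(unname(row[[paste0("counts_", ch)]]),
                         unname(oracle[[ch]]))
      }
      expect_equal(row$atom_pct_13c_monomer,
                   100 * oracle[["C13"]] / (oracle[["C12"]] + oracle[["C13"]]))
      expect_equal(row$atom_pct_15n,
                   100 * oracle[["C12N15"]] /
                     (oracle[["C12N14"]] + oracle[["C12N15"]]))
    }
  }
})

test_that("single-pixel and uniform ROIs reduce to the map value", {
  arr12 <- array(100L, c(3, 3, 2)); arr13 <- array(2L, c(3, 3, 2))
  stack <- ion_count_stack(list(C12 = arr12, C13 = arr13),
                           dwell_time_s = 0.02)
  mask <- matrix(0L, 3, 3); mask[2, 2] <- 1L
  roi <- roi_composition(stack, mask)
  acc <- accumulate(stack)
  expect_equal(roi$atom_pct_13c_monomer,
               carbon_fraction_map_monomer(acc$C12, acc$C13)[2, 2])
  # uniform ROI gives the common value; cycle-mean agrees
  full <- matrix(1L, 3, 3)
  roi_full <- roi_composition(stack, full)
  expect_equal(roi_full$atom_pct_13c_monomer, 100 * 2 / 102)
  expect_equal(roi_full$atom_pct_13c_cycle_mean, 100 * 2 / 102)
  expect_error(roi_composition(stack, matrix(0L, 3, 3)), "no labelled")
})

test_that("polygon ROIs rasterise on 0-based half-open pixel coordinates", {
  poly <- tibble::tibble(roi_id = 1L, x = c(1, 3, 3, 1), y = c(1, 1, 3, 3))
  mask <- roi_mask_from_polygons(poly, c(5, 5))
  expect_equal(sum(mask == 1L), 4)            # pixels (1,1),(1,2),(2,1),(2,2)
  expect_equal(mask[2:3, 2:3], matrix(1L, 2, 2))
  expect_true(all(mask[c(1, 4, 5), ] == 0L))
})

test_that("counting uncertainty follows Poisson propagation", {
  expect_equal(counting_uncertainty(5000, 5000), 0.5)
  # equivalent algebraic form
  a <- c(10, 500, 12000); b <- c(990, 49500, 988000)
  expect_equal(counting_uncertainty(a, b),
               100 * sqrt(a * b^2 + b * a^2) / (a + b)^2)
  # monotone decrease with total counts at fixed fraction
  s1 <- counting_uncertainty(10, 990)
  s2 <- counting_uncertainty(100, 9900)
  s3 <- counting_uncertainty(1000, 99000)
  expect_true(s1 > s2 && s2 > s3)
  expect_error(counting_uncertainty(0, 0), "> 0")

  # Monte-Carlo Poisson resampling reproduces sigma within 5%
  set.seed(53)
  a0 <- 220; b0 <- 19780
  sims <- replicate(20000, {
    aa <- rpois(1, a0); bb <- rpois(1, b0)
    100 * aa / (aa + bb)
  })
  expect_equal(sd(sims), counting_uncertainty(a0, b0), tolerance = 0.05)
})

test_that("enrichment test flags labeled ROIs against the control", {
  set.seed(54)
  same <- rnorm(12, 1.08, 0.03)
  null <- enrichment_test(same, same)
  expect_gt(null$p_value, 0.9)
  expect_false(null$significant)

  # hypha ROI regime: control near 1.08, labeled ROIs at 1.5+
  control <- rnorm(10, 1.08, 0.02)
  labeled <- rnorm(10, 1.9, 0.3)
  labeled <- pmax(labeled, 1.5)
  et <- enrichment_test(labeled, control)
  expect_lt(et$p_value, 0.001)
  expect_true(et$significant)
  expect_true(all(c(et$ks_p_labeled, et$ks_p_control) > 0))

  # Welch statistic agrees with the hand formula
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7,
         23.2, 17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 24.0, 13.2)
  et2 <- enrichment_test(x, y)
  se2 <- var(x) / 10 + var(y) / 20
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 10)^2 / 9 + (var(y) / 20)^2 / 19)
  expect_equal(et2$t, t_hand)
  expect_equal(et2$df, df_hand)

  # degenerate zero-variance convention
  deg <- enrichment_test(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_equal(enrichment_test(c(3, 3), c(2, 2))$p_value, 0)
})

test_that("stacks round-trip through multi-page TIFF plus JSON sidecar", {
  set.seed(55)
  stack <- random_small_stack(nrow = 8, ncol = 8, cycles = 3, lambda = 40)
  dir <- withr::local_tempdir()
  write_ion_stack(stack, dir)
  expect_true(file.exists(file.path(dir, "stack.json")))
  back <- read_ion_stack(dir)
  expect_identical(back$channels, stack$channels)
  expect_equal(back$dwell_time_s, stack$dwell_time_s)
  expect_equal(back$n_cycles, stack$n_cycles)

  big <- ion_count_stack(list(C12 = array(70000L, c(2, 2, 1))),
                         dwell_time_s = 0.02)
  expect_error(write_ion_stack(big, dir), "16-bit")
})

test_that("stack construction validates counts and geometry", {
  expect_error(ion_count_stack(list(C12 = array(-1L, c(2, 2, 1))),
                               dwell_time_s = 0.02), "non-negative")
  expect_error(ion_count_stack(list(C12 = array(1.5, c(2, 2, 1))),
                               dwell_time_s = 0.02), "integer")
  expect_error(ion_count_stack(list(C12 = array(1L, c(2, 2, 2)),
                                    C13 = array(1L, c(3, 3, 2))),
                               dwell_time_s = 0.02), "share")
  expect_error(ion_count_stack(list(XX = array(1L, c(2, 2, 1))),
                               dwell_time_s = 0.02), "Unknown")
})
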