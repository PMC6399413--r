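test_that("internal-standard quantification follows the area-ratio model", {
  expect_equal(quantify_from_internal_standard(1000, 1000, 10, 2), 5)
  expect_identical(quantify_from_internal_standard(0, 1000, 10, 2), 0)
  set.seed(31)
  pa <- runif(40, 0, 5e4); ia <- runif(40, 1e3, 1e5)
  amt <- runif(40, 5, 20); dw <- runif(40, 0.5, 5)
  expect_equal(quantify_from_internal_standard(pa, ia, amt, dw),
               pa / ia * amt / dw)
  expect_error(quantify_from_internal_standard(10, 0, 10, 2), "> 0")
})

test_that("methanolysis correction removes the methanol methyl carbon", {
  # fixed point: FAME at the methanol signature is unchanged
  expect_equal(as.numeric(methanolysis_correction(1.08, 16, 1.08)), 1.08)
  expect_equal(as.numeric(methanolysis_correction(2.0, 16, 1.08)), 2.0575)
  nat <- ratio_to_atom_percent(std_vpdb()$ratio)
  expect_equal(as.numeric(methanolysis_correction(nat, 18, nat)), nat)

  # forward mixing model inverts the correction to 1e-10
  set.seed(32)
  plfa <- runif(30, 0.5, 5); n <- sample(14:20, 30, replace = TRUE)
  meth <- 1.08
  fame <- (n * plfa + meth) / (n + 1)
  expect_equal(as.numeric(methanolysis_correction(fame, n, meth)), plfa,
               tolerance = 1e-10)

  # out-of-range results are flagged, not clamped
  expect_warning(out <- methanolysis_correction(0.01, 2, 50), "flagged")
  expect_true(attr(out, "flagged"))
  expect_lt(as.numeric(out), 0)
})

test_that("biomarkers map to their diagnostic groups with omega normalization", {
  recs <- tibble::tibble(biomarker = c("i15:0", "10Me17:0", "18:2ω6,9",
                                       "cy19:0", "17:0", "cis18:1w9",
                                       "16:1w5", "16:0"))
  out <- assign_groups(recs)
  expect_equal(out$group,
               c("gram_positive", "actinobacteria", "fungi_18_2w69",
                 "gram_negative", "bacteria_general", "fungi_18_1w9",
                 "gram_negative", "general"))
  expect_warning(unk <- assign_groups(tibble::tibble(biomarker = "20:0")),
                 "Unassigned")
  expect_equal(unk$group, "unassigned")

  # composite bacterial pool = three diagnostic groups plus 17:0
  bact <- group_members(out, "bacteria_general")
  expect_setequal(bact$biomarker,
                  c("i15:0", "10Me17:0", "cy19:0", "17:0", "16:1w5"))
})

test_that("group enrichment is the abundance-weighted mean of member APEs", {
  expect_equal(weighted_group_enrichment(0.42, 3), 0.42)
  expect_equal(weighted_group_enrichment(c(0.2, 0.4), c(1, 1)), 0.3)
  set.seed(33)
  for (i in 1:20) {
    ape <- rnorm(6, 0.3, 0.2); w <- runif(6, 0, 10)
    expect_equal(weighted_group_enrichment(ape, w), sum(ape * w) / sum(w))
    # convexity: bounded by member extremes
    est <- weighted_group_enrichment(ape, w)
    expect_gte(est, min(ape) - 1e-12)
    expect_lte(est, max(ape) + 1e-12)
  }
  expect_error(weighted_group_enrichment(c(1, 2), c(0, 0)), "> 0")
})

test_that("group 13C mass matches the enrichment x biomass identity", {
  expect_identical(group_13c_mass(c(0, 0), c(10, 20)), 0)
  expect_equal(group_13c_mass(1, 100), 1)
  set.seed(34)
  ape <- runif(5, 0, 2); conc <- runif(5, 1, 50)
  expect_equal(group_13c_mass(ape, conc), sum(conc * ape / 100))
  # algebraic identity with the sample-weighted enrichment
  expect_equal(group_13c_mass(ape, conc),
               weighted_group_enrichment(ape, conc) * sum(conc) / 100)
})

test_that("noise-free synthetic PLFA data recovers the generating group APEs", {
  cfg <- experiment_config(noise_cv = 0, noise_sd_delta = 0, n_boxes = 2,
                           n_control = 2)
  sim <- simulate_experiment(cfg, seed = 5)
  out <- plfa_sip_summary(sim$plfa, istd_amount_ug = cfg$istd_amount_ug)
  recovered <- out$groups |>
    dplyr::inner_join(cfg$plfa_truth, by = c("pool", "group"))
  expect_equal(recovered$ape_13c, recovered$true_ape, tolerance = 1e-8)
})
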