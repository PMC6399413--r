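# Shared fixture builders. Everything is generated in code; no binary data.

# a pool table whose per-pool 13C/15N excess masses equal the supplied
# values (unit element masses, APE chosen so mass x APE reproduces them)
pool_table_with_excess <- function(excess_13c_mg, excess_15n_ug,
                                   box_id = "b1") {
  pools <- c("leaves", "stem", "roots",
             "rhizosphere_soil", "bulk_soil", "litter")
  tibble::tibble(
    box_id = box_id,
    side = ifelse(pools %in% c("leaves", "stem"), "whole_plant",
                  "untreated"),
    pool = pools,
    c_mass_g = 1,
    n_mass_g = 1,
    ape_13c = excess_13c_mg / 10,            # mass 1 g: excess = 10 * ape
    ape_15n = excess_15n_ug / 1000 / 10
  )
}

# tiny random ion stack over all channels with a matching random ROI mask
random_small_stack <- function(nrow = 6, ncol = 5, cycles = 3,
                               lambda = 8) {
  chans <- c("C12", "C13", "C12C12", "C12C13", "C12N14", "C12N15", "P31")
  channels <- lapply(setNames(chans, chans), function(ch) {
    array(rpois(nrow * ncol * cycles, lambda), dim = c(nrow, ncol, cycles))
  })
  ion_count_stack(channels, dwell_time_s = 0.02)
}

random_roi_mask <- function(nrow, ncol, n_rois = 2) {
  mask <- matrix(sample(0:n_rois, nrow * ncol, replace = TRUE), nrow, ncol)
  if (!any(mask > 0)) mask[1, 1] <- 1L
  storage.mode(mask) <- "integer"
  mask
}

# brute-force ROI composition oracle: explicit loops over pixels and cycles
brute_force_roi <- function(stack, mask, roi_id) {
  counts <- sapply(names(stack$channels), function(ch) {
    total <- 0
    arr <- stack$channels[[ch]]
    for (i in seq_len(nrow(mask))) {
      for (j in seq_len(ncol(mask))) {
        if (mask[i, j] == roi_id) {
          for (k in seq_len(stack$n_cycles)) total <- total + arr[i, j, k]
        }
      }
    }
    total
  })
  counts
}
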