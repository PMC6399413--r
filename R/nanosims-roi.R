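# ROI statistics on ion-count stacks: pooled compositions with Poisson
# counting uncertainties, per-cycle series, and enrichment tests against a
# natural-abundance control.

#' ROI label mask helpers
#'
#' An ROI mask is an integer matrix of the stack's raster size: 0 marks
#' background, positive integers label disjoint regions of interest.
#' `roi_mask_from_polygons()` rasterises a polygon table (columns `roi_id`,
#' `x`, `y`; 0-based pixel coordinates, origin top-left, half-open raster
#' bounds) by even-odd point-in-polygon testing at pixel centres.
#'
#' @param polygons Data frame of polygon vertices with columns `roi_id`,
#'   `x`, `y` (vertex order defines the ring).
#' @param dim Raster size `c(rows, cols)`.
#' @return Integer label matrix.
#' @export
roi_mask_from_polygons <- function(polygons, dim) {
  stopifnot(all(c("roi_id", "x", "y") %in% names(polygons)))
  mask <- matrix(0L, nrow = dim[1], ncol = dim[2])
  # pixel centres in 0-based image coordinates: x = col - 0.5, y = row - 0.5
  px <- rep(seq_len(dim[2]) - 0.5, each = dim[1])
  py <- rep(seq_len(dim[1]) - 0.5, times = dim[2])
  for (id in unique(polygons$roi_id)) {
    ring <- polygons[polygons$roi_id == id, ]
    vx <- ring$x; vy <- ring$y
    n <- length(vx)
    inside <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- xor(inside, crosses)
      j <- i
    }
    if (any(mask[inside] != 0L)) abort("ROI polygons overlap.")
    mask[inside] <- as.integer(id)
  }
  mask
}

validate_roi_mask <- function(mask, stack) {
  if (!is.matrix(mask) || !identical(dim(mask), as.integer(stack$dim))) {
    abort("ROI mask must be a matrix matching the stack raster size.")
  }
  if (any(mask < 0) || any(mask != round(mask))) {
    abort("ROI labels must be non-negative integers.")
  }
  if (!any(mask > 0)) abort("ROI mask contains no labelled pixels.")
  invisible(mask)
}

#' Poisson counting uncertainty of an isotope fraction
#'
#' For a fraction estimate f = a / (a + b) from heavy-isotope counts a and
#' light-isotope counts b, independent Poisson counting noise propagates to
#' `sigma_f = sqrt(a b^2 + b a^2) / (a + b)^2 = sqrt(f (1 - f) / (a + b))`
#' (in fraction units; x100 for atom%). The dimer estimator
#' f = x / (2a + x) has `sigma_f = 2 sqrt(a x (a + x)) / (2a + x)^2`
#' (`counting_uncertainty_dimer()`).
#'
#' @param a Heavy-isotope counts (or mixed-dimer counts `x` for the dimer
#'   form), `>= 0`.
#' @param b Light-isotope counts, `>= 0`, with `a + b > 0`.
#' @return 1-sigma uncertainty of the atom% estimate.
#' @examples
#' counting_uncertainty(5000, 5000)  # 0.5 atom%
#' @export
counting_uncertainty <- function(a, b) {
  check_finite_numeric(a, "a")
  check_finite_numeric(b, "b")
  if (any(a < 0) || any(b < 0)) abort("Counts must be >= 0.")
  if (any(a + b == 0)) abort("Total counts must be > 0.")
  f <- a / (a + b)
  100 * sqrt(f * (1 - f) / (a + b))
}

#' @rdname counting_uncertainty
#' @param x Mixed-dimer (12C13C) counts for the dimer estimator.
#' @param a_dimer Unmixed-dimer (12C12C) counts.
#' @export
counting_uncertainty_dimer <- function(x, a_dimer) {
  check_finite_numeric(x, "x")
  check_finite_numeric(a_dimer, "a_dimer")
  if (any(x < 0) || any(a_dimer < 0)) abort("Counts must be >= 0.")
  den <- 2 * a_dimer + x
  if (any(den == 0)) abort("Total counts must be > 0.")
  100 * 2 * sqrt(a_dimer * x * (a_dimer + x)) / den^2
}

#' ROI compositions from an ion-count stack
#'
#' Pools ion counts over each ROI's pixels and the selected cycles, then
#' forms isotope ratios from the pooled (accumulated) counts — the
#' count-weighted estimator, not a mean of per-pixel ratios. Carbon atom%
#' 13C is computed from both the atomic-ion pair (monomer) and the C2 dimer
#' pair when the channels are present; nitrogen atom% 15N from the CN pair.
#' 1-sigma Poisson counting uncertainties accompany every estimate. A
#' per-cycle series (pooled within each cycle) and its across-cycle mean —
#' the cycle-averaging convention used for boxplot summaries of multilayer
#' stacks — are returned alongside.
#'
#' @param stack An [ion_count_stack()].
#' @param mask Integer ROI label matrix (0 = background), or a polygon
#'   table accepted by [roi_mask_from_polygons()].
#' @param cycles Cycle indices to pool (default: all).
#' @param pixel_filter Optional logical matrix; pixels where it is `FALSE`
#'   (e.g. below an intensity threshold) are excluded from all ROIs.
#'
#' @return Tibble with one row per ROI: `roi_id`, `n_pixels`, pooled counts
#'   per channel (`counts_<channel>`), `atom_pct_13c_monomer` /
#'   `sigma_13c_monomer`, `atom_pct_13c_dimer` / `sigma_13c_dimer`,
#'   `atom_pct_15n` / `sigma_15n`, and cycle-mean estimators
#'   `atom_pct_13c_cycle_mean`, `atom_pct_15n_cycle_mean`. The per-cycle
#'   series is attached as attribute `"cycle_series"`.
#' @export
roi_composition <- function(stack, mask, cycles = NULL, pixel_filter = NULL) {
  stopifnot(inherits(stack, "ion_stack"))
  if (is.data.frame(mask)) mask <- roi_mask_from_polygons(mask, stack$dim)
  storage.mode(mask) <- "integer"
  validate_roi_mask(mask, stack)
  cycles <- resolve_cycles(stack, cycles)
  if (!is.null(pixel_filter)) {
    if (!identical(dim(pixel_filter), dim(mask))) {
      abort("`pixel_filter` must match the raster size.")
    }
    mask[!pixel_filter] <- 0L
    if (!any(mask > 0)) abort("No ROI pixels survive the pixel filter.")
  }

  roi_ids <- sort(unique(mask[mask > 0L]))
  chans <- names(stack$channels)

  per_roi <- lapply(roi_ids, function(id) {
    sel <- mask == id
    if (!any(sel)) abort(sprintf("ROI %d is empty.", id))
    # pooled counts per channel and per-cycle pooled counts
    pooled <- numeric(length(chans))
    names(pooled) <- chans
    per_cycle <- matrix(0, nrow = length(cycles), ncol = length(chans),
                        dimnames = list(NULL, chans))
    for (ch in chans) {
      arr <- stack$channels[[ch]]
      for (k in seq_along(cycles)) {
        per_cycle[k, ch] <- sum(arr[, , cycles[k]][sel])
      }
      pooled[ch] <- sum(per_cycle[, ch])
    }

    ratio_or_na <- function(num, den) {
      if (den > 0) unname(100 * num / den) else NA_real_
    }

    has <- function(...) all(c(...) %in% chans)
    row <- tibble::tibble(roi_id = id, n_pixels = sum(sel))
    for (ch in chans) row[[paste0("counts_", ch)]] <- unname(pooled[ch])

    cyc <- tibble::tibble(roi_id = id, cycle = cycles)
    if (has("C12", "C13")) {
      row$atom_pct_13c_monomer <-
        ratio_or_na(pooled["C13"], pooled["C12"] + pooled["C13"])
      row$sigma_13c_monomer <- unname(counting_uncertainty(pooled["C13"],
                                                           pooled["C12"]))
      cyc$atom_pct_13c_monomer <-
        100 * per_cycle[, "C13"] / (per_cycle[, "C12"] + per_cycle[, "C13"])
    }
    if (has("C12C12", "C12C13")) {
      row$atom_pct_13c_dimer <-
        ratio_or_na(pooled["C12C13"],
                    2 * pooled["C12C12"] + pooled["C12C13"])
      row$sigma_13c_dimer <- unname(counting_uncertainty_dimer(
        pooled["C12C13"], pooled["C12C12"]))
      cyc$atom_pct_13c_dimer <- 100 * per_cycle[, "C12C13"] /
        (2 * per_cycle[, "C12C12"] + per_cycle[, "C12C13"])
      row$atom_pct_13c_cycle_mean <- mean(cyc$atom_pct_13c_dimer, na.rm = TRUE)
    } else if (has("C12", "C13")) {
      row$atom_pct_13c_cycle_mean <- mean(cyc$atom_pct_13c_monomer,
                                          na.rm = TRUE)
    }
    if (has("C12N14", "C12N15")) {
      row$atom_pct_15n <-
        ratio_or_na(pooled["C12N15"], pooled["C12N14"] + pooled["C12N15"])
      row$sigma_15n <- unname(counting_uncertainty(pooled["C12N15"],
                                                   pooled["C12N14"]))
      cyc$atom_pct_15n <- 100 * per_cycle[, "C12N15"] /
        (per_cycle[, "C12N14"] + per_cycle[, "C12N15"])
      row$atom_pct_15n_cycle_mean <- mean(cyc$atom_pct_15n, na.rm = TRUE)
    }
    list(row = row, cyc = cyc)
  })

  out <- dplyr::bind_rows(lapply(per_roi, `[[`, "row"))
  attr(out, "cycle_series") <- dplyr::bind_rows(lapply(per_roi, `[[`, "cyc"))
  out
}

#' Test ROI enrichment against a natural-abundance control
#'
#' Compares labeled-sample ROI values (atom% 13C or 15N) to control ROI
#' values with a two-sided Welch t-test; each group is additionally checked
#' for consistency with a normal distribution by a Kolmogorov-Smirnov test
#' against a normal with the group's estimated mean and sd. Significance of
#' enrichment is flagged at the conventional reporting threshold
#' `p < 0.001`.
#'
#' When both groups have zero variance the Welch statistic is undefined;
#' the limiting convention used is p = 1 if the group means are equal and
#' p = 0 otherwise, with `degenerate = TRUE` in the result.
#'
#' @param labeled,control Numeric vectors of per-ROI atom% values, length
#'   `>= 2` each.
#' @param signif_level Significance threshold for the `significant` flag.
#'
#' @return Object of class `enrichment_test` (a one-row tibble):
#'   group sizes and means, mean difference, Welch `t`, `df`, `p_value`,
#'   per-group KS normality p-values, `significant`, `degenerate`.
#' @export
enrichment_test <- function(labeled, control, signif_level = 0.001) {
  check_finite_numeric(labeled, "labeled")
  check_finite_numeric(control, "control")
  if (length(labeled) < 2L || length(control) < 2L) {
    abort("Need at least 2 values per group.")
  }

  ks_normal_p <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }

  degenerate <- sd(labeled) == 0 && sd(control) == 0
  if (degenerate) {
    p <- if (mean(labeled) == mean(control)) 1 else 0
    t_stat <- NA_real_
    df <- NA_real_
  } else {
    tt <- t.test(labeled, control, var.equal = FALSE)
    p <- tt$p.value
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
  }

  out <- tibble::tibble(
    n_labeled = length(labeled),
    n_control = length(control),
    mean_labeled = mean(labeled),
    mean_control = mean(control),
    difference = mean(labeled) - mean(control),
    t = t_stat,
    df = df,
    p_value = p,
    ks_p_labeled = ks_normal_p(labeled),
    ks_p_control = ks_normal_p(control),
    significant = p < signif_level,
    degenerate = degenerate
  )
  class(out) <- c("enrichment_test", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.enrichment_test <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.enrichment_test <- function(x, ...) {
  tibble::tibble(difference = x$difference, p_value = x$p_value,
                 significant = x$significant)
}
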