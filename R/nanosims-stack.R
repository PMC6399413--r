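# Multilayer NanoSIMS ion-count stacks: container, TIFF/JSON persistence,
# accumulation, per-pixel isotope-fraction and elemental-ratio maps, and
# intensity threshold masks.

ION_CHANNELS <- c("C12", "C13", "C12C12", "C12C13",
                  "C12N14", "C12N15", "P31", "SE")

#' Ion-count image stack
#'
#' Container for a multilayer secondary-ion acquisition: for each detected
#' mass channel, an ordered set of per-cycle 2D count planes of identical
#' raster size, together with acquisition metadata. Counts are non-negative
#' integers (ion arrivals per pixel per cycle).
#'
#' @param channels Named list of 3D integer arrays with dimensions
#'   `c(rows, cols, cycles)`; names from
#'   `C12, C13, C12C12, C12C13, C12N14, C12N15, P31, SE`. 2D matrices are
#'   promoted to single-cycle stacks.
#' @param dwell_time_s Dwell time per pixel per cycle, seconds, `> 0`.
#' @param raster_um Physical raster edge length, micrometres.
#'
#' @return Object of class `ion_stack` with elements `channels`,
#'   `dwell_time_s`, `raster_um`, `n_cycles`, `dim` (rows, cols).
#' @export
ion_count_stack <- function(channels, dwell_time_s, raster_um = NA_real_) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    abort("`channels` must be a named list of count arrays.")
  }
  bad <- setdiff(names(channels), ION_CHANNELS)
  if (length(bad)) {
    abort(paste0("Unknown channel(s): ", paste(bad, collapse = ", ")))
  }
  channels <- lapply(channels, function(x) {
    if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
    if (!is.array(x) || length(dim(x)) != 3L) {
      abort("Each channel must be a matrix or 3D array (rows x cols x cycles).")
    }
    if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
      abort("Ion counts must be non-negative integers.")
    }
    storage.mode(x) <- "integer"
    x
  })
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) {
    abort("All channels must share raster dimensions and cycle count.")
  }
  if (dims[[1]][3] < 1L) abort("Cycle count must be >= 1.")
  if (!is.numeric(dwell_time_s) || dwell_time_s <= 0) {
    abort("`dwell_time_s` must be > 0.")
  }
  structure(list(
    channels = channels,
    dwell_time_s = as.numeric(dwell_time_s),
    raster_um = as.numeric(raster_um),
    n_cycles = dims[[1]][3],
    dim = dims[[1]][1:2]
  ), class = "ion_stack")
}

#' @export
print.ion_stack <- function(x, ...) {
  cat(sprintf(
    "<ion_stack> %d x %d px, %d cycle(s), dwell %.4g s, channels: %s\n",
    x$dim[1], x$dim[2], x$n_cycles, x$dwell_time_s,
    paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write / read an ion stack as multi-page TIFFs with a JSON sidecar
#'
#' Each mass channel is stored as one multi-page 16-bit TIFF (one page per
#' cycle) under `<dir>/<channel>.tif`; acquisition metadata goes to
#' `<dir>/stack.json`. Counts above 65535 per pixel per cycle are rejected
#' (beyond 16-bit storage; split cycles instead). The round trip preserves
#' counts exactly.
#'
#' @param stack An [ion_count_stack()].
#' @param dir Directory to write to (created if needed) / read from.
#' @return `write_ion_stack()` returns `dir` invisibly; `read_ion_stack()`
#'   returns the reconstructed `ion_stack`.
#' @export
write_ion_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "ion_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(stack$channels)) {
    planes <- stack$channels[[ch]]
    if (any(planes > 65535L)) {
      abort("Counts exceed 16-bit TIFF storage (65535 per pixel per cycle).")
    }
    pages <- lapply(seq_len(dim(planes)[3]),
                    function(k) planes[, , k] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L)
  }
  meta <- list(
    channels = names(stack$channels),
    dwell_time_s = stack$dwell_time_s,
    raster_um = if (is.na(stack$raster_um)) NULL else stack$raster_um,
    n_cycles = stack$n_cycles,
    raster_px = as.integer(stack$dim)
  )
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ion_stack
#' @export
read_ion_stack <- function(dir) {
  meta_path <- file.path(dir, "stack.json")
  if (!file.exists(meta_path)) {
    abort(paste0("No stack.json sidecar found in ", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- lapply(setNames(meta$channels, meta$channels), function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")),
                            all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    arr
  })
  raster_um <- meta$raster_um
  if (is.null(raster_um) || !is.numeric(raster_um)) raster_um <- NA_real_
  ion_count_stack(channels, dwell_time_s = meta$dwell_time_s,
                  raster_um = raster_um)
}

resolve_cycles <- function(stack, cycles) {
  if (is.null(cycles)) cycles <- seq_len(stack$n_cycles)
  cycles <- as.integer(cycles)
  if (length(cycles) == 0L) abort("Empty cycle range.")
  if (any(cycles < 1L | cycles > stack$n_cycles)) {
    abort(sprintf("Cycles must lie in [1, %d].", stack$n_cycles))
  }
  cycles
}

#' Accumulate per-cycle count planes
#'
#' Element-wise integer sum of the selected cycles for every channel,
#' producing one accumulated count plane per channel (the z-stack
#' accumulation used for display and thresholding).
#'
#' @param stack An [ion_count_stack()].
#' @param cycles Integer vector of cycle indices (default: all).
#' @return Named list of integer matrices.
#' @export
accumulate <- function(stack, cycles = NULL) {
  stopifnot(inherits(stack, "ion_stack"))
  cycles <- resolve_cycles(stack, cycles)
  lapply(stack$channels, function(arr) {
    out <- arr[, , cycles[1], drop = TRUE]
    if (length(cycles) > 1L) {
      for (k in cycles[-1]) out <- out + arr[, , k, drop = TRUE]
    }
    matrix(as.integer(out), nrow = dim(arr)[1])
  })
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("Plane shapes must match.")
}

#' Per-pixel isotope fraction and relative elemental-ratio maps
#'
#' `carbon_fraction_map_monomer()` computes atom% 13C from the atomic
#' carbon secondary ions as `100 * 13C / (12C + 13C)`;
#' `carbon_fraction_map_dimer()` uses the C2 dimer species as
#' `100 * 12C13C / (2 * 12C12C + 12C13C)` (one 13C atom per mixed dimer,
#' two carbon atoms per dimer); `nitrogen_fraction_map()` computes atom%
#' 15N from the CN species as `100 * 12C15N / (12C14N + 12C15N)`.
#' `relative_ratio_map()` forms reference-normalised elemental maps such as
#' (P/C)rel = 31P / (12C + 13C), in arbitrary units. Pixels whose
#' denominator is zero are undefined and returned as `NA`, never imputed.
#'
#' @param c12_plane,c13_plane,c12c12_plane,c12c13_plane,c12n14_plane,
#'   c12n15_plane Accumulated count matrices for the respective channels.
#' @param numerator_plane Count matrix for the numerator species.
#' @param reference_planes A count matrix or list of matrices summed into
#'   the reference signal.
#' @return Numeric matrix (atom% or arbitrary units) with `NA` at masked
#'   pixels.
#' @export
carbon_fraction_map_monomer <- function(c12_plane, c13_plane) {
  check_same_shape(c12_plane, c13_plane)
  tot <- c12_plane + c13_plane
  out <- 100 * c13_plane / tot
  out[tot == 0] <- NA_real_
  out
}

#' @rdname carbon_fraction_map_monomer
#' @export
carbon_fraction_map_dimer <- function(c12c12_plane, c12c13_plane) {
  check_same_shape(c12c12_plane, c12c13_plane)
  den <- 2 * c12c12_plane + c12c13_plane
  out <- 100 * c12c13_plane / den
  out[den == 0] <- NA_real_
  out
}

#' @rdname carbon_fraction_map_monomer
#' @export
nitrogen_fraction_map <- function(c12n14_plane, c12n15_plane) {
  check_same_shape(c12n14_plane, c12n15_plane)
  tot <- c12n14_plane + c12n15_plane
  out <- 100 * c12n15_plane / tot
  out[tot == 0] <- NA_real_
  out
}

#' @rdname carbon_fraction_map_monomer
#' @export
relative_ratio_map <- function(numerator_plane, reference_planes) {
  if (is.matrix(reference_planes)) reference_planes <- list(reference_planes)
  ref <- Reduce(`+`, reference_planes)
  check_same_shape(numerator_plane, ref)
  out <- numerator_plane / ref
  out[ref == 0] <- NA_real_
  out
}

#' Intensity threshold mask on accumulated counts
#'
#' Converts accumulated counts to a count rate per pixel,
#' `counts / (dwell_time * n_cycles)`, and keeps pixels at or above the
#' threshold (the `>=` convention holds at the boundary). Pixels failing
#' the threshold are excluded from displayed maps and ROI statistics.
#'
#' @param accumulated_plane Accumulated count matrix.
#' @param threshold Threshold in counts per second per pixel, `>= 0`.
#' @param dwell_time_s Dwell time per pixel per cycle, seconds, `> 0`.
#' @param n_cycles Number of accumulated cycles, `>= 1`.
#' @return Logical matrix, `TRUE` where the pixel passes.
#' @examples
#' plane <- matrix(c(10L, 30L), 1)
#' intensity_threshold_mask(plane, 60, dwell_time_s = 0.02, n_cycles = 19)
#' @export
intensity_threshold_mask <- function(accumulated_plane, threshold,
                                     dwell_time_s, n_cycles) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  if (dwell_time_s <= 0 || n_cycles <= 0) {
    abort("`dwell_time_s` and `n_cycles` must be > 0.")
  }
  accumulated_plane / (dwell_time_s * n_cycles) >= threshold
}

#' Write an atom percent map as 32-bit float TIFF
#'
#' `NA` (masked) pixels are written as the sentinel value -1 (atom% is
#' non-negative); readers restore them to `NA`.
#'
#' @param map Numeric matrix (atom% or a.u.).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fraction_map <- function(map, path) {
  map[is.na(map)] <- -1
  tiff::writeTIFF(map / 100, path, bits.per.sample = 32L)
  invisible(path)
}
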