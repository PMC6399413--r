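# Analysis of similarities (ANOSIM) on a dissimilarity matrix, with a
# seeded permutation test.

#' ANOSIM: analysis of similarities
#'
#' Ranks all pairwise dissimilarities and compares mean between-group rank
#' to mean within-group rank: `R = (rB - rW) / (M / 2)` with
#' `M = n (n - 1) / 2`, so `R` lies in `[-1, 1]` and is near 0 when group
#' labels carry no structure. Significance comes from a label-permutation
#' test, `p = (1 + #[R_perm >= R_obs]) / (1 + n_perm)`; the same seed gives
#' the identical p-value. Groups with a single member contribute no
#' within-group pairs and are effectively excluded from the within-group
#' mean (their between-group pairs still count).
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param groups Group labels, one per observation; `>= 2` distinct groups.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation draw; `NULL` leaves the RNG
#'   state untouched.
#' @param exact Enumerate all distinct label permutations instead of
#'   sampling (feasible for small n; the observed labeling counts once in
#'   the numerator and denominator).
#'
#' @return Object of class `anosim_fit`: list with `statistic` (R),
#'   `p_value`, `n_perm`, `perm_stats`. `tidy()`/`glance()` return one-row
#'   tibbles.
#' @examples
#' m <- matrix(c(0, 0, 5, 5, 0.2, 0, 5.2, 5), ncol = 2)
#' fit <- anosim(dist(m), c("a", "a", "b", "b"), n_perm = 99, seed = 1)
#' fit$statistic
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL, exact = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12)) {
    abort("`d` must be a symmetric dissimilarity matrix.")
  }
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n) abort("One group label per observation required.")
  if (nlevels(droplevels(groups)) < 2L) abort("Need >= 2 groups.")

  low <- lower.tri(d)
  rank_d <- rank(d[low])
  M <- n * (n - 1) / 2

  same_group <- function(g) {
    outer(g, g, `==`)[low]
  }
  r_stat <- function(g) {
    within <- same_group(g)
    if (!any(within) || all(within)) return(NA_real_)
    (mean(rank_d[!within]) - mean(rank_d[within])) / (M / 2)
  }

  r_obs <- r_stat(groups)
  if (is.na(r_obs)) abort("Grouping yields no within- or no between-group pairs.")

  if (exact) {
    perms <- unique_label_permutations(groups)
    perm_stats <- vapply(perms, r_stat, numeric(1))
    perm_stats <- perm_stats[!is.na(perm_stats)]
    # observed labeling is one of the enumerated permutations
    p <- mean(perm_stats >= r_obs - 1e-12)
    n_perm <- length(perm_stats)
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
          assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    perm_stats <- vapply(seq_len(n_perm),
                         function(i) r_stat(sample(groups)), numeric(1))
    perm_stats <- perm_stats[!is.na(perm_stats)]
    p <- (1 + sum(perm_stats >= r_obs - 1e-12)) / (1 + length(perm_stats))
  }

  structure(list(statistic = r_obs, p_value = p, n_perm = n_perm,
                 perm_stats = perm_stats),
            class = "anosim_fit")
}

# all distinct assignments of the multiset of labels to positions
unique_label_permutations <- function(groups) {
  n <- length(groups)
  if (n > 9L) abort("Exact enumeration limited to n <= 9 observations.")
  idx_perms <- permutations_of(seq_len(n))
  labelings <- unique(lapply(idx_perms, function(p) as.character(groups[p])))
  lapply(labelings, factor)
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(p) c(v[i], p)))
  }
  out
}

#' @export
print.anosim_fit <- function(x, ...) {
  cat(sprintf("<anosim_fit> R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anosim_fit <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_perm = x$n_perm)
}

#' @exportS3Method generics::glance
glance.anosim_fit <- function(x, ...) tidy(x)

#' Bray-Curtis dissimilarity of a sample x variable abundance matrix
#'
#' Thin wrapper over [vegan::vegdist()], the community-ecology default for
#' abundance data and the default input to [anosim()].
#'
#' @param x Non-negative abundance matrix (rows = samples).
#' @param method Dissimilarity index passed to [vegan::vegdist()].
#' @return A `dist` object.
#' @export
community_dissimilarity <- function(x, method = "bray") {
  if (any(as.matrix(x) < 0)) abort("Abundance entries must be non-negative.")
  vegan::vegdist(as.matrix(x), method = method)
}
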