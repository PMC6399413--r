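# Rank-based group comparisons: Mann-Whitney U (paired and unpaired),
# Kruskal-Wallis, and Dunn's post-hoc z tests with Bonferroni control.

#' Mann-Whitney U test (with a paired-sample variant)
#'
#' Unpaired mode is the two-sided Mann-Whitney U test with mid-rank
#' handling of ties; p-values are exact for small untied samples and use
#' the tie-corrected normal approximation otherwise (via
#' [stats::wilcox.test()], whose W statistic is the U statistic). Because
#' the two sides of a split-root box share one plant and violate
#' independence, the paired mode applies the Wilcoxon signed-rank test to
#' within-pair differences. An exact sign-permutation test on the pair
#' differences is available as `paired_method = "sign_permutation"`
#' (enumerates all `2^n` sign assignments of the mean difference for
#' `n <= 20`).
#'
#' When every observation is tied (all pairwise differences zero) the test
#' carries no information and the conventional p = 1 is returned.
#'
#' @param x,y Numeric observation vectors; equal length in paired mode.
#' @param paired Compare as matched pairs.
#' @param paired_method `"signed_rank"` (default) or `"sign_permutation"`.
#'
#' @return One-row tibble: `statistic` (U, or V / mean difference in paired
#'   modes), `p_value`, `method`, `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))       # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, paired = FALSE,
                           paired_method = c("signed_rank",
                                             "sign_permutation")) {
  paired_method <- match.arg(paired_method)
  check_finite_numeric(x, "x")
  check_finite_numeric(y, "y")
  if (length(x) < 2L || length(y) < 2L) {
    abort("Need at least 2 observations per sample.")
  }
  if (paired && length(x) != length(y)) {
    abort("Paired mode requires equal-length samples.")
  }

  if (!paired) {
    if (all(c(x, y) == c(x, y)[1])) {
      return(tibble::tibble(statistic = length(x) * length(y) / 2,
                            p_value = 1, method = "mann_whitney_u",
                            n_x = length(x), n_y = length(y)))
    }
    wt <- suppressWarnings(wilcox.test(x, y, paired = FALSE, exact = NULL,
                                       correct = TRUE))
    return(tibble::tibble(statistic = unname(wt$statistic),
                          p_value = wt$p.value, method = "mann_whitney_u",
                          n_x = length(x), n_y = length(y)))
  }

  d <- x - y
  if (all(d == 0)) {
    return(tibble::tibble(statistic = 0, p_value = 1,
                          method = paste0("paired_", paired_method),
                          n_x = length(x), n_y = length(y)))
  }
  if (paired_method == "signed_rank") {
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                   method = "paired_signed_rank",
                   n_x = length(x), n_y = length(y))
  } else {
    n <- length(d)
    if (n > 20L) abort("Exact sign permutation limited to n <= 20 pairs.")
    obs <- abs(mean(d))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- abs(signs %*% abs(d)) / n
    p <- mean(perm >= obs - 1e-12)
    tibble::tibble(statistic = mean(d), p_value = p,
                   method = "paired_sign_permutation",
                   n_x = n, n_y = n)
  }
}

#' Kruskal-Wallis rank sum test across pools
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p-value (via
#' [stats::kruskal.test()]).
#'
#' @param values Numeric observations.
#' @param groups Group labels (factor or character), `>= 2` levels with
#'   `>= 2` observations each.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(values, groups) {
  check_finite_numeric(values, "values")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) {
    abort("Kruskal-Wallis needs at least 2 groups.")
  }
  if (any(table(droplevels(groups)) < 2L)) {
    abort("Every group needs at least 2 observations.")
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 n_groups = nlevels(droplevels(groups)))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' Follows a significant Kruskal-Wallis test: pairwise z statistics on mean
#' ranks of the pooled sample with the standard tie correction,
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Raw two-sided
#' p-values are multiplied by the number of comparisons (Bonferroni) and
#' capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @return Tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @export
dunn_bonferroni <- function(values, groups) {
  check_finite_numeric(values, "values")
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) abort("Need at least 2 groups.")
  n <- table(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p_raw <- 2 * pnorm(-abs(z))
    tibble::tibble(group1 = g1, group2 = g2, z = z, p_raw = p_raw,
                   p_adjusted = min(1, p_raw * m))
  })
  dplyr::bind_rows(out)
}

#' Compact letter display from an adjusted p-value matrix
#'
#' Assigns lowercase letters to groups so that two groups share a letter
#' exactly when their pairwise comparison is not significant at `alpha` —
#' the usual annotation above grouped bar plots. Uses the insert-and-absorb
#' algorithm over the significance graph.
#'
#' @param comparisons Output of [dunn_bonferroni()] (columns `group1`,
#'   `group2`, `p_adjusted`).
#' @param alpha Significance threshold for the display.
#' @return Tibble `group`, `letters`.
#' @export
significance_letters <- function(comparisons, alpha = 0.05) {
  groups <- sort(unique(c(comparisons$group1, comparisons$group2)))
  differs <- matrix(FALSE, length(groups), length(groups),
                    dimnames = list(groups, groups))
  for (i in seq_len(nrow(comparisons))) {
    if (comparisons$p_adjusted[i] < alpha) {
      differs[comparisons$group1[i], comparisons$group2[i]] <- TRUE
      differs[comparisons$group2[i], comparisons$group1[i]] <- TRUE
    }
  }
  # each letter = a maximal set of mutually non-different groups
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(differs[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # drop sets fully contained in another (absorption)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  lab <- vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letters = unname(lab))
}
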