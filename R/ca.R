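# Correspondence analysis by singular value decomposition of the
# chi-square standardized residual matrix.

#' Correspondence analysis of a non-negative sample x variable matrix
#'
#' Decomposes the chi-square standardized residuals of the relative
#' frequency table `P = X / sum(X)`: with row masses r and column masses c,
#' `S = diag(r)^(-1/2) (P - r c') diag(c)^(-1/2)` is factored by SVD and
#' row/column scores are returned in principal coordinates
#' (`F = diag(r)^(-1/2) U D`, `G = diag(c)^(-1/2) V D`). Squared singular
#' values are the per-axis inertias; their fractions of the total inertia
#' are the "variance explained" labels placed on ordination axes. Scores
#' have weighted mean zero on every axis, and chi-square distances between
#' row profiles equal Euclidean distances between full row scores.
#'
#' Axis signs are arbitrary in the decomposition; they are fixed here by
#' the convention that the column with the largest absolute loading on each
#' axis is positive.
#'
#' @param x Non-negative numeric matrix or data frame (rows = samples,
#'   columns = variables) with a positive grand total and no all-zero rows
#'   or columns.
#'
#' @return Object of class `ca_fit`: list with `row_scores`, `col_scores`
#'   (principal coordinates, axes as columns), `inertia` (per-axis),
#'   `inertia_fraction`, `total_inertia`, `row_mass`, `col_mass`.
#'   `tidy()` returns a long tibble of scores; `glance()` the axis summary.
#' @examples
#' m <- matrix(c(10, 2, 1, 8, 3, 9), nrow = 2)
#' correspondence_analysis(m)
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("Matrix entries must be non-negative.")
  if (sum(x) <= 0) abort("Matrix grand total must be > 0.")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("All-zero rows or columns cannot be ordinated; drop them first.")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("col", seq_len(ncol(x)))

  P <- x / sum(x)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  dec <- svd(S)

  tol <- max(dim(x)) * max(dec$d) * .Machine$double.eps * 100
  naxes <- sum(dec$d > max(tol, 1e-12))
  naxes <- min(naxes, min(dim(x)) - 1L)
  if (naxes < 1L) {
    # independence model fits exactly: no axes, zero inertia
    out <- structure(list(
      row_scores = matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL)),
      col_scores = matrix(0, ncol(x), 0, dimnames = list(colnames(x), NULL)),
      inertia = numeric(0), inertia_fraction = numeric(0),
      total_inertia = 0, row_mass = r, col_mass = cm), class = "ca_fit")
    return(out)
  }

  d <- dec$d[seq_len(naxes)]
  U <- dec$u[, seq_len(naxes), drop = FALSE]
  V <- dec$v[, seq_len(naxes), drop = FALSE]

  # sign convention: largest-|loading| column positive on each axis
  for (j in seq_len(naxes)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }

  F_scores <- diag(1 / sqrt(r)) %*% U %*% diag(d, naxes)
  G_scores <- diag(1 / sqrt(cm)) %*% V %*% diag(d, naxes)
  dimnames(F_scores) <- list(rownames(x), paste0("CA", seq_len(naxes)))
  dimnames(G_scores) <- list(colnames(x), paste0("CA", seq_len(naxes)))

  inertia <- d^2
  structure(list(
    row_scores = F_scores,
    col_scores = G_scores,
    inertia = inertia,
    inertia_fraction = inertia / sum(inertia),
    total_inertia = sum(inertia),
    row_mass = r,
    col_mass = cm
  ), class = "ca_fit")
}

#' @export
print.ca_fit <- function(x, ...) {
  cat(sprintf("<ca_fit> %d axes, total inertia %.5g\n",
              length(x$inertia), x$total_inertia))
  if (length(x$inertia)) {
    cat("variance explained (%):",
        paste(sprintf("%.1f", 100 * x$inertia_fraction), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ca_fit <- function(x, ...) {
  as_long <- function(m, type) {
    if (ncol(m) == 0L) return(NULL)
    tibble::as_tibble(m, rownames = "label") |>
      dplyr::mutate(type = type, .before = 1) |>
      tidyr::pivot_longer(-c("type", "label"),
                          names_to = "axis", values_to = "score")
  }
  dplyr::bind_rows(as_long(x$row_scores, "row"),
                   as_long(x$col_scores, "column"))
}

#' @exportS3Method generics::glance
glance.ca_fit <- function(x, ...) {
  tibble::tibble(
    n_axes = length(x$inertia),
    total_inertia = x$total_inertia,
    axis1_pct = if (length(x$inertia)) 100 * x$inertia_fraction[1] else NA_real_,
    axis2_pct = if (length(x$inertia) > 1) 100 * x$inertia_fraction[2]
                else NA_real_
  )
}

#' Chi-square distances between row profiles
#'
#' Direct computation of the chi-square distance
#' `d(i, i')^2 = sum_j (p_ij/r_i - p_i'j/r_i')^2 / c_j`, the metric that
#' correspondence-analysis row scores reproduce as Euclidean distance.
#' Mainly useful for verifying an ordination.
#'
#' @inheritParams correspondence_analysis
#' @return A `dist` object over rows.
#' @export
chi_square_distances <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  P <- x / sum(x)
  profiles <- P / rowSums(P)
  cm <- colSums(P)
  scaled <- profiles %*% diag(1 / sqrt(cm))
  rownames(scaled) <- rownames(x)
  stats::dist(scaled)
}
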