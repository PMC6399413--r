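test_that("correspondence analysis recovers chi-square geometry", {
  set.seed(71)
  x <- matrix(rpois(48, 12) + 1, nrow = 8)
  ca <- correspondence_analysis(x)
  # inertia fractions: non-negative, ordered, sum to 1
  expect_true(all(ca$inertia_fraction >= 0))
  expect_true(all(diff(ca$inertia) <= 1e-12))
  expect_equal(sum(ca$inertia_fraction), 1, tolerance = 1e-10)
  # row scores reproduce chi-square distances between row profiles
  expect_equal(as.matrix(dist(ca$row_scores)),
               as.matrix(chi_square_distances(x)), tolerance = 1e-9)
  # weighted means of scores vanish on every axis
  expect_equal(colSums(ca$row_scores * ca$row_mass),
               setNames(rep(0, ncol(ca$row_scores)),
                        colnames(ca$row_scores)), tolerance = 1e-12)
  # total inertia equals the chi-square statistic / grand total
  expect_equal(ca$total_inertia,
               unname(suppressWarnings(
                 stats::chisq.test(x)$statistic)) / sum(x),
               tolerance = 1e-10)
})

test_that("correspondence analysis cross-checks against vegan", {
  skip_if_not_installed("vegan")
  set.seed(72)
  x <- matrix(rpois(40, 9) + 1, nrow = 8)
  ca <- correspondence_analysis(x)
  vca <- vegan::cca(x)
  expect_equal(ca$inertia, unname(vca$CA$eig), tolerance = 1e-9)
})

test_that("degenerate matrices yield the documented edge behavior", {
  # rank-1 outer product: independence model exact, zero inertia
  rank1 <- outer(c(1, 2, 4), c(3, 5))
  ca1 <- correspondence_analysis(rank1)
  expect_equal(ca1$total_inertia, 0)
  expect_equal(length(ca1$inertia), 0)
  # 2x2 contingency table: one axis carrying all inertia
  ca2 <- correspondence_analysis(matrix(c(10, 2, 3, 9), 2))
  expect_equal(length(ca2$inertia), 1)
  expect_equal(ca2$inertia_fraction, 1)
  expect_error(correspondence_analysis(matrix(c(1, -1, 2, 3), 2)),
               "non-negative")
  expect_error(correspondence_analysis(matrix(c(0, 0, 2, 3), 2,
                                              byrow = TRUE)), "zero")
})

test_that("axis signs follow the largest-loading convention", {
  set.seed(73)
  x <- matrix(rpois(30, 10) + 1, nrow = 6)
  ca <- correspondence_analysis(x)
  for (j in seq_along(ca$inertia)) {
    expect_gt(ca$col_scores[which.max(abs(ca$col_scores[, j])), j], 0)
  }
})

test_that("ANOSIM separates structured groups and bounds R in [-1, 1]", {
  # perfectly separated: all between-distances exceed all within-distances
  m <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  fit <- anosim(dist(m), rep(c("a", "b"), each = 4), n_perm = 99, seed = 2)
  expect_equal(fit$statistic, 1)
  expect_true(fit$statistic >= -1 && fit$statistic <= 1)
  expect_gt(fit$p_value, 0)
  expect_lte(fit$p_value, 1)

  # identical seeds reproduce identical p-values
  set.seed(74)
  m2 <- matrix(runif(40), 8)
  g2 <- rep(c("a", "b"), 4)
  f1 <- anosim(dist(m2), g2, n_perm = 199, seed = 7)
  f2 <- anosim(dist(m2), g2, n_perm = 199, seed = 7)
  expect_identical(f1$p_value, f2$p_value)
})

test_that("ANOSIM R agrees with vegan and exact p with brute force", {
  skip_if_not_installed("vegan")
  set.seed(75)
  m <- matrix(runif(24), 6)
  g <- rep(c("a", "b"), each = 3)
  d <- community_dissimilarity(m)
  fit <- anosim(d, g, n_perm = 199, seed = 1)
  vfit <- vegan::anosim(d, g, permutations = 199)
  expect_equal(fit$statistic, unname(vfit$statistic), tolerance = 1e-12)

  # tiny instance: exact p from the package vs test-side enumeration
  m4 <- matrix(c(0.1, 0.2, 3.0, 3.3, 0.15, 0.25, 3.1, 3.2), ncol = 2)
  g4 <- c("a", "a", "b", "b")
  ex <- anosim(dist(m4), g4, exact = TRUE)
  dm <- as.matrix(dist(m4))
  low <- lower.tri(dm)
  rk <- rank(dm[low])
  M <- 6
  r_of <- function(lab) {
    w <- outer(lab, lab, `==`)[low]
    (mean(rk[!w]) - mean(rk[w])) / (M / 2)
  }
  # enumerate all 4!/(2!2!) = 6 distinct labelings
  combos <- utils::combn(4, 2)
  stats <- apply(combos, 2, function(idx) {
    lab <- rep("b", 4); lab[idx] <- "a"
    r_of(lab)
  })
  p_oracle <- mean(stats >= ex$statistic - 1e-12)
  expect_equal(ex$p_value, p_oracle)
  expect_equal(ex$statistic, r_of(g4))
})
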