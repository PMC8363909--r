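test_that("valid-value filter applies the per-group 2/3 rule", {
  g <- grouped_matrix(NA_real_, 3, c(A = 6, B = 6))
  m <- g$mat
  m[1, 1:4] <- 1          # 4/6 valid in A: boundary case, kept
  m[2, c(1:3, 7:9)] <- 1  # 3/6 in both groups: removed
  m[3, 7:12] <- 1         # 6/6 in B: kept
  out <- filter_valid(m, g$groups)
  expect_identical(rownames(out), c("f001", "f003"))

  # random matrices agree with an exhaustive per-feature oracle
  set.seed(21)
  for (rep_i in 1:5) {
    gg <- grouped_matrix(ifelse(stats::runif(50 * 9) < 0.4, NA, 1), 50,
                         c(A = 4, B = 5))
    keep_oracle <- vapply(seq_len(50), function(i) {
      a <- mean(!is.na(gg$mat[i, 1:4])); b <- mean(!is.na(gg$mat[i, 5:9]))
      a >= 2 / 3 - 1e-9 || b >= 2 / 3 - 1e-9
    }, logical(1))
    expect_identical(rownames(filter_valid(gg$mat, gg$groups)),
                     rownames(gg$mat)[keep_oracle])
  }
})

test_that("imputation draws from the down-shifted column distribution", {
  g <- grouped_matrix(stats::rnorm(100 * 6, 25, 2), 100, c(A = 3, B = 3))
  m <- g$mat
  expect_identical(impute_missing(m, seed = 1), m)  # nothing missing

  m[1, 1] <- NA
  i1 <- impute_missing(m, seed = 42)
  expect_identical(i1, impute_missing(m, seed = 42))
  expect_false(identical(i1[1, 1], impute_missing(m, seed = 43)[1, 1]))
  # down-shifted: imputed value sits below the column mean of observed values
  expect_lt(i1[1, 1], mean(m[, 1], na.rm = TRUE))
  # observed cells untouched
  expect_identical(i1[-1, ], m[-1, ])

  # downshift 0, width 1: imputed cells reproduce the column moments
  big <- matrix(stats::rnorm(2e4, 20, 3), ncol = 2,
                dimnames = list(NULL, c("s1", "s2")))
  holes <- big
  holes[sample(length(holes), 1e4)] <- NA
  imp <- impute_missing(holes, width = 1, downshift = 0, seed = 7)
  filled <- imp[is.na(holes)]
  expect_lt(abs(mean(filled) - 20), 4 * 3 / sqrt(length(filled)))
  expect_lt(abs(stats::sd(filled) - 3), 0.15)
})

test_that("moderated t matches the classical t at s0 = 0 and shrinks with s0", {
  expect_equal(moderated_t(c(1, 2, 3), c(1, 2, 3), s0 = 0.1), 0)
  t0 <- moderated_t(c(1, 2, 3), c(4, 5, 6), s0 = 0)
  expect_equal(t0, -3.674, tolerance = 1e-3)
  expect_equal(t0, unname(stats::t.test(c(1, 2, 3), c(4, 5, 6),
                                        var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  expect_lt(abs(moderated_t(c(1, 2, 3), c(4, 5, 6), s0 = 0.1)), abs(t0))
  expect_error(moderated_t(c(1, 1), c(2, 2), s0 = 0), "zero pooled variance")
  # monotone: increasing s0 never increases |t|
  set.seed(2)
  a <- stats::rnorm(5); b <- stats::rnorm(5)
  ts <- vapply(c(0, 0.05, 0.1, 0.5, 1), function(s) abs(moderated_t(a, b, s)),
               numeric(1))
  expect_true(all(diff(ts) <= 1e-12))
})

test_that("permutation FDR is symmetric, monotone and enumeration-consistent", {
  g <- grouped_matrix(stats::rnorm(200 * 6), 200, c(A = 3, B = 3))
  set.seed(31)
  g$mat[1:10, 1:3] <- g$mat[1:10, 1:3] + 4
  suppressWarnings({
    r_ab <- permutation_fdr(g$mat, g$groups, "A", "B", seed = 1)
    r_ba <- permutation_fdr(g$mat, g$groups, "B", "A", seed = 1)
  })
  expect_equal(r_ab$t_s0, -r_ba$t_s0, tolerance = 1e-12)
  expect_equal(r_ab$q, r_ba$q, tolerance = 1e-12)
  # q non-decreasing when ordered by decreasing |t|
  ord <- order(-abs(r_ab$t_s0))
  expect_true(all(diff(r_ab$q[ord]) >= -1e-12))
  # requesting many sampled permutations on a 3v3 design still enumerates
  # all 20 distinct splits, so results are identical
  suppressWarnings({
    r_s <- permutation_fdr(g$mat, g$groups, "A", "B", n_permutations = 10000,
                           seed = 99)
  })
  expect_equal(r_ab$q, r_s$q, tolerance = 1e-12)
  expect_true(attr(r_ab, "exhaustive"))
  # the planted block clearly separates from the null features
  expect_gt(mean(abs(r_ab$t_s0[1:10])), 3 * mean(abs(r_ab$t_s0[-(1:10)])))
  expect_lt(mean(r_ab$q[1:10]), mean(r_ab$q[-(1:10)]))
})

test_that("correlation summary handles pairs, groups and rank methods", {
  g <- grouped_matrix(stats::rnorm(50 * 4, 20, 2), 50, c(A = 2, B = 2))
  m <- g$mat
  m[, 2] <- m[, 1]                    # duplicated sample
  m[, 4] <- -m[, 3]                   # anti-correlated pair
  cs <- correlation_summary(m, g$groups)
  expect_equal(cs$matrix["A1", "A2"], 1)
  expect_equal(cs$matrix["B1", "B2"], -1)
  expect_true(isSymmetric(cs$matrix))
  expect_equal(unname(diag(cs$matrix)), rep(1, 4))
  # spearman equals Pearson on ranks (brute-force oracle)
  cs_sp <- correlation_summary(m, g$groups, method = "spearman")
  expect_equal(cs_sp$matrix["A1", "B1"],
               stats::cor(rank(m[, 1]), rank(m[, 3])), tolerance = 1e-12)
  # pairs with < 3 shared features are flagged missing
  m2 <- m; m2[3:50, 1] <- NA
  expect_true(is.na(correlation_summary(m2, g$groups)$matrix["A1", "B1"]))
})

test_that("PCA scores match an eigendecomposition oracle", {
  # collinear data: one component carries all variance
  base <- stats::rnorm(30)
  m <- cbind(s1 = base, s2 = 2 * base, s3 = 3 * base)
  p <- pca_scores(m)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  # four samples lying in the affine hull of three profiles: after centering
  # exactly two components carry variance
  a <- base; b <- stats::rnorm(30); cc <- stats::rnorm(30)
  m2 <- cbind(s1 = a, s2 = b, s3 = cc, s4 = (a + b + cc) / 3)
  expect_equal(sum(pca_scores(m2)$explained > 1e-12), 2)
  # random matrix: scores equal projections onto covariance eigenvectors
  set.seed(5)
  m3 <- matrix(stats::rnorm(40 * 5), 40, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  p3 <- pca_scores(m3)
  xc <- scale(t(m3), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))
  for (k in 1:4) {
    expect_lt(min(max(abs(p3$scores[, k] - xc %*% ev$vectors[, k])),
                  max(abs(p3$scores[, k] + xc %*% ev$vectors[, k]))), 1e-8)
  }
})

test_that("hierarchical clustering respects distances and input order", {
  m <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 2, 3, 4), s3 = c(9, 1, 4, 0))
  tr <- hcluster(m, "manhattan", "average")
  expect_equal(tr$height[1], 0)  # identical samples merge first at height 0
  expect_identical(sort(tr$merge[1, ]), c(-2L, -1L))
  # three points with an obvious pair: topology matches the exhaustive answer
  tr2 <- hcluster(m, "one_minus_pearson", "ward")
  expect_true(all(sort(tr2$merge[1, ]) == c(-2, -1)))
  # permutation invariance of the topology
  perm <- m[, c(3, 1, 2)]
  trp <- hcluster(perm, "manhattan", "average")
  nm <- c("s1", "s2", "s3")
  expect_equal(as.matrix(stats::cophenetic(trp))[nm, nm],
               as.matrix(stats::cophenetic(tr))[nm, nm], tolerance = 1e-12)
  # constant item under Pearson distance is flagged and maximally distant
  mc <- cbind(s1 = c(1, 1, 1, 1), s2 = c(1, 2, 3, 4), s3 = c(4, 3, 2, 1))
  expect_warning(hcluster(mc, "one_minus_pearson", "average"), "constant")
})

test_that("difference density integrates to one and resolves planted modes", {
  a <- stats::rnorm(500, 25, 1)
  dd0 <- difference_density(a, a)
  expect_lt(abs(sum(diff(dd0$x) * (head(dd0$y, -1) + tail(dd0$y, -1)) / 2) - 1),
            1e-3)
  expect_lt(abs(dd0$x[which.max(dd0$y)]), dd0$bw)
  # bimodal planted differences give two clear modes
  set.seed(8)
  b <- a + c(stats::rnorm(250, -3, 0.3), stats::rnorm(250, 3, 0.3))
  dd <- difference_density(b, a)
  y <- dd$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  expect_equal(sum(y[peaks] > max(y) / 4), 2)
  expect_error(difference_density(1:3, 4:6), "at least 5")
})

test_that("z-score series standardizes and degrades gracefully", {
  z <- zscore_series(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_warning(z0 <- zscore_series(c(2, 2, 2)), "constant")
  expect_equal(z0, c(0, 0, 0))
})
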