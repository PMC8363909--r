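test_that("count filter keeps features detected in half of one group's samples", {
  g <- grouped_matrix(0, 4, c(A = 6, B = 4))
  m <- g$mat
  m[1, 1:3] <- 1           # 3 of 6 in A: 3 >= ceil(6/2), kept
  m[2, 1:2] <- 5           # 2 of 6 in A, 0 in B: removed
  m[3, 7:8] <- 1           # 2 of 4 in B: kept
  out <- filter_features(m, g$groups)
  expect_identical(rownames(out), c("f001", "f003"))  # all-zero f004 removed too

  set.seed(41)
  gg <- grouped_matrix(stats::rpois(60 * 7, 0.6), 60, c(A = 3, B = 4))
  keep_oracle <- vapply(seq_len(60), function(i) {
    a <- sum(gg$mat[i, 1:3] >= 1) >= ceiling(3 / 2)
    b <- sum(gg$mat[i, 4:7] >= 1) >= ceiling(4 / 2)
    (a || b) && sum(gg$mat[i, ]) > 0
  }, logical(1))
  expect_identical(rownames(filter_features(gg$mat, gg$groups)),
                   rownames(gg$mat)[keep_oracle])
  # AND reading is at least as strict as the OR reading
  strict <- filter_features(gg$mat, gg$groups, require_all = TRUE)
  expect_true(all(rownames(strict) %in%
                    rownames(filter_features(gg$mat, gg$groups))))
})

test_that("median-of-ratios size factors behave like the standard estimator", {
  m <- matrix(c(10, 20, 30,
                100, 200, 300,
                5, 10, 15,
                40, 80, 120), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  sf <- size_factors(m)
  # hand computation: every sample is an exact scalar multiple of the
  # geometric-mean profile, with ratios proportional to 1:2:3
  expect_equal(unname(sf / sf[1]), c(1, 2, 3), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # identical samples: all factors 1
  ident <- matrix(rep(c(3, 7, 1), 4), nrow = 3,
                  dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(size_factors(ident)), rep(1, 4))
  # doubling one sample doubles its factor relative to the others
  set.seed(42)
  base <- matrix(stats::rnbinom(200 * 4, mu = 50, size = 5), 200, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  doubled <- base; doubled[, 2] <- base[, 2] * 2
  s0 <- size_factors(base); s2 <- size_factors(doubled)
  expect_equal(unname((s2[2] / s2[1]) / (s0[2] / s0[1])), 2, tolerance = 1e-9)
  # feature order invariance
  expect_equal(size_factors(base[sample(nrow(base)), ]), s0, tolerance = 1e-12)
  # cross-check against the reference implementation (ratios agree)
  # reference implementation takes the median in log space, ours in linear
  # space; with an even feature count the two medians differ at the 1e-4 level
  if (requireNamespace("DESeq2", quietly = TRUE)) {
    ref <- DESeq2::estimateSizeFactorsForMatrix(base)
    expect_equal(unname(s0 / s0[1]), unname(ref / ref[1]), tolerance = 1e-3)
  }
  zero_path <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(size_factors(zero_path), "library-size")
})

test_that("NB Wald test recovers planted fold changes and applies the DE rule", {
  g <- grouped_matrix(stats::rnbinom(200 * 12, mu = 100, size = 10), 200,
                      c(A = 6, B = 6))
  null_res <- nb_wald_test(g$mat, g$groups, "A", "B")
  expect_lt(mean(abs(null_res$log2fc)), 0.3)
  expect_lt(sum(null_res$de), 5)
  expect_true(all(null_res$padj >= null_res$p - 1e-12))
  # BH adjustment equals the textbook step-up formula
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(null_res$padj, bh_oracle(null_res$p), tolerance = 1e-12)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # planted 4-fold features are recovered with good power
  set.seed(43)
  mu <- matrix(100, 200, 12)
  mu[1:40, 1:6] <- 400
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 10), 200, 12,
                dimnames = dimnames(g$mat))
  res <- nb_wald_test(cnt, g$groups, "A", "B")
  expect_gte(mean(res$de[1:40]), 0.8)
})

test_that("biotype composition sums counts per class", {
  g <- grouped_matrix(0, 2, c(A = 2, B = 2))
  m <- g$mat
  m[1, ] <- c(40, 30, 10, 20)   # miRNA: 70 in A, 30 in B
  m[2, ] <- c(20, 10, 30, 40)   # tRNA
  comp <- biotype_composition(m, c("miRNA", "tRNA"), g$groups)
  expect_equal(unname(comp$by_group[, "A"]), c(0.7, 0.3))
  expect_equal(sum(comp$overall), 1, tolerance = 1e-12)
  single <- biotype_composition(m[1, , drop = FALSE], "miRNA")
  expect_equal(unname(single$overall), 1, ignore_attr = TRUE)
  excl <- biotype_composition(m, c("miRNA", "rRNA"), exclude = "rRNA")
  expect_equal(unname(excl$overall), 1, ignore_attr = TRUE)
})

test_that("codon-usage profile reproduces hand-computed proportions", {
  iso <- c("Gly", "Ala", "Ser")
  ann <- data.frame(feature = paste0("tRNA-", iso), biotype = "tRNA",
                    isotype = iso, essential = FALSE)
  g <- grouped_matrix(0, 3, c(G1 = 3, G2 = 3))
  m <- g$mat
  rownames(m) <- ann$feature
  m[, 1:3] <- 100          # group 1 uniform: 1/3 each
  m[1, 4:6] <- 800; m[2, 4:6] <- 100; m[3, 4:6] <- 100  # group 2: Gly 80%
  cup <- codon_usage_profile(m, ann, g$groups, "G1", "G2",
                             sf = stats::setNames(rep(1, 6), colnames(m)))
  gly <- cup[cup$isotype == "Gly", ]
  expect_equal(gly$fold_change, (1 / 3) / 0.8, tolerance = 1e-9)
  expect_true(all(cup$fold_change[cup$isotype != "Gly"] > 1))
  expect_equal(sum(cup$prop_group1), 1, tolerance = 1e-9)
  expect_equal(sum(cup$prop_group2), 1, tolerance = 1e-9)
  # identical groups: all fold changes 1
  m2 <- m; m2[, 4:6] <- m2[, 1:3]
  cup2 <- codon_usage_profile(m2, ann, g$groups, "G1", "G2",
                              sf = stats::setNames(rep(1, 6), colnames(m)))
  expect_equal(cup2$fold_change, rep(1, 3), tolerance = 1e-12)
  # invariant to per-sample library scaling once size factors are recomputed
  m3 <- m; m3[, 1] <- m3[, 1] * 10
  cup3 <- codon_usage_profile(m3, ann, g$groups, "G1", "G2")
  expect_equal(cup3$fold_change, cup$fold_change, tolerance = 1e-9)
})

test_that("plasma-vs-EV simulation shows the Gly-driven codon-usage pattern", {
  des <- omics_design(groups = c(plasma = 6, EV = 6), n_features = 30,
                      dispersion = 0.05, seed = 44)
  sim <- simulate_smallrna(des, library_size = 5e5)
  flt <- filter_features(sim$counts, sim$groups)
  cup <- codon_usage_profile(flt, sim$annotation, sim$groups, "EV", "plasma")
  expect_lt(cup$fold_change[cup$isotype == "Gly"], 1)
  non_gly <- cup$fold_change[cup$isotype != "Gly"]
  expect_gt(mean(non_gly > 1, na.rm = TRUE), 0.5)
})

test_that("classic GSEA running sum matches brute-force oracles", {
  ranked <- paste0("g", 1:10)
  # oracle: explicit running sum
  oracle_es <- function(ranked, set) {
    nh <- sum(ranked %in% set); n <- length(ranked)
    rs <- cumsum(ifelse(ranked %in% set, 1 / nh, -1 / (n - nh)))
    rs[which.max(abs(rs))]
  }
  top <- gsea_classic(ranked, paste0("g", 1:3), n_permutations = 100, seed = 1)
  expect_equal(top$es, oracle_es(ranked, paste0("g", 1:3)), tolerance = 1e-12)
  expect_equal(top$es, 1.0)   # top-Nh set attains the maximal running sum
  expect_lt(top$p, 0.15)
  # uniformly interleaved set: small |ES|, large p
  inter <- gsea_classic(ranked, paste0("g", c(2, 4, 6, 8, 10)),
                        n_permutations = 200, seed = 2)
  expect_lte(abs(inter$es), 1 / 5 + 1 / 5 + 1e-12)
  expect_gt(inter$p, 0.5)
  # random sets stay within [-1, 1] and match the oracle
  set.seed(45)
  ranked2 <- paste0("f", 1:20)
  for (i in 1:10) {
    s <- sample(ranked2, sample(2:10, 1))
    g <- gsea_classic(ranked2, s, n_permutations = 50, seed = i)
    expect_equal(g$es, oracle_es(ranked2, s), tolerance = 1e-12)
    expect_gte(g$es, -1); expect_lte(g$es, 1)
    expect_equal(sign(g$nes), sign(g$es))
  }
  expect_error(gsea_classic(ranked, "g1"), "fewer than 2")
  # cross-check against fgsea's unweighted enrichment statistic
  stats_vec <- stats::setNames(seq(10, 1), ranked)
  fg <- fgsea::calcGseaStat(stats_vec, selectedStats = 1:3, gseaParam = 0,
                            scoreType = "std")
  expect_equal(top$es, fg, tolerance = 1e-9)
})

test_that("exact Mann-Whitney enumeration matches brute force and wilcox.test", {
  # complete separation of two groups of six
  r <- mannwhitney_exact(1:6, 7:12)
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 924, tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0022)
  # identical interleaved samples: p near 1
  expect_gt(mannwhitney_exact(c(1, 3, 5), c(2, 4, 6))$p, 0.6)
  # n1 = n2 = 3: enumeration equals brute force over all 20 assignments
  x <- c(1.2, 3.4, 0.7); y <- c(2.2, 5.1, 0.1)
  ours <- mannwhitney_exact(x, y)
  pooled <- c(x, y); r_all <- rank(pooled)
  sel <- utils::combn(6, 3)
  u_null <- colSums(matrix(r_all[sel], nrow = 3)) - 6
  dev <- abs(u_null - 4.5)
  expect_equal(ours$p, mean(dev >= abs(ours$U - 4.5) - 1e-9), tolerance = 1e-12)
  # agrees with the reference exact test on untied data
  w <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$p, w$p.value, tolerance = 1e-12)
  expect_warning(pt <- mannwhitney_exact(c(2, 2), c(2, 2)), "tied")
  expect_equal(pt$p, 1)
  # large samples switch to the tie-corrected normal approximation
  big <- mannwhitney_exact(stats::rnorm(15), stats::rnorm(15))
  expect_identical(big$method, "normal approximation")
})

test_that("GMT gene sets load as named lists", {
  gmt <- read_gmt(system.file("extdata", "demo_genesets.gmt",
                              package = "plasmafrac"))
  expect_named(gmt, c("HDL_MIR_SIGNATURE", "PLATELET_MIR_SIGNATURE"))
  expect_true("hsa-miR-451a" %in% gmt$HDL_MIR_SIGNATURE)
  expect_length(gmt$HDL_MIR_SIGNATURE, 10)
})
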