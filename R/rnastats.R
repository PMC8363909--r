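#' Filter small-RNA features on per-group detection
#'
#' Keeps a feature if, in at least one group, it has a read count of at
#' least 1 in at least half of that group's samples (ceiling for odd group
#' sizes). All-zero features are always removed. The stricter AND reading
#' (every group must satisfy the rule) is available via `require_all`.
#'
#' @param counts integer matrix, features x samples.
#' @param groups named character vector, sample -> group.
#' @param require_all logical; require the rule in every group instead of
#'   at least one.
#' @return the filtered count matrix.
#' @export
filter_features <- function(counts, groups, require_all = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  g <- groups[colnames(counts)]
  ok <- NULL
  for (lev in unique(g)) {
    sub <- counts[, g == lev, drop = FALSE]
    pass <- rowSums(sub >= 1) >= ceiling(ncol(sub) / 2)
    ok <- if (is.null(ok)) pass else if (require_all) ok & pass else ok | pass
  }
  counts[ok & rowSums(counts) > 0, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-feature geometric means over samples are computed on features with
#' nonzero counts in all samples; each sample's factor is the median of its
#' counts divided by those geometric means, then the factors are rescaled
#' to geometric mean 1. If no feature is nonzero everywhere, library-size
#' scaling is used instead with a warning.
#'
#' @param counts integer matrix, features x samples.
#' @return named positive numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no feature with nonzero counts in all samples; ",
            "falling back to library-size scaling")
    sf <- colSums(counts)
  } else {
    sub <- counts[allpos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sub, 2, function(col) stats::median(col / geo))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#' @param counts integer matrix.
#' @param sf size factors from [size_factors()] (computed if `NULL`).
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf[colnames(counts)], "/")
}

#' Simplified negative-binomial Wald test for differential expression
#'
#' A transparent stand-in for a full shrinkage-based count model: log2
#' fold-changes come from normalized group means with a pseudo-count of
#' 0.5, the NB dispersion is a pooled method-of-moments estimate per
#' feature, and the Wald p-value uses the delta-method standard error of
#' the log fold-change. P-values are Benjamini-Hochberg adjusted and a
#' feature is flagged differentially expressed when `|log2FC| >=
#' lfc_threshold` and adjusted p <= `alpha`.
#'
#' @param counts filtered integer matrix, features x samples.
#' @param groups named character vector, sample -> group.
#' @param group_a,group_b labels to compare; log2FC is a over b.
#' @param sf size factors (computed if `NULL`).
#' @param lfc_threshold DE log2 fold-change criterion (default 1).
#' @param alpha DE adjusted-p criterion (default 0.05).
#' @param pseudo pseudo-count added to normalized group means.
#' @return data frame of class `de_result`: `feature`, `log2fc`, `p`,
#'   `padj`, `de`.
#' @export
nb_wald_test <- function(counts, groups, group_a, group_b, sf = NULL,
                         lfc_threshold = 1, alpha = 0.05, pseudo = 0.5) {
  stopifnot(is.matrix(counts))
  g <- groups[colnames(counts)]
  ia <- which(g == group_a); ib <- which(g == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts[, c(ia, ib), drop = FALSE])
  q <- normalize_counts(counts, sf)
  qa <- q[, colnames(counts)[ia], drop = FALSE]
  qb <- q[, colnames(counts)[ib], drop = FALSE]
  ma <- rowMeans(qa); mb <- rowMeans(qb)
  # pooled method-of-moments dispersion: alpha = (var - mean) / mean^2
  mom <- function(m, v) ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  va <- apply(qa, 1, stats::var); vb <- apply(qb, 1, stats::var)
  disp <- (mom(ma, va) * (ncol(qa) - 1) + mom(mb, vb) * (ncol(qb) - 1)) /
    (ncol(qa) + ncol(qb) - 2)
  log2fc <- log2((ma + pseudo) / (mb + pseudo))
  # Var(log2 mu_hat) by delta method: (1/mu + disp) / (n * ln(2)^2)
  se2 <- ((1 / (ma + pseudo) + disp) / ncol(qa) +
            (1 / (mb + pseudo) + disp) / ncol(qb)) / log(2)^2
  z <- log2fc / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(feature = rownames(counts), log2fc = log2fc, p = p,
                    padj = padj,
                    de = abs(log2fc) >= lfc_threshold & padj <= alpha,
                    row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Biotype composition of a count matrix
#'
#' Proportion of summed counts per RNA biotype among the non-excluded
#' biotypes, per group and overall.
#'
#' @param counts integer matrix, features x samples.
#' @param biotype character vector of biotypes, parallel to the rows.
#' @param groups optional named character vector, sample -> group.
#' @param exclude biotypes dropped before computing proportions (e.g.
#'   ribosomal classes).
#' @return list with `overall` (named proportions) and `by_group` (matrix,
#'   biotype x group), each column summing to 1.
#' @export
biotype_composition <- function(counts, biotype, groups = NULL,
                                exclude = character()) {
  stopifnot(length(biotype) == nrow(counts))
  keep <- !(biotype %in% exclude)
  counts <- counts[keep, , drop = FALSE]
  biotype <- biotype[keep]
  tot <- c(tapply(rowSums(counts), biotype, sum))
  overall <- tot / sum(tot)
  by_group <- NULL
  if (!is.null(groups)) {
    g <- groups[colnames(counts)]
    by_group <- vapply(unique(g), function(lev) {
      t_ <- tapply(rowSums(counts[, g == lev, drop = FALSE]), biotype, sum)
      t_ / sum(t_)
    }, numeric(length(unique(biotype))))
  }
  list(overall = overall, by_group = by_group)
}

#' tRNA codon-usage profile between two groups
#'
#' Pools normalized tRNA-fragment counts by amino-acid isotype within each
#' group, keeps only isotypes detected (count >= 1) in at least
#' `min_presence` of ALL samples, renormalizes to relative proportions per
#' group over the included isotypes, and reports the fold change
#' `proportion(group1) / proportion(group2)` per isotype. An isotype with
#' zero pooled signal in `group2` gets an `NA` fold change and a flag.
#'
#' @param counts integer matrix, features x samples.
#' @param annotation data frame with `feature`, `biotype`, `isotype`
#'   (and optionally `essential`).
#' @param groups named character vector, sample -> group.
#' @param group1,group2 group labels (fold change is group1 over group2).
#' @param sf size factors (computed if `NULL`).
#' @param min_presence minimum proportion of all samples in which an
#'   isotype must be detected (default 2/3).
#' @return data frame of class `codon_usage_profile`: `isotype`,
#'   `prop_group1`, `prop_group2`, `fold_change`, `essential`,
#'   `undefined`.
#' @export
codon_usage_profile <- function(counts, annotation, groups, group1, group2,
                                sf = NULL, min_presence = 2 / 3) {
  stopifnot(all(c("feature", "biotype", "isotype") %in% names(annotation)))
  ann <- annotation[match(rownames(counts), annotation$feature), ]
  tr <- which(ann$biotype == "tRNA")
  if (!length(tr)) stop("no tRNA features in matrix", call. = FALSE)
  if (anyNA(ann$isotype[tr])) stop("tRNA features lack isotypes", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  q <- normalize_counts(counts, sf)[tr, , drop = FALSE]
  iso <- ann$isotype[tr]

  # isotype-level detection across ALL samples
  det <- rowsum((counts[tr, , drop = FALSE] >= 1) + 0, iso) > 0
  present <- rowMeans(det) >= min_presence - 1e-9
  keep_iso <- rownames(det)[present]

  g <- groups[colnames(q)]
  pooled <- function(lev) {
    s <- rowsum(rowSums(q[, g == lev, drop = FALSE]), iso)[keep_iso, ]
    s / sum(s)
  }
  p1 <- pooled(group1); p2 <- pooled(group2)
  fc <- ifelse(p2 > 0, p1 / p2, NA_real_)
  ess <- if ("essential" %in% names(annotation)) {
    key <- annotation[annotation$biotype == "tRNA", ]
    stats::setNames(key$essential, key$isotype)[keep_iso]
  } else rep(NA, length(keep_iso))
  res <- data.frame(isotype = keep_iso, prop_group1 = p1, prop_group2 = p2,
                    fold_change = fc, essential = unname(ess),
                    undefined = is.na(fc), row.names = NULL)
  class(res) <- c("codon_usage_profile", "data.frame")
  res
}

#' Classic (unweighted) permutation gene-set enrichment
#'
#' Walks the ranked feature list incrementing the running sum by `1/Nh` at
#' set members and decrementing by `1/(N - Nh)` elsewhere; the enrichment
#' score ES is the signed maximum deviation from zero. The null permutes
#' which features carry the set label (`n_permutations` uniform draws of
#' `Nh` positions). NES is ES divided by the mean of same-sign permuted ES,
#' and the permutation p-value is the proportion of same-sign permuted ES
#' at least as extreme (with the +1 pseudo-permutation).
#'
#' @param ranked character vector of feature ids in rank order (most
#'   up-regulated first).
#' @param gene_set character vector of set members (overlap >= 2 required).
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list of class `gsea_result`: `es`, `nes`, `p`,
#'   `n_permutations`, `n_hits`, `running` (the running-sum curve).
#' @export
gsea_classic <- function(ranked, gene_set, n_permutations = 1000, seed = 1L) {
  stopifnot(is.character(ranked), !anyDuplicated(ranked))
  hits <- ranked %in% gene_set
  nh <- sum(hits); n <- length(ranked)
  if (nh < 2) stop("gene set overlaps ranked list in fewer than 2 features",
                   call. = FALSE)
  if (nh == n) stop("gene set covers the whole ranked list", call. = FALSE)
  running_es <- function(hit_positions) {
    steps <- rep(-1 / (n - nh), n)
    steps[hit_positions] <- 1 / nh
    rs <- cumsum(steps)
    rs[which.max(abs(rs))]
  }
  steps <- rep(-1 / (n - nh), n)
  steps[hits] <- 1 / nh
  running <- cumsum(steps)
  es <- running[which.max(abs(running))]

  perm_es <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    running_es(sample.int(n, nh))
  }, numeric(1)))
  same <- perm_es[sign(perm_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(es = es, nes = nes,
                 p = p, n_permutations = n_permutations, n_hits = nh,
                 running = running),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA classic: ES %.3f, NES %.3f, p %.4g (%d hits, %d perms)\n",
              x$es, x$nes, x$p, x$n_hits, x$n_permutations))
  invisible(x)
}

#' Rank features for GSEA by log2 fold-change
#'
#' Descending log2 fold-change; ties broken by mean normalized count
#' (descending), then by feature id.
#'
#' @param de a `de_result` from [nb_wald_test()].
#' @param mean_norm named vector of mean normalized counts used for
#'   tie-breaking (optional).
#' @return character vector of feature ids in rank order.
#' @export
rank_by_log2fc <- function(de, mean_norm = NULL) {
  tie <- if (is.null(mean_norm)) rep(0, nrow(de)) else -mean_norm[de$feature]
  de$feature[order(-de$log2fc, tie, de$feature)]
}

#' Exact Mann-Whitney U test
#'
#' Two-sided p-value by full enumeration of the null distribution of U over
#' all `choose(n1 + n2, n1)` group assignments of the pooled observations
#' (ties contribute 1/2 to U), used whenever `n1 + n2 <= 20`; above that, a
#' normal approximation with tie-corrected variance is used. The two-sided
#' p-value is `P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)` under the
#' enumerated null.
#'
#' @param x,y numeric samples.
#' @return list with `U` (of `x`), `p`, `method`.
#' @export
#' @examples
#' mannwhitney_exact(1:6, 7:12)$p   # 2/924 = 0.0022 for complete separation
mannwhitney_exact <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1) {
    warning("all observations tied: p = 1")
    return(list(U = u_obs, p = 1, method = "degenerate"))
  }
  center <- n1 * n2 / 2
  if (n1 + n2 <= 20) {
    sel <- utils::combn(n1 + n2, n1)
    rank_sums <- colSums(matrix(r[sel], nrow = n1))
    u_null <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_null - center) >= abs(u_obs - center) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - center) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = u_obs, p = p, method = method)
}

#' Read gene sets from a GMT file
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
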