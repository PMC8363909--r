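#' Filter features on valid values per group
#'
#' Keeps a protein if at least one group quantifies it (non-missing) in at
#' least `min_valid_fraction` of that group's samples (default 2/3, i.e.
#' "valid in >= 66.67% of at least one group"). The comparison carries a
#' 1e-9 slack so that exactly 4 valid out of 6 passes the 2/3 rule.
#'
#' @param mat numeric matrix, features x samples, `NA` = missing.
#' @param groups named character vector, sample id -> group label, covering
#'   all columns of `mat`.
#' @param min_valid_fraction minimum within-group valid proportion.
#' @return the filtered matrix.
#' @export
filter_valid <- function(mat, groups, min_valid_fraction = 2 / 3) {
  stopifnot(is.matrix(mat), all(colnames(mat) %in% names(groups)))
  g <- groups[colnames(mat)]
  keep <- rep(FALSE, nrow(mat))
  for (lev in unique(g)) {
    sub <- mat[, g == lev, drop = FALSE]
    keep <- keep | (rowSums(!is.na(sub)) / ncol(sub) >=
                      min_valid_fraction - 1e-9)
  }
  mat[keep, , drop = FALSE]
}

#' Impute missing intensities from a down-shifted normal distribution
#'
#' Missing values in each sample column are replaced by draws from
#' `Normal(mean - downshift * sd, width * sd)` of that column's observed
#' values — the conventional missing-not-at-random imputation for label-free
#' proteomics, placing imputed values in the low-intensity tail. Observed
#' values are never touched. Set `per_matrix = TRUE` to use the moments of
#' the whole matrix instead of per-column moments.
#'
#' @param mat numeric matrix with `NA` for missing values.
#' @param width sd multiplier of the imputation distribution (default 0.3).
#' @param downshift mean down-shift in column-sd units (default 1.8).
#' @param seed integer seed; imputation is reproducible.
#' @param per_matrix logical; use global instead of per-column moments.
#' @return matrix without missing values.
#' @export
impute_missing <- function(mat, width = 0.3, downshift = 1.8, seed = 1L,
                           per_matrix = FALSE) {
  stopifnot(is.matrix(mat))
  with_seed(seed, {
    out <- mat
    if (per_matrix) {
      obs <- mat[!is.na(mat)]
      if (!length(obs)) stop("matrix has no observed values", call. = FALSE)
      m <- mean(obs); s <- stats::sd(obs)
      idx <- which(is.na(out))
      out[idx] <- stats::rnorm(length(idx), m - downshift * s, width * s)
    } else {
      for (j in seq_len(ncol(mat))) {
        obs <- mat[, j][!is.na(mat[, j])]
        if (!length(obs)) {
          stop(sprintf("column %d has no observed values; cannot impute", j),
               call. = FALSE)
        }
        m <- mean(obs); s <- stats::sd(obs)
        idx <- which(is.na(out[, j]))
        if (length(idx)) {
          out[idx, j] <- stats::rnorm(length(idx), m - downshift * s, width * s)
        }
      }
    }
    out
  })
}

#' S0-moderated two-sample t statistic
#'
#' `t_s0 = (mean(a) - mean(b)) / (s0 + pooled standard error)`. With
#' `s0 = 0` this is the classical pooled-variance two-sample t; a positive
#' `s0` damps the statistic of low-variance features so that tiny but
#' consistent differences do not dominate the volcano plot.
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @param s0 non-negative moderation constant (default 0.1).
#' @return the moderated statistic (positive when `mean(a) > mean(b)`).
#' @export
#' @examples
#' moderated_t(c(1, 2, 3), c(4, 5, 6), s0 = 0)   # classical t = -3.674
moderated_t <- function(a, b, s0 = 0.1) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  assert_scalar_num(s0, "s0", lower = 0)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0 && s0 == 0) {
    stop("zero pooled variance with s0 = 0; statistic undefined", call. = FALSE)
  }
  (mean(a) - mean(b)) / (s0 + se)
}

# vectorized moderated t for all rows of x given column index sets
.row_t_s0 <- function(x, ia, ib, s0) {
  n1 <- length(ia); n2 <- length(ib)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (n1 - 1)
  vb <- rowSums((xb - mb)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
  (ma - mb) / (s0 + sqrt(sp2 * (1 / n1 + 1 / n2)))
}

#' Two-sample test with S0 moderation and permutation-based FDR
#'
#' For every feature the moderated statistic is computed for the observed
#' group labels and for label permutations (all distinct splits when their
#' number is at most `max_exhaustive`, otherwise `n_permutations` seeded
#' random splits). Each feature's q-value is
#' `min(1, mean over permutations of #{permuted |t| >= |t_i|} / #{observed
#' |t| >= |t_i|})`, monotonized by a cumulative minimum from the least to
#' the most significant feature. A feature is significant when
#' `q < fdr_alpha`.
#'
#' @param mat complete (filtered, imputed) numeric matrix, features x
#'   samples.
#' @param groups named character vector, sample -> group.
#' @param group_a,group_b labels to compare; the reported difference is
#'   `mean(group_a) - mean(group_b)` in log2 units.
#' @param s0 moderation constant.
#' @param n_permutations random permutations when exhaustive enumeration is
#'   infeasible (>= 10).
#' @param fdr_alpha significance cut-off on q.
#' @param seed integer seed for sampled permutations.
#' @param max_exhaustive largest number of distinct splits that is still
#'   enumerated exhaustively.
#' @return data frame of class `differential_result`: `feature`, `diff`,
#'   `t_s0`, `q`, `significant`.
#' @export
permutation_fdr <- function(mat, groups, group_a, group_b, s0 = 0.1,
                            n_permutations = 250, fdr_alpha = 0.05,
                            seed = 1L, max_exhaustive = 10000) {
  stopifnot(is.matrix(mat), !anyNA(mat), n_permutations >= 10)
  g <- groups[colnames(mat)]
  ia <- which(g == group_a); ib <- which(g == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  x <- mat[, c(ia, ib), drop = FALSE]
  n1 <- length(ia); n <- n1 + length(ib)
  t_obs <- .row_t_s0(x, seq_len(n1), (n1 + 1):n, s0)

  n_distinct <- choose(n, n1)
  if (n_distinct < 10) {
    warning("fewer than 10 distinct label permutations; exact enumeration used")
  }
  splits <- if (n_distinct <= max_exhaustive) {
    utils::combn(n, n1, simplify = FALSE)
  } else {
    with_seed(seed, replicate(n_permutations, sort(sample.int(n, n1)),
                              simplify = FALSE))
  }
  perm_abs <- unlist(lapply(splits, function(ia2) {
    abs(.row_t_s0(x, ia2, setdiff(seq_len(n), ia2), s0))
  }))
  n_perm <- length(splits)

  abs_obs <- abs(t_obs)
  sorted_perm <- sort(perm_abs)
  sorted_obs <- sort(abs_obs)
  # counts of values >= |t_i| via binary search on the sorted pools
  c_perm <- (length(sorted_perm) -
               findInterval(abs_obs - 1e-12, sorted_perm)) / n_perm
  c_obs <- length(sorted_obs) - findInterval(abs_obs - 1e-12, sorted_obs)
  q <- pmin(1, c_perm / c_obs)
  ord <- order(abs_obs)                       # least significant first
  q[ord] <- cummin(q[ord])

  res <- data.frame(feature = rownames(x), diff = .row_diff(x, n1),
                    t_s0 = t_obs, q = q, significant = q < fdr_alpha,
                    row.names = NULL)
  attr(res, "comparison") <- c(group_a, group_b)
  attr(res, "n_permutations") <- n_perm
  attr(res, "exhaustive") <- n_distinct <= max_exhaustive
  class(res) <- c("differential_result", "data.frame")
  res
}

.row_diff <- function(x, n1) {
  rowMeans(x[, seq_len(n1), drop = FALSE]) -
    rowMeans(x[, (n1 + 1):ncol(x), drop = FALSE])
}

#' Pairwise sample correlation summary
#'
#' Pairwise correlations over features observed in both samples of each
#' pair; pairs sharing fewer than 3 features are flagged missing. Reports
#' the full matrix plus median within-group and between-group coefficients.
#'
#' @param mat numeric matrix (may contain `NA`).
#' @param groups named character vector, sample -> group.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `correlation_summary` with `matrix`,
#'   `median_within`, `median_between`, `iqr_within`, `iqr_between`.
#' @export
correlation_summary <- function(mat, groups, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  ns <- ncol(mat)
  cm <- matrix(NA_real_, ns, ns, dimnames = list(colnames(mat), colnames(mat)))
  diag(cm) <- 1
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (sum(ok) >= 3) {
        cm[i, j] <- cm[j, i] <- stats::cor(mat[ok, i], mat[ok, j],
                                           method = method)
      }
    }
  }
  g <- groups[colnames(mat)]
  same <- outer(g, g, "==")
  ut <- upper.tri(cm)
  within <- cm[ut & same]; between <- cm[ut & !same]
  structure(list(matrix = cm, method = method,
                 median_within = stats::median(within, na.rm = TRUE),
                 median_between = stats::median(between, na.rm = TRUE),
                 iqr_within = stats::IQR(within, na.rm = TRUE),
                 iqr_between = stats::IQR(between, na.rm = TRUE)),
            class = "correlation_summary")
}

#' Principal component scores of samples
#'
#' Samples are observations, features are centred variables
#' (`stats::prcomp`, no scaling). Explained-variance proportions sum to 1.
#'
#' @param mat complete numeric matrix, features x samples.
#' @return list with `scores` (samples x components) and `explained`
#'   (proportion of variance per component).
#' @export
pca_scores <- function(mat) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl)
}

#' Hierarchical clustering of samples or features
#'
#' Distances: `one_minus_pearson` (1 - Pearson correlation between items)
#' or `manhattan`; linkage: `average` or `ward` (Ward.D2 on the chosen
#' distance). A constant item has no defined correlation; its
#' 1-Pearson distances are set to the maximum (2) with a warning.
#'
#' @param mat complete numeric matrix, features x samples.
#' @param distance,linkage see above.
#' @param items cluster `"samples"` (columns, default) or `"features"`.
#' @return an `hclust` tree.
#' @export
hcluster <- function(mat, distance = c("one_minus_pearson", "manhattan"),
                     linkage = c("average", "ward"),
                     items = c("samples", "features")) {
  distance <- match.arg(distance); linkage <- match.arg(linkage)
  items <- match.arg(items)
  x <- if (items == "samples") t(mat) else mat   # rows = items
  stopifnot(nrow(x) >= 2)
  d <- if (distance == "manhattan") {
    stats::dist(x, method = "manhattan")
  } else {
    cc <- suppressWarnings(stats::cor(t(x)))
    if (anyNA(cc)) {
      warning("constant item(s): undefined correlation set to maximum distance")
      cc[is.na(cc)] <- -1
    }
    stats::as.dist(1 - cc)
  }
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else "average")
}

#' Kernel density of per-feature differences between two conditions
#'
#' KDE (Gaussian kernel, Silverman's `nrd0` bandwidth rule) of the
#' per-feature differences `a - b`; the returned curve is renormalized to
#' integrate to 1.
#'
#' @param means_a,means_b matched per-feature mean vectors (>= 5 features).
#' @return list with `x`, `y`, `bw`.
#' @export
difference_density <- function(means_a, means_b) {
  stopifnot(length(means_a) == length(means_b))
  d <- means_a - means_b
  d <- d[!is.na(d)]
  if (length(d) < 5) stop("need at least 5 matched features", call. = FALSE)
  dd <- stats::density(d, bw = "nrd0")
  area <- sum(diff(dd$x) * (utils::head(dd$y, -1) + utils::tail(dd$y, -1)) / 2)
  list(x = dd$x, y = dd$y / area, bw = dd$bw)
}

#' Z-score transform of an ordered series
#'
#' `(x - mean) / sd`; a constant series yields all zeros with a warning.
#'
#' @param values numeric vector of length >= 2.
#' @return z-scores.
#' @export
zscore_series <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0 || is.na(s)) {
    warning("constant series: z-scores set to 0")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}
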