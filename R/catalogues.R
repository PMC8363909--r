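#' Proteins detected in a group of samples
#'
#' "Detected" means a valid (non-imputed) value in at least
#' `min_valid_fraction` of the group's replicates — the same 2/3 rule used
#' for feature filtering, reused so presence calls stay coherent with the
#' differential workflow.
#'
#' @param mat numeric matrix with `NA` for missing values (pre-imputation).
#' @param groups named character vector, sample -> group.
#' @param group group label.
#' @param min_valid_fraction minimum valid proportion.
#' @return character vector of detected feature ids.
#' @export
detected_in_group <- function(mat, groups, group, min_valid_fraction = 2 / 3) {
  g <- groups[colnames(mat)]
  sub <- mat[, g == group, drop = FALSE]
  if (!ncol(sub)) stop(sprintf("no samples in group '%s'", group), call. = FALSE)
  frac <- rowSums(!is.na(sub)) / ncol(sub)
  rownames(sub)[frac >= min_valid_fraction - 1e-9]
}

#' Select putative non-EV-associated (contaminating) proteins
#'
#' Two criteria: the protein co-elutes with EV in SEC (it is identified in
#' the crude extract) but does not share the EV buoyant density (it is
#' significantly enriched towards the LPP extract in the LPP-vs-EV
#' comparison).
#'
#' @param crude_presence character ids detected in the crude extract.
#' @param diff a `differential_result` for the LPP-vs-EV comparison
#'   (positive `diff` = LPP-enriched).
#' @param alpha q-value cut-off (on the multiple-testing-corrected scale).
#' @return data frame of class `selection_catalogue` with per-protein
#'   criterion columns and a `category` column.
#' @export
select_non_ev_associated <- function(crude_presence, diff, alpha = 0.05) {
  stopifnot(inherits(diff, "differential_result"))
  if (!length(crude_presence)) {
    warning("empty crude presence set: catalogue is empty")
  }
  out <- data.frame(
    protein = diff$feature,
    in_crude = diff$feature %in% crude_presence,
    q_lpp_vs_ev = diff$q,
    lpp_enriched = diff$significant & diff$diff > 0)
  out$category <- ifelse(out$in_crude & out$lpp_enriched,
                         "non_EV_associated", "unclassified")
  class(out) <- c("selection_catalogue", "data.frame")
  out
}

#' Select putative EV-corona candidate proteins
#'
#' Three criteria: (1) identified in the crude extract; (2) shares the EV
#' buoyant density, i.e. significantly enriched towards EV in the
#' EV-vs-LPP comparison at `q < alpha`; (3) annotated as a secreted protein
#' yet consistently identified in EV extracts (valid values in at least
#' `min_valid_fraction` of EV replicates, supplied as `ev_detection`).
#' Proteins missing from the annotation table are treated as not secreted
#' (a message reports how many).
#'
#' @param crude_presence character ids detected in the crude extract.
#' @param diff a `differential_result` for the EV-vs-LPP comparison
#'   (positive `diff` = EV-enriched).
#' @param annotations data frame with columns `protein_id`, `secreted`
#'   (logical or 0/1), optional `plasma_concentration`.
#' @param alpha q-value cut-off.
#' @param ev_detection optional character ids consistently detected in EV
#'   samples; `NULL` skips the consistency requirement.
#' @return a `selection_catalogue` data frame.
#' @export
select_corona_candidates <- function(crude_presence, diff, annotations,
                                     alpha = 0.05, ev_detection = NULL) {
  stopifnot(inherits(diff, "differential_result"),
            all(c("protein_id", "secreted") %in% names(annotations)))
  miss <- setdiff(diff$feature, annotations$protein_id)
  if (length(miss)) {
    message(length(miss), " proteins lack annotation; treated as not secreted")
  }
  secreted <- stats::setNames(as.logical(annotations$secreted),
                              annotations$protein_id)
  out <- data.frame(
    protein = diff$feature,
    in_crude = diff$feature %in% crude_presence,
    q_ev_vs_lpp = diff$q,
    ev_enriched = diff$significant & diff$diff > 0,
    secreted = unname(secreted[diff$feature]))
  out$secreted[is.na(out$secreted)] <- FALSE
  consistent <- if (is.null(ev_detection)) TRUE else diff$feature %in% ev_detection
  out$consistent_in_ev <- consistent
  out$category <- ifelse(out$in_crude & out$ev_enriched & out$secreted &
                           out$consistent_in_ev,
                         "corona_candidate", "unclassified")
  class(out) <- c("selection_catalogue", "data.frame")
  out
}

#' Correlation of corona-protein abundance with plasma concentration
#'
#' Spearman rank correlation between the mean EV-extract intensity of the
#' corona candidates and their known blood-plasma concentration, with an
#' exact permutation p-value for small n (full enumeration of rank
#' pairings, n <= 9) and the t-approximation above. Ties are handled by
#' average ranks.
#'
#' @param mean_intensities named numeric vector of mean EV-extract
#'   intensities for corona candidates.
#' @param annotations data frame with `protein_id` and
#'   `plasma_concentration`.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
corona_concentration_correlation <- function(mean_intensities, annotations) {
  conc <- stats::setNames(annotations$plasma_concentration,
                          annotations$protein_id)
  ids <- intersect(names(mean_intensities),
                   annotations$protein_id[!is.na(conc[annotations$protein_id])])
  if (length(ids) < 5) {
    stop("need at least 5 corona proteins with known concentration",
         call. = FALSE)
  }
  spearman_exact(mean_intensities[ids], conc[ids])
}

#' Spearman correlation with exact small-sample p-value
#'
#' For n <= 9 the two-sided p-value is computed by full enumeration of all
#' n! pairings of the (average) ranks; above that, the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_exact <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- .all_permutations(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact enumeration"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as an (n!) x n matrix, recursive construction
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), k)
    out[rows, 1] <- k
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}
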