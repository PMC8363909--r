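#' Grouped omics simulation design
#'
#' Shared design object for the LFQ intensity and small-RNA count
#' generators: ordered groups with replicate counts, planted per-feature
#' group effects, baseline distribution, intensity-dependent dropout
#' (missing-not-at-random) for LFQ, and a negative-binomial dispersion for
#' counts.
#'
#' @param groups named integer vector, group label -> replicate count
#'   (each >= 2).
#' @param n_features number of simulated features.
#' @param planted_effects data frame with columns `feature`, `group`,
#'   `log2_shift` (empty for a global null).
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param noise_sd replicate log2 noise sd.
#' @param dropout_mid,dropout_scale logistic dropout: a value x is missing
#'   with probability `plogis((dropout_mid - x) / dropout_scale)`;
#'   `dropout_scale = 0` disables dropout.
#' @param dispersion NB dispersion for count simulation (0 = Poisson).
#' @param seed integer; fixes all randomness of the generators.
#' @return object of class `omics_design`.
#' @export
omics_design <- function(groups, n_features = 1000,
                         planted_effects = NULL,
                         baseline_mean = 25, baseline_sd = 2, noise_sd = 0.5,
                         dropout_mid = 21.5, dropout_scale = 1,
                         dispersion = 0.1, seed = 1L) {
  stopifnot(is.numeric(groups), !is.null(names(groups)), all(groups >= 2))
  assert_scalar_num(dispersion, "dispersion", lower = 0)
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(feature = character(0), group = character(0),
                                  log2_shift = numeric(0))
  }
  stopifnot(all(c("feature", "group", "log2_shift") %in% names(planted_effects)))
  structure(list(groups = groups, n_features = as.integer(n_features),
                 planted_effects = planted_effects,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, dropout_mid = dropout_mid,
                 dropout_scale = dropout_scale, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "omics_design")
}

.design_samples <- function(design) {
  grp <- rep(names(design$groups), times = design$groups)
  ids <- unlist(lapply(names(design$groups), function(g) {
    paste0(g, "_", seq_len(design$groups[[g]]))
  }))
  stats::setNames(grp, ids)
}

#' Simulate a grouped log2 LFQ intensity matrix with MNAR dropout
#'
#' Intensities are `baseline + planted group shift + noise` on the log2
#' scale; each cell then drops out with a probability that increases
#' logistically as intensity decreases, mimicking the preferential loss of
#' low-abundance proteins in label-free proteomics.
#'
#' @param design an [omics_design()]. Feature names default to
#'   `prot_0001`... and planted effects reference those names.
#' @return list with `matrix` (features x samples, `NA` = missing),
#'   `complete` (pre-dropout matrix), `groups` (named character vector,
#'   sample -> group), and `truth` (the planted-effect table).
#' @export
simulate_lfq <- function(design) {
  stopifnot(inherits(design, "omics_design"))
  groups <- .design_samples(design)
  nf <- design$n_features
  feats <- sprintf("prot_%04d", seq_len(nf))
  with_seed(design$seed, {
    base <- stats::rnorm(nf, design$baseline_mean, design$baseline_sd)
    shift <- matrix(0, nf, length(groups), dimnames = list(feats, names(groups)))
    pe <- design$planted_effects
    for (k in seq_len(nrow(pe))) {
      i <- match(pe$feature[k], feats)
      if (is.na(i)) stop(sprintf("planted feature '%s' not in feature set",
                                 pe$feature[k]), call. = FALSE)
      shift[i, groups == pe$group[k]] <- shift[i, groups == pe$group[k]] +
        pe$log2_shift[k]
    }
    x <- base + shift +
      matrix(stats::rnorm(nf * length(groups), 0, design$noise_sd),
             nf, length(groups))
    dimnames(x) <- list(feats, names(groups))
    complete <- x
    if (design$dropout_scale > 0) {
      p_miss <- stats::plogis((design$dropout_mid - x) / design$dropout_scale)
      x[stats::runif(length(x)) < p_miss] <- NA_real_
    }
    list(matrix = x, complete = complete, groups = groups,
         truth = design$planted_effects)
  })
}

#' Default small-RNA composition for plasma and EV extracts
#'
#' Per-group biotype shares and tRNA amino-acid isotype shares emulating the
#' plasma small-RNA landscape: in EV extracts miRNA and tRNA fragments are
#' roughly equally represented minorities of the non-ribosomal reads, while
#' the whole-plasma tRNA-fragment pool is dominated by the glycine isotype,
#' so most other isotypes appear relatively enriched in EV.
#'
#' @param groups character group labels (default `c("plasma", "EV")`); any
#'   further groups reuse the plasma composition.
#' @return list of class `smallrna_composition` with `biotype` and
#'   `trna_isotype` per-group proportion tables.
#' @export
default_smallrna_composition <- function(groups = c("plasma", "EV")) {
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")
  essential <- aa %in% c("His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr",
                         "Trp", "Val")
  # plasma pool: Gly dominates; Glu and Val also over-represented so that a
  # minority (~3) of isotypes remain plasma-enriched relative to EV
  plasma_tr <- stats::setNames(rep(0.40 / 17, length(aa)), aa)
  plasma_tr[c("Gly", "Glu", "Val")] <- c(0.45, 0.08, 0.07)
  plasma_tr <- plasma_tr / sum(plasma_tr)
  ev_tr <- stats::setNames(rep(0.85 / 18, length(aa)), aa)
  ev_tr[c("Gly", "Glu")] <- c(0.10, 0.05)
  ev_tr <- ev_tr / sum(ev_tr)

  biot <- list(
    plasma = c(miRNA = 0.100, tRNA = 0.150, piRNA = 0.0040, lncRNA = 0.120,
               other = 0.626),
    EV = c(miRNA = 0.0718, tRNA = 0.0779, piRNA = 0.00358, lncRNA = 0.161,
           other = 0.68572))
  trna <- list(plasma = plasma_tr, EV = ev_tr)
  out <- list(biotype = lapply(stats::setNames(groups, groups), function(g) {
    if (g %in% names(biot)) biot[[g]] else biot$plasma
  }),
  trna_isotype = lapply(stats::setNames(groups, groups), function(g) {
    if (g %in% names(trna)) trna[[g]] else trna$plasma
  }),
  essential = stats::setNames(essential, aa))
  class(out) <- "smallrna_composition"
  out
}

#' Simulate a grouped small-RNA count matrix
#'
#' Counts are negative-binomial with mean
#' `library size x biotype share x within-biotype feature weight`, one
#' feature per tRNA isotype and rank-decaying weights within the other
#' biotypes. A dispersion of 0 falls back to Poisson sampling (the NB
#' limiting case). Planted effects from the design multiply the mean of the
#' named feature in the named group by `2^log2_shift`; an optional
#' time-course decays designated features geometrically across ordered
#' samples.
#'
#' @param design an [omics_design()] (`n_features` sets the number of
#'   miRNA features; `dropout_*` are ignored for counts).
#' @param composition a [default_smallrna_composition()]-style object whose
#'   group proportions each sum to 1 (tolerance 1e-9).
#' @param library_size expected total reads per sample.
#' @param time optional integer time index per sample (same order as the
#'   design's samples) for the time-course multiplier.
#' @param timecourse optional list `list(feature =, log2_decay_per_step =)`;
#'   the feature's mean is multiplied by `2^(log2_decay_per_step * (time-1))`.
#' @return list with `counts` (integer matrix), `groups`, `annotation`
#'   (data frame: feature, biotype, isotype, essential), and `truth`.
#' @export
simulate_smallrna <- function(design,
                              composition = default_smallrna_composition(
                                names(design$groups)),
                              library_size = 1e6, time = NULL,
                              timecourse = NULL) {
  stopifnot(inherits(design, "omics_design"))
  groups <- .design_samples(design)
  for (g in names(composition$biotype)) {
    if (any(composition$biotype[[g]] < 0) ||
        any(composition$trna_isotype[[g]] < 0)) {
      stop("composition proportions must be non-negative", call. = FALSE)
    }
    if (abs(sum(composition$biotype[[g]]) - 1) > 1e-9 ||
        abs(sum(composition$trna_isotype[[g]]) - 1) > 1e-9) {
      stop(sprintf("composition proportions for group '%s' must sum to 1", g),
           call. = FALSE)
    }
  }
  aa <- names(composition$trna_isotype[[1]])
  n_mirna <- design$n_features
  named_mirna <- c("hsa-miR-451a", "hsa-miR-25-3p", "hsa-let-7e-5p",
                   "hsa-miR-125a-5p", "hsa-miR-99b-5p", "hsa-miR-150-5p",
                   "hsa-miR-378a-3p")
  mirna_ids <- c(named_mirna,
                 sprintf("hsa-miR-sim-%03d",
                         seq_len(max(0, n_mirna - length(named_mirna)))))[seq_len(n_mirna)]
  other_feats <- list(
    tRNA = paste0("tRNA-", aa),
    piRNA = sprintf("piR-sim-%03d", 1:20),
    lncRNA = sprintf("lnc-sim-%03d", 1:30),
    other = sprintf("misc-sim-%03d", 1:30))
  ann <- rbind(
    data.frame(feature = mirna_ids, biotype = "miRNA", isotype = NA_character_),
    data.frame(feature = other_feats$tRNA, biotype = "tRNA", isotype = aa),
    data.frame(feature = other_feats$piRNA, biotype = "piRNA", isotype = NA),
    data.frame(feature = other_feats$lncRNA, biotype = "lncRNA", isotype = NA),
    data.frame(feature = other_feats$other, biotype = "other", isotype = NA))
  ann$essential <- ifelse(ann$biotype == "tRNA",
                          composition$essential[ann$isotype], NA)

  # within-biotype rank-decaying weights (Zipf-like), identical across groups
  rank_w <- function(n) { w <- 1 / seq_len(n)^0.8; w / sum(w) }
  mu_group <- function(g) {
    bi <- composition$biotype[[g]]
    mu <- numeric(nrow(ann))
    for (b in names(bi)) {
      idx <- which(ann$biotype == b)
      w <- if (b == "tRNA") {
        composition$trna_isotype[[g]][ann$isotype[idx]]
      } else rank_w(length(idx))
      mu[idx] <- library_size * bi[[b]] * w
    }
    mu
  }
  mu <- vapply(groups, mu_group, numeric(nrow(ann)))
  rownames(mu) <- ann$feature

  pe <- design$planted_effects
  for (k in seq_len(nrow(pe))) {
    i <- match(pe$feature[k], ann$feature)
    if (is.na(i)) stop(sprintf("planted feature '%s' unknown", pe$feature[k]),
                       call. = FALSE)
    sel <- groups == pe$group[k]
    mu[i, sel] <- mu[i, sel] * 2^pe$log2_shift[k]
  }
  if (!is.null(timecourse)) {
    stopifnot(!is.null(time), length(time) == length(groups))
    i <- match(timecourse$feature, ann$feature)
    if (anyNA(i)) stop("timecourse feature unknown", call. = FALSE)
    mu[i, ] <- mu[i, ] * 2^(timecourse$log2_decay_per_step * (time - 1))
  }

  counts <- with_seed(design$seed, {
    k <- length(mu)
    cnt <- if (design$dispersion <= 0) {
      stats::rpois(k, lambda = mu)
    } else {
      stats::rnbinom(k, mu = mu, size = 1 / design$dispersion)
    }
    matrix(cnt, nrow = nrow(mu), dimnames = dimnames(mu))
  })
  list(counts = counts, groups = groups, annotation = ann,
       truth = list(mu = mu, planted = pe, timecourse = timecourse))
}
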