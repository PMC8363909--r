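#' Default pipeline configuration
#'
#' Returns the bundled demo configuration: a full seeded run of
#' simulate -> fraction metrics -> proteomics -> catalogues -> small RNA at
#' desk scale. The same structure, as YAML, is accepted by
#' [validate_config()] and [run_pipeline()].
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, fracmetrics = TRUE, proteomics = TRUE,
                  catalogues = TRUE, rna = TRUE),
    windows = list(sec_fractions = c(5L, 6L),
                   lpp_density = c(1.04, 1.07),
                   ev_density = c(1.09, 1.10)),
    sec = list(noise_cv = 0.1, loss_fraction = 0),
    odg = list(noise_cv = 0.1, loss_fraction = 0),
    proteomics = list(n_features = 300L, n_ev_markers = 20L,
                      n_lpp_markers = 83L, n_corona = 10L, effect_log2 = 3,
                      s0 = 0.1, min_valid_fraction = 2 / 3,
                      n_permutations = 250L, fdr_alpha = 0.05,
                      imputation_width = 0.3, imputation_downshift = 1.8),
    catalogues = list(alpha = 0.05),
    rna = list(n_mirna = 40L, n_permutations = 200L, library_size = 1e6,
               dispersion = 0.1)
  )
}

.config_schema <- list(
  top = c("seed", "stages", "windows", "sec", "odg", "proteomics",
          "catalogues", "rna"),
  stages = c("simulate", "fracmetrics", "proteomics", "catalogues", "rna"),
  windows = c("sec_fractions", "lpp_density", "ev_density"),
  sec = c("noise_cv", "loss_fraction"),
  odg = c("noise_cv", "loss_fraction"),
  proteomics = c("n_features", "n_ev_markers", "n_lpp_markers", "n_corona",
                 "effect_log2", "s0", "min_valid_fraction", "n_permutations",
                 "fdr_alpha", "imputation_width", "imputation_downshift"),
  catalogues = c("alpha"),
  rna = c("n_mirna", "n_permutations", "library_size", "dispersion")
)

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration list or YAML file: unknown keys are
#' rejected (never silently ignored) and numeric fields are range-checked.
#'
#' @param config configuration list, or path to a YAML file.
#' @return character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0)
  chk_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      errs <<- c(errs, sprintf("unknown key(s) in %s: %s", where,
                               paste(bad, collapse = ", ")))
    }
  }
  chk_keys(config, .config_schema$top, "config")
  for (sec in intersect(names(config), setdiff(.config_schema$top, "seed"))) {
    chk_keys(config[[sec]], .config_schema[[sec]], sec)
  }
  num_in <- function(value, field, lower, upper = Inf) {
    if (is.null(value)) return(invisible(NULL))
    if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
        value < lower || value > upper) {
      errs <<- c(errs, sprintf("field `%s` must be a number in [%s, %s]",
                               field, format(lower), format(upper)))
    }
  }
  num_in(config$seed, "seed", 0, 2^31 - 1)
  num_in(config$sec$noise_cv, "sec.noise_cv", 0)
  num_in(config$sec$loss_fraction, "sec.loss_fraction", 0, 1 - 1e-12)
  num_in(config$odg$noise_cv, "odg.noise_cv", 0)
  num_in(config$odg$loss_fraction, "odg.loss_fraction", 0, 1 - 1e-12)
  num_in(config$proteomics$s0, "proteomics.s0", 0)
  num_in(config$proteomics$fdr_alpha, "proteomics.fdr_alpha", 1e-12, 1)
  num_in(config$proteomics$min_valid_fraction,
         "proteomics.min_valid_fraction", 0, 1)
  num_in(config$proteomics$n_permutations, "proteomics.n_permutations", 10)
  num_in(config$catalogues$alpha, "catalogues.alpha", 1e-12, 1)
  num_in(config$rna$dispersion, "rna.dispersion", 0)
  if (!is.null(config$windows$sec_fractions) &&
      any(config$windows$sec_fractions < 1)) {
    errs <- c(errs, "field `windows.sec_fractions` must be >= 1")
  }
  errs
}

# merge user config over defaults (shallow per section)
.merge_config <- function(config) {
  base <- default_config()
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      for (k2 in names(config[[k]])) base[[k]][[k2]] <- config[[k]][[k2]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  base
}

#' Run the end-to-end fractionation analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic inputs
#' generated from the configuration's seed: plasma simulation and SEC/ODG
#' fractionation, recovery/enrichment accounting over the configured
#' windows, the differential-proteomics workflow with planted EV/LPP/corona
#' effects, the rule-based protein catalogues, and the small-RNA analyses
#' (composition, DE, codon usage, GSEA against the bundled gene sets).
#' Per-stage seeds are derived from the global seed by a stable hash of the
#' stage name, so disabling one stage never shifts another stage's
#' randomness. All stage outputs and a JSON run report are written to
#' `out_dir`; the same configuration and seed always produce byte-identical
#' reports.
#'
#' @param config configuration list or YAML path (see [default_config()]);
#'   validated before running.
#' @param out_dir output directory (created if needed).
#' @return the run report, invisibly (list of class `run_report`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("pfrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  cfg <- .merge_config(config)
  st <- cfg$stages
  if (isTRUE(st$fracmetrics) && !isTRUE(st$simulate)) {
    stop("stage 'fracmetrics' requires stage 'simulate' to be enabled",
         call. = FALSE)
  }
  if (isTRUE(st$catalogues) && !isTRUE(st$proteomics)) {
    stop("stage 'catalogues' requires stage 'proteomics' to be enabled",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  report <- list(seed = cfg$seed, stages = st, parameters = cfg,
                 headline = list())

  withCallingHandlers({
    if (isTRUE(st$simulate)) {
      plasma <- make_default_plasma(stage_seed(cfg$seed, "simulate"))
      sec <- simulate_sec(plasma,
                          sec_column_model(noise_cv = cfg$sec$noise_cv,
                                           loss_fraction = cfg$sec$loss_fraction),
                          seed = stage_seed(cfg$seed, "simulate_sec"))
      crude <- pool_fractions(sec, cfg$windows$sec_fractions)
      odg <- simulate_odg(crude,
                          density_gradient_model(noise_cv = cfg$odg$noise_cv,
                                                 loss_fraction = cfg$odg$loss_fraction),
                          seed = stage_seed(cfg$seed, "simulate_odg"))
      write_fractionation_run(sec, file.path(out_dir, "sec_run.tsv"))
      write_fractionation_run(odg, file.path(out_dir, "odg_run.tsv"))
    }
    if (isTRUE(st$fracmetrics)) {
      w <- cfg$windows$sec_fractions
      lpp_fr <- density_window_fractions(odg, cfg$windows$lpp_density)
      ev_fr <- density_window_fractions(odg, cfg$windows$ev_density)
      prof <- elution_profile(odg, "CD9")
      report$headline$fracmetrics <- list(
        sec_recovery = list(
          CD9 = recovery_fraction(sec, w, "CD9"),
          APOA1 = recovery_fraction(sec, w, "APOA1"),
          APOB = recovery_fraction(sec, w, "APOB"),
          particles = recovery_fraction(sec, w, "particles"),
          protein = recovery_fraction(sec, w, "protein")),
        odg_recovery = list(
          APOA1_lpp_window = recovery_fraction(odg, lpp_fr, "APOA1"),
          APOB_lpp_window = recovery_fraction(odg, lpp_fr, "APOB"),
          CD9_ev_window = recovery_fraction(odg, ev_fr, "CD9"),
          CD9_peak_density = odg$fractions$density_g_ml[which.max(prof)]),
        enrichment = list(
          particles_vs_protein_sec = enrichment_factor(
            recovery_fraction(sec, w, "particles"),
            recovery_fraction(sec, w, "protein")),
          particles_vs_APOA1_sec = enrichment_factor(
            recovery_fraction(sec, w, "particles"),
            recovery_fraction(sec, w, "APOA1"))))
    }
    if (isTRUE(st$proteomics)) {
      pp <- cfg$proteomics
      prot <- .simulated_proteomics(pp, seed = stage_seed(cfg$seed, "proteomics"))
      flt <- filter_valid(prot$sim$matrix, prot$sim$groups,
                          pp$min_valid_fraction)
      imp <- impute_missing(flt, pp$imputation_width, pp$imputation_downshift,
                            seed = stage_seed(cfg$seed, "impute"))
      diff_ev <- permutation_fdr(imp, prot$sim$groups, "EV", "LPP",
                                 s0 = pp$s0, n_permutations = pp$n_permutations,
                                 fdr_alpha = pp$fdr_alpha,
                                 seed = stage_seed(cfg$seed, "permfdr"))
      utils::write.table(diff_ev, file.path(out_dir, "diff_ev_vs_lpp.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cs <- correlation_summary(imp, prot$sim$groups)
      report$headline$proteomics <- list(
        n_quantified = nrow(prot$sim$matrix), n_retained = nrow(flt),
        n_significant_ev_vs_lpp = sum(diff_ev$significant),
        median_within_group_correlation = cs$median_within,
        median_between_group_correlation = cs$median_between)
    }
    if (isTRUE(st$catalogues)) {
      al <- cfg$catalogues$alpha
      crude_ids <- detected_in_group(flt, prot$sim$groups, "crude",
                                     cfg$proteomics$min_valid_fraction)
      ev_ids <- detected_in_group(flt, prot$sim$groups, "EV",
                                  cfg$proteomics$min_valid_fraction)
      diff_lpp <- diff_ev
      diff_lpp$diff <- -diff_lpp$diff; diff_lpp$t_s0 <- -diff_lpp$t_s0
      non_ev <- select_non_ev_associated(crude_ids, diff_lpp, alpha = al)
      corona <- select_corona_candidates(crude_ids, diff_ev,
                                         prot$annotations, alpha = al,
                                         ev_detection = ev_ids)
      cand <- corona$protein[corona$category == "corona_candidate"]
      corr <- if (length(cand) >= 5) {
        mi <- rowMeans(imp[cand, prot$sim$groups[colnames(imp)] == "EV",
                           drop = FALSE])
        corona_concentration_correlation(mi, prot$annotations)
      } else NULL
      utils::write.table(non_ev, file.path(out_dir, "catalogue_non_ev.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(corona, file.path(out_dir, "catalogue_corona.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$headline$catalogues <- list(
        n_non_ev_associated = sum(non_ev$category == "non_EV_associated"),
        n_corona_candidates = length(cand),
        corona_concentration_rho = if (is.null(corr)) NA else corr$rho,
        corona_concentration_p = if (is.null(corr)) NA else corr$p)
    }
    if (isTRUE(st$rna)) {
      rr <- cfg$rna
      rna <- .simulated_rna(rr, seed = stage_seed(cfg$seed, "rna"))
      flt_c <- filter_features(rna$counts, rna$groups)
      sf <- size_factors(flt_c)
      de <- nb_wald_test(flt_c, rna$groups, "plasma", "EV", sf = sf)
      comp <- biotype_composition(rna$counts,
                                  rna$annotation$biotype[match(rownames(rna$counts),
                                                               rna$annotation$feature)],
                                  rna$groups)
      cup <- codon_usage_profile(flt_c, rna$annotation, rna$groups,
                                 "EV", "plasma", sf = sf)
      ranked <- rank_by_log2fc(de, rowMeans(normalize_counts(flt_c, sf)))
      gmt <- read_gmt(system.file("extdata", "demo_genesets.gmt",
                                  package = "plasmafrac"))
      gsea <- lapply(gmt, function(set) {
        g <- gsea_classic(ranked, set, n_permutations = rr$n_permutations,
                          seed = stage_seed(cfg$seed, "gsea"))
        list(es = g$es, nes = g$nes, p = g$p)
      })
      utils::write.table(de, file.path(out_dir, "rna_de.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(cup, file.path(out_dir, "rna_codon_usage.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gly <- cup$fold_change[cup$isotype == "Gly"]
      report$headline$rna <- list(
        n_features_retained = nrow(flt_c),
        n_de_plasma_vs_ev = sum(de$de),
        mirna_share_ev = unname(comp$by_group["miRNA", "EV"]),
        trna_share_ev = unname(comp$by_group["tRNA", "EV"]),
        gly_fold_change_ev_vs_plasma = if (length(gly)) gly else NA,
        n_isotypes_enriched_in_ev = sum(cup$fold_change > 1, na.rm = TRUE),
        n_isotypes = nrow(cup),
        gsea = gsea)
    }
  }, warning = log_warn)

  report$warnings <- warnings_log
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

# planted proteomics design shared by the pipeline and tests: EV markers
# (transmembrane, up in EV), LPP markers (up in LPP and crude), and secreted
# corona proteins (up in EV, present in crude)
.simulated_proteomics <- function(pp, seed) {
  nf <- pp$n_features
  feats <- sprintf("prot_%04d", seq_len(nf))
  ev_idx <- seq_len(pp$n_ev_markers)
  lpp_idx <- pp$n_ev_markers + seq_len(pp$n_lpp_markers)
  cor_idx <- pp$n_ev_markers + pp$n_lpp_markers + seq_len(pp$n_corona)
  eff <- rbind(
    data.frame(feature = feats[ev_idx], group = "EV",
               log2_shift = pp$effect_log2),
    data.frame(feature = feats[lpp_idx], group = "LPP",
               log2_shift = pp$effect_log2),
    data.frame(feature = feats[lpp_idx], group = "crude",
               log2_shift = pp$effect_log2),
    data.frame(feature = feats[cor_idx], group = "EV",
               log2_shift = pp$effect_log2))
  design <- omics_design(groups = c(crude = 6L, LPP = 6L, EV = 6L),
                         n_features = nf, planted_effects = eff, seed = seed)
  sim <- simulate_lfq(design)
  conc <- with_seed(seed + 1L,
                    2^(rowMeans(sim$complete)[feats] / 4 +
                         stats::rnorm(nf, 0, 0.4)))
  ann <- data.frame(protein_id = feats,
                    secreted = seq_len(nf) %in% cor_idx,
                    plasma_concentration = unname(conc))
  list(sim = sim, annotations = ann,
       truth = list(ev_markers = feats[ev_idx], lpp_markers = feats[lpp_idx],
                    corona = feats[cor_idx]))
}

# planted small-RNA design: HDL and platelet miRNA signatures higher in
# plasma, let-7e higher in EV
.simulated_rna <- function(rr, seed) {
  gmt <- read_gmt(system.file("extdata", "demo_genesets.gmt",
                              package = "plasmafrac"))
  plasma_up <- unique(unlist(gmt))
  eff <- rbind(
    data.frame(feature = plasma_up, group = "plasma", log2_shift = 1.5),
    data.frame(feature = "hsa-let-7e-5p", group = "EV", log2_shift = 1.5))
  design <- omics_design(groups = c(plasma = 6L, EV = 6L),
                         n_features = rr$n_mirna, planted_effects = eff,
                         dispersion = rr$dispersion, seed = seed)
  simulate_smallrna(design, library_size = rr$library_size)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:",
      paste(names(Filter(isTRUE, x$stages)), collapse = ", "), "\n")
  if (!is.null(x$headline$fracmetrics)) {
    fm <- x$headline$fracmetrics
    cat(sprintf("  SEC window CD9 %.1f%%, APOA1 %.2f%%; ODG APOA1 %.1f%%, APOB %.1f%% (LPP window), CD9 %.1f%% (EV window)\n",
                100 * fm$sec_recovery$CD9, 100 * fm$sec_recovery$APOA1,
                100 * fm$odg_recovery$APOA1_lpp_window,
                100 * fm$odg_recovery$APOB_lpp_window,
                100 * fm$odg_recovery$CD9_ev_window))
  }
  if (!is.null(x$headline$catalogues)) {
    cat(sprintf("  catalogues: %d non-EV-associated, %d corona candidates\n",
                x$headline$catalogues$n_non_ev_associated,
                x$headline$catalogues$n_corona_candidates))
  }
  invisible(x)
}
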