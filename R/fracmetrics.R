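#' Fractionation run container
#'
#' Ordered per-fraction measurements for one separation stage (SEC or ODG)
#' together with the whole-input reference totals against which recoveries
#' are computed. Simulated runs additionally carry the true per-class
#' particle composition so they can be pooled and re-fractionated.
#'
#' @param stage `"SEC"` or `"ODG"`.
#' @param reference list with `particle_count`, `protein_mass` and a named
#'   numeric `markers` vector of whole-input totals.
#' @param fractions data frame with columns `fraction_id` (consecutive from 1),
#'   `volume_ml`, `density_g_ml` (may be `NA` for SEC), `particle_count`,
#'   `protein_mass`, and one column per marker.
#' @param class_particles,classes,background_per_fraction,albumin_fraction
#'   internal simulation state (optional; absent for runs read from disk).
#' @return object of class `fractionation_run`.
#' @export
fractionation_run <- function(stage, reference, fractions,
                              class_particles = NULL, classes = NULL,
                              background_per_fraction = NULL,
                              albumin_fraction = NULL) {
  stage <- match.arg(stage, c("SEC", "ODG"))
  stopifnot(is.data.frame(fractions),
            all(c("fraction_id", "volume_ml", "particle_count",
                  "protein_mass") %in% names(fractions)))
  if (!identical(as.integer(fractions$fraction_id),
                 seq_len(nrow(fractions)))) {
    stop("fraction ids must be consecutive from 1", call. = FALSE)
  }
  structure(list(stage = stage, reference = reference, fractions = fractions,
                 class_particles = class_particles, classes = classes,
                 background_per_fraction = background_per_fraction,
                 albumin_fraction = albumin_fraction),
            class = "fractionation_run")
}

#' @export
print.fractionation_run <- function(x, ...) {
  cat(sprintf("<fractionation_run> stage %s, %d fractions\n",
              x$stage, nrow(x$fractions)))
  cat("analytes:", paste(setdiff(names(x$fractions),
                                 c("fraction_id", "volume_ml", "density_g_ml")),
                         collapse = ", "), "\n")
  invisible(x)
}

# resolve an analyte name to its per-fraction vector and reference total
.analyte <- function(run, analyte) {
  fr <- run$fractions
  if (analyte %in% c("particle_count", "particles")) {
    list(values = fr$particle_count, total = run$reference$particle_count)
  } else if (analyte %in% c("protein_mass", "protein")) {
    list(values = fr$protein_mass, total = run$reference$protein_mass)
  } else if (analyte %in% names(fr) &&
             !analyte %in% c("fraction_id", "volume_ml", "density_g_ml")) {
    list(values = fr[[analyte]], total = run$reference$markers[[analyte]])
  } else {
    stop(sprintf("unknown analyte '%s'", analyte), call. = FALSE)
  }
}

#' Recovery of an analyte in a set of fractions
#'
#' The proportion of the whole-input amount of an analyte found in the
#' selected fractions: `sum(analyte over fractions) / reference total`.
#' Assay noise can push a recovery marginally above 1; values above
#' 1 + `tolerance` are clamped to that bound with a warning.
#'
#' @param run a `fractionation_run`.
#' @param fractions integer fraction ids to pool (explicit; no default
#'   window is assumed).
#' @param analyte `"particles"`, `"protein"`, or a marker column name.
#' @param tolerance slack above 1 permitted before clamping.
#' @return a single proportion.
#' @export
#' @examples
#' run <- simulate_sec(make_default_plasma(1), sec_column_model(noise_cv = 0))
#' recovery_fraction(run, c(5, 6), "CD9")   # ~0.73
recovery_fraction <- function(run, fractions, analyte, tolerance = 0.05) {
  stopifnot(inherits(run, "fractionation_run"))
  a <- .analyte(run, analyte)
  if (is.null(a$total) || is.na(a$total) || a$total == 0) {
    stop(sprintf("reference total for '%s' is zero; recovery undefined", analyte),
         call. = FALSE)
  }
  idx <- match(fractions, run$fractions$fraction_id)
  if (anyNA(idx)) stop("unknown fraction id", call. = FALSE)
  r <- sum(a$values[idx]) / a$total
  if (r > 1 + tolerance) {
    warning(sprintf("recovery %.4f for '%s' exceeds 1 + tolerance; clamped", r,
                    analyte))
    r <- 1 + tolerance
  }
  r
}

#' Enrichment factor between two recoveries
#'
#' The ratio of the numerator analyte's recovery to the denominator
#' analyte's recovery over the same fraction window. Algebraically this
#' equals the selected-window analyte ratio divided by the same ratio in the
#' whole input, the conventional particle-vs-protein enrichment statistic.
#' Full precision is kept; rounding to "x-fold" is presentation only.
#'
#' @param recovery_numerator,recovery_denominator proportions in (0, 1\].
#' @return a positive factor.
#' @export
#' @examples
#' enrichment_factor(0.00685, 0.0000607)   # ~112.9, prints as 113-fold
enrichment_factor <- function(recovery_numerator, recovery_denominator) {
  assert_scalar_num(recovery_numerator, "recovery_numerator", lower = 0)
  assert_scalar_num(recovery_denominator, "recovery_denominator", lower = 0)
  if (recovery_denominator == 0) {
    stop("denominator recovery is zero; enrichment factor undefined",
         call. = FALSE)
  }
  if (recovery_numerator == 0) {
    stop("numerator recovery is zero; enrichment factor undefined",
         call. = FALSE)
  }
  recovery_numerator / recovery_denominator
}

#' Depletion factor of a marker relative to particles
#'
#' Alias of [enrichment_factor()] with the depleted marker in the
#' denominator; reported as the "relative depletion" of that marker.
#'
#' @param recovery_particles particle recovery (numerator).
#' @param recovery_marker marker recovery (denominator).
#' @return a positive factor.
#' @export
depletion_factor <- function(recovery_particles, recovery_marker) {
  enrichment_factor(recovery_particles, recovery_marker)
}

#' Per-fraction elution (or banding) profile of an analyte
#'
#' Proportion of the reference total found in each fraction; the profile
#' sums to the analyte's overall recovery (1 in lossless, noise-free runs).
#'
#' @param run a `fractionation_run`.
#' @param analyte analyte name as in [recovery_fraction()].
#' @return numeric vector of length `n_fractions`.
#' @export
elution_profile <- function(run, analyte) {
  stopifnot(inherits(run, "fractionation_run"))
  a <- .analyte(run, analyte)
  if (is.null(a$total) || is.na(a$total) || a$total == 0) {
    stop(sprintf("reference total for '%s' is zero", analyte), call. = FALSE)
  }
  p <- a$values / a$total
  names(p) <- run$fractions$fraction_id
  p
}

#' Enrichment report for one numerator/denominator pair
#'
#' @param run a `fractionation_run`.
#' @param fractions fraction ids of the selected window.
#' @param numerator,denominator analyte names.
#' @return list of class `enrichment_report` with both recoveries and the
#'   factor.
#' @export
enrichment_report <- function(run, fractions, numerator, denominator) {
  rn <- recovery_fraction(run, fractions, numerator)
  rd <- recovery_fraction(run, fractions, denominator)
  structure(list(numerator = numerator, denominator = denominator,
                 fractions = as.integer(fractions),
                 recovery_numerator = rn, recovery_denominator = rd,
                 factor = enrichment_factor(rn, rd)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("%s vs %s over fractions {%s}: %.3g%% vs %.3g%% -> %d-fold\n",
              x$numerator, x$denominator,
              paste(x$fractions, collapse = ","),
              100 * x$recovery_numerator, 100 * x$recovery_denominator,
              round(x$factor)))
  invisible(x)
}

# I/O ------------------------------------------------------------------------

#' Write a fractionation run as TSV plus a JSON sidecar
#'
#' The TSV holds the per-fraction table; the sidecar records the stage and
#' the whole-input reference totals.
#'
#' @param run a `fractionation_run`.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fractionation_run <- function(run, path) {
  stopifnot(inherits(run, "fractionation_run"))
  utils::write.table(run$fractions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(stage = run$stage,
                  reference = list(particle_count = run$reference$particle_count,
                                   protein_mass = run$reference$protein_mass,
                                   markers = as.list(run$reference$markers)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a fractionation run written by [write_fractionation_run()]
#' @param path TSV path with `<path>.json` sidecar alongside.
#' @return a `fractionation_run` (without per-class composition).
#' @export
read_fractionation_run <- function(path) {
  fr <- utils::read.delim(path, check.names = FALSE)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fractionation_run(stage = sc$stage,
                    reference = list(particle_count = sc$reference$particle_count,
                                     protein_mass = sc$reference$protein_mass,
                                     markers = unlist(sc$reference$markers)),
                    fractions = fr)
}
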