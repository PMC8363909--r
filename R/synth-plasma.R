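#' Particle class definition for the synthetic plasma model
#'
#' A particle class is one population of nanoparticles (or the soluble-protein
#' background treated as a pseudo-particle) circulating in plasma. Its size
#' distribution drives size-exclusion (SEC) elution, its buoyant density
#' drives density-gradient (ODG) banding, and its payload map defines how much
#' of each molecular marker one particle carries.
#'
#' @param name unique class label.
#' @param category one of `"EV"`, `"HDL"`, `"APOB_LPP"`, `"soluble_protein"`,
#'   `"spike_in"`.
#' @param concentration particles per ml plasma (>= 0).
#' @param size_median_nm median diameter in nm (> 0); the size distribution is
#'   log-normal.
#' @param size_gsd geometric standard deviation of the size distribution (>= 1).
#' @param density_mean mean buoyant density in g/ml, within \[0.95, 1.35\].
#' @param density_sd standard deviation of buoyant density in g/ml (>= 0).
#' @param payload named numeric vector, marker name -> amount per particle
#'   (arbitrary mass units, >= 0).
#' @param protein_per_particle protein mass contributed per particle
#'   (mass units, >= 0).
#' @return an object of class `particle_class`.
#' @export
particle_class <- function(name, category, concentration, size_median_nm,
                           size_gsd = 1.3, density_mean = 1.05,
                           density_sd = 0.005, payload = numeric(0),
                           protein_per_particle = 0) {
  category <- match.arg(category,
                        c("EV", "HDL", "APOB_LPP", "soluble_protein", "spike_in"))
  assert_scalar_num(concentration, "concentration", lower = 0)
  assert_scalar_num(size_median_nm, "size_median_nm", lower = 1e-12)
  assert_scalar_num(size_gsd, "size_gsd", lower = 1)
  assert_scalar_num(density_mean, "density_mean", lower = 0.95, upper = 1.35)
  assert_scalar_num(density_sd, "density_sd", lower = 0)
  assert_scalar_num(protein_per_particle, "protein_per_particle", lower = 0)
  if (length(payload)) {
    stopifnot(is.numeric(payload), !is.null(names(payload)), all(payload >= 0))
  }
  structure(list(name = name, category = category,
                 concentration = concentration,
                 size_median_nm = size_median_nm, size_gsd = size_gsd,
                 density_mean = density_mean, density_sd = density_sd,
                 payload = payload,
                 protein_per_particle = protein_per_particle),
            class = "particle_class")
}

#' Plasma model: particle classes plus a soluble-protein background
#'
#' @param volume_ml plasma volume loaded, in ml (> 0).
#' @param classes list of [particle_class()] objects with unique names.
#' @param background_total_per_ml soluble (non-particle) protein mass per ml.
#' @param albumin_fraction fraction of the soluble background that is albumin.
#' @return an object of class `plasma_model`.
#' @export
plasma_model <- function(volume_ml, classes, background_total_per_ml = 70,
                         albumin_fraction = 0.55) {
  assert_scalar_num(volume_ml, "volume_ml", lower = 1e-12)
  assert_scalar_num(background_total_per_ml, "background_total_per_ml", lower = 0)
  assert_scalar_num(albumin_fraction, "albumin_fraction", lower = 0, upper = 1)
  stopifnot(is.list(classes), length(classes) >= 1,
            all(vapply(classes, inherits, logical(1), "particle_class")))
  nm <- vapply(classes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("particle class names must be unique", call. = FALSE)
  names(classes) <- nm
  structure(list(volume_ml = volume_ml, classes = classes,
                 background_protein = list(total_per_ml = background_total_per_ml,
                                           albumin_fraction = albumin_fraction)),
            class = "plasma_model")
}

#' Default synthetic blood-plasma composition
#'
#' Builds the reference plasma used throughout the package: an EV population
#' at 1e10 particles/ml (50-250 nm, banding near 1.09-1.10 g/ml, carrying CD9
#' and FLOT1), HDL and apoB-containing lipoprotein classes that together are
#' about six orders of magnitude more concentrated than EV and band at
#' 1.04-1.07 g/ml (carrying APOA1 and APOB respectively, one apoB per
#' particle), a large chylomicron/VLDL class visible to particle tracking, and
#' an albumin-dominated soluble-protein background.
#'
#' The model itself is a deterministic parameter set; `seed` is stored and
#' propagated to downstream simulators.
#'
#' @param seed integer seed recorded in the model.
#' @return a `plasma_model` with attribute `seed`.
#' @export
#' @examples
#' pl <- make_default_plasma(1)
#' pl$classes$EV$concentration            # 1e10 particles/ml
make_default_plasma <- function(seed = 1L) {
  classes <- list(
    particle_class("EV", "EV", concentration = 1e10,
                   size_median_nm = 120, size_gsd = 1.4,
                   density_mean = 1.095, density_sd = 0.0067,
                   payload = c(CD9 = 1.0, FLOT1 = 0.6),
                   protein_per_particle = 2e-13),
    particle_class("HDL", "HDL", concentration = 5e15,
                   size_median_nm = 10, size_gsd = 1.15,
                   density_mean = 1.057, density_sd = 0.004,
                   payload = c(APOA1 = 1e-5),
                   protein_per_particle = 3.3e-16),
    particle_class("LDL", "APOB_LPP", concentration = 1.5e12,
                   size_median_nm = 22, size_gsd = 1.2,
                   density_mean = 1.055, density_sd = 0.003,
                   payload = c(APOB = 1e-6),
                   protein_per_particle = 8.5e-16),
    particle_class("CM_VLDL", "APOB_LPP", concentration = 2e10,
                   size_median_nm = 400, size_gsd = 1.5,
                   density_mean = 1.050, density_sd = 0.004,
                   payload = c(APOB = 1e-6),
                   protein_per_particle = 1e-14)
  )
  pl <- plasma_model(volume_ml = 2, classes = classes,
                     background_total_per_ml = 70, albumin_fraction = 0.55)
  attr(pl, "seed") <- as.integer(seed)
  pl
}

#' Total particle concentration of lipoprotein classes relative to EV
#' @param plasma a `plasma_model`.
#' @return ratio of summed HDL + APOB_LPP concentration to summed EV
#'   concentration.
#' @export
lpp_to_ev_ratio <- function(plasma) {
  conc <- vapply(plasma$classes, `[[`, numeric(1), "concentration")
  cat_ <- vapply(plasma$classes, `[[`, character(1), "category")
  sum(conc[cat_ %in% c("HDL", "APOB_LPP")]) / sum(conc[cat_ == "EV"])
}
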