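# shared in-code fixtures

# minimal hand-built fractionation run: one marker "M" with known amounts
toy_run <- function(amounts, total = sum(amounts), stage = "SEC") {
  n <- length(amounts)
  fractionation_run(
    stage = stage,
    reference = list(particle_count = 100, protein_mass = 10,
                     markers = c(M = total)),
    fractions = data.frame(fraction_id = seq_len(n), volume_ml = 1,
                           density_g_ml = NA_real_,
                           particle_count = rep(100 / n, n),
                           protein_mass = rep(10 / n, n),
                           M = amounts))
}

# wrap a plain data.frame as a differential_result
as_diff <- function(df) {
  class(df) <- c("differential_result", "data.frame")
  df
}

# grouped matrix with named samples
grouped_matrix <- function(values, n_features, groups) {
  samples <- unlist(lapply(names(groups), function(g) paste0(g, seq_len(groups[[g]]))))
  m <- matrix(values, nrow = n_features, ncol = length(samples),
              dimnames = list(sprintf("f%03d", seq_len(n_features)), samples))
  list(mat = m, groups = stats::setNames(rep(names(groups), groups), samples))
}
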