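# Shared fixtures: all built in code, nothing read from disk.

# small hand-made collection on a short grid
toy_collection <- function(n_points = 11L, n_spec = 3L, seed = 1L) {
  w <- seq(1000, 1000 + n_points - 1L, by = 1)
  a <- .with_toy_seed(seed, matrix(runif(n_points * n_spec, 0.1, 1), n_points))
  SpectrumCollection(a, w, dose = seq_len(n_spec) - 1,
                     replicate = rep(1L, n_spec))
}

.with_toy_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# deterministic noise-free designed experiment (63 spectra under defaults)
nf_design <- function(concentrations = c(0, 0.125, 0.25, 0.5, 1, 1.5, 2, 3, 4),
                      nReplicates = 7L) {
  generateDesign(noiseFreeConfig(concentrations = concentrations,
                                 nReplicates = nReplicates))
}

# single noise-free spectrum as a plain vector plus its grid
nf_trace <- function(dose) {
  s <- generateSpectrum(dose, noiseFreeConfig())
  list(w = wavenumbers(s), a = absorbance(s)[, 1L])
}
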