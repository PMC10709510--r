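# Small in-code fixtures shared across the suite.

tiny_species <- function(n = 1, g_max = 4, f_s = 500, eiv = 5) {
  species_table(data.frame(
    species_id = paste0("sp", seq_len(n)),
    name = paste("Species", seq_len(n)),
    L = eiv, T = eiv, M = eiv, R = eiv, N = eiv,
    C = 5, G = 5, TR = 5,
    g_max = g_max, f_s = f_s,
    stringsAsFactors = FALSE))
}

# homogeneous grid with matching site values (f_total = 1 when land use is 0)
tiny_grid <- function(species, initial, n_rows = 1, n_cols = 1,
                      site = c(L = 5, T = 5, M = 5, R = 5, N = 5),
                      landuse = c(C = 0, G = 0, TR = 0),
                      steps_per_year = 52, seed = 1,
                      dispersal_threshold = 100, n_years = 10, ...) {
  g <- global_params(steps_per_year = steps_per_year, n_years = n_years,
                     rng_seed = seed,
                     dispersal_threshold_pct = dispersal_threshold, ...)
  vegsucc:::homogeneous_grid(species, site, landuse, initial, g,
                             n_rows, n_cols)
}
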