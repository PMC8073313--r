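# Shared fixture builders. Everything is generated in code; no binary data.

# Independent elemental-sum oracle for diacyl-PC masses (kept separate from
# the package's own implementation on purpose).
oracle_pc_mass <- function(x, y) {
  m <- c(
    C = 12.0, H = 1.0078250319, N = 14.0030740052,
    O = 15.9949146221, P = 30.97376151
  )
  (x + 8) * m[["C"]] + (2 * x + 16 - 2 * y) * m[["H"]] +
    m[["N"]] + 8 * m[["O"]] + m[["P"]]
}

# Noiseless logistic trace in absolute fluorescence units around f0.
logistic_trace <- function(A = 1, k = 0.04, tm = 300, f0 = 100,
                           shock_time = 20, t_end = 1495, dt = 5,
                           noise_sd = 0) {
  t <- seq(0, t_end, by = dt)
  rel <- A / (1 + exp(-k * (t - shock_time - tm)))
  y <- f0 * (1 + rel) + f0 * rnorm(length(t), 0, noise_sd)
  fluorescence_trace(t, pmax(y, 0), channel = 515, shock_time = shock_time)
}

# Random normalized single-sample PC table over a species grid.
random_pc_table <- function(n_species = 8, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(x = seq(32, 40, 2), y = 0:6)
  pick <- grid[sample(nrow(grid), n_species), ]
  species_table(
    "random",
    sprintf("PC %d:%d", pick$x, pick$y),
    runif(n_species),
    normalize = TRUE
  )
}
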