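# small in-code fixtures shared across test files

toy_counts <- function() {
  m <- matrix(c(10, 12,  9, 11, 20, 22, 19, 21,
                 5,  4,  6,  5,  5,  6,  4,  5,
                50, 55, 45, 52, 12, 10, 14, 11),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("AAA", "BBB", "CCC"),
                              c("H1", "H2", "H3", "H4", "L1", "L2", "L3", "L4")))
  count_matrix(m, setNames(rep(c("high", "low"), each = 4), colnames(m)))
}

toy_groups <- function(samples = c("H1", "H2", "H3", "H4", "L1", "L2", "L3", "L4")) {
  setNames(rep(c("high", "low"), each = length(samples) / 2), samples)
}

small_sim <- function(n = 400, seed = 11, ...) {
  simulate_counts(sim_config(n_proteins = n, n_compartment = min(50, n),
                             seed = seed, ...))
}
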