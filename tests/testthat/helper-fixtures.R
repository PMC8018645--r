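# Small simulation fixtures shared across test files.

# one-compound spec with explicit variance components
one_compound_spec <- function(seed = 1, n_varieties = 5, n_locations = 4,
                              n_years = 1, n_blocks = 2,
                              mu = 10, sd_g = 1, sd_e = 2, sd_gxe = 0.5,
                              sd_eps = 0.3, block_sd = 0, ...) {
  sim_spec(n_varieties, n_locations, n_years, n_blocks,
           compounds = sim_compound("X", mu = mu, sd_g = sd_g, sd_e = sd_e,
                                    sd_gxe = sd_gxe, sd_eps = sd_eps),
           block_sd = block_sd, seed = seed, ...)
}

# deterministic non-negative means matrix for stability tests
toy_means <- function(V = 4, E = 5, seed = 42) {
  set.seed(seed)
  m <- outer(runif(V, 5, 15), rep(1, E)) +
    outer(rep(1, V), runif(E, -2, 2)) + matrix(rnorm(V * E, 0, 0.8), V, E)
  dimnames(m) <- list(sprintf("V%02d", 1:V), sprintf("E%02d", 1:E))
  m
}

# independent brute-force two-way decomposition of a means table
interaction_ss_bruteforce <- function(mm) {
  gm <- mean(mm)
  ss <- 0
  for (v in seq_len(nrow(mm)))
    for (e in seq_len(ncol(mm)))
      ss <- ss + (mm[v, e] - mean(mm[v, ]) - mean(mm[, e]) + gm)^2
  ss
}

# Heron's formula from the three pairwise side lengths
heron_area <- function(p) {
  a <- sqrt(sum((p[1, ] - p[2, ])^2))
  b <- sqrt(sum((p[2, ] - p[3, ])^2))
  c <- sqrt(sum((p[3, ] - p[1, ])^2))
  s <- (a + b + c) / 2
  sqrt(max(s * (s - a) * (s - b) * (s - c), 0))
}
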