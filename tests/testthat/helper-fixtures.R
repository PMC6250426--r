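# Random fixtures used across the property tests.  All draws go through
# with_seed-style local RNG so tests stay order-independent.

rand_fitness <- function(n, seed) {
  set.seed(seed)
  fitness_function(piC = runif(n, -1, 3), piD = runif(n, -1, 3))
}

rand_equal_gains_fitness <- function(n, seed) {
  set.seed(seed)
  linear_fitness(n, baseC = runif(1, -1, 1), baseD = runif(1, -1, 1),
                 slope = runif(1, -1, 1))
}

# fitness satisfying synergy condition 1:
# piC(i) >= piC(1) + (i - 1) [piD(1) - piD(0)]
rand_synergy_fitness <- function(n, seed) {
  set.seed(seed)
  piD <- runif(n, -1, 3)
  piC1 <- runif(1, -1, 3)
  d <- piD[2] - piD[1]
  piC <- piC1 + (seq_len(n) - 1) * d + c(0, runif(n - 1, 0, 1.5))
  fitness_function(piC = piC, piD = piD)
}

# random endpoint profile for a rare cooperator (no mass at i = 0)
rand_u_profile <- function(n, seed) {
  set.seed(seed)
  w <- rexp(n)
  structure_profile(c(0, w / sum(w)), end = "zero")
}

# closed-form selection differential for a 2-player game under the
# constant-relatedness structure: S(p) = a0 + a1 * p, derived from the
# conditional composition distributions by hand
affine_S_oracle <- function(game, r) {
  pc1 <- pi_C(game, 1); pc2 <- pi_C(game, 2)
  pd0 <- pi_D(game, 0); pd1 <- pi_D(game, 1)
  a0 <- (1 - r) * pc1 + r * pc2 - pd0
  a1 <- (1 - r) * (pc2 - pc1 - pd1 + pd0)
  c(intercept = a0, slope = a1)
}
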