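# shared fixtures: randomized exchange parameterizations spanning the
# slow, intermediate and fast exchange regimes

random_pair <- function(regime = c("slow", "intermediate", "fast"),
                        transverse = FALSE, off_resonance = FALSE) {
  regime <- match.arg(regime)
  R1_A <- runif(1, 0.1, 2)
  R1_B <- runif(1, 0.5, 10)
  A_tot <- runif(1, 10, 200)
  B_tot <- runif(1, 1, 50)
  # scale k_ex so min(kA, kB) sits in the requested regime vs max(R1)
  ratio <- switch(regime,
                  slow = runif(1, 0.001, 0.1),
                  intermediate = runif(1, 0.5, 5),
                  fast = runif(1, 200, 2000))
  k_ex <- ratio * max(R1_A, R1_B) / min(A_tot, B_tot)
  exchange_pair(R1_A = R1_A, R1_B = R1_B,
                R2_A = if (transverse) runif(1, 0.5, 5) else R1_A,
                R2_B = if (transverse) runif(1, 2, 30) else R1_B,
                omega_A = if (off_resonance) runif(1, -50, 50) else 0,
                omega_B = if (off_resonance) runif(1, -50, 50) else 0,
                k_ex = k_ex, A_tot = A_tot, B_tot = B_tot)
}

# relative discrepancy between two trajectories, normalized by the signal
# scale (guards against division by values crossing zero)
rel_discrepancy <- function(x, y) {
  max(abs(x - y)) / max(abs(y), 1e-300)
}

# canonical noiseless biexponential recovery used across fitting tests
biexp_recovery_curve <- function(a_slow = 0.7, a_fast = 0.3,
                                 T_slow = 2.0, T_fast = 0.3,
                                 times = recovery_times(), sigma = 0,
                                 seed = NULL) {
  y <- 1 - a_slow * exp(-times / T_slow) - a_fast * exp(-times / T_fast)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), sd = sigma)
  }
  decay_curve(times, y, "saturation_recovery")
}
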