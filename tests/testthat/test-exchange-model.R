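# closed-form exchange-coupled solutions vs matrix/ODE oracles

test_that("longitudinal eigenrates reduce correctly in limiting cases", {
  # decoupled pools: eigenrates are the pool relaxation rates
  p0 <- exchange_pair(R1_A = 0.4, R1_B = 3, k_ex = 0, A_tot = 50, B_tot = 5)
  expect_equal(unname(longitudinal_eigenrates(p0)), c(0.4, 3))
  # symmetric pools: (R, R + 2k)
  ps <- exchange_pair(R1_A = 1, R1_B = 1, k_ex = 0.2, A_tot = 10, B_tot = 10)
  expect_equal(unname(longitudinal_eigenrates(ps)), c(1, 1 + 2 * 0.2 * 10),
               tolerance = 1e-12)
})

test_that("eigenrates match a generic eigen-solver on random parameters", {
  set.seed(21)
  for (i in 1:20) {
    p <- random_pair(sample(c("slow", "intermediate", "fast"), 1))
    M <- matrix(c(p$r_A, -p$k_B, -p$k_A, p$r_B), 2, byrow = TRUE)
    ev <- sort(eigen(M, only.values = TRUE)$values)
    got <- longitudinal_eigenrates(p)
    expect_equal(unname(got), ev, tolerance = 1e-10)
    expect_true(got[1] >= 0 && got[1] <= got[2])
  }
})

test_that("saturation amplitudes follow the printed closed forms", {
  set.seed(22)
  for (i in 1:10) {
    p <- random_pair(sample(c("slow", "intermediate", "fast"), 1))
    ev <- longitudinal_eigenrates(p)
    sol <- longitudinal_solution(p, "saturation")
    L1 <- -p$Mz_inf_A * (p$R1_A - ev[["lambda2"]]) /
      (ev[["lambda2"]] - ev[["lambda1"]])
    L2 <- -p$Mz_inf_A * (ev[["lambda1"]] - p$R1_A) /
      (ev[["lambda2"]] - ev[["lambda1"]])
    expect_equal(sol$Lambda1, L1, tolerance = 1e-10)
    expect_equal(sol$Lambda2, L2, tolerance = 1e-10)
    # amplitude conservation and normalized coefficients
    expect_equal(sol$Lambda1 + sol$Lambda2, p$Mz_inf_A, tolerance = 1e-12)
    expect_equal(sol$a1s + sol$a1f, 1, tolerance = 1e-12)
  }
})

test_that("saturation recovery starts at zero and recovers to one", {
  set.seed(23)
  for (i in 1:5) {
    p <- random_pair("intermediate")
    expect_equal(longitudinal_signal(p, 0), 0, tolerance = 1e-12)
    expect_equal(longitudinal_signal(p, 1e4), 1, tolerance = 1e-8)
  }
  expect_error(longitudinal_signal(random_pair(), numeric(0)), "empty")
})

test_that("closed-form longitudinal trajectories match the ODE oracle", {
  set.seed(24)
  times <- exp(seq(log(1e-3), log(20), length.out = 40))
  for (regime in c("slow", "intermediate", "fast")) {
    for (i in 1:7) {
      p <- random_pair(regime)
      sol <- longitudinal_solution(p, "saturation")
      e1 <- exp(-sol$lambda1 * times); e2 <- exp(-sol$lambda2 * times)
      MA <- sol$Mz_ss_A - sol$Lambda1 * e1 - sol$Lambda2 * e2
      MB <- sol$Mz_ss_B - sol$Lambda1_B * e1 - sol$Lambda2_B * e2
      ode <- ode_reference(p, times, "longitudinal")
      scale <- max(abs(c(ode$M_A, ode$M_B)))
      expect_lt(max(abs(MA - ode$M_A), abs(MB - ode$M_B)) / scale, 1e-8)
    }
  }
})

test_that("custom initial conditions agree with the ODE oracle", {
  set.seed(25)
  times <- seq(0.01, 5, length.out = 25)
  for (i in 1:5) {
    p <- random_pair("intermediate")
    m0 <- c(runif(1, -1, 1) * p$A_tot, runif(1, -1, 1) * p$B_tot)
    s <- longitudinal_signal(p, times, initial = m0)
    ode <- ode_reference(p, times, "longitudinal", initial = m0)
    expect_equal(s, (ode$M_A + ode$M_B) / (p$Mz_inf_A + p$Mz_inf_B),
                 tolerance = 1e-8)
  }
})

test_that("transverse amplitudes satisfy their identities and limits", {
  set.seed(26)
  for (i in 1:10) {
    p <- random_pair(sample(c("slow", "intermediate", "fast"), 1),
                     transverse = TRUE, off_resonance = i %% 2 == 0)
    sol <- transverse_solution(p)
    expect_equal(sol$Theta1 + sol$Theta2, as.complex(p$Mxy0_A),
                 tolerance = 1e-12)
    expect_true(Re(sol$theta1) >= 0 && Re(sol$theta1) <= Re(sol$theta2))
  }
  # decoupled on-resonance pools decay with their own R2
  p0 <- exchange_pair(R1_A = 1, R1_B = 1, R2_A = 2, R2_B = 8,
                      k_ex = 0, A_tot = 10, B_tot = 5)
  sol0 <- transverse_solution(p0)
  expect_equal(sort(Re(c(sol0$theta1, sol0$theta2))), c(2, 8))
  tt <- c(0.01, 0.1, 0.5)
  expect_equal(transverse_signal(p0, tt),
               10 * exp(-2 * tt) + 5 * exp(-8 * tt), tolerance = 1e-12)
})

test_that("closed-form transverse trajectories match the ODE oracle", {
  set.seed(27)
  times <- exp(seq(log(5e-4), log(2), length.out = 30))
  for (regime in c("slow", "intermediate", "fast")) {
    for (i in 1:7) {
      p <- random_pair(regime, transverse = TRUE,
                       off_resonance = i %% 2 == 0)
      sol <- transverse_solution(p)
      e1 <- exp(-sol$theta1 * times); e2 <- exp(-sol$theta2 * times)
      MA <- sol$Theta1 * e1 + sol$Theta2 * e2
      MB <- sol$Theta1_B * e1 + sol$Theta2_B * e2
      ode <- ode_reference(p, times, "transverse")
      scale <- max(Mod(c(ode$M_A, ode$M_B)))
      expect_lt(max(Mod(MA - ode$M_A), Mod(MB - ode$M_B)) / scale, 1e-8)
    }
  }
})

test_that("magnetization exchange flux cancels pairwise in the oracle", {
  p <- random_pair("intermediate")
  times <- seq(0.005, 2, length.out = 50)
  ode <- ode_reference(p, times, "longitudinal")
  # d(MA+MB)/dt must equal the pure relaxation terms; compare the analytic
  # relaxation-only derivative against a numerical derivative of the sum
  tot <- ode$M_A + ode$M_B
  drel <- p$R1_A * (p$Mz_inf_A - ode$M_A) + p$R1_B * (p$Mz_inf_B - ode$M_B)
  dnum <- diff(tot) / diff(times)
  dmid <- (drel[-1] + drel[-length(drel)]) / 2
  expect_equal(dnum, dmid, tolerance = 1e-3)
})

test_that("pool-label symmetry leaves eigenrates and total signal unchanged", {
  set.seed(28)
  for (i in 1:5) {
    p <- random_pair("intermediate")
    q <- exchange_pair(R1_A = p$R1_B, R1_B = p$R1_A,
                       R2_A = p$R2_B, R2_B = p$R2_A,
                       k_ex = p$k_ex, A_tot = p$B_tot, B_tot = p$A_tot)
    expect_equal(longitudinal_eigenrates(p), longitudinal_eigenrates(q),
                 tolerance = 1e-12)
    tt <- c(0.01, 0.1, 1, 5)
    expect_equal(longitudinal_signal(p, tt), longitudinal_signal(q, tt),
                 tolerance = 1e-10)
  }
})

test_that("fast-exchange asymptotics reproduce the weighted-mean rate", {
  # xA = 0.9, xB = 0.1, R1 = (0.5, 2.0) -> 0.65 1/s
  p <- exchange_pair(R1_A = 0.5, R1_B = 2.0, k_ex = 1,
                     A_tot = 90, B_tot = 10)
  ap <- fast_exchange_approx(p)
  expect_equal(ap$lambda1_approx, 0.65, tolerance = 1e-12)
  expect_equal(ap$lambda2_approx, 1 * 100 + 0.1 * 0.5 + 0.9 * 2.0,
               tolerance = 1e-12)
  # single pool: weighted mean collapses to R1_A
  p1 <- exchange_pair(R1_A = 0.5, R1_B = 2.0, k_ex = 1,
                      A_tot = 90, B_tot = 0)
  expect_equal(fast_exchange_approx(p1)$lambda1_approx, 0.5)
  expect_error(fast_exchange_approx(
    exchange_pair(R1_A = 1, R1_B = 1, k_ex = 1, A_tot = 0, B_tot = 0)),
    "positive")
})

test_that("asymptotic eigenrate error is below 1% deep in the fast regime", {
  set.seed(29)
  for (i in 1:20) {
    p <- random_pair("fast")
    stopifnot(p$k_ex * (p$A_tot + p$B_tot) > 100 * max(p$R1_A, p$R1_B))
    ex <- longitudinal_eigenrates(p)[["lambda1"]]
    ap <- fast_exchange_approx(p)$lambda1_approx
    expect_lt(abs(ex - ap) / ex, 0.01)
  }
})

test_that("predicted coefficients interpolate between known limits", {
  # no exchange, equal pools, distinct rates: half/half
  p0 <- exchange_pair(R1_A = 0.5, R1_B = 5, k_ex = 0,
                      A_tot = 10, B_tot = 10)
  expect_equal(unname(predicted_coefficients(p0, "T1")), c(0.5, 0.5),
               tolerance = 1e-10)
  # fast exchange: slow component takes all the amplitude
  pf <- exchange_pair(R1_A = 0.5, R1_B = 5, k_ex = 100,
                      A_tot = 100, B_tot = 10)
  cf <- predicted_coefficients(pf, "T1")
  expect_equal(cf[["a_slow"]], 1, tolerance = 1e-3)
  expect_equal(cf[["a_fast"]], 0, tolerance = 1e-3)
  cf2 <- predicted_coefficients(pf, "T2")
  expect_equal(cf2[["a_slow"]], 1, tolerance = 1e-3)
})

test_that("fitting a noiseless model curve recovers predicted coefficients", {
  # intermediate exchange: both components visibly present
  p <- exchange_pair(R1_A = 0.3, R1_B = 3, k_ex = 0.02,
                     A_tot = 100, B_tot = 40)
  pred <- predicted_coefficients(p, "T1")
  y <- longitudinal_signal(p, recovery_times())
  fit <- fit_recovery(decay_curve(recovery_times(), y, "saturation_recovery"),
                      fit_config(model_order = "bi", include_offset = FALSE,
                                 ci_method = "none"))
  expect_equal(fit$a_slow, pred[["a_slow"]], tolerance = 1e-5)
  expect_equal(fit$a_fast, pred[["a_fast"]], tolerance = 1e-5)
  ev <- longitudinal_eigenrates(p)
  expect_equal(fit$T_slow, 1 / ev[["lambda1"]], tolerance = 1e-5)
  expect_equal(fit$T_fast, 1 / ev[["lambda2"]], tolerance = 1e-5)
})

test_that("observed signal composes the nonexchangeable pool correctly", {
  p <- exchange_pair(R1_A = 0.3, R1_B = 2, k_ex = 0.05,
                     A_tot = 100, B_tot = 20)
  tt <- recovery_times(n = 16)
  expect_equal(observed_signal(p, 4, 0, tt, "T1"),
               longitudinal_signal(p, tt), tolerance = 1e-12)
  expect_equal(observed_signal(p, 4, 1, tt, "T1"),
               1 - exp(-4 * tt), tolerance = 1e-12)
  expect_error(observed_signal(p, 4, 1.5, tt, "T1"), "nonexch_fraction")

  # fast exchange + third pool: biexponential fit sees a_fast ~ f_non
  pf <- exchange_pair(R1_A = 0.4, R1_B = 1.5, k_ex = 1,
                      A_tot = 500, B_tot = 100)
  f_non <- 0.25
  y <- observed_signal(pf, 1 / 0.25, f_non, recovery_times(), "T1")
  fit <- fit_recovery(decay_curve(recovery_times(), y, "saturation_recovery"),
                      fit_config(model_order = "bi", include_offset = FALSE,
                                 ci_method = "none"))
  expect_equal(fit$a_fast, f_non, tolerance = 0.01)
  expect_equal(fit$a_slow, 1 - f_non, tolerance = 0.01)
})

test_that("degenerate eigenrates yield a flagged single-exponential", {
  p <- exchange_pair(R1_A = 2, R1_B = 2, k_ex = 0, A_tot = 10, B_tot = 10)
  sol <- longitudinal_solution(p)
  expect_true(sol$degenerate)
  tt <- c(0.1, 0.5, 1)
  expect_equal(longitudinal_signal(p, tt), 1 - exp(-2 * tt),
               tolerance = 1e-12)
})

test_that("ode_reference validates its inputs", {
  p <- random_pair()
  expect_error(ode_reference(p, c(2, 1), "longitudinal"), "increasing")
  expect_error(ode_reference(p, numeric(0)), "increasing")
})
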