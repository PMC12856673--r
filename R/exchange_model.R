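#' Two-pool exchange parameterization
#'
#' Full parameterization of two exchanging proton pools: the solvent
#' (water) pool A and the solute (hydroxyl) pool B. Exchange is bimolecular
#' with a single second-order rate constant `k_ex`; the pseudo-first-order
#' coefficients are formed from the opposite pool's proton concentration,
#' kA = k_ex * B_tot and kB = k_ex * A_tot, so they are constants in an NMR
#' experiment but depend explicitly on composition.
#'
#' @param R1_A,R1_B Longitudinal relaxation rates (1/s) of the two pools in
#'   the absence of exchange.
#' @param R2_A,R2_B Transverse relaxation rates (1/s); default to the R1
#'   values.
#' @param omega_A,omega_B Precession offsets (rad/s) in the rotating frame
#'   (default 0: on resonance).
#' @param k_ex Second-order exchange rate constant (1/s per mol/m^3).
#' @param A_tot,B_tot Exchangeable proton concentrations (mol/m^3, or any
#'   common unit consistent with `k_ex`).
#' @param Mz_inf_A,Mz_inf_B Equilibrium longitudinal magnetizations;
#'   default proportional to pool sizes (`A_tot`, `B_tot`), the physical
#'   case for a uniform proton magnetic moment.
#' @param Mxy0_A,Mxy0_B Initial transverse magnetizations after the 90
#'   degree pulse; same default.
#' @param mu Magnetization scale constant relating population difference to
#'   magnetization; cancels in every normalized output (default 1).
#'
#' @return An object of class `exchange_pair` with derived fields `k_A`,
#'   `k_B`, `r_A = k_A + R1_A`, `r_B = k_B + R1_B`.
#' @export
exchange_pair <- function(R1_A, R1_B, R2_A = R1_A, R2_B = R1_B,
                          omega_A = 0, omega_B = 0,
                          k_ex, A_tot, B_tot,
                          Mz_inf_A = A_tot, Mz_inf_B = B_tot,
                          Mxy0_A = A_tot, Mxy0_B = B_tot,
                          mu = 1) {
  vals <- c(R1_A = R1_A, R1_B = R1_B, R2_A = R2_A, R2_B = R2_B,
            k_ex = k_ex, A_tot = A_tot, B_tot = B_tot)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rates, k_ex and concentrations must be finite and >= 0",
         call. = FALSE)
  k_A <- k_ex * B_tot
  k_B <- k_ex * A_tot
  structure(
    list(R1_A = R1_A, R1_B = R1_B, R2_A = R2_A, R2_B = R2_B,
         omega_A = omega_A, omega_B = omega_B,
         k_ex = k_ex, A_tot = A_tot, B_tot = B_tot,
         k_A = k_A, k_B = k_B,
         r_A = k_A + R1_A, r_B = k_B + R1_B,
         Mz_inf_A = Mz_inf_A, Mz_inf_B = Mz_inf_B,
         Mxy0_A = Mxy0_A, Mxy0_B = Mxy0_B,
         mu = mu),
    class = "exchange_pair"
  )
}

#' Build an exchange pair from a proton inventory
#'
#' Pool sizes (and hence equilibrium/initial magnetizations) are taken from
#' the inventory's exchangeable proton concentrations.
#'
#' @param inventory A [proton_inventory()] computed with a density (mol/m^3
#'   basis), so that `k_ex` has its per-(mol/m^3) meaning.
#' @inheritParams exchange_pair
#' @return An `exchange_pair`.
#' @export
exchange_pair_from_inventory <- function(inventory, R1_A, R1_B,
                                         R2_A = R1_A, R2_B = R1_B, k_ex) {
  stopifnot(inherits(inventory, "proton_inventory"))
  exchange_pair(R1_A = R1_A, R1_B = R1_B, R2_A = R2_A, R2_B = R2_B,
                k_ex = k_ex,
                A_tot = inventory$A_tot, B_tot = inventory$B_tot)
}

#' @export
print.exchange_pair <- function(x, ...) {
  cat("Two-pool exchange parameterization\n")
  cat(sprintf("  R1: %.4g / %.4g 1/s   R2: %.4g / %.4g 1/s\n",
              x$R1_A, x$R1_B, x$R2_A, x$R2_B))
  cat(sprintf("  k_ex = %.4g, A_tot = %.4g, B_tot = %.4g -> kA = %.4g, kB = %.4g 1/s\n",
              x$k_ex, x$A_tot, x$B_tot, x$k_A, x$k_B))
  invisible(x)
}

# relative tolerance used to flag numerically degenerate eigenrates
.DEGEN_TOL <- 1e-12

#' Longitudinal decay eigenrates
#'
#' Closed-form eigenrates of the exchange-coupled longitudinal
#' magnetization equations,
#' lambda_{1,2} = ((rA + rB) -/+ sqrt((rA - rB)^2 + 4 kA kB)) / 2,
#' ordered slow first (lambda1 <= lambda2).
#'
#' @param pair An [exchange_pair()].
#' @return Named numeric vector `c(lambda1, lambda2)` in 1/s.
#' @export
longitudinal_eigenrates <- function(pair) {
  stopifnot(inherits(pair, "exchange_pair"))
  s <- pair$r_A + pair$r_B
  d <- sqrt((pair$r_A - pair$r_B)^2 + 4 * pair$k_A * pair$k_B)
  c(lambda1 = (s - d) / 2, lambda2 = (s + d) / 2)
}

# Generic solution of dm/dt = -A m for a 2x2 matrix A (possibly complex),
# with m(0) = m0. Returns eigenrates (ordered by real part) and per-pool
# amplitudes: m_j(t) = amp_j1 exp(-l1 t) + amp_j2 exp(-l2 t).
# Degenerate eigenrates are only possible here when the off-diagonal
# couplings vanish, in which case A is diagonal(izable) and a flagged
# single-exponential representation is returned.
.two_pool_modes <- function(A, m0) {
  tr <- A[1, 1] + A[2, 2]
  disc <- sqrt((A[1, 1] - A[2, 2])^2 + 4 * A[1, 2] * A[2, 1])
  l <- c((tr - disc) / 2, (tr + disc) / 2)
  if (Re(l[2]) < Re(l[1])) l <- rev(l)
  degenerate <- abs(l[2] - l[1]) <= .DEGEN_TOL * max(abs(l[2]), 1)
  if (degenerate) {
    return(list(rates = l, degenerate = TRUE,
                amp = rbind(A_pool = c(m0[1], 0), B_pool = c(m0[2], 0))))
  }
  # eigenvector for eigenvalue l: (A11 - l) vA + A12 vB = 0
  V <- sapply(l, function(li) {
    if (abs(A[1, 2]) > abs(A[1, 1] - li)) c(1, -(A[1, 1] - li) / A[1, 2])
    else if (A[1, 1] - li != 0) c(-A[1, 2] / (A[1, 1] - li), 1)
    else c(1, 0)
  })
  cf <- solve(V, m0)
  list(rates = l, degenerate = FALSE,
       amp = rbind(A_pool = cf * V[1, ], B_pool = cf * V[2, ]))
}

# rate matrix A of dm/dt = -A m for the longitudinal deviation from steady
# state; same matrix governs the transverse equations with r2 in place of r
.long_matrix <- function(pair) {
  matrix(c(pair$r_A, -pair$k_B,
           -pair$k_A, pair$r_B), nrow = 2, byrow = TRUE)
}

.trans_matrix <- function(pair) {
  r2A <- pair$R2_A - 1i * pair$omega_A + pair$k_A
  r2B <- pair$R2_B - 1i * pair$omega_B + pair$k_B
  matrix(c(r2A, -pair$k_B,
           -pair$k_A, r2B), nrow = 2, byrow = TRUE)
}

# steady state of the longitudinal system (equals the stated equilibrium
# magnetizations exactly when they are proportional to pool sizes, since
# the exchange flux then vanishes at equilibrium)
.long_steady_state <- function(pair) {
  A <- .long_matrix(pair)
  b <- c(pair$R1_A * pair$Mz_inf_A, pair$R1_B * pair$Mz_inf_B)
  solve(A, b)
}

#' Closed-form longitudinal solution
#'
#' Biexponential solution of the exchange-coupled recovery equations.
#' For saturation initial conditions (both pools start at zero) with
#' equilibrium magnetizations proportional to pool sizes, the A-pool
#' amplitudes coincide with the printed closed forms
#' Lambda1 = -Mz_inf_A (R1_A - lambda2)/(lambda2 - lambda1) and
#' Lambda2 = -Mz_inf_A (lambda1 - R1_A)/(lambda2 - lambda1); for arbitrary
#' initial conditions the general 2x2 eigen-decomposition is used and
#' reduces to those forms in the saturation case.
#'
#' @param pair An [exchange_pair()].
#' @param initial `"saturation"` (both pools nulled at t = 0) or a numeric
#'   vector `c(Mz_A0, Mz_B0)` of custom initial longitudinal magnetizations.
#'
#' @return An object of class `longitudinal_solution` with eigenrates
#'   `lambda1 <= lambda2`, A-pool amplitudes `Lambda1`, `Lambda2`, B-pool
#'   amplitudes `Lambda1_B`, `Lambda2_B` (so that
#'   Mz_A(t) = Mz_ss_A - Lambda1 e^(-lambda1 t) - Lambda2 e^(-lambda2 t)
#'   and analogously for B), steady-state values `Mz_ss_A`, `Mz_ss_B`,
#'   normalized contribution coefficients `a1s`, `a1f`, and a `degenerate`
#'   flag marking the single-exponential limit.
#' @export
longitudinal_solution <- function(pair, initial = "saturation") {
  stopifnot(inherits(pair, "exchange_pair"))
  ss <- .long_steady_state(pair)
  m0 <- if (identical(initial, "saturation")) c(0, 0) else {
    stopifnot(is.numeric(initial), length(initial) == 2L)
    initial
  }
  modes <- .two_pool_modes(.long_matrix(pair), m0 - ss)
  ampA <- -Re(modes$amp["A_pool", ])   # Mz_A = ss_A - sum Lambda_i e^-li t
  ampB <- -Re(modes$amp["B_pool", ])
  tot <- pair$Mz_inf_A + pair$Mz_inf_B
  structure(
    list(lambda1 = Re(modes$rates[1]), lambda2 = Re(modes$rates[2]),
         Lambda1 = ampA[1], Lambda2 = ampA[2],
         Lambda1_B = ampB[1], Lambda2_B = ampB[2],
         Mz_ss_A = ss[1], Mz_ss_B = ss[2],
         a1s = (ampA[1] + ampB[1]) / tot,
         a1f = (ampA[2] + ampB[2]) / tot,
         degenerate = modes$degenerate,
         pair = pair, initial = initial),
    class = "longitudinal_solution"
  )
}

#' @export
print.longitudinal_solution <- function(x, ...) {
  cat(sprintf("Longitudinal solution: lambda = (%.5g, %.5g) 1/s%s\n",
              x$lambda1, x$lambda2,
              if (x$degenerate) " [degenerate: single exponential]" else ""))
  cat(sprintf("  a1s = %.5f, a1f = %.5f\n", x$a1s, x$a1f))
  invisible(x)
}

# evaluate pool trajectories of a longitudinal solution
.long_trajectories <- function(sol, times) {
  e1 <- exp(-sol$lambda1 * times)
  e2 <- exp(-sol$lambda2 * times)
  list(Mz_A = sol$Mz_ss_A - sol$Lambda1 * e1 - sol$Lambda2 * e2,
       Mz_B = sol$Mz_ss_B - sol$Lambda1_B * e1 - sol$Lambda2_B * e2)
}

#' Normalized longitudinal recovery signal
#'
#' Total observed recovery (Mz_A(t) + Mz_B(t)) / (Mz_inf_A + Mz_inf_B) of
#' the two exchangeable pools. For saturation initial conditions the signal
#' is 0 at t = 0 and recovers to 1.
#'
#' @inheritParams longitudinal_solution
#' @param times Nonnegative times in seconds.
#' @return Numeric vector of normalized signal values.
#' @export
longitudinal_signal <- function(pair, times, initial = "saturation") {
  if (length(times) == 0) stop("empty time grid", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  sol <- longitudinal_solution(pair, initial)
  tr <- .long_trajectories(sol, times)
  (tr$Mz_A + tr$Mz_B) / (pair$Mz_inf_A + pair$Mz_inf_B)
}

#' Closed-form transverse solution
#'
#' Complex biexponential solution of the exchange-coupled transverse
#' equations, obtained from the longitudinal forms by the substitutions
#' Mz_inf -> 0 and R1_j -> R2_j - i omega_j, giving complex eigenrates
#' theta_{1,2} = ((r2A + r2B) -/+ sqrt((r2A - r2B)^2 + 4 kA kB)) / 2 with
#' r2A = R2_A - i omega_A + kA, r2B = R2_B - i omega_B + kB. The A-pool
#' amplitudes satisfy Theta1 + Theta2 = Mxy0_A identically.
#'
#' @param pair An [exchange_pair()].
#' @return An object of class `transverse_solution` with complex eigenrates
#'   `theta1`, `theta2` (ordered by real part), complex amplitudes
#'   `Theta1`, `Theta2` (A pool) and `Theta1_B`, `Theta2_B` (B pool) such
#'   that Mxy_j(t) = Theta1_j e^(-theta1 t) + Theta2_j e^(-theta2 t),
#'   normalized contribution magnitudes `a2s`, `a2f`, and a `degenerate`
#'   flag.
#' @export
transverse_solution <- function(pair) {
  stopifnot(inherits(pair, "exchange_pair"))
  m0 <- c(pair$Mxy0_A, pair$Mxy0_B)
  modes <- .two_pool_modes(.trans_matrix(pair), as.complex(m0))
  cA <- modes$amp["A_pool", ]
  cB <- modes$amp["B_pool", ]
  comp <- cA + cB                     # per-mode contribution to the sum
  w <- Mod(comp)
  structure(
    list(theta1 = modes$rates[1], theta2 = modes$rates[2],
         Theta1 = cA[1], Theta2 = cA[2],
         Theta1_B = cB[1], Theta2_B = cB[2],
         a2s = if (sum(w) > 0) w[1] / sum(w) else NA_real_,
         a2f = if (sum(w) > 0) w[2] / sum(w) else NA_real_,
         degenerate = modes$degenerate,
         pair = pair),
    class = "transverse_solution"
  )
}

#' @export
print.transverse_solution <- function(x, ...) {
  cat(sprintf("Transverse solution: Re(theta) = (%.5g, %.5g) 1/s%s\n",
              Re(x$theta1), Re(x$theta2),
              if (x$degenerate) " [degenerate: single exponential]" else ""))
  cat(sprintf("  a2s = %.5f, a2f = %.5f\n", x$a2s, x$a2f))
  invisible(x)
}

.trans_trajectories <- function(sol, times) {
  e1 <- exp(-sol$theta1 * times)
  e2 <- exp(-sol$theta2 * times)
  list(Mxy_A = sol$Theta1 * e1 + sol$Theta2 * e2,
       Mxy_B = sol$Theta1_B * e1 + sol$Theta2_B * e2)
}

#' Transverse decay signal
#'
#' Evaluates the summed transverse magnetization Mxy_A(t) + Mxy_B(t) and
#' applies the detection mode. On resonance (both offsets zero) the two
#' modes coincide and the signal is a real biexponential decay.
#'
#' @inheritParams longitudinal_signal
#' @param detection `"magnitude"` (default) or `"real"`.
#' @return Numeric vector of signal values.
#' @export
transverse_signal <- function(pair, times,
                              detection = c("magnitude", "real")) {
  detection <- match.arg(detection)
  if (length(times) == 0) stop("empty time grid", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  sol <- transverse_solution(pair)
  tr <- .trans_trajectories(sol, times)
  s <- tr$Mxy_A + tr$Mxy_B
  if (detection == "magnitude") Mod(s) else Re(s)
}

#' Fast-exchange asymptotics
#'
#' First-order asymptotic eigenrates valid when both relaxation rates are
#' much smaller than the exchange coefficients kA, kB:
#' lambda1 ~ xA R1_A + xB R1_B (the population-weighted mean rate) and
#' lambda2 ~ k_ex (A_tot + B_tot) + xB R1_A + xA R1_B, with
#' xA = A_tot / (A_tot + B_tot). In this limit the slow component carries
#' all the amplitude (a_slow -> 1, a_fast -> 0).
#'
#' @param pair An [exchange_pair()].
#' @return A list with `lambda1_approx`, `lambda2_approx`, `a1s_approx = 1`,
#'   `a1f_approx = 0`, the pool fractions `x_A`, `x_B`, and `fast_regime`,
#'   a flag reporting (not enforcing) whether min(kA, kB) exceeds
#'   100 * max(R1_A, R1_B).
#' @export
fast_exchange_approx <- function(pair) {
  stopifnot(inherits(pair, "exchange_pair"))
  tot <- pair$A_tot + pair$B_tot
  if (tot <= 0) stop("A_tot + B_tot must be positive", call. = FALSE)
  xA <- pair$A_tot / tot
  xB <- pair$B_tot / tot
  list(lambda1_approx = xA * pair$R1_A + xB * pair$R1_B,
       lambda2_approx = pair$k_ex * tot + xB * pair$R1_A + xA * pair$R1_B,
       a1s_approx = 1, a1f_approx = 0,
       x_A = xA, x_B = xB,
       fast_regime = min(pair$k_A, pair$k_B) >
         100 * max(pair$R1_A, pair$R1_B))
}

#' Model-predicted contribution coefficients
#'
#' Normalized slow/fast contribution coefficients of the two-pool exchange
#' signal, for comparison with coefficients fitted to measured or simulated
#' decays. As k_ex grows the fast component vanishes (a_slow -> 1); at
#' k_ex = 0 the coefficients reduce to the pool fractions of the initial or
#' equilibrium magnetizations.
#'
#' @param pair An [exchange_pair()].
#' @param channel `"T1"` (saturation recovery) or `"T2"` (transverse decay).
#' @return Named numeric vector `c(a_slow, a_fast)`.
#' @export
predicted_coefficients <- function(pair, channel = c("T1", "T2")) {
  channel <- match.arg(channel)
  if (channel == "T1") {
    sol <- longitudinal_solution(pair, "saturation")
    c(a_slow = sol$a1s, a_fast = sol$a1f)
  } else {
    sol <- transverse_solution(pair)
    c(a_slow = sol$a2s, a_fast = sol$a2f)
  }
}

#' Observed signal including the nonexchangeable pool
#'
#' Carbon-bound solute protons do not exchange but still relax, adding a
#' third exponential component to the observed signal. The total normalized
#' signal is the proton-fraction-weighted sum of the two-pool exchange
#' signal and a single-exponential component with the nonexchangeable-pool
#' rate.
#'
#' @inheritParams longitudinal_signal
#' @param nonexch_rate Relaxation rate (1/s) of the nonexchangeable pool in
#'   the requested channel.
#' @param nonexch_fraction Fraction of all observed protons that are
#'   nonexchangeable (`xp_non` of a [proton_inventory()]), in \[0, 1\].
#' @param channel `"T1"` (recovery) or `"T2"` (decay).
#' @return Numeric vector of normalized signal values.
#' @export
observed_signal <- function(pair, nonexch_rate, nonexch_fraction, times,
                            channel = c("T1", "T2")) {
  channel <- match.arg(channel)
  if (nonexch_fraction < 0 || nonexch_fraction > 1)
    stop("nonexch_fraction must be in [0, 1]", call. = FALSE)
  if (length(times) == 0) stop("empty time grid", call. = FALSE)
  if (channel == "T1") {
    third <- 1 - exp(-nonexch_rate * times)
    two <- if (nonexch_fraction < 1) longitudinal_signal(pair, times)
           else rep(0, length(times))
  } else {
    third <- exp(-nonexch_rate * times)
    two <- if (nonexch_fraction < 1) {
      s <- transverse_signal(pair, times)
      s / (pair$Mxy0_A + pair$Mxy0_B)
    } else rep(0, length(times))
  }
  (1 - nonexch_fraction) * two + nonexch_fraction * third
}

#' Numerical reference solution of the coupled magnetization equations
#'
#' Integrates the exchange-coupled longitudinal or transverse equations
#' with tight tolerances (relative 1e-10) using `deSolve::lsoda`. Serves as
#' the independent validation oracle for the closed-form solutions.
#'
#' @inheritParams longitudinal_solution
#' @param times Strictly increasing times in seconds (t = 0 is prepended
#'   internally for the integrator and removed from the interface contract:
#'   values are returned at `times` as given).
#' @param channel `"longitudinal"` or `"transverse"`.
#' @param initial `"saturation"` (longitudinal: both pools nulled;
#'   transverse: pair's `Mxy0` values) or a numeric length-2 vector (may be
#'   complex for the transverse channel).
#' @return A data.frame with column `time` and pool trajectories `M_A`,
#'   `M_B` (complex for the transverse channel).
#' @export
ode_reference <- function(pair, times,
                          channel = c("longitudinal", "transverse"),
                          initial = "saturation") {
  channel <- match.arg(channel)
  stopifnot(inherits(pair, "exchange_pair"))
  if (length(times) == 0 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  t0 <- if (times[1] > 0) c(0, times) else times
  if (channel == "longitudinal") {
    m0 <- if (identical(initial, "saturation")) c(0, 0) else initial
    deriv <- function(t, y, p) {
      dA <- pair$R1_A * (pair$Mz_inf_A - y[1]) - pair$k_A * y[1] +
        pair$k_B * y[2]
      dB <- pair$R1_B * (pair$Mz_inf_B - y[2]) - pair$k_B * y[2] +
        pair$k_A * y[1]
      list(c(dA, dB))
    }
    scale <- max(abs(c(pair$Mz_inf_A, pair$Mz_inf_B, m0, 1)))
    out <- deSolve::lsoda(y = as.numeric(m0), times = t0, func = deriv,
                          parms = NULL, rtol = 1e-10, atol = 1e-12 * scale)
    if (attr(out, "istate")[1] < 0)
      stop("ODE integration failed (istate ",
           attr(out, "istate")[1], ")", call. = FALSE)
    out <- as.data.frame(out)[match(times, t0), ]
    data.frame(time = times, M_A = out[[2]], M_B = out[[3]])
  } else {
    m0 <- if (identical(initial, "saturation"))
      as.complex(c(pair$Mxy0_A, pair$Mxy0_B)) else as.complex(initial)
    A2 <- .trans_matrix(pair)
    # integrate real and imaginary parts of both pools
    deriv <- function(t, y, p) {
      m <- complex(real = y[c(1, 3)], imaginary = y[c(2, 4)])
      dm <- -A2 %*% m
      list(c(Re(dm[1]), Im(dm[1]), Re(dm[2]), Im(dm[2])))
    }
    scale <- max(abs(c(Mod(m0), 1)))
    y0 <- c(Re(m0[1]), Im(m0[1]), Re(m0[2]), Im(m0[2]))
    out <- deSolve::lsoda(y = y0, times = t0, func = deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12 * scale)
    if (attr(out, "istate")[1] < 0)
      stop("ODE integration failed (istate ",
           attr(out, "istate")[1], ")", call. = FALSE)
    out <- as.data.frame(out)[match(times, t0), ]
    data.frame(time = times,
               M_A = complex(real = out[[2]], imaginary = out[[3]]),
               M_B = complex(real = out[[4]], imaginary = out[[5]]))
  }
}
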