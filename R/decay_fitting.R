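#' A relaxation decay curve
#'
#' @param times Strictly increasing times in seconds.
#' @param signal Signal values (same length as `times`).
#' @param experiment `"saturation_recovery"` or `"cpmg"`.
#' @param replicate_id Integer replicate label (default 1).
#' @param metadata Optional list of sample descriptors (wt%, scenario, ...).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(times, signal,
                        experiment = c("saturation_recovery", "cpmg"),
                        replicate_id = 1L, metadata = list()) {
  experiment <- match.arg(experiment)
  if (length(times) != length(signal))
    stop("times and signal must have equal length", call. = FALSE)
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  structure(
    list(times = as.numeric(times), signal = as.numeric(signal),
         experiment = experiment, replicate_id = as.integer(replicate_id),
         metadata = metadata),
    class = "decay_curve"
  )
}

#' Fitting configuration
#'
#' @param model_order `"mono"`, `"bi"`, or `"auto"` (model selection via
#'   [select_model()]).
#' @param include_offset Include the offset constant y0 accounting for
#'   imperfect saturation and baseline drifts (default TRUE).
#' @param bounds Named list of `c(lower, upper)` bounds for `T` (time
#'   constants, s), `a` (normalized amplitudes) and `y0` (offset, in units
#'   of the normalized amplitude).
#' @param max_iterations,tolerance Optimizer control.
#' @param ci_level Confidence level for parameter intervals (default 0.80).
#' @param ci_method `"bootstrap"` (parametric, `n_boot` resamples, seeded),
#'   `"covariance"` (linearized), or `"none"`.
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Seed for the bootstrap (default 1).
#'
#' @details Reported amplitudes are normalized by the fitted signal scale:
#' the recovering amplitude (plateau minus baseline) for saturation
#' recovery, the extrapolated initial amplitude for CPMG. The scale itself
#' is a free parameter of the fit, so curves need not be pre-normalized.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(model_order = c("auto", "mono", "bi"),
                       include_offset = TRUE,
                       bounds = list(T = c(1e-4, 100), a = c(0, 1.5),
                                     y0 = c(-0.1, 0.1)),
                       max_iterations = 200, tolerance = 1e-10,
                       ci_level = 0.80,
                       ci_method = c("bootstrap", "covariance", "none"),
                       n_boot = 200, seed = 1L) {
  model_order <- match.arg(model_order)
  ci_method <- match.arg(ci_method)
  stopifnot(ci_level > 0, ci_level < 1,
            all(bounds$T > 0), bounds$a[1] >= 0)
  structure(
    list(model_order = model_order, include_offset = include_offset,
         bounds = bounds, max_iterations = max_iterations,
         tolerance = tolerance,
         ci_level = ci_level, ci_method = ci_method,
         n_boot = n_boot, seed = seed),
    class = "fit_config"
  )
}

# rough conditioning scale so absolute fit parameters are O(1): plateau
# region for recovery, maximum for CPMG; the fitted scale absorbs its bias
.rough_scale <- function(curve) {
  s <- if (curve$experiment == "saturation_recovery") {
    k <- max(3L, ceiling(length(curve$signal) / 5))
    mean(utils::tail(curve$signal, k))
  } else {
    max(curve$signal)
  }
  if (!is.finite(s) || s <= 0)
    stop("cannot scale: nonpositive signal level", call. = FALSE)
  s
}

# absolute (pre-scaled) model:
#   recovery: P - sum A_i exp(-t/T_i)   (P tied to sum(A) without offset)
#   cpmg:     sum A_i exp(-t/T_i) + C   (C = 0 without offset)
.decay_model_abs <- function(experiment, t, A, T, extra, offset) {
  s <- rowSums(vapply(seq_along(A),
                      function(i) A[i] * exp(-t / T[i]),
                      numeric(length(t))))
  if (experiment == "saturation_recovery") {
    P <- if (offset) extra else sum(A)
    P - s
  } else {
    (if (offset) extra else 0) + s
  }
}

# map raw absolute parameters to normalized Eq-style quantities
.normalize_params <- function(experiment, p, order, offset) {
  A <- if (order == "mono") p[["A1"]] else c(p[["As"]], p[["Af"]])
  T <- if (order == "mono") p[["T1"]] else c(p[["Ts"]], p[["Tf"]])
  if (order == "bi" && T[2] > T[1]) {    # enforce T_slow >= T_fast
    T <- rev(T); A <- rev(A)
  }
  if (experiment == "saturation_recovery") {
    S <- sum(A)                          # recovering amplitude = Mz_inf
    y0 <- if (offset) (p[["P"]] - S) / S else 0
  } else {
    C <- if (offset) p[["C"]] else 0
    S <- sum(A) + C                      # extrapolated initial amplitude
    y0 <- C / S
  }
  c(a_slow = A[1] / S,
    a_fast = if (order == "bi") A[2] / S else 0,
    T_slow = T[1],
    T_fast = if (order == "bi") T[2] else NA_real_,
    y0 = y0, S = S)
}

# deterministic initial guesses: profile the monoexponential time constant
# over a log grid, solving the amplitudes exactly (they enter linearly at
# fixed T), and keep the least-squares best -- immune to the local traps a
# single log-linear regression can fall into on noisy multi-decade grids
.init_heuristic <- function(curve, y, bounds) {
  t <- curve$times
  recov <- curve$experiment == "saturation_recovery"
  Tgrid <- exp(seq(log(max(bounds$T[1], min(t) / 2)),
                   log(min(bounds$T[2], 2 * max(t))), length.out = 25))
  best <- NULL
  for (T0 in Tgrid) {
    e <- exp(-t / T0)
    # recovery: y ~ P - A e ; cpmg: y ~ A e + C
    X <- if (recov) cbind(P = 1, A = -e) else cbind(A = e, C = 1)
    co <- tryCatch(stats::lm.fit(X, y)$coefficients,
                   error = function(err) NULL)
    if (is.null(co) || anyNA(co)) next
    a0 <- co[["A"]]
    if (a0 <= 0) next
    rss <- sum((y - X %*% co)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, T = T0, a = a0,
                   plateau = if (recov) co[["P"]] else NULL)
  }
  if (is.null(best))
    best <- list(T = stats::median(t), a = 1,
                 plateau = mean(utils::tail(y, 3)))
  clip <- function(v, b) min(max(v, b[1] * 1.01), b[2] * 0.99)
  list(a = clip(best$a, bounds$a + c(1e-6, 0)),
       T = clip(best$T, bounds$T),
       plateau = if (recov) best$plateau else mean(utils::tail(y, 3)))
}

.run_lm <- function(start, lower, upper, fn, t, yobs, config) {
  minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p, t, yobs) yobs - fn(p, t),
    t = t, yobs = yobs,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iterations,
      ftol = config$tolerance, ptol = config$tolerance))
}

.fit_order <- function(curve, config, order) {
  scale <- .rough_scale(curve)
  y <- curve$signal / scale
  offset <- config$include_offset
  n_par <- switch(order, mono = 2L, bi = 4L) + offset
  if (length(y) <= n_par)
    stop("fewer points than parameters (", length(y), " <= ", n_par, ")",
         call. = FALSE)
  if (order == "bi" && length(y) < 8)
    stop("biexponential fitting needs >= 8 points", call. = FALSE)
  b <- config$bounds
  recov <- curve$experiment == "saturation_recovery"
  # plateau bound derived from the amplitude and offset bounds
  P_bounds <- c(max(0.05, b$a[1]), b$a[2] * (1 + max(abs(b$y0))))
  ini <- .init_heuristic(curve, y, b)
  clipT <- function(v) pmin(pmax(v, b$T[1] * 1.01), b$T[2] * 0.99)
  clipP <- function(v) min(max(v, P_bounds[1]), P_bounds[2])
  model_fn <- function(p, t) {
    p <- unlist(p)
    if (order == "mono")
      .decay_model_abs(curve$experiment, t, p["A1"], p["T1"],
                       if (offset) p[[if (recov) "P" else "C"]] else NULL,
                       offset)
    else
      .decay_model_abs(curve$experiment, t, c(p["As"], p["Af"]),
                       c(p["Ts"], p["Tf"]),
                       if (offset) p[[if (recov) "P" else "C"]] else NULL,
                       offset)
  }
  add_extra <- function(start, lower, upper, extra_start) {
    if (!offset) return(list(s = start, l = lower, u = upper))
    if (recov) {
      start$P <- clipP(extra_start)
      list(s = start, l = c(lower, P_bounds[1]), u = c(upper, P_bounds[2]))
    } else {
      start$C <- 0
      list(s = start, l = c(lower, b$y0[1]), u = c(upper, b$y0[2]))
    }
  }
  if (order == "mono") {
    su <- add_extra(list(A1 = ini$a, T1 = ini$T),
                    c(b$a[1], b$T[1]), c(b$a[2], b$T[2]), ini$plateau)
    fit <- .run_lm(su$s, su$l, su$u, model_fn, curve$times, y, config)
  } else {
    lower <- c(b$a[1], b$a[1], b$T[1], b$T[1])
    upper <- c(b$a[2], b$a[2], b$T[2], b$T[2])
    # start 1: geometric split of the heuristic time constant
    su1 <- add_extra(list(As = 0.6 * ini$a, Af = 0.4 * ini$a,
                          Ts = clipT(3 * ini$T), Tf = clipT(ini$T / 3)),
                     lower, upper, ini$plateau)
    f1 <- .run_lm(su1$s, su1$l, su1$u, model_fn, curve$times, y, config)
    # start 2: the mono solution with a dormant second component, so the
    # biexponential fit can never end worse than the mono fit
    smono <- add_extra(list(A1 = ini$a, T1 = ini$T),
                       c(b$a[1], b$T[1]), c(b$a[2], b$T[2]), ini$plateau)
    fm <- .run_lm(smono$s, smono$l, smono$u,
                  function(p, t) {
                    p <- unlist(p)
                    .decay_model_abs(curve$experiment, t, p["A1"], p["T1"],
                                     if (offset) p[[if (recov) "P" else "C"]]
                                     else NULL, offset)
                  }, curve$times, y, config)
    pm <- stats::coef(fm)
    su2 <- add_extra(list(As = unname(pm["A1"]), Af = b$a[1],
                          Ts = unname(pm["T1"]),
                          Tf = clipT(unname(pm["T1"]) / 3)),
                     lower, upper,
                     if (offset && recov) unname(pm["P"]) else ini$plateau)
    if (offset && !recov) su2$s$C <- unname(pm["C"])
    f2 <- .run_lm(su2$s, su2$l, su2$u, model_fn, curve$times, y, config)
    fit <- if (sum(f1$fvec^2) <= sum(f2$fvec^2)) f1 else f2
  }
  p <- stats::coef(fit)
  rss <- sum(fit$fvec^2)
  tss <- sum((y - mean(y))^2)
  if (order == "bi") {
    lw <- su1$l; up <- su1$u
  } else {
    lw <- su$l; up <- su$u
  }
  list(fit = fit, par = p, y = y, scale = scale, order = order,
       offset = offset, experiment = curve$experiment,
       lower = lw, upper = up,
       rss = rss, r_squared = 1 - rss / tss,
       rmse = sqrt(rss / length(y)),
       converged = fit$info %in% 1:4,
       n_iterations = fit$niter,
       model_fn = model_fn, n_par = n_par)
}

# build the public result object from a raw fit
.as_fit_result <- function(raw, curve, config) {
  np <- .normalize_params(raw$experiment, raw$par, raw$order, raw$offset)
  out <- list(a_slow = np[["a_slow"]], a_fast = np[["a_fast"]],
              T_slow = np[["T_slow"]], T_fast = np[["T_fast"]],
              y0 = np[["y0"]],
              model_order = raw$order,
              r_squared = raw$r_squared,
              rmse = raw$rmse,
              rss = raw$rss,
              converged = raw$converged,
              n_iterations = raw$n_iterations,
              normalization = raw$scale * np[["S"]],
              experiment = curve$experiment,
              replicate_id = curve$replicate_id,
              metadata = curve$metadata,
              raw = raw)
  out$ci <- switch(config$ci_method,
                   none = NULL,
                   covariance = .ci_covariance(raw, config),
                   bootstrap = .ci_bootstrap(raw, curve, config))
  class(out) <- "relax_fit"
  out
}

# draws of the raw parameters -> quantiles of the normalized quantities
.ci_from_draws <- function(raw, draws, level, method) {
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  norm <- t(apply(draws, 1, function(pp) {
    .normalize_params(raw$experiment, pp, raw$order, raw$offset)
  }))
  keep <- setdiff(colnames(norm), "S")
  if (raw$order == "mono") keep <- setdiff(keep, c("a_fast", "T_fast"))
  est <- .normalize_params(raw$experiment, raw$par, raw$order, raw$offset)
  alpha <- (1 - level) / 2
  qs <- apply(norm[, keep, drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  data.frame(parameter = keep, estimate = unname(est[keep]),
             lower = qs[1, ], upper = qs[2, ], method = method,
             row.names = NULL)
}

.raw_covariance <- function(raw) {
  df <- length(raw$y) - raw$n_par
  cov <- tryCatch(raw$rss / df * solve(raw$fit$hessian),
                  error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  (cov + t(cov)) / 2
}

.ci_covariance <- function(raw, config) {
  cov <- .raw_covariance(raw)
  if (is.null(cov)) return(NULL)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  draws <- MASS::mvrnorm(max(500, config$n_boot), mu = raw$par, Sigma = cov)
  ci <- .ci_from_draws(raw, draws, config$ci_level, "covariance")
  attr(ci, "draws") <- draws
  ci
}

.ci_bootstrap <- function(raw, curve, config) {
  p <- raw$par
  fitted <- raw$model_fn(p, curve$times)
  sd_res <- sqrt(raw$rss / max(1, length(raw$y) - raw$n_par))
  draws <- matrix(NA_real_, nrow = config$n_boot, ncol = length(p),
                  dimnames = list(NULL, names(p)))
  nfail <- 0L
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  for (bidx in seq_len(config$n_boot)) {
    ystar <- fitted + stats::rnorm(length(fitted), sd = sd_res)
    fb <- tryCatch(
      minpack.lm::nls.lm(
        par = as.list(p), lower = raw$lower, upper = raw$upper,
        fn = function(pp, t, yobs) yobs - raw$model_fn(pp, t),
        t = curve$times, yobs = ystar,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fb) || !(fb$info %in% 1:4)) nfail <- nfail + 1L
    else draws[bidx, ] <- stats::coef(fb)
  }
  ci <- .ci_from_draws(raw, draws, config$ci_level, "bootstrap")
  attr(ci, "failure_rate") <- nfail / config$n_boot
  attr(ci, "flagged") <- nfail / config$n_boot > 0.10
  attr(ci, "draws") <- draws
  ci
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("%s %s fit: ", x$experiment,
              if (x$model_order == "mono") "mono" else "biexponential"))
  if (x$model_order == "mono")
    cat(sprintf("a = %.4f, T = %.4g s", x$a_slow, x$T_slow))
  else
    cat(sprintf("a_slow = %.4f (T = %.4g s), a_fast = %.4f (T = %.4g s)",
                x$a_slow, x$T_slow, x$a_fast, x$T_fast))
  cat(sprintf(", y0 = %.4f\n  R2 = %.6f, RMSE = %.3g, converged = %s\n",
              x$y0, x$r_squared, x$rmse, x$converged))
  invisible(x)
}

#' Fit a saturation-recovery curve
#'
#' Nonlinear least squares of the recovery
#' Mz(t)/Mz_inf = 1 + y0 - a1s exp(-t/T1s) - a1f exp(-t/T1f),
#' mono- or biexponential, with box bounds, deterministic initialization
#' (mono heuristics from a log-linear regression; the biexponential is
#' started both from a geometric split of the mono time constant and from
#' the mono solution itself, keeping the better optimum) and the
#' T_slow >= T_fast ordering convention applied after the fit. The signal
#' scale Mz_inf is fitted, so raw-amplitude curves are accepted and the
#' reported coefficients are normalized.
#'
#' @param curve A [decay_curve()] with `experiment = "saturation_recovery"`.
#' @param config A [fit_config()]. `model_order = "auto"` delegates to
#'   [select_model()].
#' @return An object of class `relax_fit` with normalized amplitudes
#'   `a_slow`, `a_fast`, time constants `T_slow >= T_fast` (s), offset
#'   `y0`, goodness of fit (`r_squared`, `rmse`), convergence flag,
#'   fitted scale `normalization`, and a `ci` table unless
#'   `ci_method = "none"`. Non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @export
fit_recovery <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "decay_curve"))
  if (curve$experiment != "saturation_recovery")
    stop("curve is not a saturation-recovery experiment", call. = FALSE)
  .fit_dispatch(curve, config)
}

#' Fit a CPMG decay curve
#'
#' As [fit_recovery()] but for the transverse decay model
#' Mxy(t)/Mxy0 = a2s exp(-t/T2s) + a2f exp(-t/T2f) + y0. The fitted
#' initial amplitude Mxy0 (echo train extrapolated to t = 0) provides the
#' normalization, so a2s + a2f = 1 - y0 by construction.
#'
#' @param curve A [decay_curve()] with `experiment = "cpmg"`.
#' @inheritParams fit_recovery
#' @return An object of class `relax_fit`.
#' @export
fit_cpmg <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "decay_curve"))
  if (curve$experiment != "cpmg")
    stop("curve is not a CPMG experiment", call. = FALSE)
  .fit_dispatch(curve, config)
}

.fit_dispatch <- function(curve, config) {
  if (config$model_order == "auto")
    return(select_model(curve, config)$selected_fit)
  raw <- .fit_order(curve, config, config$model_order)
  .as_fit_result(raw, curve, config)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' One-sided test for too few sign runs (systematic residual structure),
#' using the normal approximation with continuity correction.
#'
#' @param residuals Numeric residual vector.
#' @return List with `runs`, `expected`, `p_value` (small p: structured
#'   residuals).
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(runs = 1, expected = 1, p_value = 0))
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu + 0.5) / sqrt(v)
  list(runs = runs, expected = mu, p_value = stats::pnorm(z))
}

#' Select between mono- and biexponential models
#'
#' Fits both model orders and selects the biexponential only when it is
#' statistically justified: an F-test on the nested fits must reject the
#' monoexponential at `alpha` AND a runs test on the mono residuals must
#' detect systematic structure. This formalizes the residual-plot argument
#' commonly used to justify a second component.
#'
#' @param curve A [decay_curve()].
#' @param config A [fit_config()] (its `model_order` is ignored).
#' @param alpha Significance level for both tests (default 0.05).
#' @return A list with `selected` (`"mono"` or `"bi"`), `selected_fit`,
#'   both fits (`mono`, `bi`), `f_test` (statistic, p), and `runs`
#'   (the mono-residual runs test).
#' @export
select_model <- function(curve, config = fit_config(), alpha = 0.05) {
  stopifnot(inherits(curve, "decay_curve"))
  cfg <- config; cfg$model_order <- "mono"
  mono_raw <- .fit_order(curve, cfg, "mono")
  mono <- .as_fit_result(mono_raw, curve, cfg)
  bi <- tryCatch({
    cfg$model_order <- "bi"
    .as_fit_result(.fit_order(curve, cfg, "bi"), curve, cfg)
  }, error = function(e) NULL)
  n <- length(curve$times)
  if (is.null(bi)) {
    return(list(selected = "mono", selected_fit = mono, mono = mono,
                bi = NULL, f_test = NULL,
                runs = runs_test(mono_raw$fit$fvec)))
  }
  df1 <- bi$raw$n_par - mono_raw$n_par
  df2 <- n - bi$raw$n_par
  f <- ((mono$rss - bi$rss) / df1) / (bi$rss / df2)
  p_f <- stats::pf(max(f, 0), df1, df2, lower.tail = FALSE)
  rt <- runs_test(mono_raw$fit$fvec)
  sel <- if (p_f < alpha && rt$p_value < alpha && bi$converged) "bi"
         else "mono"
  list(selected = sel,
       selected_fit = if (sel == "bi") bi else mono,
       mono = mono, bi = bi,
       f_test = list(statistic = f, df1 = df1, df2 = df2, p_value = p_f),
       runs = rt)
}

#' Replicate statistics of fitted parameters
#'
#' Element-wise mean and standard deviation of fitted parameters across
#' replicate fits of the same sample. Per-fit confidence intervals are not
#' pooled with the replicate variability.
#'
#' @param results List of `relax_fit` objects (>= 2, same model order).
#' @return A data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
replicate_stats <- function(results) {
  if (length(results) < 2)
    stop("need >= 2 replicate fits", call. = FALSE)
  orders <- vapply(results, function(r) r$model_order, character(1))
  if (length(unique(orders)) > 1)
    stop("mixed model orders across replicates; refit with a common order",
         call. = FALSE)
  pars <- c("a_slow", "a_fast", "T_slow", "T_fast", "y0")
  if (orders[1] == "mono") pars <- setdiff(pars, c("a_fast", "T_fast"))
  m <- sapply(pars, function(p)
    vapply(results, function(r) r[[p]], numeric(1)))
  data.frame(parameter = pars,
             mean = apply(m, 2, mean),
             sd = apply(m, 2, stats::sd),
             n = length(results), row.names = NULL)
}

#' Pointwise confidence band for a fitted curve
#'
#' Band of the fitted decay at the configured confidence level, from a
#' parametric bootstrap (default) or from draws of the linearized parameter
#' covariance. Returned in the original signal units of the curve.
#'
#' @param curve The fitted [decay_curve()].
#' @param result A converged `relax_fit` for that curve.
#' @param config The [fit_config()] used (supplies level/method/seed).
#' @param times Evaluation grid (default the curve's own times).
#' @return A data.frame with columns `time`, `fit`, `lower`, `upper`; a
#'   `flagged` attribute marks bootstrap failure rates above 10%.
#' @export
confidence_band <- function(curve, result, config = fit_config(),
                            times = curve$times) {
  stopifnot(inherits(result, "relax_fit"))
  if (!result$converged)
    stop("confidence band requires a converged fit", call. = FALSE)
  raw <- result$raw
  fit0 <- raw$model_fn(raw$par, times)
  alpha <- (1 - config$ci_level) / 2
  if (config$ci_method == "covariance") {
    cov <- .raw_covariance(raw)
    if (is.null(cov)) stop("singular covariance", call. = FALSE)
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(config$seed)
    draws <- MASS::mvrnorm(max(500, config$n_boot), mu = raw$par,
                           Sigma = cov)
    flagged <- FALSE
  } else {
    ci <- .ci_bootstrap(raw, curve, config)
    draws <- attr(ci, "draws")
    draws <- draws[stats::complete.cases(draws), , drop = FALSE]
    flagged <- isTRUE(attr(ci, "flagged"))
  }
  curves <- apply(draws, 1, function(pp) {
    names(pp) <- colnames(draws)
    raw$model_fn(pp, times)
  })
  qs <- apply(curves, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(time = times, fit = fit0 * raw$scale,
                    lower = qs[1, ] * raw$scale,
                    upper = qs[2, ] * raw$scale)
  attr(out, "flagged") <- flagged
  out
}

#' Read decay curves from a CSV file
#'
#' Expects a header with columns `time_s`, `signal` and optionally
#' `replicate`; one [decay_curve()] is returned per replicate.
#'
#' @param path CSV path.
#' @param experiment Experiment kind of the file.
#' @param metadata Metadata attached to each curve.
#' @return A list of [decay_curve()] objects.
#' @export
read_decay_csv <- function(path,
                           experiment = c("saturation_recovery", "cpmg"),
                           metadata = list()) {
  experiment <- match.arg(experiment)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time_s", "signal")
  if (!all(need %in% names(df)))
    stop("CSV must have columns time_s, signal", call. = FALSE)
  if (is.null(df$replicate)) df$replicate <- 1L
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_s), ]
    decay_curve(d$time_s, d$signal, experiment,
                replicate_id = d$replicate[1], metadata = metadata)
  })
}

#' Summarize fit results across a concentration series
#'
#' @param results List of `relax_fit` objects carrying `wt_percent` in
#'   their metadata.
#' @param path Optional CSV output path.
#' @return A data.frame with columns `wt_percent`, `replicate`,
#'   `experiment`, `model_order`, `T_slow_ms`, `T_fast_ms`, `a_slow`,
#'   `a_fast`, `y0`, `R2`, `RMSE`, `converged`.
#' @export
fit_summary_table <- function(results, path = NULL) {
  stopifnot(length(results) > 0)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      wt_percent = if (is.null(r$metadata$wt_percent)) NA_real_
                   else r$metadata$wt_percent,
      replicate = r$replicate_id,
      experiment = r$experiment,
      model_order = r$model_order,
      T_slow_ms = 1000 * r$T_slow,
      T_fast_ms = 1000 * r$T_fast,
      a_slow = r$a_slow, a_fast = r$a_fast, y0 = r$y0,
      R2 = r$r_squared, RMSE = r$rmse, converged = r$converged)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
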