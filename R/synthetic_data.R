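#' Additive Gaussian noise model
#'
#' Time-domain NMR signals at high SNR carry approximately i.i.d. Gaussian
#' noise; `sigma` is expressed as a fraction of the maximum noiseless
#' signal.
#'
#' @param sigma Noise standard deviation as a fraction of max signal
#'   (>= 0; 0.01 is a typical benchtop value).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.01, seed = NULL) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

#' Default acquisition grids
#'
#' Saturation recovery: `n` log-spaced delays between `t_min` and `t_max`
#' (defaults 32 points, 4 ms to 30 s). CPMG: echo times `2 tau k`,
#' k = 1..`n_echoes` (defaults 3000 echoes, tau = 1 ms; tau is the 90-180
#' interpulse spacing so successive echoes are 2 tau apart).
#'
#' @param n,t_min,t_max Recovery grid descriptors.
#' @return Numeric vector of sampling times in seconds.
#' @export
recovery_times <- function(n = 32, t_min = 0.004, t_max = 30) {
  stopifnot(n >= 2, t_min > 0, t_max > t_min)
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' @rdname recovery_times
#' @param n_echoes Number of echoes.
#' @param tau Interpulse spacing in seconds (typical range 300-3000 us).
#' @export
cpmg_times <- function(n_echoes = 3000, tau = 1e-3) {
  stopifnot(n_echoes >= 1, tau > 0)
  2 * tau * seq_len(n_echoes)
}

#' Simulate one decay curve
#'
#' Evaluates the closed-form model signal (two-pool exchange, optionally
#' composed with a nonexchangeable third component) on the acquisition grid
#' and adds seeded Gaussian noise.
#'
#' @param pair An [exchange_pair()].
#' @param experiment `"saturation_recovery"` or `"cpmg"`.
#' @param times Acquisition grid; defaults to [recovery_times()] or
#'   [cpmg_times()] according to `experiment`.
#' @param noise A [noise_model()]; default noiseless.
#' @param nonexch_rate,nonexch_fraction Optional third-component
#'   parameters, as in [observed_signal()]; `nonexch_fraction = 0` (the
#'   default) gives the pure two-pool signal.
#' @param replicate_id,metadata Passed to [decay_curve()]; the noiseless
#'   truth and parameters are stored in the metadata.
#' @return A [decay_curve()].
#' @export
simulate_decay <- function(pair,
                           experiment = c("saturation_recovery", "cpmg"),
                           times = NULL, noise = noise_model(0),
                           nonexch_rate = 0, nonexch_fraction = 0,
                           replicate_id = 1L, metadata = list()) {
  experiment <- match.arg(experiment)
  if (is.null(times))
    times <- if (experiment == "saturation_recovery") recovery_times()
             else cpmg_times()
  channel <- if (experiment == "saturation_recovery") "T1" else "T2"
  clean <- if (nonexch_fraction > 0) {
    observed_signal(pair, nonexch_rate, nonexch_fraction, times, channel)
  } else if (channel == "T1") {
    longitudinal_signal(pair, times)
  } else {
    transverse_signal(pair, times) / (pair$Mxy0_A + pair$Mxy0_B)
  }
  y <- clean
  if (noise$sigma > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    if (!is.null(noise$seed)) set.seed(noise$seed)
    y <- clean + stats::rnorm(length(clean),
                              sd = noise$sigma * max(abs(clean)))
  }
  metadata$truth <- list(clean = clean, pair = pair,
                         nonexch_rate = nonexch_rate,
                         nonexch_fraction = nonexch_fraction,
                         sigma = noise$sigma, seed = noise$seed)
  decay_curve(times, y, experiment, replicate_id, metadata)
}

#' Default relaxation-rate profiles for sucrose solutions
#'
#' Smooth monotone-decreasing relaxation-time profiles versus sucrose
#' content, bracketing the ranges typical of benchtop measurements on
#' sucrose solutions at 25 degrees C: water-pool T1 from ~3.2 s (neat
#' water at low field) down to below 1 s at high concentration, hydroxyl
#' and carbon-bound pools faster, and T2 values shorter than T1
#' throughout. These are plausible stand-in inputs for simulation -- the
#' pool rates underlying any real sample must be supplied by the user.
#'
#' @param wt_percent Sucrose content in wt% (vectorized).
#' @return A data.frame with columns `wt_percent`, `R1_A`, `R1_B`,
#'   `R1_non`, `R2_A`, `R2_B`, `R2_non` (rates in 1/s).
#' @export
default_rate_model <- function(wt_percent) {
  stopifnot(all(wt_percent >= 0 & wt_percent <= 100))
  w <- wt_percent
  data.frame(
    wt_percent = w,
    R1_A  = 1 / (3.2 * exp(-0.022 * w)),
    R1_B  = 1 / (1.2 * exp(-0.020 * w)),
    R1_non = 1 / (0.35 * exp(-0.018 * w)),
    R2_A  = 1 / (1.8 * exp(-0.035 * w)),
    R2_B  = 1 / (0.25 * exp(-0.025 * w)),
    R2_non = 1 / (0.06 * exp(-0.015 * w)))
}

#' Concentration-series specification
#'
#' Describes a simulated experiment series: a sucrose wt% grid in one of
#' the three solvent scenarios (`"H2O"`, `"D2O"`, or `"FD-D2O"`: sucrose
#' pre-equilibrated in D2O, freeze-dried and redissolved in D2O), the
#' per-concentration pool rates, the exchange rate constant, acquisition
#' grids and noise.
#'
#' @param wt_percent_grid Sucrose contents in wt% (nonempty).
#' @param scenario `"H2O"`, `"D2O"`, or `"FD-D2O"`.
#' @param rate_model Data.frame as returned by [default_rate_model()]
#'   covering the grid (the default calls it).
#' @param k_ex Second-order exchange rate constant (1/s per mol/m^3);
#'   default 0.05, placing all three solvent scenarios in the fast-exchange
#'   regime, consistent with the millisecond-or-faster hydroxyl-water
#'   proton exchange typical near neutral pH.
#' @param noise A [noise_model()] (its seed is the series base seed).
#' @param replicates Replicates per sample (default 3).
#' @param recovery,cpmg Acquisition grids for the two channels.
#' @param solvent_protiation Residual H atom fraction of the D2O used
#'   (default [D2O_RESIDUAL_PROTIATION]; ignored for H2O).
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(wt_percent_grid,
                        scenario = c("H2O", "D2O", "FD-D2O"),
                        rate_model = default_rate_model(wt_percent_grid),
                        k_ex = 0.05,
                        noise = noise_model(0.01, seed = 1L),
                        replicates = 3L,
                        recovery = recovery_times(),
                        cpmg = cpmg_times(),
                        solvent_protiation = D2O_RESIDUAL_PROTIATION) {
  scenario <- match.arg(scenario)
  stopifnot(length(wt_percent_grid) > 0, replicates >= 1)
  if (!all(wt_percent_grid %in% rate_model$wt_percent))
    stop("rate_model does not cover the wt% grid", call. = FALSE)
  structure(
    list(wt_percent_grid = wt_percent_grid, scenario = scenario,
         rate_model = rate_model, k_ex = k_ex, noise = noise,
         replicates = as.integer(replicates),
         recovery = recovery, cpmg = cpmg,
         solvent_protiation = solvent_protiation),
    class = "series_spec"
  )
}

#' Mixture specification for a scenario
#'
#' Maps one of the three experimental scenarios to a [mixture_spec()]:
#' H2O (fully protiated), D2O (residual solvent protiation, as-purchased
#' sucrose), or FD-D2O (solute hydroxyl protiation set by
#' [freeze_dry_exchange()] of a 20 wt% sucrose / 80 wt% D2O stage-1
#' solution, then redissolved in D2O). The mixture density defaults to the
#' built-in sucrose-solution correlation so inventories come out in
#' mol/m^3.
#'
#' @param wt_percent Sucrose content in wt%.
#' @param scenario `"H2O"`, `"D2O"`, or `"FD-D2O"`.
#' @param solvent_protiation Residual H fraction of the D2O.
#' @param density Mixture density (kg/m^3); default from
#'   [sucrose_solution_density()].
#' @return A [mixture_spec()].
#' @export
scenario_mixture <- function(wt_percent,
                             scenario = c("H2O", "D2O", "FD-D2O"),
                             solvent_protiation = D2O_RESIDUAL_PROTIATION,
                             density = sucrose_solution_density(wt_percent / 100)) {
  scenario <- match.arg(scenario)
  w <- wt_percent / 100
  switch(scenario,
    "H2O" = mixture_spec(w, "H2O", density = density),
    "D2O" = mixture_spec(w, "D2O", solvent_protiation = solvent_protiation,
                         density = density),
    "FD-D2O" = {
      stage1 <- mixture_spec(0.20, "D2O",
                             solvent_protiation = solvent_protiation)
      occ <- freeze_dry_exchange(stage1)
      mixture_spec(w, "D2O", solvent_protiation = solvent_protiation,
                   solute_site_protiation = occ, density = density)
    })
}

#' Simulate a concentration series
#'
#' For each concentration and replicate, builds the proton inventory for
#' the scenario, assembles the [exchange_pair()] from the inventory pool
#' sizes and the rate model, composes the three-component observed signal
#' (two exchanging pools plus the nonexchangeable pool weighted by
#' `xp_non`), and simulates the requested channels with seeded noise.
#' Per-curve seeds are derived deterministically from the series seed, so
#' the same spec regenerates byte-identical data.
#'
#' @param spec A [series_spec()].
#' @param channels Which experiments to simulate (default both).
#' @return A list of [decay_curve()] objects; the attribute `"manifest"`
#'   holds a data.frame with scenario, wt%, replicate, experiment, seed and
#'   truth parameters for exact regeneration and truth-based scoring.
#' @export
simulate_series <- function(spec,
                            channels = c("saturation_recovery", "cpmg")) {
  stopifnot(inherits(spec, "series_spec"))
  channels <- match.arg(channels, several.ok = TRUE)
  base_seed <- if (is.null(spec$noise$seed)) 0L else spec$noise$seed
  curves <- list()
  manifest <- list()
  idx <- 0L
  for (w in spec$wt_percent_grid) {
    mix <- scenario_mixture(w, spec$scenario, spec$solvent_protiation)
    inv <- proton_inventory(mix)
    rates <- spec$rate_model[spec$rate_model$wt_percent == w, ][1, ]
    for (ch in channels) {
      t1 <- ch == "saturation_recovery"
      pair <- exchange_pair_from_inventory(
        inv, R1_A = rates$R1_A, R1_B = rates$R1_B,
        R2_A = rates$R2_A, R2_B = rates$R2_B, k_ex = spec$k_ex)
      non_rate <- if (t1) rates$R1_non else rates$R2_non
      for (rep_i in seq_len(spec$replicates)) {
        idx <- idx + 1L
        seed_i <- (base_seed + 7919L * idx) %% .Machine$integer.max
        cur <- simulate_decay(
          pair, experiment = ch,
          times = if (t1) spec$recovery else spec$cpmg,
          noise = noise_model(spec$noise$sigma, seed = seed_i),
          nonexch_rate = non_rate, nonexch_fraction = inv$xp_non,
          replicate_id = rep_i,
          metadata = list(wt_percent = w, scenario = spec$scenario,
                          xp_non = inv$xp_non, xp_exch = inv$xp_exch))
        curves[[idx]] <- cur
        manifest[[idx]] <- data.frame(
          scenario = spec$scenario, wt_percent = w, replicate = rep_i,
          experiment = ch, seed = seed_i, sigma = spec$noise$sigma,
          k_ex = spec$k_ex, A_tot = inv$A_tot, B_tot = inv$B_tot,
          xp_non = inv$xp_non, xp_exch = inv$xp_exch,
          R1_A = rates$R1_A, R1_B = rates$R1_B,
          R2_A = rates$R2_A, R2_B = rates$R2_B,
          nonexch_rate = non_rate)
      }
    }
  }
  attr(curves, "manifest") <- do.call(rbind, manifest)
  curves
}

#' Write a simulated series to disk
#'
#' One CSV per curve (columns `time_s`, `signal`, `replicate`) plus a
#' manifest JSON enabling exact regeneration and truth-based scoring.
#'
#' @param curves Output of [simulate_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_series <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- attr(curves, "manifest")
  files <- character(length(curves))
  for (i in seq_along(curves)) {
    cur <- curves[[i]]
    f <- sprintf("%s_wt%02d_%s_rep%d.csv",
                 gsub("[^A-Za-z0-9]", "", cur$metadata$scenario),
                 as.integer(cur$metadata$wt_percent),
                 if (cur$experiment == "cpmg") "cpmg" else "satrec",
                 cur$replicate_id)
    utils::write.csv(
      data.frame(time_s = cur$times, signal = cur$signal,
                 replicate = cur$replicate_id),
      file.path(dir, f), row.names = FALSE)
    files[i] <- f
  }
  manifest$file <- files
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, digits = NA, pretty = TRUE)
  invisible(mpath)
}
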