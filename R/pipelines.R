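#' Read a pipeline run configuration
#'
#' A single YAML or JSON config drives the command-line pipelines. Top-level
#' fields (all optional unless a command requires them): `mixtures` (list of
#' mixture records, see [read_mixtures()]), `scenario`, `wt_percent_grid`,
#' `k_ex` / `k_ex_grid`, `noise_sigma`, `replicates`, `seed`, `fit`
#' (fields of [fit_config()]), `input_dir`, `experiment`.
#'
#' @param path Path to `.yaml`/`.yml`/`.json`.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported config format: .", ext, call. = FALSE))
  structure(cfg, class = "run_config")
}

.cfg_fit_config <- function(config, seed = NULL) {
  f <- config$fit
  if (is.null(f)) f <- list()
  if (!is.null(seed)) f$seed <- seed
  do.call(fit_config, f)
}

#' Pipeline: proton-inventory table
#'
#' Runs the composition module over the configured mixtures (or a
#' scenario + wt% grid) and writes the inventory table CSV.
#'
#' @param config A [read_run_config()] list (or plain list).
#' @param out Output CSV path (default `inventory.csv` in the working
#'   directory).
#' @return The inventory data.frame, invisibly written to `out`.
#' @export
run_inventory <- function(config, out = "inventory.csv") {
  mixes <- if (!is.null(config$mixtures)) {
    lapply(config$mixtures, function(r)
      mixture_spec(r$wt_percent / 100, r$solvent,
                   solvent_protiation = r$solvent_protiation,
                   solute_site_protiation =
                     if (is.null(r$solute_site_protiation)) 1
                     else r$solute_site_protiation,
                   density = r$density))
  } else if (!is.null(config$scenario) && !is.null(config$wt_percent_grid)) {
    if (length(config$wt_percent_grid) == 0)
      stop("empty wt_percent_grid", call. = FALSE)
    lapply(config$wt_percent_grid, scenario_mixture,
           scenario = config$scenario)
  } else {
    stop("config needs either `mixtures` or `scenario` + `wt_percent_grid`",
         call. = FALSE)
  }
  if (length(mixes) == 0) stop("no mixtures configured", call. = FALSE)
  inv <- lapply(mixes, proton_inventory)
  inventory_table(inv, path = out)
}

#' Pipeline: eigenrate landscape sweep
#'
#' Tabulates exact relaxation times 1/lambda1, 1/lambda2 and their
#' fast-exchange approximations over a (k_ex, wt%) grid for one scenario.
#' Pool sizes come from the proton inventories; pool rates from the rate
#' model.
#'
#' @param config Config with `scenario`, `wt_percent_grid` and `k_ex_grid`
#'   (1/s per mol/m^3; default `10^seq(-5, -1, 0.5)` spanning slow to fast
#'   exchange).
#' @param out Output CSV path.
#' @return Data.frame with columns `kex`, `wt_percent`, `x_B`,
#'   `inv_lambda1`, `inv_lambda2`, `inv_lambda1_approx`,
#'   `inv_lambda2_approx` (times in s).
#' @export
run_sweep <- function(config, out = "sweep.csv") {
  scen <- if (is.null(config$scenario)) "H2O" else config$scenario
  wts <- config$wt_percent_grid
  if (is.null(wts) || length(wts) == 0)
    stop("config needs a nonempty wt_percent_grid", call. = FALSE)
  kgrid <- config$k_ex_grid
  if (is.null(kgrid)) kgrid <- 10^seq(-5, -1, by = 0.5)
  if (length(kgrid) == 0) stop("empty k_ex_grid", call. = FALSE)
  rates <- default_rate_model(wts)
  rows <- list()
  for (w in wts) {
    inv <- proton_inventory(scenario_mixture(w, scen))
    rw <- rates[rates$wt_percent == w, ][1, ]
    for (k in kgrid) {
      pair <- exchange_pair_from_inventory(inv, R1_A = rw$R1_A,
                                           R1_B = rw$R1_B, k_ex = k)
      ev <- longitudinal_eigenrates(pair)
      ap <- fast_exchange_approx(pair)
      rows[[length(rows) + 1L]] <- data.frame(
        kex = k, wt_percent = w, x_B = inv$x_B,
        inv_lambda1 = 1 / ev[["lambda1"]],
        inv_lambda2 = 1 / ev[["lambda2"]],
        inv_lambda1_approx = 1 / ap$lambda1_approx,
        inv_lambda2_approx = 1 / ap$lambda2_approx)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}

#' Pipeline: simulate a synthetic series
#'
#' @param config Config with `scenario`, `wt_percent_grid`, and optionally
#'   `k_ex`, `noise_sigma`, `replicates`, `seed`.
#' @param out Output directory for curve CSVs and the manifest.
#' @return The curve list from [simulate_series()] (manifest attached).
#' @export
run_simulate <- function(config, out = "series") {
  if (is.null(config$scenario) || is.null(config$wt_percent_grid))
    stop("config needs `scenario` and `wt_percent_grid`", call. = FALSE)
  spec <- series_spec(
    wt_percent_grid = config$wt_percent_grid,
    scenario = config$scenario,
    k_ex = if (is.null(config$k_ex)) 0.05 else config$k_ex,
    noise = noise_model(
      if (is.null(config$noise_sigma)) 0.01 else config$noise_sigma,
      seed = if (is.null(config$seed)) 1L else config$seed),
    replicates = if (is.null(config$replicates)) 3L else config$replicates)
  curves <- simulate_series(spec)
  write_series(curves, out)
  curves
}

#' Pipeline: fit a directory of decay curves
#'
#' Reads every curve CSV listed in a series manifest (or all CSVs in
#' `config$input_dir`), fits each with the configured settings, and writes
#' per-curve JSON fit records plus a summary CSV in the layout of the
#' supplementary concentration-series tables (time constants in ms).
#'
#' @param config Config with `input_dir` (a [write_series()] output
#'   directory) and optional `fit` settings.
#' @param out Output directory.
#' @param verbose Print one line per curve.
#' @return List with `results` (fits) and `summary` (data.frame).
#' @export
run_fit <- function(config, out = "fits", verbose = FALSE) {
  dirin <- config$input_dir
  if (is.null(dirin) || !dir.exists(dirin))
    stop("config$input_dir missing or not a directory", call. = FALSE)
  mpath <- file.path(dirin, "manifest.json")
  if (file.exists(mpath)) {
    manifest <- jsonlite::fromJSON(mpath)
    files <- manifest$file
    kinds <- manifest$experiment
    meta <- manifest
  } else {
    files <- list.files(dirin, pattern = "\\.csv$")
    if (length(files) == 0) stop("no curve CSVs in ", dirin, call. = FALSE)
    kinds <- rep(if (is.null(config$experiment)) "saturation_recovery"
                 else config$experiment, length(files))
    meta <- NULL
  }
  cfg <- .cfg_fit_config(config, seed = config$seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (i in seq_along(files)) {
    path <- file.path(dirin, files[i])
    if (!file.exists(path)) stop("missing curve file: ", path, call. = FALSE)
    md <- if (!is.null(meta))
      list(wt_percent = meta$wt_percent[i], scenario = meta$scenario[i],
           xp_non = meta$xp_non[i]) else list()
    curves <- read_decay_csv(path, experiment = kinds[i], metadata = md)
    for (cur in curves) {
      res <- if (cur$experiment == "cpmg") fit_cpmg(cur, cfg)
             else fit_recovery(cur, cfg)
      results[[length(results) + 1L]] <- res
      if (verbose)
        message(sprintf("%s rep %d: %s, R2 = %.5f, converged = %s",
                        files[i], cur$replicate_id, res$model_order,
                        res$r_squared, res$converged))
      rec <- res[c("a_slow", "a_fast", "T_slow", "T_fast", "y0",
                   "model_order", "r_squared", "rmse", "converged",
                   "n_iterations")]
      rec$metadata <- md
      jsonlite::write_json(
        rec, file.path(out, sprintf("%s_rep%d.json",
                                    sub("\\.csv$", "", files[i]),
                                    cur$replicate_id)),
        auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  summary <- fit_summary_table(results, path = file.path(out, "summary.csv"))
  list(results = results, summary = summary)
}

#' Pipeline: compare fitted coefficients with predicted proton fractions
#'
#' Joins a fit summary with an inventory table by wt% and reports, per
#' scenario, the mean absolute deviation between the fitted fast-component
#' coefficient and the predicted nonexchangeable proton fraction, plus
#' trend concordance (sign agreement of the wt% slopes).
#'
#' @param fit_summary Data.frame from [run_fit()]/[fit_summary_table()].
#' @param inventory Data.frame from [run_inventory()]/[inventory_table()].
#' @param out Optional CSV path for the joined table.
#' @return List with `joined` (per-sample table), `mad_a_fast` (mean
#'   absolute deviation |a_fast - xp_non|), `trend_concordant` (logical).
#' @export
run_compare <- function(fit_summary, inventory, out = NULL) {
  if (nrow(fit_summary) == 0) stop("empty fit summary", call. = FALSE)
  if (!all(fit_summary$wt_percent %in% inventory$wt_percent))
    stop("sample keys in fit summary missing from inventory table",
         call. = FALSE)
  agg <- stats::aggregate(
    fit_summary[, c("a_slow", "a_fast")],
    by = list(wt_percent = fit_summary$wt_percent), FUN = mean)
  joined <- merge(agg, inventory[, c("wt_percent", "xp_exch", "xp_non")],
                  by = "wt_percent")
  mad <- mean(abs(joined$a_fast - joined$xp_non))
  trend <- if (nrow(joined) >= 2) {
    s1 <- stats::coef(stats::lm(a_fast ~ wt_percent, joined))[2]
    s2 <- stats::coef(stats::lm(xp_non ~ wt_percent, joined))[2]
    # concordant when slopes share a sign or both are essentially flat
    (sign(s1) == sign(s2)) || (abs(s1) < 0.002 && abs(s2) < 0.002)
  } else NA
  if (!is.null(out)) utils::write.csv(joined, out, row.names = FALSE)
  list(joined = joined, mad_a_fast = mad, trend_concordant = trend)
}
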