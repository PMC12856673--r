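# mono/biexponential fitting, model selection, replicates, uncertainty

test_that("noiseless biexponential curves are recovered near-exactly", {
  truth <- c(a_slow = 0.7, a_fast = 0.3, T_slow = 2.0, T_fast = 0.3)
  cur <- biexp_recovery_curve()
  fit <- fit_recovery(cur, fit_config(model_order = "bi",
                                      include_offset = FALSE,
                                      ci_method = "none"))
  expect_true(fit$converged)
  for (p in names(truth))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)

  # same contract for the transverse decay model
  tc <- cpmg_times(n_echoes = 1000, tau = 2e-3)
  yc <- 0.6 * exp(-tc / 0.8) + 0.4 * exp(-tc / 0.05)
  fitc <- fit_cpmg(decay_curve(tc, yc, "cpmg"),
                   fit_config(model_order = "bi", include_offset = FALSE,
                              ci_method = "none"))
  expect_equal(fitc$a_slow, 0.6, tolerance = 1e-6)
  expect_equal(fitc$a_fast, 0.4, tolerance = 1e-6)
  expect_equal(fitc$T_slow, 0.8, tolerance = 1e-6)
  expect_equal(fitc$T_fast, 0.05, tolerance = 1e-6)
})

test_that("noisy recovery errors track the information bound", {
  truth <- c(a_slow = 0.7, a_fast = 0.3, T_slow = 2.0, T_fast = 0.3)
  tt <- recovery_times()
  sigma <- 0.01
  # Cramer-Rao bound for the four-parameter model on this grid: the
  # independent yardstick for what any unbiased fit can achieve
  J <- cbind(-exp(-tt / truth["T_slow"]), -exp(-tt / truth["T_fast"]),
             -truth["a_slow"] * exp(-tt / truth["T_slow"]) *
               tt / truth["T_slow"]^2,
             -truth["a_fast"] * exp(-tt / truth["T_fast"]) *
               tt / truth["T_fast"]^2)
  crlb_se <- sqrt(diag(sigma^2 * solve(crossprod(J))))
  med_bound <- 0.6745 * crlb_se / truth       # median |err| of a normal
  cfg <- fit_config(model_order = "bi", include_offset = FALSE,
                    ci_method = "none")
  errs <- sapply(1:60, function(seed) {
    cur <- biexp_recovery_curve(sigma = sigma, seed = seed)
    fit <- fit_recovery(cur, cfg)
    vapply(names(truth),
           function(p) abs(fit[[p]] - truth[[p]]) / truth[[p]], numeric(1))
  })
  med <- apply(errs, 1, median)
  # efficient to within a factor ~1.7 of the bound for every parameter
  # (nonlinearity and the plateau constraint cost a little efficiency)
  for (i in seq_along(truth)) expect_lt(med[i], 1.7 * med_bound[i])
})

test_that("normalized CPMG amplitudes sum to about one when y0 is small", {
  tc <- cpmg_times(n_echoes = 800, tau = 1e-3)
  set.seed(3)
  yc <- 5.3 * (0.65 * exp(-tc / 0.6) + 0.35 * exp(-tc / 0.06)) +
    rnorm(length(tc), sd = 0.02)
  fit <- fit_cpmg(decay_curve(tc, yc, "cpmg"),
                  fit_config(model_order = "bi", ci_method = "none"))
  expect_lt(abs(fit$y0), 0.02)
  expect_equal(fit$a_slow + fit$a_fast, 1, tolerance = 0.05)
})

test_that("slow/fast ordering is invariant under parameter relabeling", {
  tt <- recovery_times()
  # generate with the fast component listed first; fit must still order
  y <- 1 - 0.3 * exp(-tt / 0.3) - 0.7 * exp(-tt / 2.0)
  fit <- fit_recovery(decay_curve(tt, y, "saturation_recovery"),
                      fit_config(model_order = "bi", ci_method = "none"))
  expect_gte(fit$T_slow, fit$T_fast)
  expect_equal(fit$a_slow, 0.7, tolerance = 1e-4)
})

test_that("model selection prefers mono for monoexponential data", {
  tt <- recovery_times()
  set.seed(5)
  y <- 1 - 0.95 * exp(-tt / 1.2) + rnorm(length(tt), sd = 0.01)
  sel <- select_model(decay_curve(tt, y, "saturation_recovery"),
                      fit_config(ci_method = "none"))
  expect_equal(sel$selected, "mono")
  # nested models: bi can never fit worse than mono
  expect_lte(sel$bi$rss, sel$mono$rss + 1e-12)
  # the bi fit degenerates: amplitudes collapse or time constants coalesce
  expect_true(sel$bi$a_fast < 0.05 * sel$bi$a_slow ||
                sel$bi$T_slow / sel$bi$T_fast < 3)
})

test_that("model selection prefers bi for well-separated components", {
  set.seed(6)
  cur <- biexp_recovery_curve(sigma = 0.005, seed = 6)
  sel <- select_model(cur, fit_config(ci_method = "none"))
  expect_equal(sel$selected, "bi")
  expect_lt(sel$f_test$p_value, 0.05)
  expect_lt(sel$runs$p_value, 0.05)
})

test_that("runs test flags structured residuals and passes random ones", {
  set.seed(8)
  structured <- sin(seq(0, 3 * pi, length.out = 40)) + 1e-3
  expect_lt(runs_test(structured)$p_value, 0.01)
  random <- rnorm(200)
  expect_gt(runs_test(random)$p_value, 0.01)
})

test_that("replicate statistics aggregate without pooling fit errors", {
  cfg <- fit_config(model_order = "bi", ci_method = "none")
  fits <- lapply(1:3, function(i)
    fit_recovery(biexp_recovery_curve(), cfg))
  st <- replicate_stats(fits)
  expect_equal(st$sd, rep(0, nrow(st)), tolerance = 1e-8)
  expect_equal(st$mean[st$parameter == "a_slow"], 0.7, tolerance = 1e-6)

  # hand-computed mean/sd across distinct replicates
  fits2 <- lapply(c(11, 12, 13), function(s)
    fit_recovery(biexp_recovery_curve(sigma = 0.01, seed = s), cfg))
  st2 <- replicate_stats(fits2)
  a <- vapply(fits2, function(f) f$a_slow, numeric(1))
  expect_equal(st2$mean[st2$parameter == "a_slow"], mean(a))
  expect_equal(st2$sd[st2$parameter == "a_slow"], sd(a))

  mono <- fit_recovery(biexp_recovery_curve(),
                       fit_config(model_order = "mono", ci_method = "none"))
  expect_error(replicate_stats(list(mono, fits[[1]])), "mixed model orders")
  expect_error(replicate_stats(fits[1]), ">= 2")
})

test_that("bootstrap intervals bracket the truth at moderate noise", {
  truth <- c(a_slow = 0.7, a_fast = 0.3, T_slow = 2.0, T_fast = 0.3)
  cur <- biexp_recovery_curve(sigma = 0.01, seed = 42)
  fit <- fit_recovery(cur, fit_config(model_order = "bi",
                                      ci_method = "bootstrap",
                                      n_boot = 100, seed = 9))
  ci <- fit$ci
  expect_false(attr(ci, "flagged"))
  for (p in names(truth)) {
    row <- ci[ci$parameter == p, ]
    expect_lt(row$lower, row$upper)
    # 80% interval at this noise should be a few percent wide, not huge
    expect_lt((row$upper - row$lower) / truth[[p]], 0.5)
  }
})

test_that("confidence bands shrink with noise and track coverage", {
  # zero noise: the band collapses onto the fit
  cur0 <- biexp_recovery_curve()
  cfg0 <- fit_config(model_order = "bi", ci_method = "bootstrap",
                     n_boot = 50, seed = 2)
  fit0 <- fit_recovery(cur0, cfg0)
  band0 <- confidence_band(cur0, fit0, cfg0)
  expect_lt(max(band0$upper - band0$lower), 1e-4)

  # nominal 80% pointwise coverage on simulated curves (covariance bands)
  set.seed(31)
  tt <- recovery_times()
  clean <- 1 - 0.7 * exp(-tt / 2) - 0.3 * exp(-tt / 0.3)
  cfg <- fit_config(model_order = "bi", include_offset = FALSE,
                    ci_method = "covariance", ci_level = 0.80, seed = 4)
  hits <- 0; total <- 0
  for (i in 1:200) {
    cur <- decay_curve(tt, clean + rnorm(length(tt), sd = 0.01),
                       "saturation_recovery")
    fit <- fit_recovery(cur, cfg)
    if (!fit$converged) next
    band <- confidence_band(cur, fit, cfg)
    hits <- hits + sum(clean >= band$lower & clean <= band$upper)
    total <- total + length(tt)
  }
  expect_gt(hits / total, 0.70)
  expect_lt(hits / total, 0.90)
})

test_that("fit input contracts are enforced", {
  tt <- recovery_times(n = 6)
  y <- 1 - exp(-tt / 1)
  expect_error(fit_recovery(decay_curve(tt, y, "saturation_recovery"),
                            fit_config(model_order = "bi",
                                       ci_method = "none")),
               "8 points")
  expect_error(fit_recovery(decay_curve(tt, y, "cpmg"),
                            fit_config(ci_method = "none")),
               "not a saturation-recovery")
  expect_error(decay_curve(c(1, 1, 2), c(0, 0, 0), "cpmg"), "increasing")
  expect_error(decay_curve(1:3, 1:2, "cpmg"), "equal length")
})

test_that("decay CSVs round-trip through read_decay_csv", {
  tt <- recovery_times(n = 12)
  df <- data.frame(time_s = rep(tt, 2),
                   signal = c(1 - exp(-tt), 1 - exp(-tt / 2)),
                   replicate = rep(1:2, each = length(tt)))
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE)
  curves <- read_decay_csv(tmp, "saturation_recovery")
  expect_length(curves, 2)
  expect_equal(curves[[2]]$signal, 1 - exp(-tt / 2))
  expect_error(read_decay_csv(tempfile(), "cpmg"), "not found")
})
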