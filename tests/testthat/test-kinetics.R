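test_that("bimolecular k_obs closed form matches limits and the ODE oracle", {
  # equimolar, irreversible: relaxation vanishes at completion
  expect_equal(bimolecular_kobs(5, 0, 3, 3), 0)

  # vanishing receptor: pseudo-first-order limit k_on*B0 + k_off
  expect_equal(bimolecular_kobs(5, 10, 1e-10, 4), 5 * 4 + 10,
               tolerance = 1e-8)

  # worked value, cross-checked against the relaxation-rate oracle
  expect_equal(bimolecular_kobs(5, 10, 1, 4), sqrt(825))
  expect_equal(ode_relaxation_rate(5, 10, 1, 4), sqrt(825),
               tolerance = 1e-6)

  # spot grid within the experimental regime
  for (k_on in c(2, 12)) {
    for (k_off in c(5, 120)) {
      for (conc in list(c(1, 20), c(10, 10))) {
        kobs <- bimolecular_kobs(k_on, k_off, conc[1], conc[2])
        expect_equal(ode_relaxation_rate(k_on, k_off, conc[1], conc[2]),
                     kobs, tolerance = 1e-6)
      }
    }
  }

  expect_error(bimolecular_kobs(-1, 1, 1, 1), ">= 0")
})

test_that("k_obs is symmetric in concentrations and monotone in rates", {
  withr::with_seed(11, {
    for (i in 1:20) {
      k_on <- runif(1, 1, 15); k_off <- runif(1, 1, 150)
      A0 <- runif(1, 1, 20); B0 <- runif(1, 1, 20)
      expect_equal(bimolecular_kobs(k_on, k_off, A0, B0),
                   bimolecular_kobs(k_on, k_off, B0, A0))
      eps <- 0.1
      expect_gte(bimolecular_kobs(k_on + eps, k_off, A0, B0),
                 bimolecular_kobs(k_on, k_off, A0, B0))
      expect_gte(bimolecular_kobs(k_on, k_off + eps, A0, B0),
                 bimolecular_kobs(k_on, k_off, A0, B0))
      expect_gte(bimolecular_kobs(k_on, k_off, A0 * 1.05, B0 * 1.05),
                 bimolecular_kobs(k_on, k_off, A0, B0))
    }
  })
})

test_that("trace fitting recovers k_obs and flags degenerate traces", {
  # noise-free: recovery to 1e-6 relative
  tr <- simulate_trace(6.3, 2.49, 1, 8, noise_sd = 0, n_points = 300)
  fit <- fit_trace(tr)
  truth <- expt_metadata(tr)$k_obs_true
  expect_equal(fit$k_obs, truth, tolerance = 1e-6)
  expect_true(fit$converged)

  # 1% noise: close recovery with a sensible standard error
  trn <- simulate_trace(5, 10, 1, 4, noise_sd = 0.01, n_points = 1000,
                        seed = 4)
  fitn <- fit_trace(trn)
  expect_equal(fitn$k_obs, sqrt(825), tolerance = 0.05)
  expect_lt(fitn$k_obs_se / fitn$k_obs, 0.05)

  # constant signal: no amplitude, flagged rather than fitted
  flat <- experiment_table(
    data.frame(time_s = seq(0, 1, length.out = 50), signal = 1),
    "trace")
  ffit <- fit_trace(flat)
  expect_false(ffit$converged)
  expect_true("no_amplitude" %in% ffit$flags)
  expect_equal(ffit$amplitude, 0)

  # contract checks
  short <- experiment_table(data.frame(time_s = 1:4, signal = rnorm(4)),
                            "trace")
  expect_error(fit_trace(short), "at least 5")
  bad_t <- experiment_table(
    data.frame(time_s = c(0, 1, 1, 2, 3), signal = rnorm(5)), "trace")
  expect_error(fit_trace(bad_t), "strictly increasing")
})

test_that("binding-curve fits recover rate constants and K_d", {
  # noise-free series at the human PDZ3:CRIPT rates: exact recovery and
  # the K_d identity k_off / k_on
  B0 <- seq(2, 20, by = 2)
  series <- experiment_table(
    data.frame(conc_uM = B0, kobs_s = bimolecular_kobs(6.3, 2.49, 1, B0)),
    "kobs_series")
  fit <- fit_binding_curve(series, A0 = 1)
  expect_equal(fit$k_on, 6.3, tolerance = 1e-6)
  expect_equal(fit$k_off, 2.49, tolerance = 1e-6)
  expect_equal(fit$K_d, 2.49 / 6.3, tolerance = 1e-9)
  expect_equal(fit$K_d, 0.395, tolerance = 1e-3)

  # k_off = 0: curve through |A0 - B0| region, fitted k_off ~ 0
  s0 <- experiment_table(
    data.frame(conc_uM = B0, kobs_s = bimolecular_kobs(4, 0, 1, B0)),
    "kobs_series")
  fit0 <- fit_binding_curve(s0, A0 = 1)
  expect_lt(fit0$k_off, 1e-4)
  expect_equal(fit0$k_on, 4, tolerance = 1e-4)

  # under-determined input is rejected
  two <- experiment_table(data.frame(conc_uM = c(2, 4), kobs_s = c(10, 20)),
                          "kobs_series")
  expect_error(fit_binding_curve(two), "at least 4")
})

test_that("the full kinetics pipeline recovers rates at 1% trace noise", {
  series <- simulate_kobs_series(k_on = 6.3, k_off = 2.49, A0 = 1,
                                 B0 = seq(2, 20, 2), noise_sd = 0.01,
                                 seed = 17)
  fit <- fit_binding_curve(series, A0 = 1)
  expect_equal(fit$k_on, 6.3, tolerance = 0.05)
  expect_equal(fit$k_off, 2.49, tolerance = 0.05)
  expect_equal(fit$K_d, 0.395, tolerance = 0.08)
})

test_that("displacement k_off averages traces and detects saturation issues", {
  est <- displacement_koff(c(11.5, 11.6, 11.7))
  expect_equal(est$k_off, 11.6)
  expect_equal(est$k_off_se, 0.1, tolerance = 1e-9)
  expect_equal(est$source, "displacement")

  expect_error(displacement_koff(11.5), "at least 2")

  # monotone trend in k_obs with competitor: mean still reported, warned
  expect_warning(
    est <- displacement_koff(c(5, 10, 20), competitor_uM = c(100, 150, 200)),
    "monotonically")
  expect_equal(est$k_off, mean(c(5, 10, 20)))
  expect_true("unsaturated" %in% est$flags)

  # accepts trace_fit objects directly
  fits <- lapply(c(101, 102), function(s) {
    fit_trace(simulate_trace(1, 11.6, 200, 2, noise_sd = 0, n_points = 200,
                             seed = s))
  })
  est <- displacement_koff(fits)
  expect_equal(est$k_off, expt_metadata(fits[[1]]$data)$k_obs_true,
               tolerance = 1e-4)
})

test_that("K_d from rates propagates uncertainty in quadrature", {
  expect_equal(kd_from_rates(6.3, 2.49)$K_d, 0.395, tolerance = 1e-3)
  expect_equal(kd_from_rates(7.0, 117)$K_d, 16.7, tolerance = 1e-2)
  expect_equal(kd_from_rates(1, 0)$K_d, 0)

  res <- kd_from_rates(10, 5, k_on_se = 1, k_off_se = 0.25)
  expect_equal(res$K_d, 0.5)
  expect_equal(res$K_d_se, 0.5 * sqrt(0.1^2 + 0.05^2))

  expect_error(kd_from_rates(0, 1), "k_on")
})
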