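test_that("two-state signal hits its midpoint and baseline limits", {
  aN <- -11; bN <- 0.1; aD <- -3; bD <- -0.05

  # at the midpoint the exponent vanishes: mean of the two baselines
  at_mid <- two_state_signal(4, aN, bN, aD, bD, D50 = 4, m = 1.5)
  expect_equal(at_mid, ((aN + bN * 4) + (aD + bD * 4)) / 2)

  # native limit at low urea, denatured limit at high urea
  expect_equal(two_state_signal(0, aN, bN, aD, bD, D50 = 6, m = 2),
               aN, tolerance = 1e-6)
  expect_equal(two_state_signal(40, aN, bN, aD, bD, D50 = 4, m = 1.5),
               aD + bD * 40, tolerance = 1e-6)

  # numerically stable far outside the transition
  expect_true(is.finite(two_state_signal(1000, aN, bN, aD, bD, 4, 1.5)))

  # monotone between the baselines when slopes are zero
  u <- seq(0, 9, 0.1)
  y <- two_state_signal(u, -10, 0, -2, 0, D50 = 4.5, m = 1.3)
  expect_true(all(diff(y) > 0))

  expect_error(two_state_signal(1, aN, bN, aD, bD, 4, m = -1), "`m` must be > 0")
})

test_that("free denaturation fits recover truth and emit dG = m * D50", {
  cv <- simulate_denaturation(D50 = 4, m = 1.5, noise_sd = 0)
  fit <- fit_denaturation(cv)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["D50"]), 4, tolerance = 1e-6)
  expect_equal(unname(est["m"]), 1.5, tolerance = 1e-6)
  expect_equal(fit$dG, est[["m"]] * est[["D50"]])  # identity, exact

  # 1% of the signal amplitude as noise: 5% recovery
  amp <- abs(-11 - (-3))
  cvn <- simulate_denaturation(D50 = 4, m = 1.23, noise_sd = 0.01 * amp,
                               seed = 23)
  fitn <- fit_denaturation(cvn)
  estn <- setNames(fitn$params$estimate, fitn$params$term)
  expect_equal(unname(estn["D50"]), 4, tolerance = 0.05)
  expect_equal(unname(estn["m"]), 1.23, tolerance = 0.05 * 1.23)
  expect_equal(fitn$dG, estn[["m"]] * estn[["D50"]])

  # featureless data cannot converge to a transition
  flat <- experiment_table(
    data.frame(urea_M = seq(0, 8.1, 0.3),
               signal = seq(-11, -9, length.out = 28)),
    "denaturation")
  ffit <- fit_denaturation(flat)
  expect_true(!ffit$converged || length(ffit$flags) > 0)
})

test_that("curves without a denatured baseline are flagged poorly defined", {
  # midpoint close to the top of the urea range: no denatured baseline
  cv <- simulate_denaturation(D50 = 7.2, m = 1.2, noise_sd = 0,
                              urea_grid = seq(0, 8.1, 0.3))
  fit <- fit_denaturation(cv)
  expect_true("poorly_defined_m" %in% fit$flags)

  # well-centred curve is clean
  ok <- fit_denaturation(simulate_denaturation(D50 = 4, m = 1.5, noise_sd = 0))
  expect_false("poorly_defined_m" %in% ok$flags)
})

test_that("global shared-m fits honour grouping and recover truth", {
  c1 <- simulate_denaturation(D50 = 4, m = 1.23, noise_sd = 0)
  c2 <- simulate_denaturation(D50 = 6, m = 1.23, aN = -13, aD = -2.5,
                              noise_sd = 0)
  gfit <- fit_global_shared_m(list(c1, c2))
  expect_equal(unname(gfit$m_by_group["all"]), 1.23, tolerance = 1e-6)
  expect_equal(gfit$fits$D50, c(4, 6), tolerance = 1e-6)
  expect_equal(gfit$fits$dG, gfit$fits$m * gfit$fits$D50)  # identity
  expect_length(gfit$flags, 0)

  # two share groups, distinct m per group
  c3 <- simulate_denaturation(D50 = 3, m = 1.8, noise_sd = 0)
  c4 <- simulate_denaturation(D50 = 5, m = 1.8, noise_sd = 0)
  g2 <- fit_global_shared_m(list(c1, c2, c3, c4),
                            groups = c("a", "a", "b", "b"))
  expect_equal(unname(g2$m_by_group["a"]), 1.23, tolerance = 1e-5)
  expect_equal(unname(g2$m_by_group["b"]), 1.8, tolerance = 1e-5)

  # forcing curves with very different true m into one group inflates the
  # joint residuals relative to free fits
  h1 <- simulate_denaturation(D50 = 4, m = 0.8, noise_sd = 0.02, seed = 31)
  h2 <- simulate_denaturation(D50 = 5, m = 3.0, noise_sd = 0.02, seed = 32)
  hfit <- fit_global_shared_m(list(h1, h2))
  expect_true("heterogeneous_m" %in% hfit$flags)

  expect_error(fit_global_shared_m(list(c1)), ">= 2")
  expect_error(fit_global_shared_m(list(c1, c2), groups = c("a", "b")),
               "fewer than 2")
})

test_that("sharing m tightens the reported dG uncertainty", {
  # constraining m across curves adds information about each curve's
  # transition, so the propagated dG standard error must shrink relative
  # to the free fit of the same curve
  amp <- abs(-11 - (-3))
  c1 <- simulate_denaturation(D50 = 4.5, m = 1.23, noise_sd = 0.015 * amp,
                              seed = 4100)
  c2 <- simulate_denaturation(D50 = 5.5, m = 1.23, aN = -12,
                              noise_sd = 0.015 * amp, seed = 4101)
  g <- fit_global_shared_m(list(c1, c2))
  free <- fit_denaturation(c1)
  expect_lt(g$fits$m_se[1], tidy(free)$std.error[tidy(free)$term == "m"])
  expect_lt(g$fits$dG_se[1], free$dG_se)
})

test_that("spectra averaging is a pointwise mean on a common grid", {
  grid <- seq(200, 260, 1)
  sp <- lapply(1:5, function(i) tibble::tibble(wavelength_nm = grid,
                                               signal = sin(grid / 10)))
  avg <- average_spectra(sp)
  expect_equal(avg$signal, sp[[1]]$signal)

  two <- list(tibble::tibble(wavelength_nm = grid, signal = 0),
              tibble::tibble(wavelength_nm = grid, signal = 2))
  expect_equal(average_spectra(two)$signal, rep(1, length(grid)))

  off <- list(sp[[1]],
              tibble::tibble(wavelength_nm = grid + 1, signal = 0))
  expect_error(average_spectra(off), "identical wavelength grid")
})
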