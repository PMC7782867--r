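test_that("every generator is deterministic under a fixed seed", {
  tr <- toy_tree()
  f1 <- simulate_family(tr, seq_length = 30, mutation_rate = 0.5, seed = 3)
  f2 <- simulate_family(tr, seq_length = 30, mutation_rate = 0.5, seed = 3)
  expect_identical(f1$alignment, f2$alignment)
  expect_identical(f1$ancestors, f2$ancestors)
  expect_identical(as.data.frame(f1$posteriors[[1]]),
                   as.data.frame(f2$posteriors[[1]]))

  t1 <- simulate_trace(5, 10, 1, 4, noise_sd = 0.02, seed = 9)
  t2 <- simulate_trace(5, 10, 1, 4, noise_sd = 0.02, seed = 9)
  expect_identical(t1$signal, t2$signal)

  d1 <- simulate_denaturation(noise_sd = 0.05, seed = 9)
  d2 <- simulate_denaturation(noise_sd = 0.05, seed = 9)
  expect_identical(d1$signal, d2$signal)

  i1 <- simulate_itc(noise_sd = 0.05, seed = 9)
  i2 <- simulate_itc(noise_sd = 0.05, seed = 9)
  expect_identical(i1$heat_kcal_per_mol, i2$heat_kcal_per_mol)
})

test_that("family simulation respects mutation rate and motif conservation", {
  tr <- toy_tree()

  # no mutation: leaves identical to root, posteriors one-hot, AltAll == ML
  f0 <- simulate_family(tr, seq_length = 30, mutation_rate = 0, seed = 5)
  root_seq <- f0$ancestors[["root"]]
  expect_true(all(f0$alignment$seq == root_seq))
  for (nm in names(f0$posteriors)) {
    pp <- f0$posteriors[[nm]]
    expect_equal(pp_summary(pp, 1), 1)
    expect_equal(ml_sequence(pp), f0$ancestors[[nm]])
    aa <- altall_sequence(pp)
    expect_equal(aa$sequence, ml_sequence(pp))
    expect_equal(nrow(aa$flagged), 0)
  }

  # fully conserved motif: last 6 residues shared by all leaves even at
  # high mutation rate
  fhot <- simulate_family(tr, seq_length = 40, mutation_rate = 3,
                          motif_conservation = 1, seed = 7)
  tails <- substr(fhot$alignment$seq, 35, 40)
  expect_equal(length(unique(tails)), 1)
  # and the rest of the sequence did mutate
  expect_gt(length(unique(substr(fhot$alignment$seq, 1, 34))), 1)

  # branch lengths are required when mutations are requested
  bare <- ape::read.tree(text = "(A,B);")
  expect_error(simulate_family(bare, mutation_rate = 0.5),
               "branch length")
})

test_that("ambiguous_fraction controls the sub-threshold posterior sites", {
  fam <- simulate_family(toy_tree(), seq_length = 50, mutation_rate = 0.6,
                         ambiguous_fraction = 0.2, seed = 21)
  pp <- fam$posteriors[["root"]]
  n_low <- sum(1 - pp_summary(pp, 0.8)) * 50
  expect_equal(round(n_low), 10)  # 20% of 50 sites
  # ML still equals the true ancestor (mass is concentrated on the truth)
  expect_equal(ml_sequence(pp), fam$ancestors[["root"]])
})

test_that("simulated traces embed the closed-form k_obs", {
  # k_on 5 uM^-1 s^-1, k_off 10 s^-1, 1 + 4 uM: k_obs = sqrt(825)
  tr <- simulate_trace(5, 10, 1, 4, noise_sd = 0, n_points = 400, seed = 1)
  expect_equal(expt_metadata(tr)$k_obs_true, 28.7228132327, tolerance = 1e-9)
  fit <- fit_trace(tr)
  expect_equal(fit$k_obs, 28.7228132327, tolerance = 1e-6)
  expect_error(simulate_trace(5, 10, 1, 4, t_max = -1), "t_max")
})

test_that("simulated denaturation curves hit the two-state midpoint", {
  # default grid is 0 to 8.1 M in 0.3 M steps
  expect_equal(nrow(simulate_denaturation(noise_sd = 0)), 28)

  # at the midpoint the noise-free curve equals the mean of the baselines
  cv <- simulate_denaturation(D50 = 4, m = 1.5, noise_sd = 0,
                              urea_grid = seq(0, 8, 0.5))
  meta <- expt_metadata(cv)
  at_mid <- cv$signal[cv$urea_M == 4]
  baselines_mid <- ((meta$aN + meta$bN * 4) + (meta$aD + meta$bD * 4)) / 2
  expect_equal(at_mid, baselines_mid, tolerance = 1e-12)
})

test_that("simulated ITC isotherms behave like the one-site model", {
  # zero enthalpy: zero heat everywhere
  z <- simulate_itc(dH = 0, noise_sd = 0)
  expect_equal(z$heat_kcal_per_mol, rep(0, 16))

  # saturating titration: heat magnitudes shrink monotonically once past
  # the equivalence region
  s <- simulate_itc(n = 1, K_d_uM = 0.05, dH = -7.5, noise_sd = 0)
  q <- abs(s$heat_kcal_per_mol)
  post <- q[8:16]
  expect_true(all(diff(post) <= 1e-9))

  # noise-free self-consistency: the fit recovers the generator's truth
  it <- simulate_itc(n = 0.95, K_d_uM = 0.7, dH = -7.5, noise_sd = 0)
  fit <- fit_itc(it)
  expect_equal(fit$n, 0.95, tolerance = 1e-6)
  expect_equal(fit$K_d, 0.7, tolerance = 1e-6)
  expect_equal(fit$dH, -7.5, tolerance = 1e-6)
})
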