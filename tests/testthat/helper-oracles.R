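# Independent oracles used to cross-check the package's closed forms and
# forward models, plus small fixture builders. The oracles deliberately
# avoid the code paths they validate.

# Relaxation rate of A + B <=> C by numerical integration of the
# mass-action ODE from a small perturbation of equilibrium, extracting the
# late-time log-linear slope of the decaying deviation. Independent of the
# closed-form k_obs expression under test.
ode_relaxation_rate <- function(k_on, k_off, A0, B0) {
  f <- function(C) k_on * (A0 - C) * (B0 - C) - k_off * C
  C_eq <- stats::uniroot(f, c(0, min(A0, B0)), tol = 1e-14)$root
  # polish the root so the deviation ODE sees a clean fixed point
  for (i in 1:6) {
    C_eq <- C_eq - f(C_eq) / (k_on * (2 * C_eq - A0 - B0) - k_off)
  }
  fp <- k_on * (2 * C_eq - A0 - B0) - k_off
  dxdt <- function(t, x, p) list(fp * x + k_on * x^2)
  x0 <- -1e-4 * max(C_eq, 1e-3)
  run <- function(t_end) {
    out <- deSolve::ode(c(x = x0), seq(0, t_end, length.out = 400), dxdt,
                        NULL, method = "lsoda", rtol = 1e-12, atol = 1e-300)
    data.frame(t = out[, 1], x = out[, 2])
  }
  lam_lb <- max(k_off, k_on * abs(A0 - B0), 1e-3)
  d <- run(10 / lam_lb)
  rel <- abs(d$x / x0)
  ok <- which(rel > 1e-12 & rel < 1 & d$t > 0)
  lam1 <- unname(-coef(lm(log(abs(d$x[ok])) ~ d$t[ok]))[2])
  # second pass targets the deep-decay window where the quadratic term of
  # the deviation dynamics is negligible
  d <- run(30 / lam1)
  rel <- abs(d$x / x0)
  win <- which(rel > 1e-11 & rel < 1e-6)
  if (length(win) < 5) win <- which(rel > 1e-12 & rel < 1e-3)
  unname(-coef(lm(log(abs(d$x[win])) ~ d$t[win]))[2])
}

# Finite-step mass-balance oracle for ITC injection heats: each injection
# is split into many micro-steps of displacement + mixing + equilibration,
# converging to the continuous-dilution limit. Agreement with the
# package's single-step bookkeeping is expected at O(dV/V0), i.e. ~1%.
itc_heats_microstep <- function(n, K_d, dH, cell_conc, syringe_conc,
                                inj_volumes, cell_volume, steps = 400) {
  bound <- function(M, X) {
    S <- n * M
    b <- S + X + K_d
    (b - sqrt(pmax(b^2 - 4 * S * X, 0))) / 2
  }
  V0 <- cell_volume
  M <- cell_conc
  X <- 0
  C_prev <- bound(M, X)
  heats <- numeric(length(inj_volumes))
  for (i in seq_along(inj_volumes)) {
    dv <- inj_volumes[i] / steps
    q <- 0
    for (s in seq_len(steps)) {
      dil <- 1 - dv / V0
      M <- M * dil
      X <- X * dil + syringe_conc * dv / V0
      C_new <- bound(M, X)
      q <- q + dH * (C_new - C_prev * dil) * V0
      C_prev <- C_new
    }
    heats[i] <- q / (syringe_conc * inj_volumes[i])
  }
  heats
}

# Posterior table with given ML sequence and chosen sites perturbed:
# `ambig` maps site index -> c(pp_ml, alternative_residue).
make_pp <- function(sequence, ambig = list(), node_id = "test") {
  aa <- amino_acids()
  res <- strsplit(sequence, "")[[1]]
  m <- matrix(0, nrow = length(res), ncol = 20, dimnames = list(NULL, aa))
  m[cbind(seq_along(res), match(res, aa))] <- 1
  for (site in names(ambig)) {
    s <- as.integer(site)
    p <- ambig[[site]][[1]]
    alt <- ambig[[site]][[2]]
    m[s, ] <- 0
    m[s, res[s]] <- p
    m[s, alt] <- 1 - p
  }
  posterior_table(m, node_id = node_id)
}

toy_tree <- function() {
  ape::read.tree(text = "((A:0.3,B:0.3)ab:0.2,(C:0.25,D:0.25)cd:0.25)root;")
}
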