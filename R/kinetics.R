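## Stopped-flow binding kinetics.
##
## A + B <=> C with association rate k_on (uM^-1 s^-1) and dissociation
## rate k_off (s^-1). A binding trace relaxes as a single exponential with
## observed rate k_obs; plotted against ligand concentration, k_obs follows
## the exact closed form for a reversible bimolecular reaction (no
## pseudo-first-order approximation):
##
##   k_obs = sqrt( k_on^2 (A0 - B0)^2 + k_off^2 + 2 k_on k_off (A0 + B0) )
##
## which equals the linearised relaxation rate k_on (A_eq + B_eq) + k_off.
## K_d = k_off / k_on throughout, in uM.

#' Observed relaxation rate of a reversible bimolecular reaction
#'
#' Exact closed form for the relaxation rate of A + B <=> C starting from
#' free A and B at total concentrations `A0` and `B0`. Symmetric in
#' `A0`/`B0` and non-decreasing in every argument.
#'
#' @param k_on Association rate constant, uM^-1 s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param A0,B0 Total concentrations of the two species, uM.
#' @return k_obs in s^-1 (vectorised over any argument).
#' @export
#' @examples
#' bimolecular_kobs(5, 10, 1, 4)  # sqrt(225 + 100 + 500)
bimolecular_kobs <- function(k_on, k_off, A0, B0) {
  if (any(c(k_on, k_off, A0, B0) < 0)) {
    abort("all arguments to bimolecular_kobs() must be >= 0")
  }
  sqrt(k_on^2 * (A0 - B0)^2 + k_off^2 + 2 * k_on * k_off * (A0 + B0))
}

#' Fit a single-exponential binding trace
#'
#' Nonlinear least-squares fit of `signal = offset + amplitude *
#' exp(-k_obs * t)`, initialised from a log-linear regression on the
#' baseline-subtracted early part of the trace. Traces with no resolvable
#' amplitude (flat signal) are returned flagged rather than fitted.
#'
#' @param trace An experiment table of kind `"trace"` with columns
#'   `time_s` (strictly increasing, >= 5 points) and `signal`.
#' @return Object of class `trace_fit` with elements `k_obs`, `k_obs_se`,
#'   `amplitude`, `offset`, `residual_sd`, `converged`, `flags`, `data`.
#' @export
fit_trace <- function(trace) {
  assert_expt(trace, "trace")
  t <- trace$time_s
  y <- trace$signal
  if (length(t) < 5) abort("a trace needs at least 5 time points")
  if (any(diff(t) <= 0)) abort("`time_s` must be strictly increasing")

  tail_n <- max(3L, ceiling(length(y) * 0.1))
  offset0 <- mean(tail(y, tail_n))
  amp0 <- mean(head(y, max(3L, ceiling(length(y) * 0.02)))) - offset0
  noise0 <- sd(tail(y, tail_n))

  flags <- character()
  if (abs(amp0) <= 3 * noise0 || abs(amp0) < 1e-12) {
    return(new_trace_fit(k_obs = NA_real_, k_obs_se = NA_real_,
                         amplitude = 0, offset = offset0,
                         residual_sd = sd(y), converged = FALSE,
                         flags = "no_amplitude", data = trace))
  }

  ## log-linear initial estimate on early points still well above baseline
  dev <- (y - offset0) / amp0
  early <- which(dev > 0.1)
  if (length(early) >= 3) {
    k0 <- unname(-coef(lm(log(dev[early]) ~ t[early]))[2])
  } else {
    k0 <- 1 / (t[length(t)] / 5)
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / diff(range(t))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * exp(-k_obs * t),
      start = list(offset = offset0, amplitude = amp0, k_obs = k0),
      lower = c(-Inf, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_trace_fit(k_obs = NA_real_, k_obs_se = NA_real_,
                         amplitude = amp0, offset = offset0,
                         residual_sd = sd(y), converged = FALSE,
                         flags = "no_convergence", data = trace))
  }
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (cf[["k_obs"]] < 0) abort("fitted k_obs is negative")
  if (cf[["k_obs"]] == 0) flags <- c(flags, "k_obs_at_bound")
  new_trace_fit(k_obs = cf[["k_obs"]], k_obs_se = se[["k_obs"]],
                amplitude = cf[["amplitude"]], offset = cf[["offset"]],
                residual_sd = summary(fit)$sigma, converged = TRUE,
                flags = flags, data = trace)
}

new_trace_fit <- function(...) structure(list(...), class = "trace_fit")

#' @export
print.trace_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<trace fit: not converged (%s)>\n",
                paste(x$flags, collapse = ",")))
  } else {
    cat(sprintf("<trace fit: k_obs = %.4g +/- %.2g s^-1, amplitude = %.3g>\n",
                x$k_obs, x$k_obs_se, x$amplitude))
  }
  invisible(x)
}

#' Fit k_obs versus concentration to the reversible bimolecular model
#'
#' Least-squares fit of [bimolecular_kobs()] over `(k_on, k_off)` to an
#' observed-rate series measured at fixed receptor concentration `A0` and
#' varying ligand concentration. The exact model is used rather than the
#' pseudo-first-order linear approximation, so the receptor concentration
#' need not be negligible. `K_d = k_off / k_on`, with its standard error
#' from first-order propagation.
#'
#' @param series Experiment table of kind `"kobs_series"` with columns
#'   `conc_uM` (ligand B0) and `kobs_s`; >= 4 points required.
#' @param A0 Fixed receptor concentration in uM (1 uM is typical).
#' @param weighted If `TRUE` and the series has a `kobs_se_s` column,
#'   points are weighted by 1/se^2.
#' @return Object of class `kinetic_fit`: `k_on`, `k_off`, `K_d` with
#'   standard errors, `source = "binding_curve"`, `flags`, `data`.
#' @export
fit_binding_curve <- function(series, A0 = 1, weighted = FALSE) {
  assert_expt(series, "kobs_series")
  if (nrow(series) < 4) {
    abort("need at least 4 (concentration, k_obs) pairs; fit is under-determined")
  }
  B0 <- series$conc_uM
  kobs <- series$kobs_s
  w <- if (weighted && "kobs_se_s" %in% names(series)) {
    1 / pmax(series$kobs_se_s, 1e-12)^2
  } else {
    rep(1, nrow(series))
  }
  init <- lm(kobs ~ B0, weights = w)
  kon0 <- max(unname(coef(init)[2]), 1e-3)
  koff0 <- max(unname(coef(init)[1]), 1e-3)

  fit <- minpack.lm::nlsLM(
    kobs ~ bimolecular_kobs(k_on, k_off, A0, B0),
    start = list(k_on = kon0, k_off = koff0),
    lower = c(0, 0), weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  flags <- character()
  if (any(cf <= 0)) flags <- c(flags, "rate_at_bound")
  resid_sd <- summary(fit)$sigma
  mono <- diff(kobs[order(B0)])
  if (any(mono < -3 * resid_sd)) {
    warn("k_obs decreases with concentration beyond noise; check the series")
    flags <- c(flags, "non_monotone")
  }
  kd <- kd_from_rates(cf[["k_on"]], cf[["k_off"]],
                      se[["k_on"]], se[["k_off"]])
  new_kinetic_fit(
    k_on = cf[["k_on"]], k_on_se = se[["k_on"]],
    k_off = cf[["k_off"]], k_off_se = se[["k_off"]],
    K_d = kd$K_d, K_d_se = kd$K_d_se,
    source = "binding_curve", flags = flags,
    A0 = A0, data = series, residual_sd = resid_sd
  )
}

new_kinetic_fit <- function(...) structure(list(...), class = "kinetic_fit")

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic fit (%s)>\n", x$source))
  if (!is.na(x$k_on)) {
    cat(sprintf("  k_on  = %.3g +/- %.2g uM^-1 s^-1\n", x$k_on, x$k_on_se))
  }
  cat(sprintf("  k_off = %.3g +/- %.2g s^-1\n", x$k_off, x$k_off_se))
  if (!is.na(x$K_d)) {
    cat(sprintf("  K_d   = %.3g +/- %.2g uM\n", x$K_d, x$K_d_se))
  }
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' Dissociation rate from displacement experiments
#'
#' In a displacement experiment a preformed complex is mixed with a large
#' excess of unlabelled competitor; at saturation the observed rate equals
#' k_off, independent of competitor concentration. The reported k_off is
#' the mean of the individual k_obs values with their standard deviation.
#' A monotone trend of k_obs with competitor concentration indicates
#' incomplete saturation and is flagged with a warning.
#'
#' @param fits List of `trace_fit` objects (or a numeric vector of k_obs
#'   values, s^-1) from >= 2 displacement traces.
#' @param competitor_uM Optional competitor concentrations, used only for
#'   the saturation check.
#' @return Object of class `kinetic_fit` with `k_off` (mean), `k_off_se`
#'   (sd across traces), `source = "displacement"`.
#' @export
#' @examples
#' displacement_koff(c(11.5, 11.6, 11.7))
displacement_koff <- function(fits, competitor_uM = NULL) {
  kobs <- if (is.numeric(fits)) {
    fits
  } else {
    vapply(fits, function(f) {
      stopifnot(inherits(f, "trace_fit"))
      f$k_obs
    }, numeric(1))
  }
  kobs <- kobs[is.finite(kobs)]
  if (length(kobs) < 2) {
    abort("need at least 2 displacement traces to estimate k_off")
  }
  flags <- character()
  ord <- if (!is.null(competitor_uM)) order(competitor_uM) else seq_along(kobs)
  d <- diff(kobs[ord])
  spread <- sd(kobs) / mean(kobs)
  if ((all(d > 0) || all(d < 0)) && spread > 0.1) {
    warn("k_obs trends monotonically with competitor concentration; displacement may not be saturated")
    flags <- c(flags, "unsaturated")
  }
  new_kinetic_fit(
    k_on = NA_real_, k_on_se = NA_real_,
    k_off = mean(kobs), k_off_se = sd(kobs),
    K_d = NA_real_, K_d_se = NA_real_,
    source = "displacement", flags = flags,
    data = tibble(kobs_s = kobs,
                  competitor_uM = competitor_uM %||% rep(NA_real_, length(kobs)))
  )
}

#' Equilibrium dissociation constant from rate constants
#'
#' `K_d = k_off / k_on` (uM); the standard error combines the relative
#' errors of the two rates in quadrature.
#'
#' @param k_on,k_off Rate constants (uM^-1 s^-1 and s^-1).
#' @param k_on_se,k_off_se Their standard errors (0 if omitted).
#' @return Tibble with `K_d` and `K_d_se` in uM.
#' @export
#' @examples
#' kd_from_rates(6.3, 2.49)  # 0.395 uM
kd_from_rates <- function(k_on, k_off, k_on_se = 0, k_off_se = 0) {
  if (any(k_on <= 0)) abort("`k_on` must be > 0")
  if (any(k_off < 0)) abort("`k_off` must be >= 0")
  kd <- k_off / k_on
  rel <- sqrt((k_on_se / k_on)^2 +
                ifelse(k_off > 0, (k_off_se / k_off)^2, 0))
  tibble(K_d = kd, K_d_se = kd * rel)
}
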