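## Equilibrium urea denaturation, two-state model with linear baselines.
##
## The observed spectroscopic signal (here: ellipticity at 222 nm) is the
## population-weighted average of a native and a denatured baseline, each
## linear in denaturant:
##
##   F(u) = [ (aN + bN u) + (aD + bD u) exp(m (u - D50) / (R T)) ]
##          / [ 1 + exp(m (u - D50) / (R T)) ]
##
## D50 ([Urea]50%) is the midpoint; m (kcal mol^-1 M^-1) measures the
## unfolding cooperativity and, in the linear-extrapolation model, the
## stability is dG = m * D50. Because m is poorly determined when the
## denatured baseline is short, curves from proteins of similar size can
## be fitted jointly with one shared m per group, which stabilises dG.

#' Two-state denaturation signal
#'
#' @param urea Denaturant concentration(s), M.
#' @param aN,bN Native baseline intercept and slope.
#' @param aD,bD Denatured baseline intercept and slope.
#' @param D50 Midpoint, M.
#' @param m m-value, kcal mol^-1 M^-1 (> 0).
#' @param temperature_K Temperature in kelvin (default 283.15, i.e. 10 C).
#' @return Signal values (same units as the baselines).
#' @export
#' @examples
#' two_state_signal(seq(0, 8, 0.5), -11, 0.1, -3, -0.05, D50 = 4, m = 1.5)
two_state_signal <- function(urea, aN, bN, aD, bD, D50, m,
                             temperature_K = 283.15) {
  if (any(m <= 0)) abort("`m` must be > 0")
  if (any(temperature_K <= 0)) abort("`temperature_K` must be > 0")
  ## fraction denatured via the logistic form, numerically stable for
  ## large |m * (u - D50)| where the raw exponential would overflow
  fD <- stats::plogis(m * (urea - D50) / (R_KCAL * temperature_K))
  (aN + bN * urea) * (1 - fD) + (aD + bD * urea) * fD
}

#' Fit one urea-denaturation curve (free m)
#'
#' Six-parameter nonlinear least squares: two linear baselines, `D50` and
#' `m`. `D50` is initialised at the urea value nearest the half-amplitude
#' crossing and `m` at 1 kcal mol^-1 M^-1. The stability is reported as
#' `dG = m * D50` (free energy of folding, positive for a stable protein),
#' with its standard error from first-order propagation including the
#' D50-m covariance.
#'
#' A curve whose highest urea points do not reach the denatured baseline
#' (fraction unfolded < 0.95 at the top of the range, or fewer than 3
#' points past `D50 + 1` M) is flagged `"poorly_defined_m"`; featureless
#' data that the optimiser cannot fit come back flagged
#' `"no_convergence"`.
#'
#' @param curve Experiment table of kind `"denaturation"` with columns
#'   `urea_M` and `signal`; >= 10 points spanning both baselines.
#' @param temperature_K Temperature, K (default 283.15).
#' @return Object of class `denat_fit`: baselines, `D50`, `m`, `dG`,
#'   standard errors, `flags`, `converged`, `data`.
#' @export
fit_denaturation <- function(curve, temperature_K = 283.15) {
  assert_expt(curve, "denaturation")
  u <- curve$urea_M
  y <- curve$signal
  if (length(u) < 10) abort("need at least 10 points spanning both baselines")

  start <- denat_start(u, y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ two_state_signal(u, aN, bN, aD, bD, D50, m, temperature_K),
      start = start,
      lower = c(-Inf, -Inf, -Inf, -Inf, min(u), 1e-3),
      upper = c(Inf, Inf, Inf, Inf, max(u), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_denat_fit(params = start_as_tibble(start), dG = NA_real_,
                         dG_se = NA_real_, converged = FALSE,
                         flags = "no_convergence",
                         temperature_K = temperature_K, data = curve,
                         residual_sd = sd(y)))
  }
  cf <- as.list(coef(fit))
  se <- summary(fit)$coefficients[, "Std. Error"]
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  flags <- denat_quality_flags(u, cf, temperature_K)
  ## baseline separation at the midpoint: without it the transition (and
  ## hence D50, m) is not actually in the data
  sep <- abs((cf$aD + cf$bD * cf$D50) - (cf$aN + cf$bN * cf$D50))
  if (sep < 0.05 * diff(range(y))) flags <- c(flags, "no_transition")
  dg <- dg_from_fit(cf$m, cf$D50, se[["m"]], se[["D50"]],
                    if (!is.null(V)) V["m", "D50"] else 0)
  params <- tibble(
    term = c("aN", "bN", "aD", "bD", "D50", "m"),
    estimate = unlist(cf[c("aN", "bN", "aD", "bD", "D50", "m")]),
    std_error = unname(se[c("aN", "bN", "aD", "bD", "D50", "m")])
  )
  new_denat_fit(params = params, dG = dg$dG, dG_se = dg$dG_se,
                converged = TRUE, flags = flags,
                temperature_K = temperature_K, data = curve,
                residual_sd = summary(fit)$sigma)
}

denat_start <- function(u, y) {
  aN0 <- mean(y[u <= stats::quantile(u, 0.15)])
  aD0 <- mean(y[u >= stats::quantile(u, 0.85)])
  half <- (aN0 + aD0) / 2
  D50_0 <- u[which.min(abs(y - half))]
  list(aN = aN0, bN = 0, aD = aD0, bD = 0,
       D50 = max(min(D50_0, max(u) - 1e-6), min(u) + 1e-6), m = 1)
}

start_as_tibble <- function(start) {
  tibble(term = names(start), estimate = unlist(start),
         std_error = NA_real_)
}

denat_quality_flags <- function(u, cf, temperature_K) {
  flags <- character()
  fu_top <- 1 / (1 + exp(-cf$m * (max(u) - cf$D50) / (R_KCAL * temperature_K)))
  if (fu_top < 0.95 || sum(u > cf$D50 + 1) < 3) {
    flags <- c(flags, "poorly_defined_m")
  }
  if (cf$D50 <= min(u) + 1e-6 || cf$D50 >= max(u) - 1e-6) {
    flags <- c(flags, "D50_outside_range")
  }
  flags
}

dg_from_fit <- function(m, D50, m_se, D50_se, cov_mD50 = 0) {
  dG <- m * D50
  var <- (D50 * m_se)^2 + (m * D50_se)^2 + 2 * D50 * m * cov_mD50
  list(dG = dG, dG_se = sqrt(max(var, 0)))
}

new_denat_fit <- function(...) structure(list(...), class = "denat_fit")

#' @export
print.denat_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<denaturation fit: not converged (%s)>\n",
                paste(x$flags, collapse = ",")))
    return(invisible(x))
  }
  est <- setNames(x$params$estimate, x$params$term)
  cat(sprintf("<denaturation fit: D50 = %.3g M, m = %.3g kcal/mol/M, dG = %.3g kcal/mol>\n",
              est[["D50"]], est[["m"]], x$dG))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' Global fit of several curves with a shared m-value
#'
#' Joint nonlinear least squares over a list of denaturation curves:
#' every curve keeps its own baselines and `D50`, while curves in the same
#' share group are constrained to a common `m`. This is the standard way
#' to stabilise `dG = m * D50` when individual curves pin `m` poorly; the
#' grouping (e.g. constructs of different length getting their own shared
#' m) is supplied by the user, not inferred.
#'
#' After the joint fit each curve is also fitted freely; if the joint
#' residual sum of squares exceeds `flag_ratio` times the free-fit total,
#' the shared-m assumption is flagged (`"heterogeneous_m"`).
#'
#' @param curves List of denaturation experiment tables (>= 2 per group).
#' @param temperature_K Temperature, K.
#' @param groups Share-group labels, one per curve; default all in one
#'   group.
#' @param flag_ratio Residual-ratio threshold for the heterogeneity flag.
#' @return Object of class `denat_global_fit`: `fits` tibble (one row per
#'   curve: group, baselines, `D50` +/- se, shared `m` +/- se, `dG` +/- se),
#'   `m_by_group`, `flags`, `rss_shared`, `rss_free`.
#' @export
fit_global_shared_m <- function(curves, temperature_K = 283.15,
                                groups = NULL, flag_ratio = 2) {
  if (!is.list(curves) || length(curves) < 2) {
    abort("`curves` must be a list of >= 2 denaturation tables")
  }
  purrr::walk(curves, assert_expt, kind = "denaturation")
  n_curve <- length(curves)
  groups <- groups %||% rep("all", n_curve)
  if (length(groups) != n_curve) {
    abort("`groups` must have one label per curve")
  }
  tab <- table(groups)
  if (any(tab < 2)) {
    abort(sprintf("share group(s) with fewer than 2 curves: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  g_levels <- unique(groups)
  g_idx <- match(groups, g_levels)

  starts <- purrr::map(curves, ~ denat_start(.x$urea_M, .x$signal))
  ## parameter vector: per-curve (aN, bN, aD, bD, D50), then one m per group
  p0 <- c(
    unlist(purrr::map(starts, ~ unlist(.x[c("aN", "bN", "aD", "bD", "D50")]))),
    rep(1, length(g_levels))
  )
  unpack <- function(p) {
    percurve <- matrix(p[seq_len(5 * n_curve)], nrow = 5)
    ms <- pmax(p[5 * n_curve + seq_along(g_levels)], 1e-3)
    list(percurve = percurve, ms = ms)
  }
  resid_fn <- function(p) {
    pp <- unpack(p)
    unlist(purrr::imap(curves, function(cv, i) {
      q <- pp$percurve[, i]
      cv$signal - two_state_signal(cv$urea_M, q[1], q[2], q[3], q[4],
                                   q[5], pp$ms[g_idx[i]], temperature_K)
    }))
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  )
  p <- fit$par
  pp <- unpack(p)
  n_obs <- sum(vapply(curves, nrow, integer(1)))
  dof <- n_obs - length(p)
  s2 <- sum(fit$fvec^2) / max(dof, 1)
  V <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  se_of <- function(i) if (is.null(V)) NA_real_ else sqrt(max(V[i, i], 0))
  cov_of <- function(i, j) if (is.null(V)) 0 else V[i, j]

  free_fits <- purrr::map(curves, fit_denaturation,
                          temperature_K = temperature_K)
  rss_free <- sum(purrr::map_dbl(seq_along(curves), function(i) {
    f <- free_fits[[i]]
    if (!f$converged) return(Inf)
    f$residual_sd^2 * (nrow(curves[[i]]) - 6)
  }))
  rss_shared <- sum(fit$fvec^2)
  flags <- character()
  if (is.finite(rss_free) && rss_shared > flag_ratio * rss_free) {
    flags <- c(flags, "heterogeneous_m")
  }

  fits <- purrr::map_dfr(seq_len(n_curve), function(i) {
    base <- (i - 1) * 5
    m_i <- 5 * n_curve + g_idx[i]
    m_hat <- pp$ms[g_idx[i]]
    D50_hat <- pp$percurve[5, i]
    dg <- dg_from_fit(m_hat, D50_hat, se_of(m_i), se_of(base + 5),
                      cov_of(m_i, base + 5))
    tibble(
      curve = i, group = groups[i],
      aN = pp$percurve[1, i], bN = pp$percurve[2, i],
      aD = pp$percurve[3, i], bD = pp$percurve[4, i],
      D50 = D50_hat, D50_se = se_of(base + 5),
      m = m_hat, m_se = se_of(m_i),
      dG = dg$dG, dG_se = dg$dG_se
    )
  })
  structure(
    list(fits = fits,
         m_by_group = setNames(pp$ms, g_levels),
         flags = flags, rss_shared = rss_shared, rss_free = rss_free,
         temperature_K = temperature_K, data = curves,
         free_fits = free_fits),
    class = "denat_global_fit"
  )
}

#' @export
print.denat_global_fit <- function(x, ...) {
  cat(sprintf("<global denaturation fit: %d curves, shared m per group: %s>\n",
              nrow(x$fits),
              paste(names(x$m_by_group),
                    sprintf("%.3g", x$m_by_group), sep = "=", collapse = ", ")))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  print(dplyr::select(x$fits, "curve", "group", "D50", "m", "dG", "dG_se"))
  invisible(x)
}

#' Average replicate CD spectra
#'
#' Pointwise mean of replicate spectra recorded on identical wavelength
#' grids (e.g. five scans, 200-260 nm).
#'
#' @param spectra List of tibbles, each with columns `wavelength_nm` and
#'   `signal` on the same grid.
#' @return Tibble `wavelength_nm`, `signal` (mean across replicates).
#' @export
average_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0) {
    abort("`spectra` must be a non-empty list")
  }
  grid <- spectra[[1]]$wavelength_nm
  ok <- vapply(spectra, function(s) {
    length(s$wavelength_nm) == length(grid) &&
      all(s$wavelength_nm == grid)
  }, logical(1))
  if (!all(ok)) abort("all spectra must share an identical wavelength grid")
  sig <- rowMeans(vapply(spectra, function(s) s$signal, numeric(length(grid))))
  tibble(wavelength_nm = grid, signal = sig)
}
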