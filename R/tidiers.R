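## broom-style tidy()/glance() and ggplot2 autoplot() methods for the
## fitted objects.

#' @export
tidy.trace_fit <- function(x, ...) {
  tibble(
    term = c("k_obs", "amplitude", "offset"),
    estimate = c(x$k_obs, x$amplitude, x$offset),
    std.error = c(x$k_obs_se, NA_real_, NA_real_)
  )
}

#' @export
glance.trace_fit <- function(x, ...) {
  tibble(k_obs = x$k_obs, k_obs_se = x$k_obs_se,
         residual_sd = x$residual_sd, converged = x$converged,
         flags = paste(x$flags, collapse = ","), nobs = nrow(x$data))
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(
    term = c("k_on", "k_off", "K_d"),
    estimate = c(x$k_on, x$k_off, x$K_d),
    std.error = c(x$k_on_se, x$k_off_se, x$K_d_se)
  )
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(k_on = x$k_on, k_off = x$k_off, K_d = x$K_d,
         source = x$source, flags = paste(x$flags, collapse = ","),
         nobs = nrow(x$data))
}

#' @export
tidy.denat_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::rename(x$params, std.error = "std_error"),
    tibble(term = "dG", estimate = x$dG, std.error = x$dG_se)
  )
}

#' @export
glance.denat_fit <- function(x, ...) {
  est <- setNames(x$params$estimate, x$params$term)
  tibble(D50 = unname(est["D50"]), m = unname(est["m"]),
         dG = x$dG, dG_se = x$dG_se,
         residual_sd = x$residual_sd, converged = x$converged,
         flags = paste(x$flags, collapse = ","), nobs = nrow(x$data))
}

#' @export
tidy.denat_global_fit <- function(x, ...) x$fits

#' @export
glance.denat_global_fit <- function(x, ...) {
  tibble(n_curves = nrow(x$fits), n_groups = length(x$m_by_group),
         rss_shared = x$rss_shared, rss_free = x$rss_free,
         flags = paste(x$flags, collapse = ","))
}

#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(
    term = c("n", "K_d", "dH", "dG", "TdS", "dilution_offset"),
    estimate = c(x$n, x$K_d, x$dH, x$dG, x$TdS, x$dilution_offset),
    std.error = c(x$n_se, x$K_d_se, x$dH_se, NA_real_, NA_real_, NA_real_)
  )
}

#' @export
glance.itc_fit <- function(x, ...) {
  tibble(n = x$n, K_d = x$K_d, dH = x$dH, dG = x$dG, TdS = x$TdS,
         c_value = x$c_value, converged = x$converged,
         flags = paste(x$flags, collapse = ","), nobs = nrow(x$data))
}

fit_plot <- function(data, xvar, yvar, pred, xlab, ylab) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]])) +
    ggplot2::geom_point(colour = "grey30", size = 1) +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]]),
                       colour = "firebrick") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trace_fit <- function(object, ...) {
  d <- as_tibble(as.data.frame(object$data))
  pred <- tibble(
    time_s = d$time_s,
    signal = object$offset + object$amplitude * exp(-object$k_obs * d$time_s)
  )
  fit_plot(d, "time_s", "signal", pred, "time (s)", "signal (a.u.)")
}

#' @export
autoplot.kinetic_fit <- function(object, ...) {
  if (object$source != "binding_curve") {
    abort("autoplot is available for binding-curve fits only")
  }
  d <- as_tibble(as.data.frame(object$data))
  grid <- tibble(conc_uM = seq(min(d$conc_uM), max(d$conc_uM),
                               length.out = 200))
  grid$kobs_s <- bimolecular_kobs(object$k_on, object$k_off,
                                  object$A0, grid$conc_uM)
  fit_plot(d, "conc_uM", "kobs_s", grid,
           "ligand concentration (uM)", expression(k[obs] ~ (s^-1)))
}

#' @export
autoplot.denat_fit <- function(object, ...) {
  d <- as_tibble(as.data.frame(object$data))
  est <- setNames(object$params$estimate, object$params$term)
  grid <- tibble(urea_M = seq(min(d$urea_M), max(d$urea_M), length.out = 200))
  grid$signal <- two_state_signal(grid$urea_M, est["aN"], est["bN"],
                                  est["aD"], est["bD"], est["D50"],
                                  est["m"], object$temperature_K)
  fit_plot(d, "urea_M", "signal", grid, "[urea] (M)", "signal")
}

#' @export
autoplot.itc_fit <- function(object, ...) {
  d <- as_tibble(as.data.frame(object$data))
  meta <- expt_metadata(object$data)
  inj <- meta$inj_volume_uL
  if (length(inj) == 1) inj <- rep(inj, nrow(d))
  pred <- tibble(
    injection = d$injection,
    heat_kcal_per_mol = one_site_heats(
      object$n, object$K_d, object$dH, meta$cell_conc_uM,
      meta$syringe_conc_uM, inj, meta$cell_volume_uL) + object$dilution_offset
  )
  fit_plot(d, "injection", "heat_kcal_per_mol", pred,
           "injection", "heat (kcal/mol of injectant)")
}
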