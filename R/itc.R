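## Isothermal titration calorimetry, one-site binding model.
##
## Ligand is titrated from the syringe into a fixed-volume cell containing
## the macromolecule. Because the cell overflows, each injection of volume
## dV first displaces dV of the pre-mixed cell solution and then mixes.
## The discrete bookkeeping used by both generator and fitter:
##
##   M_i = M_{i-1} (1 - dV_i/V0)
##   X_i = X_{i-1} (1 - dV_i/V0) + X_syr dV_i/V0
##
## At each step the complex concentration C_i solves the one-site
## quadratic n M_i X_i binding equilibrium; the heat of injection i is
## dH * V0 * (C_i - C_{i-1} (1 - dV_i/V0)) normalised per mole injected.
## Thermodynamics: dG = R T ln(K_d in M) (negative for binding),
## T dS = dH - dG, so dG + TdS = dH exactly in every emitted result.

one_site_bound <- function(M_tot, X_tot, n, K_d) {
  ## complex concentration for sites S = n*M binding X with dissociation
  ## constant K_d: C^2 - (S + X + Kd) C + S X = 0, take the root in [0, min]
  S <- n * M_tot
  b <- S + X_tot + K_d
  disc <- pmax(b^2 - 4 * S * X_tot, 0)
  (b - sqrt(disc)) / 2
}

#' Per-injection heats of a one-site ITC titration
#'
#' Forward model for integrated injection heats, in kcal per mole of
#' injectant, including the displaced-volume dilution bookkeeping
#' described above. Concentrations in uM, volumes in uL.
#'
#' @param n Binding stoichiometry (sites per macromolecule).
#' @param K_d_uM Dissociation constant, uM.
#' @param dH Binding enthalpy, kcal/mol.
#' @param cell_conc_uM Initial macromolecule concentration in the cell, uM.
#' @param syringe_conc_uM Ligand concentration in the syringe, uM.
#' @param inj_volumes_uL Vector of injection volumes, uL.
#' @param cell_volume_uL Working cell volume, uL.
#' @return Numeric vector of per-injection heats (kcal/mol of injectant).
#' @export
#' @examples
#' one_site_heats(1, 0.7, -7.5, 35, 350, rep(2.4, 16), 200)
one_site_heats <- function(n, K_d_uM, dH, cell_conc_uM, syringe_conc_uM,
                           inj_volumes_uL, cell_volume_uL) {
  if (any(c(cell_conc_uM, syringe_conc_uM, inj_volumes_uL,
            cell_volume_uL) <= 0)) {
    abort("concentrations and volumes must be > 0")
  }
  if (n <= 0 || K_d_uM <= 0) abort("`n` and `K_d_uM` must be > 0")
  V0 <- cell_volume_uL
  M <- cell_conc_uM
  X <- 0
  C_prev <- 0
  heats <- numeric(length(inj_volumes_uL))
  for (i in seq_along(inj_volumes_uL)) {
    dV <- inj_volumes_uL[i]
    dil <- 1 - dV / V0
    M <- M * dil
    X <- X * dil + syringe_conc_uM * dV / V0
    C_new <- one_site_bound(M, X, n, K_d_uM)
    ## heat from newly formed complex; complex displaced out of the cell
    ## released its heat earlier and does not count
    dq_kcal <- dH * (C_new - C_prev * dil) * V0 * 1e-12  # uM*uL -> mol
    mol_injected <- syringe_conc_uM * dV * 1e-12
    heats[i] <- dq_kcal / mol_injected
    C_prev <- C_new
  }
  heats
}

#' Fit ITC injection heats to the one-site model
#'
#' Nonlinear least squares over stoichiometry `n`, `K_d`, enthalpy `dH`
#' and a constant heat-of-dilution offset. Standard errors come from the
#' fit covariance. The c-value (`n * cell_conc / K_d`) determines whether
#' `K_d` is identifiable: fits with c < 1 or c > 1000 are flagged
#' `"Kd_poorly_constrained"`.
#'
#' @param heats Experiment table of kind `"itc"` (>= 8 injections) with
#'   columns `injection`, `heat_kcal_per_mol` and metadata
#'   `cell_conc_uM`, `syringe_conc_uM`, `cell_volume_uL`, `inj_volume_uL`
#'   (scalar or per-injection) and `temperature_K`.
#' @return Object of class `itc_fit`: `n`, `K_d`, `dH` with standard
#'   errors, derived `dG` and `TdS` (so that `dG + TdS == dH` exactly),
#'   `dilution_offset`, `c_value`, `flags`, `data`.
#' @export
fit_itc <- function(heats) {
  assert_expt(heats, "itc")
  if (nrow(heats) < 8) abort("need at least 8 injections to fit")
  meta <- expt_metadata(heats)
  req <- c("cell_conc_uM", "syringe_conc_uM", "cell_volume_uL", "inj_volume_uL")
  missing_meta <- setdiff(req, names(meta))
  if (length(missing_meta) > 0) {
    abort(sprintf("itc metadata incomplete; missing: %s",
                  paste(missing_meta, collapse = ", ")))
  }
  temperature_K <- meta$temperature_K %||% 298.15
  inj <- meta$inj_volume_uL
  if (length(inj) == 1) inj <- rep(inj, nrow(heats))
  q <- heats$heat_kcal_per_mol

  ## featureless data: enthalpy indistinguishable from dilution noise
  if (diff(range(q)) < 1e-12 || sd(q) < 1e-12) {
    return(new_itc_fit(n = NA_real_, n_se = NA_real_, K_d = NA_real_,
                       K_d_se = NA_real_, dH = 0, dH_se = NA_real_,
                       dG = NA_real_, TdS = NA_real_,
                       dilution_offset = mean(q), c_value = NA_real_,
                       converged = FALSE, flags = "Kd_unconstrained",
                       temperature_K = temperature_K, data = heats))
  }

  offset0 <- mean(tail(q, 3))
  dH0 <- q[1] - offset0
  ## molar ratio at each injection midpoint, for the stoichiometry guess
  ratio <- cumsum(meta$syringe_conc_uM * inj) /
    (meta$cell_conc_uM * meta$cell_volume_uL)
  half <- offset0 + dH0 / 2
  n0 <- ratio[which.min(abs(q - half))]
  n0 <- min(max(n0, 0.2), 5)
  Kd0 <- meta$cell_conc_uM / 20

  model <- function(p) {
    one_site_heats(p[[1]], p[[2]], p[[3]], meta$cell_conc_uM,
                   meta$syringe_conc_uM, inj, meta$cell_volume_uL) + p[[4]]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(n = n0, K_d = Kd0, dH = dH0, off = offset0),
      fn = function(p) q - model(p),
      lower = c(1e-3, 1e-6, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit) && !(fit$info %in% 1:4)) fit <- NULL
  if (is.null(fit)) {
    return(new_itc_fit(n = NA_real_, n_se = NA_real_, K_d = NA_real_,
                       K_d_se = NA_real_, dH = NA_real_, dH_se = NA_real_,
                       dG = NA_real_, TdS = NA_real_,
                       dilution_offset = NA_real_, c_value = NA_real_,
                       converged = FALSE, flags = "no_convergence",
                       temperature_K = temperature_K, data = heats))
  }
  cf <- fit$par
  se <- summary(fit)$coefficients[, "Std. Error"]
  c_value <- cf[["n"]] * meta$cell_conc_uM / cf[["K_d"]]
  flags <- character()
  if (c_value < 1 || c_value > 1000) flags <- c(flags, "Kd_poorly_constrained")
  th <- derive_entropy(cf[["dH"]], cf[["K_d"]], temperature_K)
  new_itc_fit(
    n = cf[["n"]], n_se = se[["n"]],
    K_d = cf[["K_d"]], K_d_se = se[["K_d"]],
    dH = cf[["dH"]], dH_se = se[["dH"]],
    dG = th$dG, TdS = th$TdS,
    dilution_offset = cf[["off"]], c_value = c_value,
    converged = TRUE, flags = flags,
    temperature_K = temperature_K, data = heats,
    residual_sd = summary(fit)$sigma
  )
}

new_itc_fit <- function(...) structure(list(...), class = "itc_fit")

#' @export
print.itc_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<itc fit: not converged (%s)>\n",
                paste(x$flags, collapse = ",")))
    return(invisible(x))
  }
  cat(sprintf("<itc fit: n = %.3g, K_d = %.3g uM, dH = %.3g kcal/mol (c = %.3g)>\n",
              x$n, x$K_d, x$dH, x$c_value))
  cat(sprintf("  dG = %.3g, TdS = %.3g kcal/mol at %.2f K\n",
              x$dG, x$TdS, x$temperature_K))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' Binding free energy and entropy from ITC parameters
#'
#' `dG = R T ln(K_d)` with K_d expressed in mol/L against the 1 M standard
#' state (negative for favourable binding) and `TdS = dH - dG`, so the
#' thermodynamic closure `dG + TdS = dH` holds exactly.
#'
#' @param dH Binding enthalpy, kcal/mol.
#' @param K_d_uM Dissociation constant, uM (> 0).
#' @param temperature_K Temperature, K (default 298.15, i.e. 25 C).
#' @return Tibble with `dG` and `TdS`, kcal/mol.
#' @export
#' @examples
#' derive_entropy(-7.5, 0.7)  # TdS ~ 0.9 kcal/mol
derive_entropy <- function(dH, K_d_uM, temperature_K = 298.15) {
  if (any(K_d_uM <= 0)) abort("`K_d_uM` must be > 0")
  if (any(temperature_K <= 0)) abort("`temperature_K` must be > 0")
  dG <- R_KCAL * temperature_K * log(K_d_uM * 1e-6)
  tibble(dG = dG, TdS = dH - dG)
}
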