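## Synthetic-data generation with known ground truth.
##
## Every input the pipeline consumes can be generated here: a conserved
## protein family evolved down a tree (with per-node posterior tables and
## the true ancestral sequences kept for recovery tests), exponential
## stopped-flow traces obeying the bimolecular k_obs relation, two-state
## urea curves with sloping baselines, and one-site ITC isotherms. Noise
## is homoscedastic Gaussian per experiment; all generators are
## deterministic under a fixed seed.
##
## Default truths mirror the conditions of a well-behaved PDZ:peptide
## system: k_on = 6.3 uM^-1 s^-1 and k_off = 2.49 s^-1 (K_d = 0.395 uM) for
## kinetics at 10 C; D50 = 4 M, m = 1.23 kcal/mol/M on a 0-8.1 M urea grid
## in 0.3 M steps for denaturation; n = 1, K_d = 0.7 uM, dH = -7.5 kcal/mol
## with 16 injections for ITC at 25 C.

local_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (abs(seed) >= 2^31) abort("`seed` must be a 32-bit integer")
    withr::local_seed(as.integer(seed), .local_envir = parent.frame())
  }
  invisible(NULL)
}

#' Simulate a conserved protein family down a tree
#'
#' Evolves a root sequence along a tree with branch lengths under a
#' uniform 20-letter replacement model (per-site substitution probability
#' `1 - exp(-mutation_rate * branch_length)`, replacement drawn uniformly
#' from the 19 other residues). A C-terminal window of 6 residues can be
#' held invariant to emulate a conserved PDZ-binding motif. For every
#' internal node an empirical posterior table is built: confident sites
#' are (near-)one-hot on the true ancestral residue, while a controllable
#' fraction of sites with leaf-level variation get PP(ML) = 0.6 with the
#' remaining mass spread over residues observed beneath the node in
#' proportion to their frequency - the statistical feature the AltAll
#' logic consumes. With `mutation_rate = 0` every posterior is exactly
#' one-hot and ML = AltAll = the true ancestor.
#'
#' @param tree [ape::phylo] tree; branch lengths required unless
#'   `mutation_rate = 0`. Internal nodes without labels are auto-named
#'   `anc<i>`.
#' @param root_seq Root residue string; default a random sequence of
#'   length `seq_length` ending in a type I motif window.
#' @param seq_length Root sequence length when `root_seq` is `NULL`.
#' @param mutation_rate Substitutions per site per unit branch length.
#' @param motif_conservation Probability that each of the last 6 sites is
#'   exempt from mutation (1 = motif fully conserved).
#' @param ambiguous_fraction Target fraction of sites per node forced
#'   below PP 0.8 (only sites with variation beneath the node are
#'   eligible).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `alignment` (tibble `id`, `seq` for the leaves),
#'   `ancestors` (named vector of true internal-node sequences), `tree`
#'   (with internal labels filled in) and `posteriors` (named list of
#'   `evb_pp` tables, one per internal node).
#' @export
simulate_family <- function(tree, root_seq = NULL, seq_length = 60,
                            mutation_rate = 0.3, motif_conservation = 1,
                            ambiguous_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  local_seed_if(seed)
  if (is.null(tree$edge.length)) {
    if (mutation_rate > 0) {
      abort("tree has no branch lengths but `mutation_rate` > 0")
    }
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (mutation_rate > 0 && all(tree$edge.length == 0)) {
    abort("all branch lengths are zero but `mutation_rate` > 0")
  }
  aa <- amino_acids()
  if (is.null(root_seq)) {
    root_seq <- paste0(
      c(sample(aa, seq_length - 6, replace = TRUE),
        "Y", "K", "Q", "T", "S", "V")[seq_len(seq_length)],
      collapse = "")
  }
  root <- strsplit(toupper(root_seq), "")[[1]]
  L <- length(root)
  motif_sites <- seq.int(max(1L, L - 5L), L)
  invariant <- rep(FALSE, L)
  invariant[motif_sites] <- stats::runif(length(motif_sites)) < motif_conservation

  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label))) {
    tree$node.label <- paste0("anc", seq_len(tree$Nnode))
  }
  labels <- node_labels_in_order(tree)
  seqs <- vector("list", n_tip + tree$Nnode)
  root_node <- n_tip + 1L
  seqs[[root_node]] <- root
  ## preorder down the edge list (ape edges are parent-before-child when
  ## reordered cladewise)
  tr_ord <- ape::reorder.phylo(tree, "cladewise")
  edge <- tr_ord$edge
  bl <- tr_ord$edge.length
  for (e in seq_len(nrow(edge))) {
    parent <- seqs[[edge[e, 1]]]
    p_sub <- 1 - exp(-mutation_rate * bl[e])
    child <- parent
    hit <- which(stats::runif(L) < p_sub & !invariant)
    for (s in hit) {
      child[s] <- sample(setdiff(aa, parent[s]), 1)
    }
    seqs[[edge[e, 2]]] <- child
  }

  leaf_mat <- do.call(rbind, seqs[seq_len(n_tip)])
  internal <- root_node:(n_tip + tree$Nnode)
  tips_below <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(edge[edge[, 1] == node, 2], tips_below))
  }
  posteriors <- list()
  for (node in internal) {
    truth <- seqs[[node]]
    tips <- tips_below(node)
    sub <- leaf_mat[tips, , drop = FALSE]
    varied <- vapply(seq_len(L), function(s) {
      length(unique(c(sub[, s], truth[s]))) > 1
    }, logical(1))
    n_ambig <- min(sum(varied), round(ambiguous_fraction * L))
    ambig <- rep(FALSE, L)
    if (n_ambig > 0) {
      ambig[sample(which(varied), n_ambig)] <- TRUE
    }
    m <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, aa))
    for (s in seq_len(L)) {
      t_idx <- match(truth[s], aa)
      others <- table(sub[, s][sub[, s] != truth[s]])
      if (!varied[s]) {
        m[s, t_idx] <- 1
      } else if (ambig[s]) {
        m[s, t_idx] <- 0.6
        if (length(others) > 0) {
          m[s, names(others)] <- 0.4 * as.numeric(others) / sum(others)
        } else {
          m[s, sample(setdiff(aa, truth[s]), 1)] <- 0.4
        }
      } else {
        m[s, t_idx] <- 0.9
        if (length(others) > 0) {
          m[s, names(others)] <- 0.1 * as.numeric(others) / sum(others)
        } else {
          m[s, t_idx] <- 1
        }
      }
    }
    posteriors[[labels[node]]] <- posterior_table(m, node_id = labels[node])
  }
  list(
    alignment = tibble(id = tree$tip.label,
                       seq = apply(leaf_mat, 1, paste0, collapse = "")),
    ancestors = setNames(
      vapply(seqs[internal], paste0, "", collapse = ""),
      labels[internal]),
    tree = tree,
    posteriors = posteriors
  )
}

#' Simulate a stopped-flow binding trace
#'
#' Single-exponential relaxation `signal(t) = offset + amplitude *
#' exp(-k_obs t)` plus Gaussian noise, with the embedded `k_obs` computed
#' from [bimolecular_kobs()] at the given rates and concentrations.
#'
#' @param k_on,k_off Rate constants (uM^-1 s^-1, s^-1), > 0.
#' @param A0,B0 Total concentrations, uM, > 0.
#' @param noise_sd Gaussian noise sd, signal units.
#' @param n_points Number of time points (default 1000).
#' @param t_max Trace length, s; default `10 / k_obs` so the trace decays
#'   fully.
#' @param amplitude,offset Signal amplitude and baseline.
#' @param seed Integer seed.
#' @return Experiment table of kind `"trace"`; the true `k_obs` and inputs
#'   are stored in its metadata.
#' @export
simulate_trace <- function(k_on, k_off, A0, B0, noise_sd = 0,
                           n_points = 1000, t_max = NULL,
                           amplitude = 1, offset = 0, seed = NULL) {
  if (any(c(k_on, k_off, A0, B0) <= 0)) {
    abort("rates and concentrations must be > 0")
  }
  local_seed_if(seed)
  k_obs <- bimolecular_kobs(k_on, k_off, A0, B0)
  t_max <- t_max %||% (10 / k_obs)
  if (t_max <= 0) abort("`t_max` must be > 0")
  t <- seq(0, t_max, length.out = n_points)
  y <- offset + amplitude * exp(-k_obs * t) +
    stats::rnorm(n_points, sd = noise_sd)
  experiment_table(
    tibble(time_s = t, signal = y),
    "trace",
    metadata = list(k_obs_true = k_obs, k_on = k_on, k_off = k_off,
                    A0_uM = A0, B0_uM = B0, noise_sd = noise_sd)
  )
}

#' Simulate a urea denaturation curve
#'
#' Two-state signal ([two_state_signal()]) on a urea grid plus Gaussian
#' noise. The default grid is 0 to 8.1 M in 0.3 M steps (28 points).
#'
#' @param D50 Midpoint, M.
#' @param m m-value, kcal/mol/M.
#' @param aN,bN,aD,bD Baseline parameters (defaults emulate ellipticity at
#'   222 nm: deep native signal relaxing to a shallow denatured baseline).
#' @param urea_grid Urea concentrations, M, within \[0, 12\].
#' @param temperature_K Temperature, K (default 283.15).
#' @param noise_sd Gaussian noise sd, signal units.
#' @param seed Integer seed.
#' @return Experiment table of kind `"denaturation"` with the truth in its
#'   metadata.
#' @export
simulate_denaturation <- function(D50 = 4, m = 1.23,
                                  aN = -11, bN = 0.1, aD = -3, bD = -0.05,
                                  urea_grid = seq(0, 8.1, by = 0.3),
                                  temperature_K = 283.15,
                                  noise_sd = 0, seed = NULL) {
  if (any(urea_grid < 0 | urea_grid > 12)) {
    abort("`urea_grid` must lie within [0, 12] M")
  }
  if (D50 <= 0 || m <= 0) abort("`D50` and `m` must be > 0")
  local_seed_if(seed)
  y <- two_state_signal(urea_grid, aN, bN, aD, bD, D50, m, temperature_K) +
    stats::rnorm(length(urea_grid), sd = noise_sd)
  experiment_table(
    tibble(urea_M = urea_grid, signal = y),
    "denaturation",
    metadata = list(D50_true = D50, m_true = m, aN = aN, bN = bN,
                    aD = aD, bD = bD, temperature_K = temperature_K,
                    noise_sd = noise_sd)
  )
}

#' Simulate a one-site ITC titration
#'
#' Per-injection heats from [one_site_heats()] plus Gaussian noise.
#' Defaults give 16 equal injections at a c-value of 50
#' (`n * cell_conc / K_d`), the comfortably identifiable regime.
#'
#' @param n Stoichiometry.
#' @param K_d_uM Dissociation constant, uM.
#' @param dH Enthalpy, kcal/mol.
#' @param cell_conc_uM,syringe_conc_uM Concentrations, uM.
#' @param n_injections Number of injections (default 16).
#' @param inj_volume_uL Injection volume(s), uL (scalar or vector).
#' @param cell_volume_uL Cell volume, uL.
#' @param temperature_K Temperature, K (default 298.15).
#' @param noise_sd Gaussian noise sd, kcal/mol of injectant.
#' @param seed Integer seed.
#' @return Experiment table of kind `"itc"` with complete metadata, ready
#'   for [fit_itc()].
#' @export
simulate_itc <- function(n = 1, K_d_uM = 0.7, dH = -7.5,
                         cell_conc_uM = 35, syringe_conc_uM = 350,
                         n_injections = 16, inj_volume_uL = 2.4,
                         cell_volume_uL = 200, temperature_K = 298.15,
                         noise_sd = 0, seed = NULL) {
  local_seed_if(seed)
  inj <- if (length(inj_volume_uL) == 1) {
    rep(inj_volume_uL, n_injections)
  } else {
    inj_volume_uL
  }
  q <- one_site_heats(n, K_d_uM, dH, cell_conc_uM, syringe_conc_uM,
                      inj, cell_volume_uL) +
    stats::rnorm(length(inj), sd = noise_sd)
  experiment_table(
    tibble(injection = seq_along(inj), heat_kcal_per_mol = q),
    "itc",
    metadata = list(cell_conc_uM = cell_conc_uM,
                    syringe_conc_uM = syringe_conc_uM,
                    inj_volume_uL = inj_volume_uL,
                    cell_volume_uL = cell_volume_uL,
                    temperature_K = temperature_K,
                    n_true = n, K_d_true_uM = K_d_uM, dH_true = dH,
                    noise_sd = noise_sd)
  )
}

#' Simulate a full k_obs-versus-concentration series
#'
#' Convenience wrapper chaining [simulate_trace()] and [fit_trace()] at a
#' range of ligand concentrations, as in a stopped-flow binding-curve
#' experiment (fixed receptor at `A0`, ligand varied).
#'
#' @param k_on,k_off True rate constants.
#' @param A0 Receptor concentration, uM.
#' @param B0 Ligand concentrations, uM (default 2-20 uM in 2 uM steps).
#' @param noise_sd Trace noise sd (signal units; traces have unit
#'   amplitude).
#' @param n_points Points per trace.
#' @param seed Integer seed (each trace gets a sub-seed derived from it).
#' @return Experiment table of kind `"kobs_series"` with columns
#'   `conc_uM`, `kobs_s`, `kobs_se_s`.
#' @export
simulate_kobs_series <- function(k_on = 6.3, k_off = 2.49, A0 = 1,
                                 B0 = seq(2, 20, by = 2), noise_sd = 0.01,
                                 n_points = 500, seed = NULL) {
  local_seed_if(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, length(B0))
  fits <- purrr::map2(B0, sub_seeds, function(b, s) {
    fit_trace(simulate_trace(k_on, k_off, A0, b, noise_sd = noise_sd,
                             n_points = n_points, seed = s))
  })
  experiment_table(
    tibble(conc_uM = B0,
           kobs_s = purrr::map_dbl(fits, "k_obs"),
           kobs_se_s = purrr::map_dbl(fits, "k_obs_se")),
    "kobs_series",
    metadata = list(k_on_true = k_on, k_off_true = k_off, A0_uM = A0,
                    noise_sd = noise_sd)
  )
}
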