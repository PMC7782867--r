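---
title: "Models and methods behind evobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evobind)
```

evobind covers the computational side of an ancestral-resurrection study
of a PDZ domain and its C-terminal peptide ligand: post-processing
ancestral-reconstruction posteriors, classifying PDZ-binding motifs on a
tree, and fitting the three biophysical experiment types used to
characterise resurrected proteins. This vignette is the package's own
account of those models: the assumptions behind each, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not demonstrate.

## Binding kinetics

The kinetic model is reversible bimolecular association, A + B ⇌ C, with
association rate constant $k_{on}$ (µM⁻¹s⁻¹) and dissociation rate
constant $k_{off}$ (s⁻¹). Concentrations are µM throughout, so $k_{on}$
carries the units in which stopped-flow results are conventionally quoted
for peptide binding.

A mixing experiment relaxes toward equilibrium as a single exponential
whose observed rate is, exactly,

$$k_{obs} = \sqrt{k_{on}^2 (A_0 - B_0)^2 + k_{off}^2
  + 2\,k_{on} k_{off}\,(A_0 + B_0)},$$

equal to the linearised relaxation rate $k_{on}(A_{eq} + B_{eq}) +
k_{off}$. We use this exact form rather than the pseudo-first-order
approximation $k_{obs} \approx k_{on} B_0 + k_{off}$, because typical
designs (receptor at 1 µM, ligand from 2 µM) violate the large-excess
assumption at the low end of the titration. The test suite checks the
closed form against an independent oracle — numerical integration of the
mass-action ODE from a perturbed equilibrium, with the rate extracted
from the late-time log-linear slope — to $10^{-6}$ relative over a
5×5×5×5 grid spanning $k_{on}$ 1–15 µM⁻¹s⁻¹, $k_{off}$ 1–150 s⁻¹ and
concentrations 1–20 µM.

One transcription hazard deserves a note: the final parenthesis of this
expression is sometimes mangled in print into forms like
$(A_0 + B_0 + A_0)$. The oracle equivalence above is what pins our
implementation to $(A_0 + B_0)$.

`fit_trace()` fits $\text{signal} = \text{offset} + \text{amplitude}
\cdot e^{-k_{obs} t}$ by Levenberg–Marquardt least squares
(minpack.lm), initialised from a log-linear regression of the
baseline-subtracted early trace. A trace whose amplitude is
indistinguishable from the tail noise (within 3 sd) is returned flagged
`no_amplitude` instead of fitted: $k_{obs}$ is unidentifiable there, and a
number would be noise. `fit_binding_curve()` fits the exact $k_{obs}$
model over $(k_{on}, k_{off})$ with non-negativity bounds, initialised
from the slope and intercept of a straight-line fit (the high-
concentration limit). Points may be weighted by their trace-fit standard
errors via `weighted = TRUE`; the default is unweighted, since the
weighting used in published analyses of this kind is typically
unstated. `displacement_koff()` averages the observed rates of
displacement traces — at saturating competitor the relaxation rate equals
$k_{off}$ — reporting their standard deviation, and warns when $k_{obs}$
trends monotonically with competitor concentration (relative spread
above 10%), the signature of incomplete saturation.

$K_d = k_{off}/k_{on}$ exactly in every emitted result; its standard
error combines the two relative errors in quadrature, a first-order
propagation adequate at the few-percent error level these fits produce.

## Equilibrium urea denaturation

The observed signal (ellipticity at 222 nm in the motivating experiments)
is modelled as the population-weighted average of two baselines, each
linear in denaturant:

$$F(u) = \frac{(\alpha_N + \beta_N u) + (\alpha_D + \beta_D u)\,
  e^{m (u - D_{50})/RT}}{1 + e^{m (u - D_{50})/RT}}$$

with midpoint $D_{50}$ (M), cooperativity $m$ (kcal mol⁻¹ M⁻¹), $R =
1.9872 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ and $T$ defaulting to 283.15 K
(10 °C, the usual CD measurement temperature; overridable everywhere).
The two-state assumption — no populated intermediates — is the standard
reading of a single cooperative CD transition. Stability is reported as
$\Delta G = m \cdot D_{50}$ (linear extrapolation to zero denaturant,
positive for a stable protein), and this identity holds exactly in every
emitted fit; its standard error propagates the $m$ and $D_{50}$ errors
including their covariance.

The implementation evaluates the denatured fraction through the logistic
function rather than the raw exponential ratio, which overflows a few
dozen molar past the midpoint during optimiser excursions.

`fit_denaturation()` is a six-parameter fit; $D_{50}$ is initialised at
the urea value nearest the half-amplitude crossing and $m$ at 1 kcal
mol⁻¹ M⁻¹, with $D_{50}$ bounded to the measured range. Quality flags
mirror how an experimentalist reads these curves: `poorly_defined_m` when
the curve never reaches 95% unfolded or has fewer than three points past
$D_{50} + 1$ M (a short denatured baseline makes $m$ unreliable),
`no_transition` when the fitted baselines are separated by less than 5%
of the data range at the midpoint (featureless data), and
`D50_outside_range` when the optimiser pins the midpoint at an edge.

`fit_global_shared_m()` fits several curves jointly — per-curve baselines
and $D_{50}$, one $m$ per share group — via `minpack.lm::nls.lm` on the
stacked residuals. Proteins of similar size bury similar surface area on
unfolding, so a shared $m$ is physically motivated and statistically
stabilising; but the grouping is *user configuration*, not inference,
because real studies deliberately give constructs of different length
(e.g. with and without a C-terminal helix extension) their own shared
value. After the joint fit each curve is also fitted freely; a joint
residual sum of squares exceeding twice the free-fit total flags
`heterogeneous_m` — curves that genuinely differ in $m$ were forced
together. The variance argument for sharing is kept testable: across
replicate simulated curve pairs with a common true $m$, the spread of
shared-m $\Delta G$ estimates must not exceed the free-fit spread, and
the per-fit propagated $\Delta G$ uncertainty must shrink.

## Isothermal titration calorimetry

The one-site model treats $n$ binding sites per macromolecule with a
single $K_d$ and enthalpy $\Delta H$. Because the instrument cell
overflows, each injection of volume $dV$ into working volume $V_0$ first
displaces $dV$ of pre-mixed cell solution and then mixes; the package's
bookkeeping is the discrete form of that statement,

$$M_i = M_{i-1}(1 - dV_i/V_0), \qquad
  X_i = X_{i-1}(1 - dV_i/V_0) + X_{syr}\,dV_i/V_0,$$

with the complex concentration at each step from the one-site quadratic
and the injection heat $\Delta H \cdot V_0 \cdot (C_i - C_{i-1}(1 -
dV_i/V_0))$, normalised per mole of injectant. Instrument vendors differ
in the exact displaced-volume convention; ours is documented here, shared
by generator and fitter, and cross-checked in the tests against an
independent micro-step mass-balance oracle (many small
displacement-mix-equilibrate steps per injection). The two conventions
agree to $O(dV/V_0)$, about 1% at the default 2.4 µL into 200 µL, which
is the tolerance the cross-check asserts — the point of the oracle is to
guard against self-consistency bias between generator and fitter, not to
adjudicate vendor conventions.

`fit_itc()` fits $(n, K_d, \Delta H)$ plus a constant heat-of-dilution
offset by bounded Levenberg–Marquardt, initialised from the heat of the
first injection ($\Delta H$), the tail mean (offset) and the molar ratio
at the half-amplitude heat ($n$). The optimiser is driven through
`nls.lm` directly rather than the formula-interface wrapper: the wrapper
rebuilds a Gauss–Newton model object at the converged optimum, and on
noise-free synthetic data that post-hoc construction can reject a
perfectly good optimum with a spurious singular-gradient error.
Identifiability follows the c-value $c = n \cdot [\text{cell}]/K_d$:
fits outside $1 < c < 1000$ are flagged `Kd_poorly_constrained`, and
all-zero heats return a flagged non-fit rather than numbers.

Derived thermodynamics use $\Delta G = RT \ln K_d$ (K_d in mol/L, 1 M
standard state, negative for binding) at $T$ = 298.15 K by default, with
$T\Delta S = \Delta H - \Delta G$, so the closure $\Delta G + T\Delta S =
\Delta H$ is exact by construction in every output row.

## Ancestral-sequence post-processing

Input is one posterior table per internal node: sites in order, one
column per amino acid in strict alphabetical order, rows summing to 1.
Rows off by more than $10^{-3}$ are rejected; deviations up to that are
accepted and renormalised, a band that tolerates files written with few
digits while still catching real corruption. The TSV dialect (header
`site` + 20 columns, 1-based sites, one file per node) is this package's
own convention — phylogenetics packages emit various formats, and the
conversion to this one is a mechanical reshape.

The ML sequence takes the per-site maximum-posterior residue. The AltAll
("alternative at all ambiguous positions") sequence substitutes the
second-highest-probability residue at every site where the ML residue's
posterior is *strictly* below the threshold, 0.8 by default — the
conventional worst-case construct for testing robustness of resurrection
results. Ties at the maximum or the runner-up are broken alphabetically:
real posteriors essentially never tie exactly, but a deterministic rule
is required for reproducibility, and the uniform-row corner case then
resolves to alanine by construction rather than by accident.

Identity and similarity between aligned sequences exclude positions
where either sequence has a gap from the denominator. "Similar" means a
positive score in a log-odds substitution matrix; BLOSUM62 is the default
and the matrix is injectable, since different studies compute their
printed similarity percentages with different (sometimes uncited)
matrices. For that reason we make no claim of reproducing any particular
published identity/similarity figure — the convention, not the
arithmetic, is the variable.

## Motif classification

`classify_pbm()` reads only the last three residues: type I requires
P−2 ∈ {T, S}, type III P−2 ∈ {D, E}, type II P−2 ∈ Φ, all with P0 ∈ Φ.
The hydrophobic set defaults to Φ = {V, I, L, M, F}. That choice is
inferred from how such peptides behave experimentally: valine- and
leucine-terminated peptides bind the canonical groove, while alanine-,
threonine- and cysteine-terminated ones do not act as type I ligands, so
small residues (A, G, C) are excluded at P0. Φ is an argument precisely
because the literature draws this boundary differently for some domains.
Precedence I > III > II resolves overlaps that a customised Φ can create
(with the default set, the predicates are disjoint). Classification is a
total function on sequences of length ≥ 3, and prefix-invariance (only
the last three residues matter) is enforced by property tests.

`annotate_tree_motifs()` classifies every named node of a tree given
leaf and (optionally) ancestral sequences, and lists the edges along
which the class changed — the tree-level summary used to date motif
gains and losses. Annotated trees are serialised as newick with
`[&key=value]` comments attached to node labels, written by a small
recursive serialiser because ape's writer cannot carry comments; the
reader strips them, parses with ape, and re-attaches. This keeps
annotations lossless under round-trip without abusing branch lengths.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested with
known ground truth and no instrument or database access. Its defaults
describe one realistic, well-behaved study condition:

* **Kinetics** — $k_{on}$ = 6.3 µM⁻¹s⁻¹, $k_{off}$ = 2.49 s⁻¹
  ($K_d$ = 0.395 µM), receptor 1 µM, ligand 2–20 µM, unit-amplitude
  traces of 1000 points over $10/k_{obs}$ (the trace length and density
  are this package's choice; instruments vary), Gaussian noise of 1% of
  the amplitude in the standard recovery tests.
* **Denaturation** — $D_{50}$ = 4 M, $m$ = 1.23 kcal mol⁻¹ M⁻¹, urea 0 to
  8.1 M in 0.3 M steps (28 points), CD-like baselines ($\alpha_N = -11$,
  $\beta_N = 0.1$, $\alpha_D = -3$, $\beta_D = -0.05$), 10 °C.
* **ITC** — $n$ = 1, $K_d$ = 0.7 µM, $\Delta H$ = −7.5 kcal/mol, 35 µM
  cell (c = 50, comfortably identifiable), 350 µM syringe, 16 × 2.4 µL
  injections into 200 µL at 25 °C.
* **Families** — a root sequence evolves down the tree under a uniform
  20-letter replacement model (per-site substitution probability $1 -
  e^{-\mu t}$ per branch, replacement uniform over the other 19
  residues). The last six residues can be held invariant with
  probability `motif_conservation`, emulating a conserved C-terminal
  motif. Posterior tables are synthesised by rule: confident sites are
  (near-)one-hot on the true ancestral residue; a controllable fraction
  of sites with leaf-level variation get PP(ML) = 0.6 with the remainder
  spread over residues observed beneath the node in proportion to their
  frequency. With zero mutation every posterior is exactly one-hot.

Noise is homoscedastic Gaussian per experiment. Every generator is
deterministic under a fixed seed (seeds are ordinary 32-bit integers;
`simulate_kobs_series()` derives per-trace sub-seeds from the one it is
given).

What the generator deliberately does **not** emulate: instrument
artifacts (stopped-flow dead time, photobleaching, baseline drift, ITC
first-injection anomalies), heteroscedastic or correlated noise,
empirical amino-acid substitution matrices, indels, rate heterogeneity
across sites, or phylogenetic uncertainty in the tree itself. Posterior
tables are synthesised by rule, not by running phylogenetics software —
this removes the external-tool dependency while preserving exactly the
statistical feature the AltAll logic consumes (a tunable set of sub-0.8
sites). Consequently, passing recovery tests demonstrates that the
estimators are correct and well-conditioned under the stated models; it
does not certify behaviour on instrument data whose deviations from
those models (dead time, drift, intermediates, misalignment) are real
and sometimes dominant.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale by design:
kinetic series of 10 concentrations with 500–1000-point traces;
28-point denaturation curves; 16-injection isotherms; families of 4–5
leaves and 40–80 sites; 50 replicate pairs for the shared-m variance
comparison; a 625-point grid for the $k_{obs}$ oracle equivalence at
$10^{-6}$ relative. Noise-free recovery is asserted at $10^{-6}$
relative; 1%-noise recovery at 5% relative (15% for ITC $K_d$, whose
sampling error at c = 50 is intrinsically larger); identities
($K_d = k_{off}/k_{on}$, $\Delta G + T\Delta S = \Delta H$,
$\Delta G = m \cdot D_{50}$) are exact by construction and tested as
such. At 1% noise the free-fit $m$ has a sampling spread of a few
percent, so single realisations can land outside 5% — the recovery
assertions therefore run under fixed seeds, which is the honest
statement of what a single synthetic experiment shows.

## Known limitations

* Kinetic fitting covers single-exponential traces only: no
  double-exponential models, no mixing dead-time correction, no global
  fitting across trace sets.
* Thermal denaturation is out of scope (the motivating experiments could
  not determine thermal midpoints reliably); only chemical denaturation
  is modelled.
* ITC input is already-integrated injection heats; peak integration and
  baseline handling of raw thermograms belong to instrument software.
* Internal (non-C-terminal) PDZ-binding motifs are not searched for.
* Bayesian sampling of whole ancestral sequences is not implemented; the
  AltAll construct is the supported robustness check.
* The uniform replacement model in the simulator is a testing device,
  not an evolutionary model for inference.
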