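# evobind

Evolutionary biophysics of PDZ domain–ligand interactions in R.

PDZ domains are small protein-interaction modules that read the extreme
C-terminus of their partner proteins: the last residue (P0), and the third
from the end (P−2), define the canonical binding-motif classes
(type I: T/S‑X‑Φ, type II: Φ‑X‑Φ, type III: D/E‑X‑Φ, with Φ a large
hydrophobic residue). Studies that resurrect ancestral versions of a PDZ
domain and its peptide ligand follow a standard arc: reconstruct ancestral
sequences at internal nodes of a species tree, build worst-case "AltAll"
variants to bound reconstruction uncertainty, classify how the C-terminal
motif changed along the tree, then express the proteins and measure
binding kinetics (stopped-flow), thermodynamic stability (urea
denaturation) and binding thermodynamics (ITC) for each node.

evobind implements the computational side of that arc as a tidyverse-style
R package: every user-facing function takes a data frame (or a tagged
experiment table) and fitted objects support `tidy()`, `glance()` and
`autoplot()`. A synthetic-data generator with known ground truth stands in
for instrument data, so the whole pipeline is testable end to end.

## The models

**Binding kinetics.** For A + B ⇌ C with association rate constant
k<sub>on</sub> (µM⁻¹s⁻¹) and dissociation rate constant k<sub>off</sub>
(s⁻¹), a stopped-flow trace relaxes as a single exponential with observed
rate

> k<sub>obs</sub> = √( k<sub>on</sub>²(A₀ − B₀)² + k<sub>off</sub>² + 2 k<sub>on</sub>k<sub>off</sub>(A₀ + B₀) )

the exact closed form for a reversible bimolecular reaction — no
pseudo-first-order approximation, so the receptor concentration need not
be negligible. Traces are fitted per concentration
(`fit_trace()`), the k<sub>obs</sub>-vs-concentration series is fitted for
(k<sub>on</sub>, k<sub>off</sub>) (`fit_binding_curve()`), displacement
experiments give k<sub>off</sub> directly (`displacement_koff()`), and
K<sub>d</sub> = k<sub>off</sub>/k<sub>on</sub> (`kd_from_rates()`).

**Equilibrium stability.** Urea denaturation curves follow the two-state
model with linear baselines,

> F(u) = [(α<sub>N</sub> + β<sub>N</sub>u) + (α<sub>D</sub> + β<sub>D</sub>u)·e<sup>m(u−D₅₀)/RT</sup>] / [1 + e<sup>m(u−D₅₀)/RT</sup>]

with stability ΔG = m·[Urea]₅₀ (linear extrapolation). Curves can be
fitted freely (`fit_denaturation()`) or jointly with a shared m-value per
user-defined group (`fit_global_shared_m()`), the standard remedy when a
short denatured baseline pins m poorly.

**ITC.** One-site isotherms are fitted for stoichiometry n, K<sub>d</sub>
and ΔH plus a constant heat-of-dilution offset (`fit_itc()`), with
ΔG = RT·ln K<sub>d</sub> and TΔS = ΔH − ΔG (`derive_entropy()`); the
closure ΔG + TΔS = ΔH holds exactly in every emitted result.

**Ancestral sequences.** Per-node posterior-probability tables (TSV, one
row per site, 20 amino-acid columns) post-process into the ML sequence
(`ml_sequence()`), the AltAll worst-case variant — second-best residue at
every site with PP(ML) < 0.8 (`altall_sequence()`) — confidence summaries
(`pp_summary()`) and identity/similarity percentages
(`identity_similarity()`). `classify_pbm()` and `annotate_tree_motifs()`
map motif classes and their transitions onto a tree; `build_report()`
assembles everything into an annotated newick plus a consolidated table.

## Worked example

Simulate a stopped-flow binding-curve experiment at the human PDZ3:CRIPT
rate constants (k_on = 6.3 µM⁻¹s⁻¹, k_off = 2.49 s⁻¹; 1 µM receptor,
ligand 2–20 µM, 1% trace noise) and refit it:

```r
library(evobind)

series <- simulate_kobs_series(k_on = 6.3, k_off = 2.49, A0 = 1,
                               B0 = seq(2, 20, 2), noise_sd = 0.01, seed = 42)
fit_binding_curve(series, A0 = 1)
#> <kinetic fit (binding_curve)>
#>   k_on  = 6.32 +/- 0.015 uM^-1 s^-1
#>   k_off = 2.45 +/- 0.13 s^-1
#>   K_d   = 0.388 +/- 0.021 uM
```

The fit recovers the true rates within their standard errors and the
derived K_d (0.39 µM) is the sub-micromolar affinity typical of a type I
PDZ:peptide pair. Thermodynamics of the same interaction from ITC
parameters (ΔH = −7.5 kcal/mol, K_d = 0.7 µM, 25 °C):

```r
derive_entropy(-7.5, 0.7)
#> # A tibble: 1 × 2
#>      dG   TdS
#>   <dbl> <dbl>
#> 1 -8.40 0.897
```

so binding is enthalpy-driven with a small favourable entropy. Motif
classification works straight from C-terminal sequence:

```r
classify_pbm(c(human = "YKQTSV", fly = "YRQSST", nematode = "KKLKMSAV"))
#> # A tibble: 3 × 6
#>   id       c_terminal p0    p_minus1 p_minus2 motif_class
#> 1 human    TSV        V     S        T        type_I
#> 2 fly      SST        T     S        S        undefined
#> 3 nematode SAV        V     A        S        type_I
```

— the fly peptide ends in Thr, which cannot occupy the hydrophobic P0
pocket, so it carries no canonical motif despite differing from the human
peptide at a single position.

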