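---
title: "Characterizing G-quadruplex DNA and its ligand complexes with g4char"
author: "g4char authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing G-quadruplex DNA and its ligand complexes with g4char}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4char)
```

`g4char` implements the standard in-vitro evidence chain for a promoter
G-quadruplex (G4): a sequence that *can* fold (motif scan), a complex that
*does* exist in the gas phase (native ESI-MS), a topology (CD band rule),
and a stability gain upon ligand binding (melting thermodynamics). This
vignette documents the models behind each stage, the tunable parameters
and their defaults, what the synthetic-data generators do and do not
emulate, and the numerical choices that matter.

## Motif scanning

A putative intramolecular G4 motif is a chain of at least four G-tracts
(maximal runs of ≥ `min_tract` guanines, default 3) whose intervening
loops are `loop_min`–`loop_max` nucleotides long (defaults 1 and 7).
Coordinates are 0-based, half-open, and only the given strand is scanned;
reverse-complement (C-tract) scanning amounts to scanning the
reverse complement with the same function.

Two design points deserve emphasis:

* **Tracts are maximal G-runs and are never split.** A run of seven Gs is
  one tract, not a 3-G tract plus a 1-G loop plus a 3-G tract. Regex-style
  scanners that allow splitting enumerate alternative decompositions of
  the same G-rich stretch; for characterizing a single candidate locus the
  maximal-run reading is the appropriate one, and it is what the tract/loop
  report and the tetrad-layer prediction are defined on. The test suite
  carries both an independent maximal-run oracle (exact agreement) and the
  regex form `G{3,}([ACGT]{1,7}G{3,}){3,}` (every reported motif must
  match it).
* **Loop bounds are a convention.** The 1–7 nt default is the common
  putative-quadruplex rule; any reasonable bound admits the 1–2 nt loops
  of the relaxin-promoter motif this package was validated on.

`predicted_tetrad_layers()` encodes the structural reading of the motif:
the quadruplex stacks as many G-tetrad layers as the shortest tract is
long, and monovalent cations occupy the `layers − 1` sites between
adjacent layers. This is the number to compare against the ammonium count
retained in native MS ions.

## Oligonucleotide masses and ion species

Neutral masses are accumulated from a built-in elemental-composition
table of phosphodiester residues (nucleoside monophosphate minus water)
plus one water, in either average (default) or monoisotopic mode. This
bookkeeping makes the mass exactly additive under concatenation
(`mass(ab) = mass(a) + mass(b) − mass(H2O)`), which the assignment
arithmetic relies on; it corresponds to an oligonucleotide carrying one
phosphate per residue. Synthetic oligos are usually 5′-OH and lighter by
one HPO3 (79.98 Da); because observed instrument m/z values are treated
as calibrated observations rather than exactness anchors (see below),
this convention does not affect any assignment at the default tolerance
relative to a consistent candidate set.

Negative-mode electrospray of a folded G4 retains interlayer ammonium
ions and any bound ligand cations. The ion convention is

\[ m/z = \frac{M + a\,m(\mathrm{NH_4}) + b\,M_L - (z+a+b)\,m(\mathrm{H})}{z} \]

i.e. every retained cation displaces one additional proton so the net
charge is −z — the only bookkeeping consistent with ion labels of the
form [DNA + 2NH4 − 6H]^4−. The built-in ligand table currently holds
berberine (average cation mass 336.4 Da); any other ligand is supplied
by numeric mass.

**Printed instrument m/z values are observations, not oracles.** Reported
peak positions from ion-trap spectra carry the instrument's calibration;
they are not reproduced by adduct arithmetic to better than the peak
width, and the package deliberately does not force agreement. Assignment
uses a configurable tolerance, default 1.0 Th — roughly half a peak width
for a broad 4− ion-trap peak.

## Peak assignment and the IRa statistic

`assign_peaks()` performs greedy nearest-match assignment: all
candidate–peak pairs within the tolerance are ranked by |m/z error| (ties
broken toward smaller ligand count, preferring the more parsimonious
species), and accepted one at a time so that each peak claims at most one
species and vice versa. For well-separated synthetic spectra this is
identical to exhaustive matching; the tests verify it against a
brute-force oracle.

The relative binding-affinity statistic pools assigned intensities by
ligand stoichiometry b over all charge states and ammonium counts:

\[ IR_a = \frac{\sum I(G\!+\!P) + \sum I(G\!+\!2P) + \sum I(G\!+\!3P)}
               {\sum I(G) + \sum I(G\!+\!P) + \sum I(G\!+\!2P) + \sum I(G\!+\!3P)} \]

IRa lies in [0, 1], increases in any complex intensity, decreases in the
free-species intensity, and is reported to 2 decimals by default.
Relative intensities are percent of the base peak, so IRa is independent
of absolute ion current. Pooling across charge states follows the
summation notation the statistic is defined with; it assumes comparable
response factors across charge states, which is the usual working
assumption for relative statements at fixed instrument settings.

## CD topology

The classification rule is the classical band-position heuristic:
parallel quadruplexes show a positive maximum near 264 nm (with a
negative band near 242 nm), antiparallel ones near 295 nm. The spectrum
is smoothed with a centered moving average (default 5 points), extrema
are read off the grid, and the call is made on the global positive
maximum with a ± `window` tolerance, default ± 6 nm. The window was
chosen so that spectra peaking at 264 nm classify as parallel while a
272 nm maximum — the signature of a non-G4 conformation observed for
G→T mutants — falls outside both windows and is called `"other"`.
Spectra with dual 264/295 character (hybrid topologies) are likewise
reported as `"other"` with both evidence wavelengths, because a
band-position rule alone cannot adjudicate hybrids. Classification is
invariant under uniform positive scaling; it is **not** a substitute for
NMR or crystallography.

## Melting thermodynamics

### Model

For an intramolecular two-state transition the folding equilibrium
constant is concentration-independent, \(K = \theta/(1-\theta)\) with
\(\theta\) the fraction folded, and van't Hoff's relation gives
\(\ln K = -\Delta H/(RT) + \Delta S/R\) (R = 8.314 J mol⁻¹ K⁻¹).
`vant_hoff_fit()` regresses ln K on 1/T over the points with
\(\theta \in [0.15, 0.85]\) (default band): the slope yields ΔH, the
intercept ΔS, and Tm is the ln K = 0 crossing of the regression,
Tm = ΔH/ΔS in kelvin. The band restriction is standard practice: outside
it, ln K diverges and is dominated by baseline error. The raw θ = 0.5
crossing is also reported in the diagnostics, together with a warning if
θ is not monotone inside the band. Temperatures are kelvin internally;
reports use °C and kJ/mol (67 °C ≡ 340.15 K).

The fit is returned as a classed model object with the usual methods
(`coef`, `predict`, `residuals`, `plot`, `summary`, `simulate`), and
`thermo_params()` wraps externally published (ΔH, ΔS, Tm) values in the
same interface so that `gibbs()` (ΔG = ΔH − TΔS) and `stabilization()`
(component-wise bound − free differences, ΔG differenced at full
precision before rounding) work on either source.
`intramolecularity_check()` compares fitted Tm across strand
concentrations (default tolerance 1 °C): a concentration-independent Tm
is the operational justification for the intramolecular model.

### Normalization

`normalize_curve()` converts signal to fraction folded with linear folded
and unfolded baselines,
\(\theta(T) = (b_{up}(T) - y(T)) / (b_{up}(T) - b_{lo}(T))\), oriented so
θ → 1 at low temperature regardless of the transition's sign. Baselines
are initialized by linear fits in a low- and a high-temperature window
(defaults: the outer 15% of the span each) — and then, by default,
refined by a global Levenberg–Marquardt fit of the complete curve model
(two linear baselines plus the two-state sigmoid, analytic Jacobian).
The refinement matters quantitatively: a transition with ΔH ≈
−200 kJ/mol decays only exponentially, so even the outermost windows of
a 20–95 °C scan contain 0.5–3% residual transition, and window-only
baselines bias Tm by several tenths of a degree and ΔH by several
percent. With refinement, noiseless synthetic curves are recovered to
better than 10⁻⁹ in θ. `refine = FALSE` restores the window-only
behaviour; if the global fit does not converge the function falls back
to it with a warning. A curve whose two baselines coincide within noise
(e.g. a straight line) raises a no-transition error rather than
returning meaningless θ.

### Units in published thermodynamic tables

Published van't Hoff tables for G4 melting are sometimes on a scale far
smaller than the −100 to −400 kJ/mol enthalpies that sharp three-tetrad
transitions imply; such values cannot regenerate a realistic sigmoid.
The package therefore treats externally supplied (ΔH, ΔS) pairs purely
as arithmetic inputs to `gibbs()`/`stabilization()` — the identity
ΔG = ΔH − TΔS holds on any scale — while the melting generator uses its
own physically plausible enthalpy (below). Sign conventions (folding vs
unfolding direction) are likewise left as supplied.

## Synthetic data

The generators are pure functions of their parameters and seed and attach
a `truth` attribute with every generating parameter, so each downstream
analysis is a parameter-recovery exercise.

* `gen_melting_curve()` — two-state θ(T) with linear baselines and
  optional Gaussian noise (sd = `noise_sd` × transition amplitude).
  Presets encode the three measured buffer conditions: `"KCl-free"`
  Tm = 67 °C, `"KCl-berberine"` Tm = 77 °C (both on a 20–95 °C grid) and
  `"LiCl-free"` Tm = 37 °C (10–75 °C grid, bracketing the lower Tm), all
  at 0.5 °C steps. The generator enthalpy is −200 kJ/mol — a typical
  sharp three-tetrad intramolecular transition — and baseline slopes are
  gentle (−0.012 and −0.004 signal/°C).
* `gen_ms_spectrum()` — Gaussian peak profiles (default FWHM 0.6 Th) at
  the theoretical m/z of the requested species, centroided back to a
  peak list, with optional sub-threshold noise peaks. Species closer
  than one FWHM merge, with a warning.
* `gen_cd_spectrum()` — sums of Gaussian bands on a 220–320 nm grid
  (0.5 nm step): +264/−242 nm (parallel), +295/−265 nm (antiparallel),
  +272 nm only (the mutant-like non-G4 control).

What the generators do **not** emulate: instrument drift and shot noise,
isotopologue fine structure and charge-state envelopes beyond those
requested, CD baseline offsets, or non-two-state (multi-state, kinetic)
melting. Passing recovery tests on this synthetic data therefore
demonstrates the correctness of the analysis pipeline under its own
model assumptions — not robustness to every pathology of real
instrument data.

## Problem sizes and reproducibility

All validation runs are small by design: melting grids of 110–151 points,
CD grids of 201 points, spectra of a handful of peaks, 25 replicate seeds
for noisy-recovery checks, and a (Tm, ΔH) recovery grid spanning
40–85 °C × −100 to −400 kJ/mol. Everything completes in seconds.
`run_characterization()` echoes its config and seeds into the JSON
report, and identical inputs reproduce every numeric field exactly.

## Known limitations

* The motif scanner targets single candidate loci; it makes no attempt at
  genome-scale performance and computes no propensity score.
* Peak assignment assumes a resolved, centroided peak list; overlapping
  charge envelopes are not deconvolved.
* IRa is a relative-affinity statistic, not a dissociation constant; no
  titration fitting is provided.
* The melting model is strictly two-state and intramolecular, without a
  heat-capacity (ΔCp) term; curves that violate these assumptions will
  fit, but the diagnostics (R², monotonicity warning, raw vs fitted Tm)
  should be inspected.
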