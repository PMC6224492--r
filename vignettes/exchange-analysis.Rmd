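---
title: "Quantifying slow conformational exchange: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying slow conformational exchange: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrexchange)
```

## The problem this package models

A ligand-binding domain that interconverts slowly between two long-lived
conformations produces *doubled* NMR peaks: when the difference in
resonance frequency between the states (Δν, in Hz) is much larger than
the interconversion rate k~ex~, each conformer contributes its own peak,
with area proportional to its population. This package implements the
quantitative toolbox for that regime, motivated by inverse-agonist-bound
nuclear-receptor pharmacology (where the two conformations of the AF-2
coregulator surface have opposite corepressor/coactivator preferences):

1. **ZZ-exchange (EXSY) kinetics** — extract k~ex~, the microscopic
   rates, populations, and R~1~ from auto-/cross-peak build-up curves.
2. **Bloch–McConnell lineshape simulation and titration fitting** —
   forward-model 1D exchange-broadened spectra under coupled
   binding–isomerization schemes and fit observed titration series,
   selecting among 2-, 3-, and 4-state topologies.
3. **¹⁹F spectral deconvolution** — area-fraction populations from
   two-component helix-12 probe spectra.
4. **Hydrogen-bond occupancy** — direct and water-bridged interaction
   fractions across multi-frame coordinate sets.
5. **Synthetic-data generation** — every input above with known ground
   truth, so the full pipeline is testable without raw spectra.

## Exchange models

### Kinetic schemes

A scheme is a set of states (label, role, chemical shift, R~1~, R~2~)
plus directed rate-law edges. Isomerization edges carry first-order
rates (s⁻¹); binding edges carry association rate constants (M⁻¹s⁻¹)
that are multiplied by the free-ligand concentration when the generator
matrix is built — the pseudo-first-order treatment. The supported
topologies are:

* `TWO_SITE_ISO`: A ⇌ B (free receptor only; the ZZ-exchange case);
* `U`: R + P ⇌ RP (two-state binding);
* `U_RL`: R + P ⇌ RP ⇌ R\*P (binding then bound-state isomerization);
* `U_R_RL`: R ⇌ R\*, both bind P, RP ⇌ R\*P (the full four-state
  cycle).

For `U_R_RL` the eight rate constants traverse a thermodynamic cycle
whose equilibrium constants must multiply to 1. Rather than asking the
user for a redundant (and unidentifiable) eighth constant,
`scheme_u_r_rl()` computes the reverse bound-isomerization rate from the
other seven, so cycle closure holds by construction; assembling raw
edges that violate closure by more than 10⁻⁶ is rejected.

Binding is treated as pseudo-first-order with the free-ligand
concentration taken from the equilibrium solve at each titration point.
Titration spectra are equilibrium-series data, so nothing is lost by not
propagating full second-order kinetics, and the lineshape operator stays
linear.

The equilibrium composition itself is found by root-finding on the
peptide mass balance: the ligand partition function is monotone in the
free-ligand concentration, so Brent bracketing on [0, P~tot~] followed
by a Newton polish converges to a relative mass-balance residual below
10⁻⁹ (the tests compare against an independent oracle that builds
species from products of equilibrium constants and bisects).

### Lineshape

For state frequencies ν~j~ (from ppm via the spectrometer context),
transverse rates R~2,j~ and exchange generator K, the spectrum is

$$S(\omega) = \mathrm{Re}\left[\mathbf{1}^{T} (i\omega I - \Lambda)^{-1} M_0\right],
\qquad \Lambda = 2\pi i\,\mathrm{diag}(\nu_j) - \mathrm{diag}(R_{2,j}) + K,$$

with M~0~ proportional to the state populations. This is evaluated by a
single eigendecomposition of Λ and a rational sum over the axis, which
is exact (no time-domain discretization); the test suite checks it
against an independent time-domain route (stepwise matrix-exponential
FID propagation plus discrete Fourier transform) to 0.5%.

Useful limits the implementation reproduces: a lone state is a
Lorentzian of full width R~2~/π Hz; in slow exchange the component
areas equal the populations; in fast exchange one peak appears at the
population-weighted shift. For symmetric two-site exchange the two
maxima merge at the classic coalescence point — note the convention:
the textbook rate πΔν/√2 is the *per-site jump rate* k = k~AB~ = k~BA~,
i.e. k~ex~ = k~AB~ + k~BA~ = √2·πΔν. The package states rates as k~ex~
throughout, so the transition sits at √2·πΔν in those units (verified
numerically on a dense grid).

ppm↔Hz conversion always goes through an explicit
`spectrometer_context()`; at the default 700 MHz field the derived base
frequencies are ≈70.96 MHz (¹⁵N) and ≈658.7 MHz (¹⁹F). Contexts are
never inferred from data.

### ZZ exchange

During the mixing delay the magnetization evolves longitudinally,

$$M(T) = e^{(K - R_1)T} M(0),$$

giving auto peaks from the diagonal propagator entries and cross peaks
from the off-diagonal ones. For equal R~1~ this reduces to the familiar
closed forms (e.g. I~AB~(T) = p~A~p~B~(1 − e^(−k~ex~T))e^(−R₁T)·A);
the matrix-exponential route and the closed form agree to 10⁻¹⁰ across
1000 random parameter draws in the tests.

`fit_zz()` fits all four curves simultaneously by weighted least
squares with log-parameterized rates. Two design choices matter:

* **R~1~ is shared between states by default** (`share_r1 = FALSE`
  fits per-state values). The two-state interconversion fits this
  package targets do not resolve separate R~1~ values at typical
  signal-to-noise.
* **Starting magnetizations are two free amplitudes**, not pinned to
  the equilibrium populations, because receiver scaling between
  experiments is arbitrary. Populations therefore come from the fitted
  rates via detailed balance (p~A~ = k~BA~/k~ex~), and the amplitude
  fraction is reported alongside as a consistency check.

`zz_detectability()` answers whether exchange is measurable at all: the
maximum cross-peak intensity over the delay range, relative to the
larger zero-mixing auto peak, must exceed a threshold (default 5%).
With k~ex~ ≈ 2 s⁻¹ and R~1~ ≈ 1.5 s⁻¹ cross peaks rise well above
this; at k~ex~ < 0.2 s⁻¹ they never do within a 0–2 s mixing range —
the quantitative form of "visible at elevated temperature, invisible at
room temperature".

On rate-label conventions: the package defines p~A~ = k~BA~/k~ex~
(detailed balance) and treats (p~A~, k~ex~) as the primary quantities;
per-direction rate labels in external sources do not always follow the
same convention, so downstream comparisons here use only k~ex~ and the
populations.

### Titration fitting and model selection

`fit_titration()` fits a topology's shift and kinetic parameters to all
spectra of a series simultaneously. Numerical choices:

* Rates, dissociation constants and R~2~ are fitted in log space;
  shifts in ppm.
* Each titration point carries one global intensity scale (receiver
  gain varies between points). The scale is profiled analytically at
  every objective evaluation — ĉ = ⟨y,s⟩/⟨s,s⟩ — so it never burdens
  the optimizer.
* Multi-start: the first start comes from data-driven heuristics (peak
  positions of the first and last spectra; K~d~ of the order of the
  receptor concentration), subsequent starts jitter the rate-like
  parameters on a log scale under a caller-supplied seed.
* The standard workflow pins the free-receptor isomerization rates of
  the 4-state model to the ZZ-exchange values via `fixed = list(k_ab =
  ..., k_ba = ...)` — the lineshape data alone cannot determine them.

`select_model()` ranks candidate topologies by the small-sample
corrected Akaike criterion, AICc = n·log(RSS/n) + 2k + 2k(k+1)/(n−k−1),
with k counting the free model parameters, the per-point scales, and
the residual variance. AICc was chosen over plain AIC because titration
series are short, and over likelihood-ratio testing because the
candidate set mixes nested and non-nested pairs. Exact ties go to the
smaller model.

## ¹⁹F deconvolution

Components are pseudo-Voigt profiles — a linear Gaussian/Lorentzian mix
with per-component mixing fraction — which is the standard flexible
model for processed 1D peaks when the true profile is unknown. The
baseline defaults to a constant and can be raised to a quadratic.
Populations are **area** fractions, not height fractions, because the
two conformational states need not share a linewidth.

Initial centers default to the n tallest local maxima after 3-point
smoothing, with ties broken toward downfield and an exclusion zone of
1/20 of the axis span so noise wiggles on one peak cannot supply two
starting centers. Fits are box-bounded (centers on-axis, widths between
two grid steps and the axis span); fitted components whose centers end
up closer than 0.05 of their width trigger an error suggesting fewer
components rather than returning a degenerate split.

Axis calibration against an internal reference (`calibrate_axis()`) is
a uniform shift, exactly invertible, and population estimates are
invariant to it and to intensity scaling.

## Hydrogen-bond geometry

A donor–H–acceptor triplet counts as a hydrogen bond when the
heavy-donor-to-acceptor distance is ≤ 3.5 Å and the D–H–A angle is
≥ 100° — the defaults of the common trajectory-analysis convention.
Two points deserve emphasis:

* The distance cutoff is **heavy-atom to heavy-atom**, not
  hydrogen-to-acceptor. Analysis tools differ here; this package adopts
  the heavy–heavy convention and exposes both thresholds in
  `hbond_criteria()`.
* Donors and acceptors are classified by element plus hydrogen
  connectivity (N/O with an H within 1.2 Å donates; any N/O accepts),
  rather than by residue-name lookup, so covalently modified ligand
  adducts and nonstandard residues are handled uniformly.

A water bridge exists when one water satisfies the criteria with both
solute partners simultaneously (either side may donate); several waters
may bridge the same pair in one frame, but occupancy counts the frame
once. Occupancy is a per-frame existence fraction and is by
construction invariant to frame order and rigid-body motion, and
monotone in the two thresholds — all properties the suite checks
against a brute-force all-triplet oracle.

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed, and
returns the generating truth alongside the artifact. They emulate:

* ZZ build-up curves with additive Gaussian intensity noise (the
  thermal-noise model appropriate for processed spectra);
* titration series under any binding topology, noise scaled to the
  tallest peak of the series;
* 1D multi-component spectra for deconvolution;
* toy multi-MODEL coordinate frames with hydrogen bonds and water
  bridges planted on an exact schedule, and adjustable planted geometry
  for probing the criteria boundaries.

They deliberately do **not** emulate raw time-domain acquisition
artifacts (phase errors, baseline roll, apodization), peak overlap with
unrelated resonances, temperature-dependent shift drift, or genuine
molecular-dynamics physics. Passing recovery tests therefore
demonstrates the correctness of the estimators under the stated noise
model — not robustness to every pathology of real data.

### Fixed study conditions

Where the emulated study prints values, the generators default to them:
two-state kinetics with p~A~ = 0.37 and k~ex~ = 2.1 s⁻¹ (hence
k~AB~ = 1.323, k~BA~ = 0.777 s⁻¹), R~1~ = 1.5 s⁻¹, mixing delays
{0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.2, 1.6, 2.0} s, receptor total 200 µM,
¹⁹F population pairs 78/22 and 66/34. Values the study does not print
are fixed here once, as conventions rather than claims: ¹⁵N state
shifts 109.0/110.0 ppm (Δδ = 1.0 ppm ≈ 71 Hz at 70.96 MHz, safely slow
exchange against k~ex~ = 2.1 s⁻¹, Δν ≥ 10·k~ex~), ¹⁹F component
centers −116.5/−115.5 ppm with FWHM 0.1 ppm (10 linewidths apart), and
a ¹H/¹⁵N assignment-transfer weight of 0.2 on the nitrogen shift.

The titration fixtures encode the two qualitative regimes: a four-state
corepressor-like scheme with the free-receptor isomerization pinned to
the ZZ kinetics and a 10× higher affinity for the B conformation, and a
two-state coactivator-like scheme with weaker (20 µM) affinity.

### Problem sizes in the shipped tests

The recovery studies run at sizes chosen to exercise the estimators
while keeping the suite quick to iterate on: 128-point axes and
five-point ratio series for the model-selection replicates (20 seeded
replicates per topology at 2% noise), 300 replicates for the ZZ
Monte-Carlo calibration, 200 for the deconvolution error study, and
1000 random draws for the closed-form equivalence property.

## Known limitations

* Lineshape fitting is 1D; full 2D fitting and TROSY-specific
  corrections are out of scope.
* Binding kinetics are pseudo-first-order; strongly second-order
  regimes (sub-stoichiometric, sub-K~d~ concentrations with fast
  association) are outside the model.
* At most two conformers per ligation state; three-site ZZ exchange is
  not modeled.
* The component count in deconvolution is user-specified; there is no
  automated selection.
* AICc-based topology selection inherits the usual caveat that an
  over-parameterized nested model occasionally wins on noisy data; the
  replicate tests quantify that rate under the shipped conditions
  rather than hiding it.
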