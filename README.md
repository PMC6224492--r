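# nmrexchange

Quantitative analysis of **slow conformational exchange** in protein
NMR, built for the regime where a receptor interconverts between two
long-lived conformations and every observable doubles: peaks, binding
preferences, and populations. The motivating system is a
nuclear-receptor ligand-binding domain whose inverse-agonist-bound
ensemble toggles between a corepressor-selective and a
coactivator-like conformation of the AF-2 surface, but every tool here
is generic to two-state slow exchange.

The package is tidyverse-native: data frames in, tibbles out, fitted
objects with `tidy()` / `glance()` methods and `autoplot()` figures.

## What it computes

**ZZ-exchange (EXSY) kinetics.** Longitudinal mixing transfers
magnetization between slowly interconverting states; auto- and
cross-peak build-up curves follow

```
M(T) = exp((K − R1) T) · M(0),      K = [−k_AB  k_BA; k_AB  −k_BA]
```

`fit_zz()` fits all four curves at once and reports
`k_ex = k_AB + k_BA`, the populations `p_A = k_BA / k_ex`,
`p_B = 1 − p_A` (detailed balance), and R1. `zz_detectability()` tells
you whether cross peaks can rise above a threshold at all for given
kinetics and delays.

**Exchange-broadened lineshapes.** For any binding–isomerization
scheme (2-state `U`, 3-state `U_RL`, 4-state `U_R_RL`, or pure
two-site isomerization) the 1D spectrum is the Bloch–McConnell
steady-state

```
S(ω) = Re[ 1ᵀ (iωI − Λ)⁻¹ M₀ ],   Λ = 2πi·diag(ν_j) − diag(R2_j) + K
```

`simulate_titration()` forward-models a peptide titration (equilibrium
compositions from `solve_binding_equilibrium()`), `fit_titration()`
fits a series under a chosen topology with any parameters pinned
(e.g. free-receptor isomerization rates from the ZZ fit), and
`select_model()` ranks topologies by corrected AIC.

**¹⁹F deconvolution.** `deconvolve()` decomposes a 1D spectrum into
pseudo-Voigt components plus baseline and reports conformational
populations as area fractions; `calibrate_axis()` pins the axis to an
internal reference signal.

**Hydrogen-bond occupancy.** `read_frames()` /`gen_frames()` +
`occupancy()` count direct and water-bridged hydrogen bonds across
multi-MODEL coordinate frames with the standard geometric criteria
(heavy-donor–acceptor distance ≤ 3.5 Å, D–H–A angle ≥ 100°).

**Synthetic data.** `gen_zz()`, `gen_titration()`, `gen_spectrum()`,
`gen_frames()` generate every input with known ground truth and a
seed, so the full pipeline is testable end to end.

## Worked example

Fit noisy ZZ-exchange build-up curves, deconvolve a two-component ¹⁹F
spectrum, and cross-compare the populations the two experiments see:

```r
library(nmrexchange)

z   <- gen_zz(g399_kinetics(), r1 = 1.5, noise_sd = 0.01, seed = 7)
fit <- fit_zz(z$data)
fit
#> ZZ-exchange two-state fit
#> Two-site exchange: k_ex = 2.246 /s  (k_ab = 1.43, k_ba = 0.8161)
#>   populations: p_a = 0.3634, p_b = 0.6366
#>   R1 = 1.496 /s;  RSS = 26.9;  converged: TRUE
#>   amplitude fraction A = 0.363 (cross-check vs p_a = 0.363)

sp  <- gen_spectrum(f19_components(c(0.66, 0.34)), context_19f(),
                    noise_sd = 0.01, seed = 7)
dec <- deconvolve(sp$spectrum, 2)
tidy(dec)[, c("center", "fwhm", "population")]
#> # A tibble: 2 × 3
#>   center   fwhm population
#>    <dbl>  <dbl>      <dbl>
#> 1  -117. 0.0992      0.660
#> 2  -115. 0.0995      0.340

compare_populations(fit, dec)
#> # A tibble: 2 × 4
#>   state zz_percent deconv_percent difference_points
#>   <chr>      <dbl>          <dbl>             <dbl>
#> 1 minor       36.3           34.0              2.38
#> 2 major       63.7           66.0              2.38
```

Reading: the ZZ fit recovers an exchange rate of ~2.2 s⁻¹ and a
36/64 population split from 1%-noise data generated at k_ex = 2.1 s⁻¹
and 37/63; the fitted amplitude fraction independently agrees with the
rate-derived p_A. The ¹⁹F deconvolution sees a 34/66 split on the
helix-12 probe, and `compare_populations()` lines the minor/major
states up and reports the difference in percentage points — the
quantitative form of "the two probes see the same two-state ensemble".

Titration analysis follows the same pattern:

```r
kin <- g399_kinetics()
g   <- gen_titration(t007_ncor1_scheme(), context = context_15n(),
                     noise_sd = 0.02, seed = 1)
sel <- select_model(g$series,
                    candidates = c("U", "U_RL", "U_R_RL"),
                    fixed = list(U      = list(r2 = 25),
                                 U_RL   = list(r2 = 25),
                                 U_R_RL = list(r2 = 25, k_ab = kin$k_ab,
                                               k_ba = kin$k_ba)))
sel[, c("topology", "n_par", "rss", "aicc", "delta_aicc", "rank")]
```

which ranks the four-state model (both free conformations bind, with
isomerization in free and bound states) first on data generated under
it, with the free-receptor rates held at the ZZ values.

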