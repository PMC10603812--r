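---
title: "Mean-field crowding thermodynamics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field crowding thermodynamics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdfh)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open and a choice had to be
made.

## The physical picture

Added sugars and polyols shift a two-state folding equilibrium
D &#8652; N. Three distinct physical effects contribute, and the model
keeps them separate by construction:

1. **Excluded volume.** A cosolute of partial molar volume
   $\bar V_C = \nu \bar V_S$ cannot approach the protein surface closer
   than roughly half its size; folding buries surface area $\Delta SASA$
   together with its sterically cosolute-free depletion shell, recovering
   osmotic work $-\Pi\,\Delta SASA\,\delta$. This is the depletion
   (Asakura–Oosawa) picture and is always stabilizing for $\nu > 1$.
2. **Nonideal mixing.** The surface layer generally holds cosolute at a
   volume fraction $\phi_s \ne \phi_b$. Folding remixes that layer into
   the bulk; for an unfavorably mixing pair ($\chi > 0$) this costs
   $N\,RT\,\chi\,(\phi_s-\phi_b)^2$ and is destabilizing — quadratic in
   the composition difference, hence growing steeply for large, strongly
   excluded cosolutes.
3. **Soft interactions.** Replacing a protein–water contact by a
   protein–cosolute contact carries a free energy $\varepsilon$ (kT per
   solvent-sized site). Folding releases $N = \Delta SASA/d_s^2$ sites,
   contributing $-N\,RT\,\varepsilon\,\phi_s$: repulsive contacts
   ($\varepsilon > 0$) add stabilization, attractive ones destabilize.
   This term is what differs between proteins exposed to the *same*
   sugar, and its enthalpy/entropy split
   $\varepsilon = \varepsilon_H - \varepsilon_{TS}$ encodes the mechanism
   (water release entropy versus hydrogen-bond enthalpy).

The surface composition solves the exchange equilibrium
$\hat\mu(\phi_s) + \nu\varepsilon = \hat\mu(\phi_b)$ with
$\hat\mu(\phi) = \ln\phi - \nu\ln(1-\phi) + (1-\nu) +
\chi\nu\big[(1-\phi)^2-\phi^2\big]$, the cost of swapping $\nu$ solvent
molecules for one cosolute on the lattice. A cosolute at the surface pays
$\varepsilon$ on each of the $\nu$ sites it covers, which is what couples
cosolute size to the strength of soft exclusion or inclusion.

### Assumptions

- Strict two-state folding (supported in data by an invariant isodichroic
  point; `isodichroic_locate()` quantifies this).
- Partial molar volumes and $\Delta SASA$ are concentration- and
  temperature-independent constants; temperature enters only through the
  explicit $RT$ factors, $\chi(T) = a + b/T$ and
  $\varepsilon(T) = \varepsilon_h T_0/T + \varepsilon_s$.
- The depletion shell is a flat slab of thickness
  $\delta = (d_s/2)(\nu^{1/3}-1)$: no curvature corrections, no
  multi-cosolute mixtures.
- $\Delta C_P$ of folding is constant over the analyzed temperature range.

## Parameters, units, defaults

| Parameter | Meaning | Units | Default / source |
|---|---|---|---|
| $\bar V_S$ | water partial molar volume | cm³/mol | 18.07 |
| $\nu$ | cosolute/water size ratio | — | fitted from density |
| $\chi(T)=a+b/T$ | nonideal mixing | — (b in K) | fitted from water activity |
| $\varepsilon$ | per-contact replacement free energy at $T_0$ | kT | fitted from $\Delta\Delta G^0(c)$, bounds $[-10, 10]$ |
| $\varepsilon_{TS}$ | entropic part of $\varepsilon$ | kT | fitted from $\Delta\Delta H^0$, $T\Delta\Delta S^0$ |
| $\Delta SASA$ | area buried upon folding | Å² | required input (1000 for the default synthetic miniprotein) |
| $d_s$ | lattice site edge | Å | $(\bar V_S/N_A)^{1/3} \approx 3.107$; exposed as a knob since a fitted per-site area is equally defensible |
| $T_0$ | reference temperature | K | 298 |

The stored split conventions are exact identities:
$\chi_H(T) = b/T$, $\chi_{TS} = -a$, so $\chi = \chi_H - \chi_{TS}$
holds term by term, and likewise
$\varepsilon_H(T_0) = \varepsilon_h$, $\varepsilon_{TS}(T_0) =
-\varepsilon_s$ with $\varepsilon(T_0) = \varepsilon_h + \varepsilon_s$.
When `fit_epsilon_ts()` proposes a candidate $\varepsilon_{TS}$ it sets
$\varepsilon_s = -\varepsilon_{TS}$ and
$\varepsilon_h = \varepsilon + \varepsilon_{TS}$, which preserves the
already-fitted $\varepsilon(T_0)$ exactly for every candidate — the
enthalpy–entropy fit can never degrade the free-energy fit.

## What the synthetic generator emulates — and what it does not

`ground_truth()` defaults describe a trehalose-like disaccharide
($M_C = 342.3$ g/mol, $\bar V_C = 209.5$ cm³/mol so $\nu \approx 11.6$;
$\chi(298) \approx 0.60$ with entropically unfavorable mixing,
$\chi_{TS} = -1.2 < 0$, $\chi_H < 0$) acting on a marginally stable
16-residue-scale protein ($\Delta G^0(298) \approx -4$ kJ/mol from
$\Delta H^0 = -10$ kJ/mol, $\Delta S^0 = -20$ J/mol/K,
$\Delta C_P = -150$ J/mol/K) with weak per-contact repulsion
$\varepsilon = 0.05$ and a compensating split $\varepsilon_{TS} = 1$
(both $\varepsilon_H$ and $\varepsilon_{TS}$ positive). With these values
the model yields monotone stabilization to 1.5 molal,
$\Delta\Gamma_S < 0$ throughout, and large compensating
$\Delta\Delta H_\varepsilon$, $T\Delta\Delta S_\varepsilon$ — the
phenomenology typical of small osmolytes. The per-contact value is small
deliberately: a surface cosolute pays $\nu\varepsilon \approx 0.6$ kT,
and much larger values drive the mixing penalty to dominate and the net
effect destabilizing, which is not how sugars behave.

Noise scales (all configurable): density $5\times10^{-5}$ g/cm³, water
activity $10^{-4}$, $\Delta G^0$ 0.1 kJ/mol, MRE 200 deg·cm²/dmol —
magnitudes chosen to resemble routine densitometry, osmometry and CD
scatter. One seed governs all tables through fixed per-table offsets
(+101 density, +202 activity, +303 folding, +404 spectra, +505 H-bonds),
so a bundle is reproducible piecewise.

The CD basis curves are Gaussian mixtures shaped like helix (double
minimum) and sheet (single minimum) classes, with the denatured basis
offset to cross the native one exactly at the configured isodichroic
wavelength. They are props for testing the two-state reduction: no band
physics, no temperature drift of baselines. Consequently, passing tests
demonstrate correctness of the *reduction and fitting machinery* — not
that real CD baselines are temperature-independent (an optional
linear-in-T baseline flag exists in the generator's absence because real
data often need it; the default analysis takes baselines constant, which
the invariant isodichroic point supports). Similarly, the H-bond truth
tables emulate the structure of MD summaries (protein–water bonds weaken
and lose counts when sugar is added; small protein–sugar terms appear;
sugar-partner pairs exist with zero counts in pure water) but not any
force-field physics; per-bond free energies are consumed as inputs, and
their estimation from trajectories is out of scope.

```{r generator}
truth <- ground_truth(seed = 42)
bundle <- synthetic_bundle(truth, molalities = seq(0, 1, 0.25),
                           temperatures = c(293, 298, 303),
                           wavelengths = seq(200, 230, 5))
bundle
```

## Numerical choices

- **Root solving.** The exchange equilibrium is solved by Brent's method
  on a bracket, absolute tolerance $10^{-15}$ in $\phi_s$. The exchange
  potential is monotone iff $2\chi\nu \le (1+\sqrt\nu)^2$; beyond that
  (demixing regime) a deterministic scan selects the most dilute root,
  the branch continuously connected to the bulk. Targets beyond
  floating-point brackets (e.g. $\nu\varepsilon$ of tens of kT) use the
  asymptotic dilute/concentrated expansions of $\hat\mu$.
- **One-parameter fits.** $\Delta\Delta G^0$ is *not* monotone in
  $\varepsilon$ (the product $\varepsilon\phi_s$ peaks near
  $\nu\varepsilon \approx 1$), so the least-squares objective can be a
  narrow well on a nearly flat background with nearby secondary basins.
  `fit_epsilon()` therefore scans 401 grid points over the bounds, refines
  with a second 41-point scan inside the best bracket, and only then
  applies Brent, keeping the best scanned candidate if Brent lands in a
  worse basin. The scan doubles as a multimodality diagnostic (flagged on
  the returned object). Bootstrap refits use the same scan-then-refine
  strategy inside a ±2 kT window around the point estimate.
- **Enthalpy route.** Model enthalpies come from a central-difference
  Gibbs–Helmholtz derivative, $\Delta\Delta H = \partial(\Delta\Delta
  G/T)/\partial(1/T)$ with $\Delta T = 0.5$ K; $T\Delta\Delta S =
  \Delta\Delta H - \Delta\Delta G$ then holds exactly. Two reductions of a
  measured $\Delta G^0(c,T)$ surface are provided: the smoothing
  integrated van't Hoff fit (`vant_hoff_fit()`; for noisy data) and the
  matched finite-difference estimator (`gibbs_helmholtz_deltas()`). The
  noiseless closure suite uses the latter, because the model's
  $\Delta\Delta G(c,T)$ is not exactly of integrated van't Hoff form (the
  surface composition drifts with temperature), so the van't Hoff route
  carries a small lack-of-fit (order $10^{-2}$ kT in
  $\varepsilon_{TS}$ for large $\nu$) that the derivative-matched route
  avoids; with matched $\Delta T$ the inversion is solver-limited.
- **Preferential hydration.** $\Delta\Gamma_S$ uses three-point
  finite differences on a non-uniform $\Pi$ grid, with a step-halving
  self-check that warns above a 0.1% relative change.
- **Degenerate inputs.** Activities pushed outside $(0,1]$ by noise are
  clipped and reported; fractions outside $(0,1)$ are clipped to
  $[10^{-6}, 1-10^{-6}]$ with a warning; constant bootstrap residuals
  yield a zero-width interval with a warning rather than an error.

## Open design choices, and how they were settled

- **Two-domain composite.** The depletion shell carries the osmotic work
  term and the contact layer carries the $\chi$- and
  $\varepsilon$-physics. This construction reproduces the closed form
  $\Delta\Delta G_\chi^0 = \chi(\nu\bar V_S)^2(m^{surf}-m)^2$ exactly,
  reduces to $\Pi\Delta V_{ex}$ when $\chi = \varepsilon = 0$, and gives
  $\delta = 0$ for solvent-sized cosolutes. A consequence worth noting:
  here the excluded-volume term is independent of $\varepsilon$, whereas
  in a fully coupled treatment the surface composition would also
  modulate the steric term; the coupling survives only in the $\chi$ and
  $\varepsilon$ terms through $\phi_s$.
- **$\chi(T) = a + b/T$** is the minimal two-parameter van't Hoff form;
  per-temperature $\chi$ fits followed by regression in $1/T$ is the
  default route, with a direct global fit equally possible from the same
  building blocks. When per-temperature standard errors are supplied, the
  regression covariance treats them as known (generalized least squares)
  rather than rescaling by the few-degrees-of-freedom residual variance —
  with only 3–5 temperatures the latter badly miscalibrates the intervals.
- **Strength versus number split.** The sugar-induced change of a
  network total is decomposed as
  $\sum_i n_i^{w}(\bar G_i^{s}-\bar G_i^{w}) + \sum_i (n_i^{s}-n_i^{w})
  \bar G_i^{s}$ — reference counts price the strength change, perturbed
  strengths price the count change. It is an exact decomposition but not
  the unique one; the symmetric (Shapley) convention is available behind
  `symmetric = TRUE` and is also exact.
- **Bootstrap.** Residual resampling with percentile intervals (default
  B = 1000, 68% level to mirror ±1σ error bars), seeded and
  deterministic. Chosen as a distribution-free default that is honest
  about the small numbers of concentrations involved; its calibration is
  itself tested (60–76% empirical coverage at nominal 68% on a seeded
  toy study).
- **$\Delta C_P$.** Fixed to 0 by default unless the temperature span
  exceeds 25 K; releasing it does not change any qualitative conclusion
  of the synthetic studies, mirroring the usual robustness practice.

## Problem sizes

The test suite and the acceptance script run, by choice, at desk scale:
closure over an 18-point truth grid (ν ∈ {2, 6, 12} × χ ∈ {0.2, 1.5} ×
ε ∈ {−1, 0, 1}) with 7 concentrations to 1.5 molal; activity series kept
below 0.35 molal for the strongly nonideal large cosolutes so the binary
mixture stays in its single-phase regime ($a_S \le 1$); Monte-Carlo
calibrations at 100–500 replicates with bootstrap B of 150–200 in tests
(B = 1000 remains the analysis default). The complete suite runs in a few
minutes on one core.

## Known limitations

- Single cosolute species only; no mixed osmolytes, no electrolytes.
- The flat-slab depletion geometry ignores protein curvature; thin
  depletion layers on small proteins are the worst case.
- $\varepsilon$ is weakly identified when the free-energy curve is nearly
  linear in $c$ (small $\nu$ or small $\chi$): the objective flattens,
  and for noisy data the multimodality diagnostic should be checked
  before trusting a point estimate.
- At strongly nonideal compositions ($2\chi\nu$ beyond the spinodal
  bound) the binary mixture model itself predicts demixing; results
  there are extrapolations of a mean-field form, not descriptions of a
  stable solution.
- The H-bond module is bookkeeping on supplied per-bond free energies; it
  inherits whatever biases the upstream estimator carries.
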