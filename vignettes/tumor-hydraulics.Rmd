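---
title: "Tumor hydraulic conductivity, interstitial flow and drug penetration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor hydraulic conductivity, interstitial flow and drug penetration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorflow)
```

`tumorflow` links three pieces of tumor biophysics: bench measurement of
tissue hydraulic conductivity $K$, its statistical relation to the tumor
microenvironment (TME), and its consequences for interstitial fluid
pressure (IFP), interstitial fluid velocity (IFV) and drug penetration in
a simulated solid tumor. This vignette records the models, every tunable
parameter with its default and provenance class, the numerical choices,
and what the synthetic-data tests do and do not demonstrate.

## 1. Ex-vivo conductivity from bubble tracking

A tissue disc (thickness $w$, wet diameter $d$) clamped in a modified
Ussing chamber filters buffer under a constant hydrostatic head $h$. The
flow is read as the drift of an air bubble in a tube of diameter $b$.
Darcy's law across the disc gives the nominal conductivity

$$K' = \left(\frac{b}{d}\right)^2 w\,\frac{dx/dt}{\rho g h},$$

and the in-vivo estimate corrects the buffer viscosity to interstitial
fluid at body temperature, $K = (\mu_{PBS}/\mu_{IF})\,K'$.

Chamber defaults (`ussing_measurement()`): $w = 1$ mm, $d = 5.05$ mm
(the exposed-area diameter, not the 12 mm punch diameter — the area
actually open to flow is what enters the Darcy balance), $b = 1$ mm,
$\rho = 998$ kg/m³, $h = 0.16$ m (≈1.6 kPa, a realistic elevated-IFP
magnitude), $g = 9.81$ m/s², $\mu_{IF} = 3.5\times10^{-3}$ Pa·s.

Design choices:

* **Velocity estimator.** The bubble is imaged every 10 min for 2 h
  (13 frames). We estimate $dx/dt$ as the OLS slope over *all* frames
  rather than a first/last difference: it uses all observations and
  yields a standard error that propagates to an uncertainty on $K$.
* **Viscosity–temperature model.** $\mu_{PBS}(T)$ is linearly
  interpolated between the water anchors $1.1\times10^{-3}$ Pa·s at
  18 °C and $8.9\times10^{-4}$ Pa·s at 25 °C. Over this 7 °C span the
  water viscosity curve deviates from the chord by well under 1%, so a
  fancier correlation would change $K$ by less than the bubble-tracking
  noise. Outside [18, 25] °C the line is extrapolated with a warning.
* **Negative velocities** (bubble drifting backwards) are reported with
  a `leak_suspect` flag rather than rejected: leakage is screened
  separately on the bench, and discarding signed values would bias
  small-$K$ samples.

## 2. Microstructure relations

Porosity $\varepsilon$, pore surface density $\alpha$ and the
Kozeny–Carman constant $Q$ (≈5 for $\varepsilon < 0.7$) give the
intrinsic permeability $k = \varepsilon^3/(Q\alpha^2)$, hence
$K = k/\mu$. Diffusion is hindered by the solid fraction,
$D_{eff} = \varepsilon D$.

Combining the two relations fixes the conductivity–diffusivity link used
by the drug solver:
$K \propto \varepsilon^3$ and $D_{eff} \propto \varepsilon$ force

$$\frac{D_{eff}}{D_{eff}^\circ} = \left(\frac{K}{K^\circ}\right)^{1/3}.$$

The exponent is a genuinely open modelling choice (a cubic reading,
$(K/K^\circ)^3$, is also conceivable if one takes the power law the
other way around); we default to $1/3$ because it is the unique value
consistent with the two porosity relations above, and expose it as the
`exponent` argument of `diffusivity_scaling()` / `drug_params()` so both
readings can be run. The baseline pair $(K^\circ, D_{eff}^\circ)$
defaults to $(8.8\times10^{-15}\ \mathrm{m^2/Pa\,s},\ 3\times10^{-10}\
\mathrm{m^2/s})$: the middle of the three measured anchor
conductivities, and a small-molecule (cisplatin-scale) effective
diffusivity in tissue. $K^\circ$ is deliberately a *fixed, study-wide*
baseline: if each run re-anchored $K^\circ$ to its own tumor $K$, every
tumor would see the same diffusivity and the cross-tumor penetration
contrast the model exists to quantify would vanish by construction.

## 3. TME correlation statistics

`fit_simple_regression()` fits $y \sim x$ by OLS and reports slope,
intercept, signed Pearson $r$ (and $|r|$, since published correlation
tables often tabulate the magnitude next to a signed slope), $R^2$, the
two-sided $p$-value of the slope $t$-test with $n-2$ df (sidedness is
our choice; the tabulated analyses do not state one), and `SE` — by
default the standard error of the slope, switchable to the residual
standard error (`se_type = "estimate"`) since published "SE" columns are
ambiguous between the two. No multiple-testing correction is applied,
matching how such tables are conventionally reported.

`correlation_table()` evaluates all density–density pairs and $K$–density
pairs, pooled and per tumor type; groups with fewer than 3 samples are
emitted with a reason code. Because measured $K$ spans more than a
decade, $K$ regressions are fitted on $\log_{10} K$ by default
(`log10_K = FALSE` gives linear $K$): on the linear scale a single
high-$K$ sample dominates the fit, while the planted generative model
(section 5) and the observed order-of-magnitude spread are both
log-scale phenomena. Mixed-effects models accounting for multiple slices
per tumor are deliberately out of scope — slices are pooled as
independent samples, as in the source analyses.

## 4. The flow and drug-transport model

### Geometry and conductivity maps

A sphere of radius $R_t = 5$ mm holds a necrotic core ($R_n = 2.5$ mm)
and a hypoxic shell of 2.5 mm; the viable rim is whatever remains
(width zero under these defaults — the stated region sizes exactly fill
the tumor, and the solver treats empty regions gracefully). Normal
tissue extends to $R_{domain} = 4R_t = 20$ mm where the IFP is grounded
to 0 Pa; this outer sphere stands in for the distant boundary of a 3-D
box domain, far enough that its shape is immaterial for the radial
fields reported.

`k_profile()` supports a homogeneous tumor value or a heterogeneous map
anchored at $K_2$ (interior, at $R_n$) and $K_1$ (tumor edge), constant
at `K_necrotic` (default $K_2$ — the deep-slice value is the only
measurement available for the core, and no published value exists for
necrotic tissue; it is configurable) in the core, with a smooth ramp to
$K_{normal}$ (default $5\times$ the tumor-edge value) over
`transition_width` = 0.5 mm. All interpolation is a cubic smoothstep in
$\log_{10} K$: positive by construction, monotone between anchors, and
$C^1$ at every region boundary. The exact published functional form of
the heterogeneity profile is not available; the smoothstep honors the
stated anchors and continuity without inventing extra parameters.

### Steady interstitial flow

Darcy's law $u_i = -K\nabla p_i$ and continuity
$\nabla\cdot u_i = J_V - J_L$ with Starling filtration

$$J_V = L_p \tfrac{S}{V}\,(p_v - p_i - \sigma(\pi_v - \pi_i)),\qquad
  J_L = L_{pL}\tfrac{S_L}{V_L}\,(p_i - p_L)$$

combine to a single elliptic equation for $p_i$. Regional switches
(`transport_params()`): the vascular source is off in the necrotic core
(avascular by definition; configurable, since this is not stated
explicitly in the source analyses) and on elsewhere; lymphatics operate
only in normal tissue.

Parameter defaults are classic literature values for solid-tumor
interstitial flow (the exact simulation table of the source study is in
its supplement, which is not distributed with the text; the packaged
values are the standard ranges that table draws on, and every one is
overridable):

| parameter | tumor | normal | units |
|---|---|---|---|
| $L_p$ | $2.1\times10^{-11}$ | $2.7\times10^{-12}$ | m/Pa·s |
| $S/V$ | $2\times10^{4}$ | $7\times10^{3}$ | 1/m |
| $p_v$ | 2080 | 2080 | Pa |
| $\sigma$ | 0.82 | 0.91 | — |
| $\pi_v$ | 2666 | 2666 | Pa |
| $\pi_i$ | 2000 | 1330 | Pa |
| $L_{pL}S_L/V_L$ | 0 (off) | $1.33\times10^{-7}$ | 1/Pa·s |

These give a tumor effective filtration pressure
$p_e = p_v - \sigma(\pi_v - \pi_i) \approx 1.53$ kPa — the ceiling the
IFP plateau approaches, consistent with the ~1.5 kPa maximum the
simulations are expected to reproduce — and a normal-tissue baseline
IFP of ~0.1 kPa.

### Drug transport

$$\frac{\partial C}{\partial t} =
  \nabla\cdot(D_{eff}\nabla C) - \nabla\cdot(u_i C) + \phi_V - \phi_L$$

with transvascular exchange
$\phi_V = L_d \tfrac{S}{V}(c_p - C)\,\mathrm{Pe}/(e^{\mathrm{Pe}}-1)
 + J_V(1-\sigma_d)c_p$, $\mathrm{Pe} = J_V(1-\sigma_d)/(L_d S/V)$, and
lymphatic uptake $\phi_L = J_L C$. The governing equation is often
written with a constant-coefficient diffusion term $D_{eff}\nabla^2 C$;
since $D_{eff}(r)$ varies with the local $K$, we implement the
conservative form $\nabla\cdot(D_{eff}\nabla C)$ — the two coincide for
homogeneous maps and only the conservative form preserves mass across
diffusivity gradients.

Drug defaults (`drug_params()`): $L_d = 5\times10^{-7}$ m/s and
$\sigma_d = 0.1$ (small hydrophilic molecule across leaky tumor
vasculature), plasma concentration $c_p = 0$ throughout (a 30–60 min
intraperitoneal session is short against systemic accumulation), bath
concentration $C = 0.17$ mol/m³ held at the tumor edge (typical
intraperitoneal cisplatin), exposure 3600 s. The Dirichlet condition
acts at the cell nearest $R_t$ and feeds both the tumor and the adjacent
normal tissue, as a bath in contact with the tumor surface does; the
outer domain boundary is held at $C = 0$ (the far field is a sink —
unstated in the source, and any condition 15 mm from the tumor is
invisible to the millimeter-scale penetration). The **penetration
depth** is the largest distance inward from the edge where $C$ exceeds
1% of the bath value (`threshold_frac`, configurable — reported
penetration contrasts depend only weakly on the threshold because the
concentration decays near-exponentially).

### Numerics

* Uniform finite-volume grid of spherical shells, default 800 cells to
  20 mm (25 µm resolution); the constructor refuses grids that resolve
  any nonzero-width region with fewer than 5 cells. Problem sizes were
  chosen so a full five-case parameter study with drug transport runs
  in a few seconds on one core.
* Face conductivities/diffusivities by harmonic averaging — the unique
  choice that preserves flux continuity across coefficient jumps.
* The steady IFP system is linear (both exchange terms are linear in
  $p_i$) and solved directly as a sparse tridiagonal system; symmetry
  ($u = 0$) at $r = 0$, Dirichlet 0 at the outer face. Verified against
  the closed-form uniform-sphere solution
  $p(r) = p_e[1 - (R/r)\sinh(\alpha r/R)/\sinh\alpha]$,
  $\alpha = R\sqrt{L_pS/V/K}$: relative $L_2$ error ~0.01% at 400
  cells, observed convergence order ≈ 2.
* Drug transport uses first-order upwinding for advection and
  backward-Euler time stepping (default $\Delta t = 10$ s). The system
  matrix is an M-matrix, so concentrations stay nonnegative and bounded
  by the bath value without any CFL restriction; $\Delta t$ controls
  only time accuracy. Transvascular Peclet factors evaluate the
  removable singularity at $\mathrm{Pe}=0$ by its limit 1. A discrete
  drug-mass budget (boundary influx minus vascular/lymphatic clearance
  against stored mass) is audited every step from independently
  recomputed face fluxes and must close to $10^{-6}$ relative.
* Upwinding introduces numerical diffusion $\sim u\,\Delta r/2$; at the
  peak IFV (~$5\times10^{-8}$ m/s) and 25 µm cells this is
  $\sim6\times10^{-13}$ m²/s, three orders below $D_{eff}$, so the
  penetration results are diffusion-resolved.

## 5. Synthetic data: what it emulates and what it does not

`generate_bubble_track()` inverts the chamber equation: a true $K$, the
sampled operating temperature (uniform in [18, 25] °C) and the chamber
geometry determine the bubble velocity; Gaussian position noise
(default 5 µm, an optical localization scale) is added to 13 frames
spanning 2 h. Noiseless tracks must round-trip to machine precision;
noisy tracks recover $K$ within 3 standard errors at the
$t$-distribution coverage (~98.8% with 11 df).

`generate_cohort()` plants
$\log_{10}K = a + b\cdot\mathrm{collagen\%} + \epsilon$,
$\epsilon\sim N(0, s^2)$, with collagen uniform on [10, 50]%,
$a = -13.85$, $b = -0.025$, $s = 0.15$; cell and fibroblast densities
are independent of $K$. Noise is lognormal in $K$ because conductivities
are positive and spread over an order of magnitude. The defaults were
set analytically before any test was run: the expected
$R^2 = b^2\mathrm{Var}(x)/(b^2\mathrm{Var}(x)+s^2) \approx 0.787$,
bracketing the measured pooled value of 0.79, and the implied $K$ range
($\sim8\times10^{-16}$ to $8\times10^{-15}$, widened by noise) sits
inside the measured tumor envelope. Tumor-type labels are assigned
round-robin and are cosmetic.

A passing synthetic suite therefore shows that the *pipeline* recovers
planted effects of realistic size at the study's sample count — it does
not validate the biological claim on real tissue, reproduce the measured
per-sample $K$ values or the per-type correlation table (no raw data are
deposited; the published values serve only as envelope checks), and it
does not emulate chamber leakage, slice-to-slice correlation within a
tumor, or histology image artifacts.

Statistical acceptance thresholds are rate criteria: at $\alpha = 0.05$
the true non-significance rate for a null association is exactly 95%,
so observed rates are tested against binomial tolerance bands at the
simulated seed count rather than as sharp inequalities.

## 6. The parameter study and its expected orderings

`run_parameter_study()` runs three homogeneous anchors — the measured
$9.4\times10^{-16}$, $8.8\times10^{-15}$ and $1.6\times10^{-14}$
m²/Pa·s — and two heterogeneous maps. The published heterogeneous maps
are given only graphically; the packaged stand-ins (T1:
$K_1 = 6\times10^{-15}, K_2 = 2\times10^{-15}$; T2:
$K_1 = 1.4\times10^{-14}, K_2 = 1.5\times10^{-15}$) are **synthetic**
values chosen within the measured envelope, with T2 given the larger
edge-to-core contrast as described for the second specimen.

Expected and tested orderings: maximum IFP ≈ $p_e$ for every map
(spread < 5%); lower $K$ → higher near-edge IFP; higher $K$ → higher
peak IFV, wider non-zero-IFV extent, deeper penetration (highest vs
lowest anchor ≈ 2× within generous threshold latitude — the model
yields ~1.6× at the 1% threshold, driven by
$\sqrt{D_{eff}}\propto K^{1/6}$ plus convection). Heterogeneous maps
are compared against the homogeneous tumor held at their *interior*
anchor $K_2$ — the value a single deep biopsy would assign — and show
lower intratumoral IFP, higher IFV and deeper penetration. Against a
homogeneous tumor at the *edge* value $K_1$ the radial fields are
nearly indistinguishable: in a spherically symmetric steady state the
edge boundary layer controls everything outside the plateau, which is
itself pinned at $p_e$. This near-degeneracy is a genuine property of
the 1-D model, not a bug, and is why the interior-anchor comparison is
the meaningful one.

## 7. Known limitations

* Spherical symmetry: no corner effects of a box domain, no real tumor
  shapes or resolved vasculature.
* Steady flow + quasi-static drug exposure: no poroelastic coupling,
  transient IFP, binding, metabolism or pharmacodynamics.
* The pressure head in the chamber model is treated as constant over
  the 2 h run (as maintained experimentally); head decay is not
  modelled.
* First-order upwinding is diffusive for advection-dominated regimes;
  irrelevant here (cell Peclet « 1) but worth revisiting for much
  coarser grids or faster flows.
* Parameter defaults are literature-range values, not a transcription
  of any specific supplement table; users reproducing a particular
  study should override `transport_params()`/`drug_params()` with the
  exact table.
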