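# tumorflow

Hydraulic conductivity of tumor tissue, interstitial fluid flow, and
drug penetration — an R package for tumor biophysics.

## The problem

Elevated interstitial fluid pressure (IFP) is a hallmark of solid tumors
and a major barrier to drug delivery. How high the IFP rises, how fast
interstitial fluid moves, and how deep a drug penetrates all depend on
the tissue **hydraulic conductivity** *K* [m²/Pa·s] — the ease of bulk
flow through the interstitium, equal to the intrinsic permeability *k*
divided by the interstitial fluid viscosity *μ*. `tumorflow` implements
the full computational chain for studying this dependence:

1. **Ex-vivo measurement analysis.** In a modified Ussing chamber a
   tissue disc separates two compartments under a hydrostatic head
   *h*; the filtration flow is read off as the drift of an air bubble
   in a tracking tube. From Darcy's law, the nominal conductivity is

   *K′ = (b/d)² · w · (dx/dt) / (ρ g h)*

   with tube diameter *b*, tissue wet diameter *d*, thickness *w*, and
   bubble velocity *dx/dt* estimated by least squares over all frames.
   The in-vivo estimate corrects for the buffer/interstitial-fluid
   viscosity ratio: *K = (μ_PBS/μ_IF) · K′*.

2. **Microstructure relations.** Kozeny–Carman permeability
   *k = ε³/(Qα²)*, conductivity *K = k/μ*, effective diffusivity
   *D_eff = εD*, and the derived power law
   *D_eff/D_eff° = (K/K°)^(1/3)* linking drug diffusivity to local
   conductivity.

3. **Tumor-microenvironment statistics.** Simple linear regressions
   (slope, intercept, *r*, *R²*, two-sided slope-*t* p-value, SE)
   between *K* and collagen-fiber / cancer-cell / fibroblast area
   densities, pooled and per tumor type.

4. **Flow and drug transport simulation.** A conservative
   finite-volume solver on a spherically symmetric three-region tumor
   (necrotic core, hypoxic shell, viable rim) in normal tissue:
   steady IFP/IFV from Darcy flow with Starling transvascular exchange
   *J_V = L_p S/V (p_v − p_i − σ(π_v − π_i))* and lymphatic drainage
   (normal tissue only), then transient interstitial drug
   concentration by advection–diffusion with transvascular exchange
   (Peclet-corrected) and lymphatic uptake, under a constant bath
   concentration at the tumor edge (intraperitoneal delivery).

5. **Synthetic data with known ground truth** for every stage: bubble
   tracks inverted from a chosen *K*, and sample cohorts with a
   planted inverse collagen–log₁₀*K* relation.

## Worked example

```r
library(tumorflow)

# 1. a synthetic chamber run with known K = 7.3e-15 m^2/Pa.s
m <- generate_bubble_track(K_true = 7.3e-15, noise_sd_position = 5e-6,
                           seed = 42)
measure_conductivity(m)
#> <conductivity_result> synthK7.3e-15
#>   velocity    1.124e-06 +/- 6.5e-10 m/s
#>   K_nominal   2.813e-14 m^2/Pa.s
#>   K_corrected 7.297e-15 m^2/Pa.s  (mu_PBS 0.000908 / mu_IF 0.0035)
```

The recovered `K_corrected` is within one standard error of the true
value: the 5 µm bubble-localization noise propagates to ~0.06%
uncertainty on *K* over a 2 h track.

```r
# 2. the K parameter study: three measured anchor conductivities
#    (homogeneous) and two heterogeneous slice-derived radial maps
st <- run_parameter_study(run_config())
st$summary[, c("case", "max_ifp_Pa", "edge_ifp_Pa", "max_ifv_m_s",
               "penetration_depth_m")]
#>       case max_ifp_Pa edge_ifp_Pa max_ifv_m_s penetration_depth_m
#> 1  hom_low       1534      1115.0   1.068e-08            0.000550
#> 2  hom_mid       1534       960.1   3.683e-08            0.000825
#> 3 hom_high       1534       911.7   5.212e-08            0.000900
#> 4   het_T1       1534       988.0   2.956e-08            0.000750
#> 5   het_T2       1534       920.0   4.804e-08            0.000850
```

The maximum IFP plateaus at the effective filtration pressure
*p_e = p_v − σ(π_v − π_i)* ≈ 1.53 kPa regardless of *K*, while the
near-edge IFP falls and the peak interstitial velocity and drug
penetration depth rise with *K*: penetration for the highest measured
anchor (1.6×10⁻¹⁴) is ~1.6× that of the lowest (9.4×10⁻¹⁶).
Heterogeneous maps give lower intratumoral IFP, higher IFV and deeper
penetration than a homogeneous tumor held at their interior value.

```r
# 3. cohort statistics (n = 29, planted inverse collagen effect)
co <- generate_cohort(cohort_spec(seed = 1))
tab <- correlation_table(co)
subset(tab, grouping == "all" & grepl("^K_vs", pair))[
  , c("pair", "n", "r", "R2", "p", "slope")]
#>              pair  n      r     R2        p    slope
#> 4      K_vs_fiber 29 -0.937 0.8783 7.20e-14 -0.02611
#> 5       K_vs_cell 29  0.109 0.0118 5.75e-01  0.00347
#> 6 K_vs_fibroblast 29 -0.125 0.0156 5.19e-01 -0.00422
```

A strong, significant inverse collagen–*K* association and null
cell/fibroblast associations, as planted.

A thin command-line wrapper over the same functions ships at
`inst/cli/tumorflow.R` (subcommands `synth-cohort`, `synth-tracks`,
`conductivity`, `correlate`, `study`).

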