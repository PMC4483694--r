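---
title: "Methods: multimedia fugacity modelling and multi-pathway risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimedia fugacity modelling and multi-pathway risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fugrisk)
```

## The model and its assumptions

`fugrisk` implements an unsteady (Level IV) four-compartment multimedia
fugacity model. Each compartment — air, water, soil, sediment — is a
well-mixed box whose chemical content is expressed as a fugacity `f` (Pa);
concentration follows as `C = Z f`, with the fugacity capacity `Z`
(mol·m⁻³·Pa⁻¹) built per sub-phase:

* gas: `Z = 1/(R T)`;
* dissolved water: `Z = 1/H`, with the Henry constant derived as
  `H = P_S / S` from vapour pressure and solubility so that both act as
  primary parameters;
* sorbed solids (suspended matter, soil and sediment solids):
  `Z = K_oc f_oc ρ / H`, with `K_oc = 0.41 K_ow` (Karickhoff) unless
  supplied;
* aerosol: `Z = Z_gas · 6×10⁶ / P_L`, with the sub-cooled-liquid vapour
  pressure obtained from the solid value by the fugacity-ratio correction
  `P_L = P_S · exp(6.79 (T_m/T − 1))`;
* biota: a 5%-lipid equivalent `Z = 0.05 K_ow / H`.

Bulk capacities are phase-fraction-weighted sums; equilibrium is assumed
*within* a compartment, never between compartments. Transport and
transformation enter as D values (mol·Pa⁻¹·day⁻¹): two-film diffusion at the
air–water and air–soil interfaces, dry aerosol deposition, rain dissolution
and aerosol washout (individually switchable), suspended-solids deposition
and resuspension, soil runoff of water and solids, first-order degradation
`D_r = V Z ln2 / t_½`, and advection `D_ad = G Z`. Two regional mechanisms
are first-class: irrigation moves dissolved chemical from water to soil
(`D_wso = G_irr Z_water`), and the built-up fraction of the soil surface
scales *all* air–soil exchange by `(1 − builtup)`, representing sealed
urban surfaces. Sediment burial is folded into the sediment loss term
rather than modelled separately.

The resulting system `df/dt = A(t) f + b(t)` is linear; off-diagonals of
`A` are gains `D_ji/(V_i Z_i)`, diagonals collect losses, and
`b_i = (E_i + G_i c_i)/(V_i Z_i)` carries emissions and background inflows
(air and water only). Everything downstream inherits this linearity, which
the test suite exploits heavily (superposition, scaling, annual-mean
commutation).

## Exposure and risk

Fugacities map to four pathway doses. Food ingestion assumes the fugacity
of fish equals the water fugacity and that of all other diet items the air
fugacity — the standard constant-fugacity approximation for moderately
hydrophobic persistent chemicals in agricultural food chains — giving

`D_f = 1000 M K_ow Z_water (f_a Σ v_k m_k + f_w v_fish m_fish)/(ρ_lp W)`

in mg·kg⁻¹·day⁻¹, where `v_k, m_k` are lipid fractions and daily intakes.
Tap water uses the dissolved phase only (treatment removes suspended
solids); inhalation uses the bulk air capacity including the particle-bound
fraction, because the chemical of interest is predominantly particle-bound
and inhalation unit risks refer to total air concentration (a `gas_only`
flag restricts to the gas phase); dermal contact sums an ambient-air term
and a shower-water term weighted by the shower-time fraction. Risk is
linear — `R_f = D_f SF_f`, `R_w = D_w UR_w`, `R_i = D_i UR_i`,
`R_d = D_d SF_d`, `R_t` their exact sum — deliberately excluding any
hormesis-type low-dose structure. Doses are computed on the daily grid and
averaged to calendar years; by linearity this equals computing risks from
annual-mean fugacities.

## The packaged scenario and its calibration

The packaged case study (`nanjing_default()`) describes a ~6582 km² region,
11% surface water, 1000 m mixing height, with a seven-year (2002–2008,
2557-day) horizon. Printed inputs are taken as-is: the yearly emission
table (air 1.32→2.12, water 0.17→0.12 mol/day), initial fugacities
(10⁻¹¹, 10⁻¹⁰, 10⁻¹¹, 10⁻¹⁰ Pa), and constant background inflow
concentrations (10⁻¹¹ mol/m³ air, 10⁻⁷ mol/m³ water). The remaining
parameters are a *reconstruction*: Mackay-typical phase compositions and
film velocities, plus one documented calibration pass over values the
source never printed — aerosol volume fraction (3×10⁻¹⁰), suspended-solids
fraction (2.5×10⁻⁵), soil mixing depth (5 mm: the thin surface layer that
actually receives atmospheric deposition), dry deposition velocity
(10 m/day ≈ 0.01 cm/s, accumulation-mode aerosol), scavenging ratio (2000),
solids deposition to sediment (2.4×10⁻⁷ m/day), particle-bound air
half-life (200 d), soil half-life (10 y), irrigation flow (1.4×10⁷ m³/day)
and an effective cross-border air-exchange section (1.2×10⁴ m²).

Two properties of the source constrain this calibration strongly and are
worth stating plainly. First, the reported relative sensitivity of the
total risk to the air emission rate (~93%) forces the air burden to be
almost entirely emission-driven, which caps the effective cross-border
ventilation at a value far below a literal wind-times-city-cross-section
estimate; the air compartment should be read as a persistent urban boundary
layer exchanging weakly with the regional background. Second, the reported
compartment concentrations together with any Mackay-standard Z set imply
fugacities around 10⁻⁹–10⁻¹⁰ Pa, several orders above the 10⁻¹⁴–10⁻¹³ Pa
the source text quotes; both cannot hold at once. The reconstruction
reproduces the *concentrations* (they are the verifiable numbers), and the
dose–response factors — unavailable in the original — absorb the scale
difference when calibrated to the reported per-pathway risk levels
(`SF_f = 9.4×10⁻⁴`, `SF_d = 4.4×10⁻³` per mg·kg⁻¹·day⁻¹,
`UR_w = 2.8×10⁻⁸` per µg/L, `UR_i = 5.4×10⁻⁸` per ng/m³). They are
therefore internal model constants of this reconstruction, **not**
regulatory potency values.

## The synthetic forcing generator

`synth_meteorology()` emulates the statistical structure the analysis
needs, not any particular meteorological record: temperature as an annual
sinusoid around 288.55 K (amplitude 12.5 K, Gaussian day-to-day noise of
2 K), rain as Bernoulli occurrence (p = 1/3) with gamma intensities
calibrated so the expected depth is 1000 mm/yr, lognormal wind speeds
(mean 3 m/s), and an 8-point direction drawn from prevailing-direction
weights dominated by east/southeast/northeast. Yearly emissions are held
constant within each calendar year. What this generator does *not*
emulate: autocorrelated synoptic weather, the seasonal covariance of rain
and temperature, inter-annual meteorological variability tied to specific
years, or any within-year emission seasonality. Consequently the packaged
run reproduces the *structure* of the reported dynamics (stepwise water
response to yearly forcing, bounded air/water fluctuation, monotone soil
and sediment accumulation) but not year-specific wiggles — notably the
reported 2004 risk peak, which has no printed driver and is absent here;
the reconstruction's total risk instead follows the emission series.
Passing tests therefore certify the model mechanics and the calibrated
climatology, not fidelity to any individual year's weather.

## Numerical choices

* Integrator: `deSolve::lsoda`, rtol 10⁻⁸, atol 10⁻¹⁸ Pa; soil/sediment
  time constants exceed air's by orders of magnitude, so a stiff-capable
  method is required. Daily forcing discontinuities cap the step at one
  day; constant-forcing runs leave the solver free.
* Forcing interpolation: piecewise-constant per day (daily inputs), with
  identical days memoized into one system assembly.
* Negative-value guard: values within −10⁻¹⁵ Pa are clipped to zero;
  anything more negative raises an error, because a genuinely negative
  fugacity signals a broken parameter set, not solver wobble.
* Steady state (`steady_state()`) solves `A f = −b` directly and serves as
  the oracle for the integrator: constant-forcing runs must land on it
  within 1% at twenty time constants (tested on 50 randomized instances).
* Mass balance is audited by flux quadrature: the inventory change
  `Σ V_i Z_i Δf_i` must match the time integral of sources minus
  degradation and advection to within 0.1% over the full run
  (inter-compartment transfers cancel identically).
* Monte Carlo seeding is per-stream (`seed + distribution index`), so
  single-group and combined runs share draws and are bit-reproducible;
  triangular sampling is by inverse CDF.
* Sensitivity runs hold the meteorological seed fixed so paired runs
  differ only through the perturbed parameter; exposure-side parameters
  reuse the baseline trajectory and rerun only the risk stage.

## Design choices where the ground was open

* Temperature dependence of `H` and `P` is available (van't Hoff form) but
  off by default: the source gives no temperature correction, and enabling
  one would change the calibration target silently.
* Both aerosol wet scavenging and rain dissolution contribute to air-to-
  surface transfer, each individually switchable, since their split is not
  documented in the source.
* Group 1 (environmental/physicochemical) Monte Carlo uncertainty enters
  through symmetric triangular rescalings `(0.5, 1, 1.5)` of the
  point-estimate fugacities rather than re-running the fate model per
  draw — exactly the decomposition the source describes, which also
  sidesteps the unknown correlations among those parameters.
* The multi-region mode advects only air and water (soil and sediment are
  immobile); wind-aligned faces without a neighbouring district exchange
  with the domain exterior (outflow downwind, background inflow upwind),
  and district geometry is schematic grid cells shipped as a synthetic
  GeoJSON fixture — the model consumes only areas and land-use fractions.
* The "S" of the sensitivity analysis is aqueous solubility: its
  sensitivity must equal `K_ow`'s in a lipid-partitioning dose
  (`D_f ∝ K_ow Z_water = K_ow S / P`), which is how the chemical record
  came to define `H = P/S`.

## Problem sizes

The packaged run integrates 4 states over 2557 days (seconds on one CPU);
the sensitivity table is 8 parameters × 2 factors with full re-runs
(~1 minute); Monte Carlo uses 5000 draws per group combination (seconds);
the spatial mode integrates 52 states over 365 days (seconds). The test
suite randomizes 50 small instances for the steady-state oracle and keeps
all fixtures programmatic.

## Known limitations

* Single chemical, single (averaged) receptor; no age stratification, no
  non-cancer endpoints, no hormesis.
* The dose–response constants are calibration artefacts of this
  reconstruction (see above) and must not be reused as potency values.
* Inter-district exchange magnitudes and the river-flow partitioning in
  the spatial fixture are assumptions; district polygons are synthetic.
* Linear low-dose extrapolation and the constant-fugacity food-chain
  assumption bound the interpretation of absolute risk numbers; relative
  and structural conclusions (pathway ordering, accumulation trends,
  sensitivity ranking) are the robust outputs.
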