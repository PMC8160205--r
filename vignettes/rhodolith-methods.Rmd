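---
title: "Models and methods behind the rhodolith pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the rhodolith pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodolith)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and the numerical decisions taken where the design was open.

## 1. Microprofiles, DBL thickness and Fick's-law fluxes

A microsensor trace records O₂ (µmol L⁻¹) or pH against distance from
the thallus surface (z = 0, µm, increasing into the water). In the
diffusive boundary layer, transport is molecular and — at steady state
with no reaction in the water itself — the concentration profile is
linear. `estimate_dbl()` therefore fits an ordinary least-squares line
to the points within a fixed near-surface window and extrapolates it to
the bulk concentration; the crossing depth is the *effective* DBL
thickness δ of Jørgensen-style boundary-layer analysis:

$$\delta = \frac{C_\mathrm{bulk} - C_0}{\mathrm{d}C/\mathrm{d}z}, \qquad
  J = -D\,\frac{\mathrm{d}C}{\mathrm{d}z}.$$

Choices and parameters:

* **Fit window** (`fit_window_um`, default 100 µm): the in-DBL sampling
  grid is 25 µm, so the default window holds five points — enough to
  regress, short enough to stay inside the linear region for any δ ≳
  150 µm. We chose a fixed window over iterative window growth because
  it is deterministic and matches the sampling design. It is
  configurable for coarser grids.
* **Bulk value**: the mean of the outermost three points
  (`estimate_bulk()`), with a regression-slope check that this tail is
  stationary; a significant tail slope raises a warning, not an error,
  because a drifting far field biases but does not invalidate the
  extrapolation.
* **Degenerate gradients**: if the slope's t-test cannot reject zero at
  `alpha` (default 0.05) no DBL is definable and the function aborts
  with a typed error, as it does when the extrapolated δ exceeds the
  profiled depth — both symptoms of a profile that never reaches its
  bulk plateau.
* **Sign convention**: fluxes are positive out of the thallus, so light
  photosynthetic efflux is positive and dark respiratory uptake
  negative. Report magnitudes with a direction label where unsigned
  numbers are wanted.
* **Unit conversion**: gradients in µmol L⁻¹ µm⁻¹ times D in m² s⁻¹
  convert to µmol cm⁻² h⁻¹ through a single factor 3.6×10⁸; the default
  D = 2.01×10⁻⁹ m² s⁻¹ is the O₂ diffusion coefficient in seawater at
  the experimental temperature.
* **Replicate traces**: microprofilers commonly run two consecutive
  traces per spot; `average_profiles()` aligns them on the common depth
  grid and averages point-wise before estimation.

ΔpH = pH_S − pH_B is taken directly from the measured surface value
rather than a fitted intercept: pH is not conservative across the DBL
(it mixes with the carbonate system), so a linear extrapolation has no
physical warrant; the measured z = 0 reading is the estimand itself.
The pipeline deliberately makes no assumption about the *sign* of dark
ΔpH — small positive dark anomalies at protuberance tips occur in real
data.

## 2. Gran alkalinity

An acid titration of a ~12 mL seawater sample with 0.1 M HCl crosses the
alkalinity equivalence point near pH 4.5; past it, every mole of acid
adds a mole of free protons, so the Gran function
\(F(v) = (V_0+v)\,[\mathrm{H}^+]\) is linear in v and its root is the
equivalence volume. Two numerical points matter:

* **Residual bicarbonate correction.** In the fitting window pH 3.0–3.5
  a small fraction of the DIC is still HCO₃⁻ (order 5–10 µmol/kg), so
  acid is still being consumed and the classical Gran extrapolation is
  biased low — about −10 µmol/kg under these conditions. The
  implemented Gran function subtracts a bicarbonate estimate
  \([\mathrm{HCO_3^-}] = K_1\,\mathrm{DIC}/[\mathrm{H}^+]\) using a
  nominal DIC hint (default 2000 µmol/kg); the result is insensitive to
  ±10% errors in the hint, and noise-free round trips through the
  titration generator recover A_T to better than 1 µmol/kg.
* **Window and fallback** (`ph_window`, default pH 3.0–3.5): standard
  practice — acid enough that borate and carbonate alkalinity are
  protonated, shallow enough to limit CO₂ degassing in real titrations.
  If fewer than five readings fall in the window, a contiguous
  five-point acid-side window minimising the linear-fit residual is
  used instead.

Duplicate tubes of the same water sample are processed independently
and averaged by `mean_alkalinity()`. Mass–volume conversions use the
international one-atmosphere equation of state, `seawater_density()`.

## 3. The seawater CO₂ system

`solve_carbonate()` takes the two measured master variables (pH, A_T)
and solves the speciation directly — with H⁺ known, no iteration is
needed. Constants: Lueker et al. (2000) K₁/K₂ on the total scale,
Dickson (1990) K_B, Millero (1995) K_w, Mucci (1983) calcite K_sp,
Uppström (1974) total borate, and Ca²⁺ proportional to salinity. The
implementation reproduces the canonical printed evaluations of each
constant at 25 °C, S = 35 to four decimals, and a root-finding
recomputation of the full system is cross-checked in the test suite.

Three conventions are deliberate calibrations and are configurable:

* **Salinity** (default 35): typical open-shelf value; never measured
  alongside the carbonate data this package targets.
* **pH scale** (`ph_scale_offset`, default 0): electrode pH calibrated
  against NBS buffers is inserted directly against total-scale
  constants. The offset between scales is ~0.13, but the *ratio* of
  saturation states between two treatments at equal alkalinity is
  insensitive to it (it drifts only ~5% across offsets 0–0.15), and the
  zero default reproduces the treatment Ω values the generators target.
* **Reference temperature** (default 25 °C): the carbonate system is
  evaluated at the titration-laboratory reference temperature rather
  than the 24 °C incubation temperature; with S = 35 and offset 0 this
  yields Ω_calc = 6.05 and 2.73 for the ambient and low-pH treatment
  chemistries (pH 8.12 / A_T 2378 and pH 7.698 / A_T 2377). At 24 °C
  the same inputs give 5.88 and 2.64 — the 1-degree choice is within
  the uncertainty any unreported constant set introduces, and we pin it
  once, here.

## 4. Chamber incubations

Closed 150 mL chambers, 30 min light then 30 min dark. Oxygen rates are
endpoint differences corrected by a rhodolith-free control chamber and
normalised by thallus surface area:
\(P = (\Delta O_2 - \Delta O_2^{ctl})\,V/(SA\,t)\). Gross photosynthesis
is reconstructed as net light rate plus dark respiration magnitude —
the standard construction, assuming respiration is unchanged by light.
Calcification uses the alkalinity anomaly (2 eq A_T per mol CaCO₃):
\(G = -\tfrac{1}{2}\Delta A_T\, V\rho/(SA\,t)\), with the control
correction defaulting to zero because alkalinity controls are rarely
run. Daily net calcification is the photoperiod-weighted sum
\(G_{net} = h_L G_L + h_D G_D\) with a 14:10 default.

G_net is computed **per replicate and then averaged**; the
mean-of-means variant (daily sum of mean hourly rates) is returned
alongside in `rate_table()`. The two differ once rates are rounded, and
reporting both makes the provenance of a printed daily value checkable.

## 5. Voxel morphometrics

Volume is unambiguous: voxel count × voxel volume. Surface area of a
binary mask is not, and the choice matters at the accuracy this
pipeline claims:

* voxel-face counting overestimates curved surfaces by up to ~50% (a
  digitized sphere's faces total ~1.5 × 4πr²);
* a raw mid-point marching-tetrahedra mesh still overestimates a sphere
  by ~17% (staircase facets);
* Gaussian-smoothing the field before meshing fixes the sphere but
  rounds sharp edges, underestimating a cube by 6–9%.

`measure_morphology()` therefore meshes the mask at level 0.5 with
marching tetrahedra and weights every facet's area by |n·ĝ|, the cosine
between the facet normal n and the local surface normal ĝ estimated
from the gradient of a lightly smoothed (σ = 0.8 voxel) signed
Euclidean distance field. Flat axis-aligned faces are exact (ĝ is
face-normal right up to the edge seam); staircase facets on curved
surfaces are projected down to the true area. Measured accuracy: +1.3%
on a digitized sphere of r = 25 voxels, −1.7% on a cube of edge 48; the
residual cube deficit is the half-voxel edge chamfer of any mid-point
mesh and decays as 1/n. The scale laws SA ∝ k², V ∝ k³ hold to the same
accuracy.

Filtering follows CT practice: a cubic-neighbourhood median filter
(reflective edges) for shot noise, an unsharp mask
(in + amount·(in − blur)) clipped to the input range for edge recovery,
then Otsu or fixed-threshold segmentation with largest-26-connected-
component retention to drop speckle. Interior porosity counts as
surface; masks are assumed isotropic. Filter radii and threshold method
are configuration, not science — the package defaults (radius 1,
σ = 1, amount 0.8) are ordinary starting points.

## 6. The statistics layer

One- and two-way fixed-effects ANOVA are delegated to `aov()`; with the
balanced designs this pipeline produces, sums of squares are identical
across SS types, and imbalance triggers an explicit warning. The
Newman–Keuls post hoc is implemented directly: means are ordered, the
range spanning p means is tested against `qtukey(1−α, p, df_error)`,
and every range inside a non-significant span is declared
non-significant without testing (the step-down protection that defines
the procedure). Critical values come from the studentized-range
distribution evaluated numerically, so any group count and error df
work without tables. The significance relation is rendered as a compact
letter display by the standard insert-and-absorb algorithm over the
sorted means, ties broken by input order. Shapiro–Wilk and Levene
checks are advisory: their failures are reported but never gate an
analysis, matching how such screens are used in practice. Degenerate
inputs (constant groups) yield F = 0/letters "a"/flagged NA p-values
rather than errors.

## 7. What the generators emulate — and what they do not

Every generator records its complete ground truth, and every estimator
has a recovery test against that truth.

* `simulate_microprofile()` draws the steady-state no-reaction DBL
  model: linear inside δ, constant beyond, sampled 25 µm/100 µm, with
  additive Gaussian noise. A `curvature` knob bows the in-DBL segment
  to stress the linear estimator. It does **not** model flow-dependent
  DBL compression, sensor response times or reaction inside the DBL.
* `simulate_titration()` is a closed-system forward model: after each
  acid increment the diluted alkalinity/DIC/borate system is
  re-equilibrated with the same constants the analysis uses. Real
  titrations degas CO₂ and include sulfate/fluoride pairs; both are
  outside the model, which is why the Gran test tolerances (±5 µmol/kg
  under noise) should not be read as field accuracy.
* `simulate_incubation()` inverts the rate equations to endpoints and
  adds endpoint noise (defaults: 1 µmol/L O₂, 2 µmol/kg A_T — chosen to
  give standard errors at n = 5 of the size the chamber design
  produces). The low-pH treatment applies a fixed effect structure:
  dark calcification shifted −0.15 µmol cm⁻² h⁻¹ in all species, gross
  photosynthesis ×1.15 and dark respiration ×1.40 in the *L.
  atlanticum* preset only, light calcification unchanged.
* `simulate_rhodolith_volume()` builds a sphere-plus-capped-cylinders
  solid on quasi-uniform (Fibonacci) directions and stores *exact*
  constructive-geometry surface area and volume; protuberance
  directions are kept disjoint so the closed forms stay exact, and a
  crowding or sub-4-voxel protuberance raises an error. Real rhodoliths
  branch, anastomose and are porous; the phantoms only span the
  SA/V range of the three morphotypes.
* `simulate_study()` crosses everything into a full design from one
  seed (identical seeds give identical bundles). Species presets pin
  the tip/base ΔpH decomposition so tip/base means equal the species
  means the presets target, and base DBL thickness increases linearly
  with protuberance length (20 µm per mm over a 300 µm offset) so the
  cross-stage regression has known structure.

Passing tests on these bundles demonstrates that the estimators invert
the generators' models at the stated noise levels — not that real
electrodes, titrators or scanners meet those noise levels.

## 8. Problem sizes and determinism

The shipped tests and the acceptance script run scaled-down designs —
two individuals × one spot for profile grids, one to two volumes per
species rasterised at 350–400 µm voxels, 50 noisy titrations, 2000 null
ANOVA simulations — sizes chosen so the whole suite completes in about
a minute on one CPU while every tolerance is still binding. All
randomness flows from explicit seeds; `run_pipeline()` on identical
inputs and configuration is deterministic.

## 9. Known limitations

* One-dimensional DBL analysis only; no 2-D/3-D mass transfer over real
  topography.
* Calcite saturation only (the organisms are high-Mg calcite
  producers); no aragonite Ω, pCO₂ or nutrient alkalinity terms.
* The pH-scale and constant-set calibration (§3) reproduces treatment
  chemistry targets; absolute Ω accuracy inherits the unreported
  salinity and scale conventions.
* No NRRD reader: voxel volumes travel as TIFF slice stacks.
* No photosynthesis–irradiance fitting; a single saturating light level
  is assumed throughout.
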