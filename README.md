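# rhodolith

Rhodoliths are free-living nodules of crustose coralline red algae whose
branch-like protuberances shape the thin diffusive boundary layer (DBL) of
water hugging the thallus. Inside that layer, photosynthesis and
respiration drive large day–night swings of oxygen and pH at the algal
surface, and those swings in turn modulate calcification and the algae's
response to ocean acidification. `rhodolith` implements the complete
computational chain used to quantify this: from raw microsensor depth
profiles to DBL thickness and diffusive fluxes, from acid titrations to
total alkalinity and calcification rates, from the seawater CO₂ system to
calcite saturation states, and from micro-CT voxel volumes to surface-area
morphometrics — plus the regression/ANOVA layer that ties them together,
and seeded generators that emulate every input so the whole pipeline runs
and is testable without instrument data.

It is written for marine ecophysiologists and carbonate-chemistry
practitioners: every user-facing function takes a data frame (or a typed
tibble) and returns a tibble, so stages chain with the pipe; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods.

## The quantities it computes

**DBL thickness and flux.** A straight line fitted to the near-surface
points of an O₂ microprofile gives the surface gradient d*C*/d*z*; the
effective DBL thickness is the extrapolation to the bulk concentration,
δ = (C_bulk − C₀)/(dC/dz), and the diffusive flux follows Fick's first
law, J = −D·dC/dz (D = 2.01×10⁻⁹ m² s⁻¹ for O₂ in seawater). Surface pH
anomalies are ΔpH = pH_S − pH_B.

**Alkalinity and calcification.** Total alkalinity comes from a Gran
titration: F(v) = (V₀+v)·(10^−pH − [HCO₃⁻]ₑₛₜ) is linear past the
equivalence point, whose root v_eq gives A_T = C_acid·v_eq/m. Each mole of
CaCO₃ precipitated removes two equivalents of A_T, so chamber
calcification is G = −ΔA_T/2 scaled by the water mass, area and duration;
daily net calcification weights hourly light and dark rates by a 14:10
photoperiod.

**Carbonate system.** From measured pH and A_T the solver partitions
alkalinity into HCO₃⁻, CO₃²⁻, B(OH)₄⁻, OH⁻ and H⁺ (Lueker 2000 K₁/K₂,
Dickson 1990 K_B, Millero 1995 K_w, Mucci 1983 K_sp, Uppström 1974 B_T)
and returns Ω_calc = [Ca²⁺][CO₃²⁻]/K_sp.

**Morphometrics.** Binary voxel volumes (median/unsharp filtering, Otsu
or fixed-threshold segmentation, largest 26-connected component) are
measured by a marching-tetrahedra mesh whose facet areas are projected on
normals from a smoothed signed distance field — accurate to a few percent
on both curved and flat phantoms, where naive voxel-face counting errs by
~50% on spheres.

**Statistics.** OLS with confidence bands, one/two-way ANOVA, Shapiro–Wilk
and Levene checks, and a Newman–Keuls stepwise post hoc with compact
letter displays computed from the studentized-range distribution.

## Worked example

```r
library(rhodolith)

# a light O2 microprofile at a protuberance base (seeded synthetic data)
prof <- simulate_microprofile(bulk = 210, dbl_thickness_um = 450, flux = 0.65,
                              noise_sd = 1, species = "L. atlanticum",
                              location = "base", condition = "light", seed = 42)
bulk <- estimate_bulk(prof)      # mean of the stationary outer points
dbl  <- estimate_dbl(prof, bulk) # linear-gradient extrapolation
dbl
#>   thickness_um surface_value surface_gradient bulk_value fit_r2 n_fit analyte
#> 1          450         614.8          -0.9012      209.2 0.9996     5  oxygen
fick_flux(dbl)
#>     flux diffusion_coefficient
#> 1 0.6521              2.01e-09
```

The imposed thickness (450 µm) and efflux (0.65 µmol O₂ cm⁻² h⁻¹) are
recovered from the noisy trace. Treatment chemistry and alkalinity:

```r
solve_carbonate(ph = 8.12, at = 2378, temp_c = 25, salinity = 35)
#>     ph   at  dic   co3 omega_calcite
#> 1 8.12 2378 2024 251.4          6.05

gran_alkalinity(simulate_titration(at_true = 2378, noise_sd_ph = 0.003, seed = 7))
#>        at  v_eq_ml gran_fit_r2 n_used
#> 1 2375.63 0.291731    0.999556      8

daily_net_calcification(g_light = 0.12, g_dark = 0.04)   # 14 h light : 10 h dark
#> [1] 2.08
```

Ambient seawater sits at Ω_calc ≈ 6.05, a noisy titration recovers the
true alkalinity within ~2 µmol/kg, and hourly calcification rates of
0.12/0.04 µmol CaCO₃ cm⁻² h⁻¹ integrate to 2.08 µmol cm⁻² day⁻¹. A whole
simulated study — profiles, chambers, titration tubes, CT volumes — runs
through every stage with:

```r
study <- simulate_study(seed = 1, noise = 0)
write_study_bundle(study, "bundle")
report <- run_pipeline("bundle", output_dir = "results")
report$delta_ph_vs_calcification
#> Linear regression calcification ~ delta_ph: slope 0.2943, R2 = 0.953, p = 0.0008416
```

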