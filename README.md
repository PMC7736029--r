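# spraydry

Data-driven process development for lab-scale spray drying of sugar
and peptide formulations.

Spray drying is a fast, gentle way to turn a solution of a sensitive
biomolecule (a peptide such as glucagon, stabilized by an amorphous
sugar such as trehalose) into a dry powder — but only inside a narrow
window of operating conditions. Run the dryer too cold or too wet and
droplets never dry, moisture plasticizes the amorphous sugar, its
glass-transition temperature collapses, and the product smears onto
the walls or crystallizes as a dihydrate; run it too hot and the gas
state crosses the stickiness curve in the cyclone and yield is lost
there. `spraydry` implements the quantitative toolkit for finding and
defending that window:

* **Psychrometrics** — moist-air states, saturation pressure
  (Magnus/Buck form), humidity/energy bookkeeping of an open-loop
  dryer, with supersaturation flagged rather than clipped.
* **Material state** — Gordon–Taylor glass-transition prediction
  `Tg(w_w) = ((1-w_w) Tg_s + K w_w Tg_w) / ((1-w_w) + K w_w)`,
  GAB sorption isotherms, the stickiness curve
  `T_db = Tg(RH) + offset` on the psychrometric chart, and
  safe / transition / risk zone classification.
* **Dryer model** — station-by-station states (P1–P9), exhaust-RH
  response surface and operation limit band, Barth equilibrium-orbit
  cyclone cut size, moisture-compensated yield, sensor-log parsing,
  phase segmentation and steady-state extraction.
* **Single-droplet drying** — moment-equivalent ellipse from binary
  masks, oblate-spheroid geometry, d²-law evaporation rate κ, lock
  point, Péclet number `Pe = κ/(8 D_s)`, surface enrichment
  `E = c_s/c_m ≈ 1 + Pe/5 + Pe²/100 + Pe³/4000` and its inversion for
  the solute diffusivity.
* **Voxel morphology** — sphericity ψ, solidity, convexity and
  solid-phase density ρ_XRT from segmented 3D particle masks.
* **Powder QC** — TGA residual moisture (RM₈₀/RM₁₁₀/RM₁₈₀), dihydrate
  content from the 80–110 °C step, vacuum-drying removal fractions,
  volume-weighted PSD quantiles (D₁₀/D₅₀/D₉₀), and a from-scratch
  Hartigan dip test with a seeded bootstrap for agglomeration scoring.
* **Synthetic data** — seeded generators for every input (droplet
  series, sensor logs, TGA curves, PSDs, sorption data, voxel
  particles), so the whole pipeline is testable without instruments.

See `vignettes/spray-drying-design-space.Rmd` for the models, their
assumptions and the numerical choices.

## Worked example

Classify two candidate operating points of a small open-loop dryer
(ambient air 22 °C / 40 %RH, 1.86 mL/min aqueous trehalose feed):

```r
library(spraydry)

gt  <- gordon_taylor_params()        # trehalose-water: 389 K, 136 K, K = 6.04
iso <- default_trehalose_isotherm()  # GAB placeholders, refit from your data

cfg_hot <- dryer_config(
  dry_gas_mass_flow = 0.0063, inlet_set_temperature = 403.15,  # 130 degC
  feed_rate = 1.86e-6 / 60, heat_loss_p4_p5 = 2, heat_loss_p5_p9 = 1,
  ambient_state = moist_air_state(295.15, relative_humidity = 0.4))
station_states(cfg_hot, gt, iso)
#>   station_id dry_bulb_temperature specific_humidity relative_humidity supersaturated       zone
#> 1         P1                295.1          0.006561          0.400000          FALSE       safe
#> 2         P3                403.1          0.006561          0.003937          FALSE       risk
#> 3         P4                391.6          0.011482          0.009760          FALSE transition
#> 4         P5                361.5          0.011482          0.027884          FALSE       safe
#> 5         P7                356.3          0.011482          0.034113          FALSE       safe
#> 6         P9                351.2          0.011482          0.042021          FALSE       safe

cold <- within_config(cfg_hot, inlet_set_temperature = 318.15,  # 45 degC
                      feed_rate = 2.5e-6 / 60)
st <- station_states(cold, gt, iso)
st[st$station_id %in% c("P5", "P9"), ]
#>   station_id dry_bulb_temperature specific_humidity relative_humidity supersaturated zone
#> 4         P5                300.3           0.01317            0.5858          FALSE risk
#> 6         P9                299.5           0.01317            0.6139          FALSE risk
```

At the hot set point the gas is only briefly above the stickiness
curve right at the dry inlet (P3, before any product exists) and every
product-side station (P5–P9) is in the safe zone. At the cold set
point the exhaust sits at ~60 %RH: moisture plasticizes the sugar
below the local gas temperature and all product-side stations are in
the risk zone — the classic insufficient-drying failure.

Particle-formation analysis of a (synthetic) levitated-droplet
experiment — 0.5% optical axis noise, true κ = 4.5e-9 m²/s:

```r
s     <- gen_droplet_series(d0 = 2e-3, kappa = 4.5e-9, lock_time = 400,
                            aspect_ratio = 1.2, noise_sigma = 0.005, seed = 1)
curve <- drying_curve(s)
fit   <- fit_evaporation_rate(curve, fit_window = c(0, 300))
#> kappa = 4.484e-09 +/- 1.7e-11 m^2/s
lp    <- detect_lock_point(curve, fit$kappa, slope_fraction = 0.5, persistence = 20)
#> lock point at t = 394 s, c_m = 70.9 kg/m^3
estimate_diffusivity(fit$kappa, lp, surface_concentration = 2.4 * lp$mean_concentration)
#> Peclet estimate: kappa = 4.48e-09 m^2/s, Pe = 5.37, E = 2.4, D_s = 1.04e-10 m^2/s
```

A Péclet number of ~5 with enrichment 2.4 is the diffusion-limited
regime that yields dense, round sugar particles; Pe well above 10
signals early skin formation and buckling, as seen for slowly
diffusing peptides.

Residual-moisture accounting over the bundled reference campaign table
(`reference_moisture_table()`, trehalose runs SPT1–SPT6 and glucagon
runs SPG1–SPG5):

```r
rm_reduction(8.24, 4.13)        # RM180, 70 degC vs 130 degC trehalose run
#> 49.88                         # raising T_in halves residual moisture
dihydrate_content(4.33 - 2.45)  # SPT1's 80-110 degC TGA step
#> 19.74                         # wt% upper bound on crystalline dihydrate
```

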