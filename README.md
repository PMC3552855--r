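# mfaflow

Quantification of platelet accumulation in microfluidic flow assays (MFAs).

Flow assays perfuse whole blood through shallow rectangular microchannels
(50 µm × 500 µm here) over immobilized type 1 collagen at controlled wall
shear rates — 150 and 300 s⁻¹ (venous) to 750 and 1500 s⁻¹ (arterial) —
while fluorescently labeled platelets are imaged every 7 s for 5 minutes.
The assay is a candidate clinical tool for bleeding and thrombotic
disorders, but using it that way requires reproducible, objective
quantification and a characterization of the normal range. This package
implements that quantification pipeline end to end for assay developers
and platelet-biology labs:

* **Hemodynamics** — wall shear rate ↔ flow rate in rectangular ducts via
  `γ_w = (f·Re/2)·Q/(A·D_h)` with the Shah–London polynomial for `f·Re(α)`;
  equal-drive syringe-bank design; Fåhræus and Fåhræus–Lindqvist
  corrections from the Pries in vitro relations.
* **Segmentation** — per-frame triangle (Zack) histogram thresholding of
  8-bit fluorescence frames plus removal of connected components smaller
  than one platelet (~47 px at 0.3225 µm/px), yielding percent surface
  coverage per frame.
* **Metrics** — end-point surface coverage (SC), lag time to 1% coverage
  (Lag_T), and accumulation velocity (V_PLT) from a robust bisquare
  straight-line fit (IRLS, tuning 4.685, MAD scale); runs never reaching
  1% contribute SC only.
* **Synthetic data** — donor cohorts with realistic covariate
  distributions (VWF, hematocrit, platelet count, sex, GP6 genotype,
  anticoagulant, a latent low-binder subgroup), a lag + nucleation/growth
  deposition model with shear-dependent kinetics and VWF coupling, and a
  renderer producing low-SNR image stacks with exact ground-truth masks.
* **Cohort statistics** — low-binder classification (SC < 1% at
  150/300/750 s⁻¹), covariate-quartile summaries, and the nonparametric
  association battery (Spearman, Mann-Whitney U, Kruskal-Wallis + Tukey
  HSD on ranks, two-way ANOVA interactions).

## Worked example

Simulate one donor's run at 300 s⁻¹, render it to a noisy 512×512 stack,
and push it through the exact pipeline a real TIFF would follow:

```r
library(mfaflow)

geom <- channel_geometry(height = 50, width = 500)
flow_rate_for_shear(c(150, 300, 750, 1500), geom)
#> [1]  1.932  3.864  9.659 19.319        # uL/min, ratio 1:2:5:10

donor <- sample_cohort(1, seed = 7)
sim   <- simulate_sc_curve(donor, shear_rate = 300, seed = 7)
run   <- render_stack(sim, seed = 8)

ts <- process_stack(run$stack)           # triangle threshold + size filter
tail(as.data.frame(ts), 3)
#>    time_s sc_percent threshold_level
#> 41    280   4.220581              52
#> 42    287   4.529190              52
#> 43    294   5.088425              50

compute_metrics(ts)
#> SC(end) = 5.09%, Lag_T = 189 s, V_PLT = 0.03599 %/s
tail(run$truth_sc, 1)                    # ground-truth coverage: 4.59%
```

The pipeline's end-point coverage (5.09%) sits within half a percentage
point of the rendered ground truth (4.59%); the 189 s lag reflects this
donor's draw of the slow VWF-adsorption phase at mid-range VWF. Real runs
enter the same way via `read_image_stack("run.tif")`, and
`inst/scripts/mfa.R` wraps the pipeline for shell use
(`Rscript mfa.R process --stack run.tif --out run_sc.csv`).

Channel-scale rheology:

```r
fahraeus_tube_hematocrit_ratio(50, 0.45)  # 0.8096 — tube hematocrit ~80% of feed
relative_apparent_viscosity(50, 0.45)     # 2.05, vs 3.19 at 1 mm
```

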