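# gbeorient

Quantitative analysis of myosin-II orientation during *Drosophila*
germband extension (GBE), on 2D cylindrical pullback maps of the embryo
surface.

During GBE, anisotropic non-muscle myosin II on cell–cell junctions
drives convergent-extension flow. Pair-rule gene (PRG) stripes are
passively advected — they deform and rotate with the tissue — while the
orientation of myosin anisotropy stays anchored to the embryo's
dorsal-ventral (DV) axis, deflecting only transiently where the tissue
rotates. This package implements the analyses that establish and
quantify that contrast, for people who study tissue mechanics and
cytoskeletal patterning:

* **Segmentation-free junction detection** — myosin-rich junctions
  (MRJs) detected by a windowed Radon transform (`radon_detect()`),
  robust at low signal-to-noise, plus intensity-weighted nematic
  orientation fields (`anisotropy_field()`) and circular statistics
  (`angular_distribution()`).
* **Tissue-flow analysis** — vorticity and local rotation rate
  (`rotation_rate()`), Lagrangian advection of points, polylines and
  patterns (`advect_points()`), and temporal autocorrelation of flow
  direction and nematic orientation fields.
* **PRG stripe analysis** — smoothed gradients, stripe segmentation and
  inter-stripe lines, stripe orientation fields, and the linear
  regression of the myosin map on PRG gradient patterns
  (`prg_regression()`).
* **The static-source relaxation model** — the package's core. The mean
  deflection of myosin orientation from the DV axis obeys

  dθ̄/dt = ρ(t) − θ̄/τ

  where ρ is the local tissue rotation rate (half the vorticity,
  deg/min) and τ the effective myosin lifetime, the model's single free
  parameter. Steady state under constant rotation is θ̄ = ρτ; after
  rotation ceases θ̄ decays as e^(−t/τ). `fit_tau()` recovers τ by
  minimizing the rotation-rate-adjusted angle between prediction and
  observation across the germband.
* **FRAP kinetics** — recovery-curve models and fits (`fit_frap()`)
  linking the effective lifetime to single-motor residence times.
* **A synthetic-embryo generator** — stationary four-vortex flows,
  seven-stripe PRG patterns, junction ensembles obeying the model,
  rendered noisy images, and FRAP traces, so every stage is testable
  without imaging data (`make_chart()`, `flow_spec()`,
  `make_prg_pattern()`, `simulate_junction_ensemble()`,
  `render_junction_image()`, `make_frap_trace()`).

`run_pipeline()` orchestrates everything end to end, with genotype
presets (`wt`, `twist`, `eve`, `fat2`) that alter only documented knobs
(flow amplitude, lifetime, egg geometry).

## Worked example

```r
library(gbeorient)
cfg <- run_config("wt", seed = 1, n_junctions = 2000)
report <- run_pipeline(cfg)
print(report)
```

```
run_report (wt, seed 1)
  tau_hat = 6.07 min (identifiable: TRUE)
  autocorrelation C(t_first, t_last): flow 1.00, Runt 0.69, myosin 0.97
  regression R^2 = 0.533; stripes found: 7
  DV support: myosin 172.5 um, Runt 252.5 um
```

Reading the numbers: the flow direction is perfectly stationary by
construction (autocorrelation 1.00 between the first and last flowing
frames); the Runt stripe orientation decorrelates strongly over GBE
(0.69) while the myosin orientation barely moves (0.97) — the paper's
central contrast. Seven stripes are segmented; the myosin recruitment
zone ends near 175 µm from the ventral furrow while Runt expression
persists further dorsally. The fitted effective lifetime from this
single 2000-junction embryo is 6.1 min; single-embryo estimates scatter
by roughly ±1 min around the generating value of 5 min, which is why
the quantitative analysis pools an ensemble of five embryos (see
below). `report$stripe_timeseries` holds the per-stripe Runt/myosin/
adjusted-angle series, and `run_pipeline(cfg, out_dir = "...")` writes
all tables (CSV), fields (TIFF) and the report (JSON) to disk.

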