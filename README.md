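# stocbct — a virtual spatiotemporally optimized 4D cone-beam CT scanner

Respiratory-correlated (4D) cone-beam CT images a breathing patient as one
3D volume per respiratory bin. The conventional protocol oversamples —
1320 projections over 240 s with no relationship between gantry angle and
breathing phase — because retrospective sorting must leave every bin with
usable data. **Spatiotemporal optimization (STO)** closes the acquisition
loop instead: a chest-height surrogate signal is monitored, the respiratory
phase a latency τ ahead is predicted from an ellipse fitted to the lag plot
`(y(t), y(t−ω))`, and the gantry speed and projection gate are modulated so
that projection *k* is acquired at angle

    S_ideal(k) = k · θ_arc / N_p ,   in bin  j(k) = ((k−1) mod N_b) + 1 .

Every bin then holds exactly `N_p/N_b` projections spaced `N_b·θ_arc/N_p`
apart (10° for a 200-projection scan, 3.3° for 600), at 85% / 55% lower dose
than the conventional scan. Sparse per-bin data is reconstructed with a
motion-compensated ("adaptive") chain: phase-resolved FDK, a McKinnon–Bates
perturbation step that shares information between bins through the
motion-blurred full reconstruction, B-spline deformable registration of the
MKB frames to peak inhale (Mattes mutual information, 16 mm control grid),
averaging of the warped frames, and synthesis of the other phases with
inverted deformation fields.

`stocbct` is a research sandbox implementing that entire system in silico
for R: breathing thorax phantom and surrogate generator, streaming phase
predictor, closed-loop controller with the hardware constraint set
(unidirectional rotation, ≤ 6°/s, ≥ 0.3°/s abort, ≤ 2°/s², 5.5 Hz trigger),
cone-beam projector with short-scan (Parker-weighted) FDK, the
MKB/registration/adaptive reconstruction chain, and the evaluation metrics:
schedule MAE, interbin angular separation, dose bookkeeping, CNR, tissue
interface width (TIW) and motion-model robustness.

## Worked example

A closed-loop 200-projection STO scan of a regularly breathing phantom:

```r
library(stocbct)

trace    <- generate_breathing_trace(
  trace_params(period_s = 4, period_sd_s = 0, amplitude_sd_frac = 0,
               drift_mm_per_min = 0, noise_sd_mm = 0),
  duration_s = 130, seed = 1)
protocol <- scan_protocol(200, 10, mode = "STO")
sim <- simulate_scan(make_phantom(), trace, protocol, scan_geometry(),
                     predictor_config(), grid_spec(64, 4))

nrow(sim$schedule)                                 # 200
schedule_mae(sim$schedule, sim$ideal)              # 0.1364 degrees
all(sim$schedule$bin == rep(1:10, 20))             # TRUE: ideal bin sequence
diff(range(sim$schedule$t_s))                      # 79.45 s  (~20 breaths)
range(unlist(interbin_separation(sim$schedule)))   # 9.63 .. 10.94 degrees
nrow(validate_constraints(sim$trajectory, protocol, sim$schedule))  # 0

rec <- adaptive_reconstruct(sim$projections, 10, reg_config(), grid_spec(64, 4))
```

The numbers mean: the scan acquired exactly its 200-projection budget in 20
breaths (a 63%-scale scan time, 85% fewer projections than the conventional
1320), the realized gantry angles deviate from the ideal interleaved
schedule by 0.14° on average, each bin's projections are spread ~10° apart
as targeted, and no hardware constraint was violated. `rec$adaptive` holds
the ten motion-compensated frames, `rec$mkb` and `rec$fdk4d` the
intermediate reconstructions, `rec$dvfs` the displacement fields.

An end-to-end trial arm with artifacts on disk (trace/schedule CSV, raw
float32 projections with a JSON sidecar, NIfTI frames, metrics report):

```r
run_pipeline(run_config(seed = 1), "STO200", out_dir = "sto200_run")
```

or from a shell, `inst/cli/stocbct demo --scenario STO200 --out sto200_run`.

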