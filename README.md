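# mrfepi

Quantitative T1, T2\* and proton-density (PD) mapping with **slice-interleaved
magnetic resonance fingerprinting** on a spoiled gradient-echo EPI readout.

In MR fingerprinting, many rapid images are acquired while flip angle, echo
time and effective repetition time vary, giving every tissue a distinctive
signal trace (*fingerprint*) that is matched against a dictionary of
Bloch-simulated candidates. This package implements the computational chain
for the slice-interleaved variant, in which four slices share one global
inversion pulse and are excited in block-wise pseudo-random alternation
within a 17-s slice group — a four-fold per-slice acceleration that enables
whole-brain coverage (32 slices) in 3:36 min:

* **Scheduling** — uniform readout allocation under a scan-time budget,
  block-wise randomized slice interleaving, per-slice effective-TR timelines,
  whole-protocol timing (`build_protocol()`, `build_group_schedule()`).
* **Signal model** — longitudinal Bloch recursion for the inversion-prepared
  spoiled GRE; readout `j` emits `|Mz sin(b1·α_j)|·exp(−TE_j/T2*)`
  (`simulate_fingerprint()`, with `ernst_signal()` as closed-form oracle).
* **Dictionary matching** — per-TR-pattern dictionaries on the standard grids
  (T1 20–2000/10 + 2000–6000/500 ms; T2\* 10–100/2 + 100–300/5 ms; B1
  0.6–1.4/0.1; entries with T1 < T2\* discarded → 151,938 entries), maximum
  magnitude inner product, closed-form `M0 = |k'k|/|k'f|`
  (`build_dictionary()`, `match_fingerprint()`).
* **Quantification** — per-voxel maps from baseline series
  (`reconstruct_maps()`), log-domain Gaussian bias-field estimation (60-mm
  FWHM), CSF-normalized PD in percentage units (100 pu ≡ 110.3 mol/l water at
  37 °C), plus reference fits: IR T1, multi-echo T2\*, double-angle B1,
  phantom PD formula.
* **Design analysis** — linearized noise amplification
  `sqrt(diag((J'J)^{-1}))` and Monte-Carlo matching precision versus the
  number of baseline images; randomized-vs-sequential slice-ordering
  comparison (`sweep_baseline_images()`, `compare_slice_orderings()`).
* **Synthetic data** — digital brain and agarose-vial phantoms with known
  ground truth, forward rendering with coil-sensitivity and B1 fields and
  seeded noise (`make_digital_brain()`, `render_baseline_series()`,
  `evaluate_against_truth()`).

## Worked example

Build a 4-slice group schedule, simulate a grey-matter fingerprint for slice
1, and match it against that slice's dictionary:

```r
library(mrfepi)

grp <- build_group_schedule(default_patterns(), n_slices = 4,
                            images_per_slice = 40,
                            group_duration_ms = 17000, seed = 1)
grp
#> MRF slice-group schedule: 4 slices x 40 images (randomized order)
#>   group duration 17000.0 ms, event spacing 106.25 ms, seed 1

tl <- grp$timelines[[1]]
dict <- build_dictionary(parameter_grid(b1 = 1), tl)
dict
#> MRF dictionary: 16882 entries x 40 readouts (timeline g4x40-d17000-randomized-seed1-s1)
#>   T1 20-6000 ms (207), T2* 10-300 ms (86), B1 1-1 (1)

fp <- simulate_fingerprint(tl, tissue_params(t1_ms = 1200, t2star_ms = 52))
match_fingerprint(fp, dict)
#> MRF match: T1 = 1200 ms, T2* = 52 ms, B1 = 1, M0 = 1, score = 1.000000
```

The matched triple is the simulated tissue (noiseless self-consistency), the
score is the cosine similarity between trace and entry, and `M0 = 1` recovers
the unit amplitude. A full synthetic study — render a digital brain,
reconstruct maps, calibrate PD against the CSF ventricles:

```r
ph    <- make_digital_brain(c(64, 64), n_slices = 1, seed = 2)
proto <- build_protocol(4, 4, images_per_slice = 40, seed = 3)
study <- render_baseline_series(ph, proto, seed = 4)
dictb <- build_dictionary(parameter_grid(b1 = seq(0.8, 1.2, 0.1)),
                          protocol_timeline(proto, 1))
maps  <- reconstruct_maps(study$series[[1]], dictb)
bias  <- estimate_bias_field(maps$m0, maps$mask, fwhm_mm = 60,
                             voxel_mm = ph$voxel_mm)
csf   <- ph$labels[, , 1] == 3
pd    <- normalize_pd(maps$m0, bias, csf)
round(c(WM = mean(pd[ph$labels[,,1] == 1]), CSF = mean(pd[csf])), 1)
#>   WM  CSF
#> 71.6 100.0
```

CSF reads exactly 100 pu by construction of the calibration; white matter
lands near its ground-truth 72 pu, the residual reflecting bias-field
estimation error at 1% rendering noise.

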