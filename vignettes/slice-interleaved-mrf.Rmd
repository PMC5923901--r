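---
title: "Slice-interleaved MR fingerprinting with EPI readout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-interleaved MR fingerprinting with EPI readout: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfepi)
```

## The problem

Magnetic resonance fingerprinting (MRF) quantifies tissue parameters by
acquiring many rapid images under deliberately varying sequence settings
(flip angle, echo time, repetition time) and matching each voxel's signal
trace — its *fingerprint* — against a dictionary of Bloch-simulated
candidates. An EPI-based spoiled gradient-echo variant maps T1 and T2*
jointly, but a single slice occupies the scanner for a full inversion-recovery
train (17 s) plus a recovery pause, so whole-brain coverage is slow.

`mrfepi` implements the computational side of a *slice-interleaved* variant:
after one global inversion pulse, several slices (four by default) are excited
in rapid alternation within one 17-s slice group. Because the sequence is
spoiled, exciting one slice does not disturb the longitudinal magnetization of
the others; each slice simply sees longer, irregular effective repetition
times that include the other slices' acquisition time. A 32-slice protocol
then needs 8 groups of (17 s + 10 s pause) = 216 s (3:36 min), a four-fold
per-slice acceleration over single-slice operation at 17 s + 10 s per slice.

## Scheduling model

A slice group lays `n_slices * images_per_slice` readout modules uniformly
over the group duration, i.e. the repetition time is maximized under the
scan-time budget. Slices are assigned to readout events block-wise: every
consecutive block of `n_slices` events contains each slice exactly once, in an
independently drawn uniform permutation. This keeps the early
inversion-recovery period sampled at a similar rate for every slice while
making the per-slice effective-TR patterns dissimilar — which is what makes
the four fingerprints of a group distinct and is why one dictionary must be
precomputed per slice.

Timing conventions the package fixes (they are not dictated by physics and
are documented here as package choices):

* Event *start* = excitation time, measured from the global inversion pulse.
  The echo follows TE after excitation inside the same readout module.
* Readout modules end on the uniform grid `i * spacing`, so the last module
  ends exactly at the group duration; the start of module `i` is
  `i * spacing - readout_overhead_ms`. The overhead (80 ms by default)
  accounts for fat suppression, crusher gradients and the EPI train; these
  are modeled as dead time only.
* One recovery pause is counted per slice group (8 groups of 17 s + 10 s give
  the 216 s total above).
* Slice indices are 1-based throughout, the R convention.

The TE and flip-angle trains are protocol inputs. The shipped default is a
160-point train respecting the published operating ranges — flip angles in
smooth sinusoidal lobes spanning 4–58 degrees, echo times pseudo-random
uniform in 17–78 ms from a fixed internal seed — and any measured train can be
supplied through `acquisition_patterns()` or a YAML/JSON protocol file. When
fewer baseline images are acquired per slice, both trains are interpolated
piecewise-linearly over the normalized readout index, preserving endpoints.

```{r schedule}
grp <- build_group_schedule(default_patterns(), n_slices = 4,
                            images_per_slice = 40, group_duration_ms = 17000,
                            seed = 1)
grp
range(unlist(lapply(grp$timelines, function(tl) tl$effective_tr_ms)))
```

## Signal model

Fingerprints are simulated with a longitudinal-only Bloch recursion for an
inversion-prepared, perfectly spoiled gradient echo. Starting from
equilibrium `m0`, the global inversion flips `Mz` to `-inv_efficiency * m0`
(ideal adiabatic inversion, `inv_efficiency = 1`, by default). Before each
readout of the simulated slice, `Mz` relaxes freely over the elapsed time;
readout `j` then contributes

    s_j = | Mz * sin(b1 * alpha_j) | * exp(-TE_j / T2*)

and the excitation leaves `Mz * cos(b1 * alpha_j)` behind. Key assumptions:

* **Perfect spoiling** — no transverse coherence survives between readouts;
  this is the standard model for a crusher-spoiled gradient echo and is what
  makes interleaving slices harmless to each other's signal.
* **B1+ as a flip-angle scale** — transmit-field inhomogeneity multiplies the
  nominal excitation flip angle only; the (adiabatic) inversion is unaffected.
  Consequently fingerprints depend on B1 only through `b1 * alpha`, an
  identity the test suite checks.
* **Magnitude signals** — EPI magnitude images are matched, so magnitudes are
  simulated. Since all simulated pre-echo signals enter through `|.|`, a
  signed simulation followed by taking magnitudes would be equivalent.
* **Single water compartment** — fat is suppressed by the sequence and not
  modeled.

For constant flip angle and TR the recursion must converge to the spoiled-GRE
Ernst steady state; `ernst_signal()` provides that closed form as an
independent oracle and the suite requires agreement to 1e-6 relative.

## Dictionary and matching

Default grids: T1 = 20–2000 ms in 10-ms steps joined with 2000–6000 ms in
500-ms steps (207 values); T2* = 10–100 ms in 2-ms steps joined with
100–300 ms in 5-ms steps (86 values); B1 scale 0.6–1.4 in steps of 0.1
(9 values); joint values are counted once. Entries with T1 < T2* are
unphysical and discarded, leaving 151,938 entries — the package's enumerated
count from these ranges, verified against a brute-force pair count in the
tests. Entries are simulated at unit m0, normalized to unit Euclidean norm
(pre-normalization norms retained), and ordered lexicographically by
(B1, T1, T2*), which fixes deterministic tie-breaking at equal scores.

Matching maximizes the inner product between the magnitude trace and the
unit-norm entries; the reported score divides by the trace norm, i.e. cosine
similarity, the scale-invariant MRF convention. The semi-quantitative
amplitude uses the closed form `M0 = |k'k| / |k'f|`. Two conventions of this
formula differ under noise: against the *unit-norm* entry it returns
`amplitude * fingerprint-norm`, whereas against the *unnormalized* unit-m0
fingerprint it returns the amplitude itself. `match_fingerprint()` and
`reconstruct_maps()` use the latter, so a trace `c * fingerprint` yields
`M0 = c` regardless of the TR pattern — this is what makes M0 comparable
across the four slices of a group. Note the closed form is not the orthogonal
projection estimator `k'f / ||f||^2`; under noise the two differ (by the
`1 + ||e||^2` identity covered in the tests), and the closed form is kept as
the package's definition.

```{r match}
tl <- grp$timelines[[1]]
dict <- build_dictionary(parameter_grid(b1 = 1), tl)
fp <- simulate_fingerprint(tl, tissue_params(t1_ms = 1200, t2star_ms = 53))
match_fingerprint(fp, dict)
```

## Proton-density mapping

The matched amplitude factorizes as `M0 = C * rho * S`: proton density `rho`,
smooth receive-coil sensitivity `S`, and a spatially invariant gain `C`. The
pipeline estimates `S` by mask-aware Gaussian smoothing of `log(M0)`
(normalized convolution, 60-mm FWHM cutoff by default) renormalized to unit
geometric mean inside the mask, then fixes `C` by normalizing the mean of the
bias-corrected map over a cerebrospinal-fluid reference region to 100
percentage units (pu); 100 pu corresponds to the proton density of pure water
at 37 °C, 110.3 mol/l. Values above 100 pu can occur under noise and are
reported as-is.

This estimator deliberately replaces probabilistic segmentation-based bias
correction: the smoothness model (no energy below the spatial cutoff) is the
transferable core, it works on phantoms where tissue-probability models do
not, and masks/ROIs come from phantom labels or user-supplied NIfTI images.
Its known limitation is anatomy leakage — genuine tissue contrast at spatial
scales comparable to the FWHM is partially absorbed into the field — so PD is
most accurate where the true field varies on scales well above the cutoff.
The suite requires 2% RMSE recovery of a known synthetic field over the mask
interior; near the mask boundary the normalized convolution is less accurate.

For phantom validation the package also provides the reference chain used
against scanner ground truth: a two-parameter magnitude inversion-recovery T1
fit `|A (1 - 2 e^{-TI/T1})|` (multi-start over a log-spaced T1 grid to handle
the null-point sign ambiguity), a three-parameter multi-echo T2* fit
`S0 e^{-TE/T2*} + c`, double-angle B1 mapping
`acos(I_2a / 2 I_a) / alpha`, and the phantom PD formula
`rho = C * I * B1 * S / e^{-TE/T2*}` normalized to a full-water region.

## Choosing the number of interleaved slices

For a fixed 17-s group time, more slices per group means fewer baseline
images per slice but longer effective TRs (higher per-image SNR). The design
module quantifies this trade-off two ways, mirroring each other:

1. **Linearized noise amplification.** For tissue `theta = (T1, T2*)`, the
   Jacobian of the *unit-norm* fingerprint with respect to `ln theta`
   (central differences, relative step 0.01) gives the Cramér–Rao-style
   proxy `sqrt(diag((J'J)^{-1}))` — relative parameter uncertainty per unit
   noise. The combined metric is the unweighted mean of the T1 and T2*
   values. With one or two samples the two-parameter system is singular and
   the sweep reports `NA`.
2. **Monte-Carlo matching precision.** Gaussian noise of standard deviation
   `sigma * ||fingerprint|| / sqrt(n)` (i.e. `sigma` relative to the RMS
   sample amplitude) is added to each of `n_draws` replicates, which are
   matched against the dictionary; the coefficient of variation of the
   matched T1 and T2* is averaged over the evaluation set. The default
   `sigma = 0.05` was fixed once so that matched-parameter CVs are of order
   one percent at 160 baseline images; the default `n_draws = 1000` matches
   the standard repetition count for such simulations. Noise is Gaussian on
   magnitudes (not Rician) so that the noiseless limit is exact; a Rician
   option would be an extension.

Both are averaged over an 18-pair evaluation set spanning the in-vivo range,
laid out as a 6 × 3 grid over T1 {1000…2500} ms × T2* {50, 60, 70} ms (the
count and ranges are standard; the grid layout is the package's choice). The
sweep interpolates the trains to each image count `n`, re-maximizes TR in the
17-s budget, and evaluates both metrics. Monte-Carlo dictionaries default to
the standard T1/T2* grids restricted to nominal B1, since the design question
concerns T1/T2*.

With the default trains the characteristic published shape emerges: noise
amplification is comparatively flat between 40 and 160 images and rises
rapidly below about 40, because sparse sampling of the inversion recovery
degrades T1 encoding — hence four slices of 40 images each as the operating
point. The exact location of the T2* minimum depends on the true scanner
trains and is exposed, not asserted, for surrogate defaults. The rank
agreement between the linearized and Monte-Carlo curves (Spearman > 0.8) is a
tested invariant.

`compare_slice_orderings()` runs the same Monte-Carlo per slice under
randomized versus fixed sequential block ordering and reports per-slice
precision plus its across-slice dispersion; randomization aims to homogenize
precision across the slices of a group.

## Synthetic data and what the tests do (and do not) show

`make_digital_brain()` builds a concentric 2D-per-slice geometry (GM ring, WM
core, two CSF ventricles, optional WM lesion) with representative in-vivo
defaults (T1/T2*/PD: WM 746/57/72, GM 1200/53/92, lesion 1285/95/62; CSF is
set to 4000 ms/200 ms/100 pu — full water, chosen inside the dictionary
bounds). `make_vial_phantom()` emulates a bank of doped-agarose vials with
log-spaced parameters. Both carry smooth low-order-harmonic B1 (0.8–1.2) and
coil-sensitivity fields and a noise level (default 1% of the mean tissue
signal). Rendering composes sensitivity × fractional PD × fingerprint per
voxel, adds seeded Gaussian noise, takes magnitudes, and records ground truth
before noise.

The generator deliberately omits EPI k-space artifacts, partial-volume
mixing, susceptibility-induced T2* variation, motion and Rician noise
statistics. Passing tests therefore demonstrate the correctness of the
*computational chain* — scheduling, simulation, matching, bias handling,
design metrics — under the stated forward model, not scanner-level accuracy;
the published phantom/in-vivo accuracy figures require scanner data and are
out of scope.

Problem sizes used by the shipped checks (chosen to exercise every stage at
desk scale): 64 × 64 single-slice studies for the PD pipeline, 24–32 px
phantoms for round-trip tests, coarse exhaustive grids for matching
round-trips, a full 1–160-image design sweep with 100 Monte-Carlo draws per
point, and the full default dictionary only where enumeration itself is under
test.

## Numerical choices and degenerate inputs

* Ties in matching are broken toward the lowest entry index; entry order is
  fixed, so results are deterministic.
* All randomized APIs require a seed and are bit-reproducible given it.
* All-zero voxel traces (background) are marked `NA` rather than matched;
  all-zero dictionary fingerprints (e.g. zero flip angles) are an error.
* The magnitude operation makes fingerprints non-smooth where an inversion
  null crosses a readout; the Jacobian's default relative step (0.01) is
  small enough in practice, and the convergence test uses steps on the smooth
  side of any kink.
* Maps store `NA` outside the mask; NIfTI export writes float32.
* Dictionaries are serialized with `saveRDS()`; parameter tables export to
  CSV. PD values are not clipped.
* The infeasible-schedule error names the minimum achievable group duration.

## Limitations

Quantification is per-slice 2D; no registration, segmentation, or k-space
reconstruction is provided. The bias estimator assumes the receive field is
smooth relative to the 60-mm cutoff and will absorb slowly varying anatomy.
The dictionary model ignores slice-profile integration, diffusion and
magnetization transfer; B1 correction applies to excitation only. These match
the scope of the computational method the package implements.
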