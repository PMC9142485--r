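---
title: "Simulating and analysing outcome-monitoring EEG in deterministic reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing outcome-monitoring EEG in deterministic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

In a deterministic reversal-learning task, a subject chooses one of two
colored squares and sees an outcome object. Three outcome categories
exist: the exact anticipated target (SAME), a semantically similar but
non-identical object (SIMI), and an unrelated object (DIFF). Two
instruction conditions give the *same physical* SIMI stimulus *opposite
behavioral meaning*: under the "identical" instruction it signals that
the target failed to appear (switch squares next trial); under the
"semantical" instruction it counts as a hit (stay). Comparing brain
responses to SIMI across the two conditions therefore isolates
outcome processing by behavioral relevance from processing by physical
appearance — the electrophysiological signature of interest for
orbitofrontal reality filtering (ORFi), the hypothesized mechanism that
signals when an anticipated outcome fails to occur.

The original recordings of this paradigm are not publicly shareable, so
this package pairs the complete analysis chain with a synthetic-EEG
generator that emulates the paradigm's statistical structure. Every
stage — task simulation, preprocessing, mass-univariate ANOVA,
cluster-permutation statistics, time-frequency analysis, and beamformer
source localization — is implemented as a tested, reusable function;
the generator provides ground truth for recovery and calibration tests.

## Task model

`generate_block()` builds 240-trial blocks with exactly 180 SAME, 30
SIMI and 30 DIFF outcomes, each rare outcome preceded by 2–6
consecutive SAME trials. Because 60 rare trials and 180 SAME trials
must tile the block exactly, run lengths cannot be i.i.d. uniform on
{2..6} (their mean must be 3, not 4); we sample **uniformly over the
constrained compositions** of 180 into 60 parts in [2, 6] by
dynamic-programming-weighted sequential sampling, then shuffle. Every
block satisfies the composition and run-length invariants exactly.

Two choices the task description leaves open:

* **Outcome after an error.** We show a DIFF-category object whenever
  the subject picks the wrong square (an unequivocal "absence" signal),
  and the agent treats it as a switch signal.
* **Scheduled counts vs. shown counts.** The 180/30/30 composition
  refers to outcome categories behind the *correct* square; error
  trials reveal DIFF without consuming scheduled SIMI/DIFF slots.

`simulate_agent()` provides a stand-in subject with a lapse rate
(random choice) and a perseveration rate (ignoring a switch signal —
the mechanism behind extinction errors), with log-normal reaction times
per previous-outcome category. `score_behavior()` reports percent
correct, extinction errors (incorrect stay after a reversal) and
association errors (unprompted switch after a correct stay outcome).
Error rates are expressed **per opportunity** (per post-reversal trial,
per post-correct-stay trial): with ~97% overall accuracy an extinction
rate of several percent is only arithmetically possible against the
~60 reversal opportunities per block, not against all 240 trials. With
the default policy (lapse 0.024, perseveration 0.072) simulated cohorts
land near 97% correct, ~7% extinction and ~1.2% association errors,
inside the plausible range for healthy adults on this task.

## Forward model and montage

All scalp projection goes through a single homogeneous conducting
sphere (radius 90 mm, center 40 mm above the MNI origin, conductivity
0.33 S/m). The surface potential of an interior current dipole is the
classical spherical-harmonic series; we sum it **in closed form** via
Legendre generating-function identities, and the test suite checks the
closed form against an independent truncated-series oracle to 1e-6
relative error (agreement is at machine precision). A single sphere
rather than a multi-shell or realistic model is a deliberate choice:
it is exactly testable, fast enough to build 10 mm lead fields in
under a second, and the beamformer contract only requires *a* lead
field; nothing downstream depends on the head model's realism.

The 156-channel montage is generated analytically from extended-10/20
geometry (rows Fp…I at 9° steps along the midline, columns at 9° steps
along coronal great circles through the preauricular axis), giving a
left/right symmetric cap that contains the three 5-electrode regional
cluster sets used by the focused analyses (frontal: AFp1, AFp2, AFz,
AFF1h, AFF2h; central: Cz, CCP1h, CCP2h, FCC1h, FCC2h; posterior: POz,
PPO1h, PPO2h, POO1, POO2). Digitized positions are unavailable, so
template positions on the model sphere are used throughout. Electrode
contiguity for the spatial-extent criterion is the Delaunay
triangulation of the azimuthal-equidistant projection with edges over
5 cm pruned (the `deldir` planar triangulation replaces a 3-D convex
hull, equivalent for an upper-cap montage).

## Synthetic EEG generator

`effect_preset("default")` encodes the study conditions: 22 subjects,
~50–57 generated epochs per condition × trial-type cell (matching the
retained-epoch bookkeeping of the study after ~5% artifact rejection),
1000 Hz sampling, 1400 ms epochs (−700..+700 ms around outcome onset).
Switch-signalling cells (DIFF in both conditions, SIMI under
"identical") receive: a frontal positivity at 250 ms (Gaussian, 45 ms
width), a central negativity at 350 ms (a feedback-related-negativity
analogue), a central/posterior positivity at 400–600 ms (a P300
analogue), an ongoing 5.5 Hz frontocentral theta source whose envelope
rises +4 dB between 150 and 650 ms, and a 20 Hz centroparietal beta
source suppressed −4 dB between 350 and 600 ms. Stay-signalling cells
carry the same components strongly attenuated (so both conditions show
the qualitative theta increase, with a reliable difference).

Numeric choices and what they mean:

* **Dipole moments** are in nAm (transients 8–40 nAm; ongoing theta
  110 nAm — a regional synchronous source; these were set so that the
  sensor-level effect sizes, against the 9 µV 1/f background, make a
  22-subject cohort recover the qualitative pattern, which is the
  generator's stated purpose; amplitudes are free parameters of the
  preset, not measured quantities).
* **Background noise** is 1/f (exponent 1) band-limited to 0.7–46 Hz,
  generated at 60 random superficial sources and mixed through the same
  forward model — this produces realistic inter-channel correlation,
  which matters for the calibration of cluster statistics — plus 1.5 µV
  white sensor noise, jointly scaled to a 9 µV per-channel sd.
* **Between-subject variability** is a log-normal amplitude factor
  (sd 0.3) multiplying all effect amplitudes (and dB changes) of a
  subject.
* **Artifacts**: 5% of epochs get a 180 µV, 200 ms half-sine excursion
  on one random channel, flagged in metadata so the ±100 µV rejection
  can be verified to remove exactly them.

What the generator does **not** emulate: ocular/muscular artifact
morphology, non-stationary noise, volume-conduction inaccuracies of
real heads, latency jitter across trials, and any correlation between
behavior and single-trial EEG. Passing recovery tests therefore shows
the *analysis chain* is correct and calibrated — not that it would
detect effects of this size in arbitrary real data.

## Preprocessing

Fixed order: band-pass → average reference → rejection → interpolation
→ averaging (whether the original rejection preceded interpolation is
not documented; this order is our decision and is flagged here).

* The 1–45 Hz FIR is a Hamming windowed-sinc cascade (high-pass
  transition 1 Hz, low-pass transition 5 Hz, −6 dB at the edges),
  applied forward once with exact group-delay compensation
  (zero-phase). At 1000 Hz the kernel has 3961 taps, longer than a
  1400 ms epoch, so `preprocess_cell()` applies it only to inputs that
  can support it and otherwise records the step as skipped — the
  synthetic generator emits band-limited data by construction, whereas
  the original filter ran on continuous recordings before epoching.
* Rejection is strict: an epoch is dropped iff any channel sample
  exceeds 100 µV in magnitude (the boundary value itself is kept).
* Bad channels are rebuilt with spherical splines (order m = 4, 50
  Legendre terms, ridge 1e-5 — the standard smooth-interpolant choice);
  detection itself is replaced by an explicit bad-channel list.
* ERPs are plain trial means with **no baseline correction** — the
  paradigm carries anticipation-related slow activity that baseline
  subtraction would smear into the post-outcome window.

## Statistics

**Mass-univariate rmANOVA.** A 2 (condition) × 3 (trial type)
within-subject ANOVA at every electrode × timeframe, vectorized over
features. Greenhouse–Geisser ε is estimated from the orthonormal
contrast covariance (closed 2 × 2 form) and applied when Mauchly's test
rejects sphericity at 0.05 (`gg_gate = TRUE`), mirroring the "in case
of sphericity violation" reporting convention; the ungated version is
used when comparing against oracles. Significance maps are pruned by
`extent_filter()`: p < 0.01 sustained ≥ 20 ms and spanning ≥ 5
contiguous electrodes, iterated to a fixed point so retained points
satisfy both criteria jointly; both prunings are monotone, so relaxing
any threshold never removes a retained point.

**Cluster permutation.** For the 5-electrode cluster timecourses,
paired t statistics form clusters of contiguous 1 ms frames at
two-sided p < 0.05; the null is built by within-subject sign flips of
the difference waves, with the maximum cluster **size in timeframes**
(the statistic named by the protocol, not cluster mass) recorded per
permutation. Corrected p values use the (1 + r)/(n + 1) convention
with the observed statistic included, and a cluster is retained when
that exact permutation rank gives p ≤ 0.05 — identical to "larger than
95% of the permutation distribution" at 5000 permutations up to
rounding, and exactly level-5% valid at any permutation count (the
bare percentile rule is marginally anti-conservative at small counts). The same engine runs in 2-D
(freq × time, 4-connectivity) and 3-D (source grid, 6-connectivity);
connected components are found by iterative max-label propagation,
which converges in a handful of sweeps for the small clusters typical
under permutation.

**Time-frequency.** 300 ms Hanning windows every 10 ms, frequencies
3–45 Hz at 1 Hz steps evaluated by direct windowed DFT — the 1 Hz grid
is finer than the ~3.3 Hz Rayleigh resolution of a 300 ms window and is
therefore interpolative, which we document rather than hide. Power is
averaged over trials first, then log-transformed (10·log10, i.e. dB)
and baseline-corrected by subtracting the mean log power of window
centers in −550..0 ms. Whether channels are averaged before or after
the spectral transform is unstated in the protocol; we average **power
after the STFT** over each cluster's electrodes.

**Beamformer.** A scalar minimum-variance spatial filter on a 10 mm
grid: sensor covariance from band-limited Hanning-windowed Fourier
coefficients (real part; with multi-bin bands this equals the
band-summed cross-spectrum), regularized as C + λ·mean(diag C)·I with
λ = 0.05 (the toolbox value is unpublished; λ is exposed), orientation
chosen as the minimum generalized eigenvector of L'C⁻¹L (maximum
output power), unit-gain weights w = C⁻¹l/(l'C⁻¹l). Weights are
computed once per band from the all-window covariance (a common filter
avoids window-level instability) and applied to 300 ms windows stepped
50 ms; dB baseline correction as in sensor space. Raw minimum-variance
power is depth-biased (voxels with small lead fields inflate), so
*localization* uses the noise-normalized neural activity index
(power / w'w), while the dB maps — the analysis quantity — cancel the
bias by construction. Group inference uses sign-flip SnPM with
6-connected spatial clusters and the same 95th-percentile rule.

## Problem sizes and determinism

All simulations are seeded; `derive_seed(master, tag)` hashes a stage
or subject tag into an independent 31-bit sub-seed, so re-running any
configuration is bit-identical. The calibration suite uses 1000
simulated null experiments at 500 permutations for the temporal
cluster test's family-wise error; recovery tests run the full
22-subject default preset with permutations reduced to 500 (the
permutation count changes only the resolution of the null quantile,
not the simulated physiology). The beamformer localization check uses
50 seeds at sensor SNR 10. The analysis drivers under `analysis/`
use the same module functions at the same settings.

## Known limitations

* The head model is schematic; source coordinates labelled "MNI" are
  positions in the model sphere's MNI-aligned frame, not
  anatomically-warped locations.
* The SIMI/DIFF slots are not balanced across block halves (left open
  as a generator extension).
* The epoched synthetic data cannot support the full-length 1–45 Hz
  FIR; filtering is exercised on long signals in tests and skipped for
  1400-sample epochs.
* Effect amplitudes are preset conventions, not estimates; only the
  *qualitative* spatiotemporal pattern (which contrast is significant,
  where and when) is meaningful, never the simulated effect
  magnitudes.
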