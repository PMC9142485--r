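# orfieeg

Simulation and statistical analysis of outcome-monitoring EEG in a
deterministic reversal-learning task.

## The scientific problem

In deterministic reversal learning, a subject repeatedly chooses one of
two cues and watches the outcome: the anticipated target object (SAME),
a semantically similar object (SIMI), or an unrelated object (DIFF).
Instructions give the *same* SIMI stimulus opposite behavioral meaning
in two conditions — under "identical" it signals the target failed to
appear (switch next trial), under "semantical" it counts as a hit
(stay). Contrasting brain responses to physically identical SIMI
outcomes across conditions isolates how outcome monitoring tracks
behavioral relevance rather than appearance — the signature relevant to
orbitofrontal reality filtering, the mechanism thought to flag when an
anticipated outcome fails to occur.

Because recordings of this paradigm cannot be shared, the package pairs
the full analysis chain with a synthetic high-density EEG generator
(156 channels, 1000 Hz, −700..+700 ms epochs, 22 simulated subjects)
whose effect preset reproduces the qualitative outcome-monitoring
pattern: an early frontal positivity (~200–300 ms), a central
negativity (~350 ms, FRN-like), a late central/posterior positivity
(400–600 ms, P300-like), a frontocentral theta-power increase, and a
late centroparietal beta suppression for switch-signalling outcomes.

## What is implemented

* **Task model** — `generate_block()` (240 trials; 180/30/30
  SAME/SIMI/DIFF; rare outcomes after uniform 2–6 SAME runs, sampled
  exactly over constrained compositions), `simulate_agent()` (lapse /
  perseveration policy), `score_behavior()` (accuracy, extinction and
  association error rates per opportunity, RT by previous outcome).
* **Forward model** — closed-form dipole potentials in a homogeneous
  sphere (tested to 1e-6 against a Legendre-series oracle), analytic
  156-channel extended-10/20 montage, 10 mm MNI source grid and lead
  field.
* **Synthetic EEG** — forward-projected ERP components and
  amplitude-modulated oscillatory sources, spatially correlated 1/f
  background noise, flagged >100 µV artifact epochs, log-normal
  between-subject amplitude variability; bit-reproducible under a seed.
* **Preprocessing** — zero-phase 1–45 Hz windowed-sinc FIR, average
  reference, strict ±100 µV epoch rejection, spherical-spline (m = 4)
  bad-channel interpolation, trial averaging with no baseline
  correction.
* **ERP statistics** — vectorized 2×3 repeated-measures ANOVA per
  electrode × timeframe with Greenhouse–Geisser correction gated by
  Mauchly's test; extent thresholding (p < 0.01, ≥ 20 ms, ≥ 5
  contiguous electrodes); 5-electrode regional cluster timecourses;
  paired-t temporal cluster-permutation test (sign flips,
  maximum-cluster-size null, exact permutation-rank retention).
* **Time–frequency** — 300 ms Hanning STFT every 10 ms, 3–45 Hz at
  1 Hz, dB baseline correction (−550..0 ms), 2-D cluster permutation,
  topographic band/interval maps.
* **Source analysis** — scalar minimum-variance beamformer (common
  filter per band, λ = 0.05 regularization), per-band dB source maps,
  noise-normalized localization scans, SnPM-style sign-flip spatial
  cluster correction; NIfTI export.
* **Pipeline** — `run_config()` / `run_all()` orchestrate the stages
  with hashed sub-seeds and content-addressed stage outputs; thin
  narrative drivers live under `analysis/`.

## Worked example

```r
library(orfieeg)

sched <- generate_block("identical", seed = 1)
log   <- simulate_agent(sched, agent_policy(), seed = 2)
sc    <- score_behavior(sched, log)
```

This prints, for one 240-trial block of the default (human-plausible)
agent:

```
accuracy 96.7% | extinction 6.1% | association 1.7%
  prev_outcome   n mean_ms sd_ms
1         SAME 170   472.3 158.0
2         SIMI  27   494.0 118.5
3         DIFF  34   483.4 169.9
```

i.e. the agent follows the reversal rule almost perfectly, occasionally
perseverates after a switch signal (extinction errors, counted per
post-reversal trial), rarely abandons a rewarded square (association
errors, per stay trial), and is slightly slower after a DIFF outcome.

A minimal cluster-permutation call on simulated subject timecourses —
18 subjects of 1/f noise with a boxcar effect injected at −100..+20 ms:

```r
set.seed(3)
a <- t(pink_noise(600, 18)); b <- t(pink_noise(600, 18))
a[, 200:320] <- a[, 200:320] + 0.9
paired_t_cluster_perm(a, b, n_perm = 1000, seed = 4,
                      times = seq_len(600) - 300)$clusters
```

```
  start  end size p_corrected significant
...
5   -75   -4   72       0.003        TRUE
...
```

Only the run of supra-threshold timeframes inside the injected window
survives the maximum-cluster-size correction (null 95th percentile: 33
frames); isolated noise runs of 2–20 frames do not.

The full 22-subject sensor-space contrast (SIMI identical vs SIMI
semantical) is driven by `analysis/02_sensor_stats.R`; with the default
preset (seed 2026) it recovers a significant early positive frontal ERP
cluster at 180–263 ms (p = 0.009) plus late central (293–409 ms) and
posterior (342–664 ms) clusters, a frontocentral theta/low-alpha
increase (3–10 Hz, p = 0.001) and a late central beta suppression
(16–25 Hz, 210–550 ms), writing the cluster tables under
`results/run/`.

## Repository layout

```
R/                  package implementation (all computation)
analysis/           numbered narrative drivers writing results/
scripts/acceptance.R  design/calibration reproduction script
tests/testthat/     unit, property and acceptance test suites
vignettes/          methods vignette (models, parameters, choices)
```
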