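---
title: "Shape-based clustering and template matching for QT analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based clustering and template matching for QT analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The QT interval — from QRS onset to T-wave end — is the standard ECG
measure of ventricular repolarization time, and its drug-induced
prolongation is a proarrhythmic risk marker. On long-term (Holter-type)
recordings with ~100,000 beats per day, fully manual delineation is
infeasible and naive automatic T-end detectors are unreliable precisely
where it matters: when T-wave morphology changes. `qtshape` implements a
semi-automated strategy: beats are grouped by shape, a human registers two
fiducials (QRS onset, T end) on **one representative template per group**,
and the machine transfers those fiducials to every beat through an elastic
alignment. The per-record human effort is constant (12 templates), not
proportional to the number of beats.

## Pipeline and model

1. **Segmentation.** Each beat is the half-open window from 120 ms before
   its R peak to 80 ms before the next R peak, standardized to a fixed
   1600 ms duration: longer windows are truncated, shorter ones tail-padded
   with the mean of the raw window's first and last samples. R peaks are an
   input (annotations or an upstream detector), not something this package
   detects.
2. **Exclusions.** A beat is dropped when its preceding RR interval is
   < 300 ms or > 2000 ms, or is < 70 % or > 130 % of the following RR
   interval — bradycardia, tachycardia and unstable rhythm make both the
   rate correction and the fixed window unreliable. All four comparisons
   are strict, so boundary values are retained.
3. **Filtering.** High-frequency noise is removed by a low-pass filter
   with passband edge 50 Hz (max 3 dB loss) and stopband edge 60 Hz
   (min 40 dB attenuation), applied to the continuous record before
   segmentation.
4. **Normalization.** Each beat is z-normalized,
   \(z = (x - \mu)/\sigma\) with the population SD, so clustering sees
   shape, not amplitude or offset.
5. **K-shape clustering** with \(k = 12\): assignment by the shape-based
   distance
   \(\mathrm{SBD}(x,y) = 1 - \max_w \mathrm{CC}_w(x,y) / \sqrt{R_0(x,x) R_0(y,y)}\),
   centroid update by the shape-extraction eigenproblem, 100 restarts of at
   most 100 iterations, best run by minimal inertia (total squared SBD to
   the assigned centroid). Clusters with fewer than five beats are
   excluded.
6. **Templates.** Per cluster, the member with the smallest DTW distance
   to the centroid becomes the template; members at or above the cluster's
   90th-percentile DTW distance are excluded as outliers. An operator
   registers QRS onset and T end on each template (`register_fiducials()`
   consumes the resulting CSV).
7. **Fiducial transfer.** For each retained beat, a warping path between
   template and beat is computed by DTW under limited warping path length
   (LDTW) with `max_length` equal to the series length plus 10. When the
   path links a fiducial to several beat samples, the QRS onset takes the
   **latest** linked sample and the T end the **earliest** — the
   conservative choice that shortens, never stretches, a smeared QT.
8. **Measurement.** `QT = (t_end - qrs_onset)/fs × 1000` ms;
   `QTcB = QT / sqrt(RR_prev / 1000)` (Bazett, preceding RR in seconds).
9. **Agreement.** Against a reference delineation: Shrout–Fleiss ICC(2,1)
   with F-based 95 % CI, Bland–Altman bias and limits of agreement,
   Pearson r, and morphology-stratified mean ± SD difference tables
   (machine − reference).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| beat window | −120 / −80 | ms re R peaks | catches QRS onset with margin; ends before the next QRS |
| beat duration | 1600 | ms | fixed length for shape comparison; covers QT at any retained RR |
| RR gates | 300–2000, 70–130 % | ms, % | rate-correction validity and window stability |
| low-pass | 50/60, 3/40 | Hz, dB | removes muscle/powerline-range noise, preserves QRS slopes |
| k | 12 | – | morphology granularity vs per-template operator cost |
| n_init / max_iter | 100 / 100 | – | restart robustness of a non-convex clustering |
| min cluster size | 5 | beats | a template for < 5 beats is not worth operator time |
| outlier percentile | 90th | – | drops beats the template cannot represent |
| LDTW max_length | L + 10 | pairs | allows ~10 samples of elastic slack, forbids pathological stretches |
| pairing tolerance | 150 | ms | beat matching for evaluation only |

## Numerical choices

* **SBD denominator.** The normalized cross-correlation divides by
  \(\sqrt{R_0(x,x)R_0(y,y)}\). Without the square root the self-distance
  would not vanish and the metric would not be scale-consistent.
* **Sign-flip bound.** \(\mathrm{SBD} \in [0, 2]\), but
  \(\mathrm{SBD}(x, -x) = 1 + \min_k \mathrm{CC}_k(x,x)/R_0\): for
  realistic dense signals the lag-maximized value sits near 1, and the
  upper bound 2 is attained only at the zero lag (where the NCC of a sign
  flip is exactly −1) or for length-1 series. The tests assert exactly
  this.
* **Cross-correlation route.** FFT with zero padding to the next power of
  two for series longer than 64 samples, direct summation otherwise; both
  routes are tested to agree to 1e-9.
* **DTW convention.** Squared local cost, symmetric steps
  {(1,1),(1,0),(0,1)}, no slope weighting, reported distance
  \(\sqrt{\text{sum}}\). Ties between predecessors break diagonal, then
  vertical, then horizontal, so paths are deterministic.
* **LDTW solver.** Exact dynamic program over states (i, j, path length),
  O(m·n·max_length), iterated in path-length layers with byte-coded
  predecessors for backtracking (~65 MB at production sizes). A state
  (i, j) is feasible at length ℓ iff max(i,j)+1 ≤ ℓ ≤ i+j+1.
* **Shape extraction.** Members are aligned to the current centroid at
  their optimal SBD shift; the new centroid is the leading eigenvector of
  the centered Gram matrix \(Q S Q\), found by power iteration seeded at
  the current centroid (LAPACK `eigen` fallback on non-convergence), sign
  chosen to minimize SBD to the previous centroid, then z-normalized.
* **Empty clusters** are reseeded with the beat farthest from its own
  centroid (with a warning), so k never silently shrinks.
* **Percentile.** Linear interpolation between order statistics (R type
  7); the ≥ comparison is kept as stated, but all-equal clusters are
  exempt and exclusions are capped at ⌈10 % of cluster size⌉ so ties can
  never empty a cluster.
* **Ties in template selection and assignment** go to the lowest index;
  SBD shift ties prefer the smallest |shift|, negative first.
* **Degenerate inputs.** Constant beats cannot be z-normalized and are
  excluded with a warning; zero-energy series are rejected by `sbd()`;
  non-positive transferred QT flags the beat `invalid_qt`.

## Design choices where the design was open

* **Filter realization.** A zero-phase filter was required so fiducial
  timing is not shifted. With no IIR design infrastructure available, the
  filter is a linear-phase Kaiser-window FIR low-pass applied with exact
  integer group-delay compensation and edge replication — exactly zero
  phase by construction, and verified against the 3 dB / 40 dB template on
  pure tones. An equivalent forward–backward IIR would differ only inside
  the transition band.
* **Tail padding** interprets "interpolate the end portions with the
  average of the two endpoints" as constant padding with
  (first + last)/2 of the raw window; linear interpolation between the
  endpoints is a defensible alternative. Constant padding adds no spurious
  slope into the clustering window.
* **Bazett RR.** The preceding RR interval is used: it is the only RR the
  exclusion gates guarantee to lie in [300, 2000] ms, and preceding-RR is
  the common convention.
* **Outlier percentile scope** is per cluster (distances are computed from
  each centroid to its own members), not pooled.
* **Sub-seeding.** Restart r of the clustering uses `seed + r`; all other
  randomness flows through a single seeded generator, so every artifact is
  reproducible from one integer.
* **Channel choice** for two-channel records is a parameter (default
  channel 0); no default could be justified from first principles.

## The synthetic generator: what it emulates and what it does not

`generate_record()` builds beats as sums of Gaussian waves (P, Q, R, S, T)
with five T morphologies — normal, inverted, biphasic (two opposite-sign
lobes 60 ms apart), flat (≤ 0.05 mV) and tall (2× normal) — at jittered RR
intervals, with additive Gaussian noise and a smooth monotone per-beat time
warp. Defaults describe a desk-scale 15-minute Holter stand-in: 900 beats,
RR 1000 ± 40 ms, 0.05 mV noise, warp strength 1.2, 250 Hz, mixture 60/20/20
normal/inverted/biphasic. Because the model is analytic, every beat carries
exact ground-truth fiducials; the warp is applied identically to samples
and fiducials, and is pinned at the R peak because R-peak positions enter
the pipeline as exact annotations.

What a green test on this generator establishes: the geometry of the
method — segmentation arithmetic, metric identities, clustering recovery of
well-separated shapes, exactness of fiducial transfer under the identity
warp, and bounded error under bounded warps and noise. What it does **not**
establish: performance on real Holter data, with baseline wander,
electrode artifacts, arrhythmic beats, gradual morphology drift, or
T-waves whose end is genuinely ambiguous. Those claims require annotated
clinical recordings (see the `replicate-qtdb` stage, which runs the
pipeline over downloaded WFDB records given an explicit include-list) and
a human in the registration loop.

## Known limitations

* R-peak detection is out of scope; garbage R peaks give garbage windows.
* The manual registration step is the accuracy bottleneck by design: a
  mis-registered template biases every beat in its cluster.
* Beats whose morphology sits between two templates inherit whichever
  template their cluster won; with mixed-morphology clusters the
  transferred T end can be systematically off by a few samples (visible as
  a larger per-beat error spread in the mixed-morphology acceptance run
  than in the single-morphology one).
* The LDTW path-length budget (10 extra pairs) bounds how much elastic
  correction is available; beats displaced by more than ~10 samples of
  cumulative warp inside the QT region will be clipped toward the template
  timing.
* ICC confidence intervals assume the two-way random-effects normal ANOVA
  model; heavy-tailed disagreement makes them optimistic.
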