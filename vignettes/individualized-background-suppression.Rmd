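---
title: "Individualized ASL background suppression: models, optimizer and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized ASL background suppression: models, optimizer and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslbs)
```

# The problem

Arterial spin labeling (ASL) isolates perfusion as the difference between a
control and a label image; the difference is 1–2 % of the static tissue
signal.  Background suppression (BS) inversion pulses are timed so that
static tissue crosses its longitudinal null close to image readout, which
suppresses the physiological signal fluctuations that would otherwise leak
into the subtraction.  The timing depends on tissue T1, and gray matter T1
varies by roughly 10 % across adults.  `aslbs` estimates the subject's own
tissue T1 from a rapid two-flip-angle acquisition and re-times the pulses
for that subject, then quantifies the benefit on simulated data and on a
bundled 10-volunteer cohort table.

# Signal models

## Spoiled gradient echo and the two-point T1 fit

The steady-state spoiled gradient echo signal is
$$S(\alpha) = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1}.$$
With $y = S/\sin\alpha$ and $x = S/\tan\alpha$ this is the line
$y = E_1 x + M_0(1-E_1)$; two flip angles (defaults 9° and 20°, one
acquired as the ASL label condition and one as the control) give the slope
$E_1$ and hence $T_1 = -TR/\ln E_1$.  `fit_t1_vfa()` implements the
two-point solution; `fit_t1_vfa_nls()` is an independent per-voxel
nonlinear least-squares route kept purely as a cross-check (the two agree
to machine precision on noiseless data — one of the acceptance tests).

**Which TR?**  The protocol's sequence TR is 4000 ms, but the signal
equation's TR must be the *excitation repetition* time.  Implementing the
fit with TR = 4000 ms makes it noise-degenerate: $E_1 \approx 0.06$ for
gray matter, the two abscissae nearly coincide, and at 1 % noise a
Monte-Carlo gives a median gray matter T1 of ~2100 ms instead of 1443 ms
with half the voxels invalid.  The configuration therefore carries both
`tr` (4000 ms, the sequence TR, kept for provenance) and `tr_excitation`
(default 15 ms), and the simulator and fit operate at the latter.  At
15 ms and 1 % noise the median error is 0.03 % and the per-voxel
interquartile range ±3 %.

**Invalid-voxel policy.**  Non-finite or non-positive inputs, and slopes
outside (0, 1), mark a voxel invalid (`NA`); nothing is clipped to a T1
ceiling, because clipping would bias the whole-brain mean that drives the
timing.  The fit is symmetric in its two inputs, mirroring the empirical
finding that it does not matter whether the low flip angle is acquired as
label or control.

## Longitudinal Bloch dynamics and the timing optimizer

Between events the longitudinal magnetization relaxes as
$M_z(t) = M_0 + (M_z^+ - M_0)\,e^{-\Delta t/T_1}$; presaturation sets
$M_z(0) = 0$; an inversion pulse of efficiency $\eta$ maps
$M_z \to (1-2\eta)M_z$.  `mz_at_readout()` evaluates this closed-form
recursion; `mz_at_readout_euler()` is the validation oracle, a forward
Euler integration whose per-segment result is evaluated through the exact
algebra of the Euler recursion ($M_{z,n} = 1 + (M_{z,0}-1)(1-h/T_1)^n$) so
that a 0.01-ms step is affordable without a 10^7-iteration loop.

`optimize_schedule()` minimizes the weighted sum of squared normalized
residuals $\sum_i w_i (M_{z,i}(T)/M_0)^2$ over ordered pulse-time tuples in
$[0, T]$, $T$ = labeling duration + post-labeling delay (2000 + 1700 ms by
default).  The search is an exhaustive coarse grid (default 25 ms; tuples
above `max_candidates` raise an explicit error) followed by Nelder–Mead
refinement on the sorted, clamped times; grid ties break to the
lexicographically smallest tuple, so results are deterministic.  A
sum-of-squares objective (rather than max-abs) keeps the refinement
surface smooth; `metric = "maxabs"` is available.

Open choices resolved here:

* **Number of pulses**: default 2 (configurable 0–4).  Two pulses can null
  two target T1s essentially exactly (residuals ~10⁻¹⁰ M0 for the cohort
  means); more pulses trade suppression breadth against signal loss from
  imperfect inversion.
* **Optimization targets**: the subject's mean gray *and* white matter T1,
  equally weighted.  CSF is not targeted — with two pulses a third long-T1
  target cannot be nulled and only degrades the GM/WM nulls; any
  GM/WM-optimized schedule leaves a similar ~7 % CSF residual anyway.
* **The "routine fixed" schedule** is defined as the schedule optimized for
  literature T1s (GM 1300 ms, WM 850 ms at 3 T), since vendor timings are
  proprietary; both defaults are configurable.
* **Inversion efficiency** defaults to 1.0 (ideal pulses) and is a plain
  parameter in (0.5, 1].

# Tissue segmentation

The clinical pipeline uses anatomical-prior segmentation; `aslbs` replaces
it with intensity-only classification of the T1 map itself so the whole
chain is testable on phantoms (users with real data can supply their own
masks through the CLI).  Two methods:

* `gmm3`: a 3-component 1-D Gaussian mixture fitted by EM **on log T1**,
  initialized from the *exact* 1-D k-means partition computed by dynamic
  programming on a 512-bin histogram.  Log-space fitting matters: at low
  SNR the two-point fit produces heavy tails on both sides (slopes near 0
  or 1 give T1 estimates of 20 ms or 10⁵ ms), and on the raw scale those
  tails capture mixture components.  Components map to WM/GM/CSF by
  ascending mean.  Two guards, both standard practice and both
  configurable: voxels outside a physiologic `fit_range` (200–8000 ms) are
  treated as fit failures and left unassigned, and voxels whose fitted M0
  is below 10 % of the median (pure-noise voxels outside the head, which
  pass the slope test by chance) are excluded — the intensity-floor
  equivalent of brain masking.
* `fixed-windows`: assignment by T1 ranges (defaults WM 500–1100 ms,
  GM 1100–2000 ms, CSF 3000–8000 ms); voxels matching nothing stay
  unassigned.

`mean_tissue_t1()` is the arithmetic mean over mask ∧ valid; invalid
voxels never contribute.  A hard (binary) gray matter mask is assumed.

# The synthetic world

`make_phantom()` builds a concentric-geometry labeled volume (CSF core
standing in for the ventricles, white matter around it, a gray matter
shell as cortex; a `blocks` variant exists).  No anatomical realism is
attempted.  Defaults state the simulated world once:

| parameter | default | why |
|---|---|---|
| tissue T1 (GM/WM/CSF) | 1442.8 / 900.2 / 4042.9 ms | bundled cohort means at 3 T |
| M0 (GM/WM/CSF) | 0.8 / 0.7 / 1.0 a.u. | proton density relative to CSF |
| perfusion (GM/WM) | 0.012 / 0.004 a.u. | control−label difference of ~1.5 % / 0.6 % of M0, the intrinsic ASL contrast regime |
| voxel size | 3.6 × 3.6 × 4 mm | the protocol's readout resolution |
| labeling / PLD | 2000 / 1700 ms | protocol timing; readout at 3700 ms |
| flip angles | 9° / 20° | the modified label/control pair |
| `noise_sigma` | 0 | noise is opt-in, as in any simulator; tests use 1 % where noise is the point |
| `physio_noise` | 1 % | physiological fluctuation of the static signal |
| `n_repeats` | 20 | label/control pairs per simulated ASL run |

`simulate_asl_pair()` is the package's minimal mechanism for *why*
suppression helps: per repeat and condition the static signal
$m_0 \cdot M_z^{res}(T_1)$ is multiplied voxelwise by $1+\varepsilon$,
$\varepsilon \sim N(0, \texttt{physio\_noise})$, and the perfusion
difference is the phantom perfusion scaled by $(-\eta)^{n_{pulses}}$ (each
suppression pulse also inverts the label, hence the parity factor).
$\varepsilon$ is drawn **per voxel**: a spatially coherent fluctuation
would shift the whole background by a constant and leave any spatial-SD
quality metric blind to suppression, voiding the very mechanism the
simulation exists to exhibit.  This leakage model is an artifact of the
package, not an empirical physiological model.

`evaluate_perfusion()` reports the mean GM difference (also the relative
CBF readout, arbitrary units — no kinetic-model quantification), the SD
over a background region, and their ratio (SBR).  The background region is
caller-chosen; the *air* region is the documented default, but for judging
suppression quality the pipeline uses the **white matter mask**: air
carries no suppression-dependent signal, and CSF is excluded because
neither schedule targets its long T1, so its ~7 % residual would compare
the two schedules on an arbitrary quantity.  Zero background SD (the
noiseless perfect-suppression limit) flags SBR as infinite rather than
erroring.

# What a green test establishes — and what it does not

The end-to-end property exercised by the acceptance suite is: for subjects
whose gray matter T1 deviates by at least 10 % from the literature values
(deviation drawn uniformly from ±10–25 %, white matter deviating at 60 %
of the GM rate), the individually adapted schedule achieves an SBR at
least as high as the fixed schedule in ≥ 90 % of 50 seeded runs (observed:
50/50).  This establishes internal consistency of the method under the
stated generative model — piecewise-constant tissue, ideal inversion,
voxelwise multiplicative physiological noise.  It does **not** establish
the clinical effect size: real brains have partial-volume voxels, B1
inhomogeneity, motion, and spatially correlated physiology, none of which
are modeled, and the bundled rCBF magnitudes are scanner arbitrary units
that the simulation does not attempt to reproduce.  The reader-rating
outcome of the bundled study is reproduced only as an exact tally of the
shipped table.

# Numerical choices

* Additive Gaussian noise on magnitude signals (not Rician); at the
  simulated SNR the distinction is negligible and it keeps every
  expectation exact.
* Wilcoxon signed-rank: zero differences dropped, midranks for ties, and
  the exact null distribution enumerated over all $2^n$ sign assignments
  ($n \le 20$) via subset-sum doubling on doubled ranks; two-sided
  $p = \min(1,\, 2\min(P(V \le v), P(V \ge v)))$, matching the classical
  exact tables ($n = 10$, one-signed differences → $p = 2/1024$).
* Table statistics use the sample (n−1) standard deviation; the bundled
  tables reproduce their printed means/SDs at one decimal.  (The source
  study's in-text deviation percentages, 12.4 %/6.6 %, equal neither
  sd/mean of its own table at printed precision — 12.5 %/6.7 % — and are
  not targeted.)
* Determinism: every stochastic step is seeded; the EM initialization is
  deterministic (the `seed` argument of `segment_t1()` is accepted but not
  consumed); pipeline reports exclude wall-clock data and are
  byte-identical across reruns, stamped with an FNV-1a hash of the
  canonical-JSON configuration.
* NIfTI-1 I/O is implemented in-package (little-endian single-file,
  common scalar datatypes, sform RAS+ from the voxel size) because no
  NIfTI-capable R package is available in the target environment; it is
  deliberately not a general NIfTI library.

# Known limitations

* No B1+ correction, slice-profile or more-than-two-angle fitting.
* No RF pulse design, no blood-magnetization trajectory optimization, no
  labeling-train interaction: pulses may be placed anywhere in
  $[0, T]$.
* Segmentation is intensity-only; subjects with pathology would need
  user-supplied masks.
* Absolute CBF quantification is out of scope; all perfusion readouts are
  relative.
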