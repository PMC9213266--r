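# aslbs — individualized background suppression timing for ASL MRI

Arterial spin labeling (ASL) measures brain perfusion from the difference
between a *label* image (arterial blood magnetically inverted at the neck)
and a *control* image.  That difference is only 1–2 % of the static tissue
signal, so ASL sequences apply **background suppression (BS)**: nonselective
inversion pulses timed so that the longitudinal magnetization of static
tissue is near zero at readout.  Conventionally the pulse times are computed
from *literature* T1 values, although gray matter T1 varies by ~10 %
between subjects.

`aslbs` implements the full individualization pipeline for researchers
working on ASL protocol optimization:

1. **Rapid T1 mapping** from a two-flip-angle spoiled-gradient-echo pair
   embedded in the ASL scan (variable flip angle / DESPOT1):
   `S = M0 sin α (1 − E1)/(1 − E1 cos α)`, `E1 = exp(−TR/T1)`, linearized
   as `S/sin α = E1 · S/tan α + M0(1 − E1)` — `fit_t1_vfa()`, with an
   independent nonlinear cross-check `fit_t1_vfa_nls()`.
2. **Tissue segmentation** of the T1 map (GM/WM/CSF) by a deterministic
   3-component Gaussian mixture or fixed T1 windows — `segment_t1()`,
   `mean_tissue_t1()`.
3. **Bloch simulation and timing optimization**: between events
   `Mz(t) = M0 + (Mz⁺ − M0) e^{−Δt/T1}`, presaturation sets `Mz(0) = 0`,
   each pulse maps `Mz → (1 − 2η) Mz`; pulse times minimize
   `Σᵢ wᵢ (Mzᵢ(T)/M0)²` over the subject's tissue T1s by grid search plus
   local refinement — `mz_at_readout()`, `optimize_schedule()`,
   `compare_schedules()`.
4. **Digital phantom & ASL simulator** so every stage is testable without
   scanner data — `make_phantom()`, `simulate_spgr()`,
   `simulate_asl_pair()`, `evaluate_perfusion()`.
5. **Cohort statistics**: exact (full-enumeration) Wilcoxon signed-rank
   test, table summaries, reader-rating tallies — bundled with the
   per-volunteer tables of a 10-subject 3-T study.

Minimal NIfTI-1 I/O (`read_nifti()`/`write_nifti()`) and a CLI
(`inst/cli/aslbs.R`) are included.

## Worked example

```r
library(aslbs)

# Pulse timing for the bundled cohort-mean T1s (GM 1442.8 ms, WM 900.2 ms),
# 2000 ms labeling + 1700 ms post-labeling delay:
opt <- optimize_schedule(2, c(1442.8, 900.2))
opt$schedule
#> BS schedule: 2 pulse(s) at [1885.6, 3277.0] ms, readout 3700 ms, eta 1, presaturated
opt$result
#> Residual Mz at readout (fraction of M0), objective (sumsq) = 6.76e-20
#>     1442.8      900.2
#> -1.471e-10  2.143e-10
```

Both target tissues are nulled to ~1e−10 of M0.  A fixed schedule computed
from literature values (GM 1300 ms, WM 850 ms) leaves ~1 % of M0 unsuppressed
on this subject:

```r
fixed <- optimize_schedule(2, c(1300, 850))$schedule
compare_schedules(fixed, opt$schedule, c(1442.8, 900.2))$residual_fixed
#> [1]  0.009862421 -0.005512357
```

The bundled cohort shows the perfusion gain was systematic — every one of
the 10 volunteers had higher gray matter rCBF with the adapted timing:

```r
tab <- cohort_rcbf_table()
wilcoxon_signed_rank_exact(tab$rcbf_regular, tab$rcbf_adaptive)
#> Exact Wilcoxon signed-rank: W = 0 (n = 10), two-sided p = 0.0019531
```

End-to-end on a synthetic subject (phantom → T1 fit → segmentation →
schedule optimization → suppressed ASL simulation → quality report):

```r
res <- run_pipeline(pipeline_config(seed = 1),
                    subject_t1 = c(gm = 1823, wm = 974, csf = 4030))
res$mean_gm_t1   # estimated from the simulated two-angle scan: 1826.6 ms
res$sbr_ratio    # adapted / fixed signal-to-background ratio: >> 1
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/aslbs.R", package = "aslbs"))')
Rscript $CLI simulate --shape 32,32,16 --noise 0.01 --seed 1 --out sim/
Rscript $CLI fit-t1 --low sim/spgr_low.nii.gz --high sim/spgr_high.nii.gz --out t1map.nii.gz
Rscript $CLI segment --t1map t1map.nii.gz --out masks/
Rscript $CLI optimize-bs --t1 1442.8,900.2 --n-pulses 2 --out schedule.json
TAB=$(Rscript -e 'cat(system.file("extdata/cohort_rcbf.csv", package = "aslbs"))')
Rscript $CLI stats --paired $TAB --a rcbf_regular --b rcbf_adaptive
```

Exit codes: 0 success, 2 parameter error, 3 data/structural error.

## Documentation

The methods vignette
(`vignettes/individualized-background-suppression.Rmd`) describes the
signal models, the optimizer, the synthetic data generator and all
numerical design choices in detail.
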