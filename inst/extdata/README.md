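# Bundled cohort fixtures

Per-volunteer measurements from a 10-subject healthy-volunteer 3-T study of
individualized ASL background suppression, transcribed as printed:

- `cohort_t1.csv` — whole-brain mean GM/WM/CSF T1 (ms) per volunteer, from
  the two-flip-angle mapping scan. CSF values may be inaccurate given the
  long relaxation times.
- `cohort_rcbf.csv` — mean gray matter relative CBF (arbitrary scanner
  units) under the routine fixed and the individually adapted suppression
  timing.
- `reader_ratings.csv` — blinded 3-point ratings (-1 original better,
  0 equal, 1 modified better) of two neuroradiologists in three categories.

These are in-study measurements, not synthetic data; the package's own
simulations never use them as ground truth.
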