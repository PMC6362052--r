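# segepi

Simulation and group analysis of **segmented (multishot) vs single-shot
echo-planar imaging** for rodent resting-state fMRI.

## The problem

EPI acquires a whole image (or image segment) after one excitation through
a long train of gradient echoes. Along the phase-encode (PE) direction the
per-pixel bandwidth is only `1/(ETL × echo spacing)` (ETL = echo train
length), so static-field off-resonance Δf — hundreds of Hz near the air
cavities of a rodent head at high field — displaces tissue by
`Δf / bw_pe` voxels, distorting geometry and destroying signal exactly
where the deep nuclei (amygdala, hypothalamus, VTA, accumbens) sit.
Segmenting k-space over `NSHOTS` excitations shortens the echo train and
multiplies the PE bandwidth by `NSHOTS`: a 4-shot protocol suffers exactly
one quarter of the single-shot displacement, at the price of a longer
volume TR, stronger T1 saturation and sensitivity to inter-shot
instability.

`segepi` implements the full quantitative comparison between the two
protocols as a verifiable pipeline driven by a digital phantom:

* **EPI physics generator** — ellipsoidal rat-head phantom with cortical /
  subcortical parcels and air cavities; Gaussian off-resonance field;
  Ernst steady-state signal; PE displacement with Jacobian intensity
  modulation; TE-governed and through-readout dephasing dropout;
  band-limited BOLD networks; thermal, physiological and inter-shot noise;
  motion spikes.
* **Preprocessing** — 12-confound regression, 0.01–0.1 Hz band-pass,
  DVARS, IQR censoring.
* **Quality metrics** — ROI SNR, voxelwise tSNR, and group comparison by
  two-sample t → TFCE → max-statistic permutation FWE.
* **Distortion metrics** — Dice overlap of brain masks, Jacobian
  determinants of the known inverse-distortion warp, field-map dewarping.
* **Networks** — spatial fixed-point ICA (subject level and temporally
  concatenated group level), rule-based component classification,
  non-aggressive denoising, dual regression, per-component arm comparison.
* **Connectome** — atlas parcellation, 2:1 boxcar rate matching, clipped
  Fisher-z adjacency matrices, edge-wise one-sample-t "robustness"
  z-statistics, stratified paired Wilcoxon arm comparison, and
  noncentral-t sample-size analysis (`n` s.t. a two-sided one-sample t at
  level α reaches the target power for effect d = mean/SD).

## A worked example

```r
library(segepi)

seq_params_ms()
#> EPI protocol: TR 500 ms x 4 shot(s), TE 17 ms, flip 60 deg
#>   matrix 96x96x16, FOV 35x35x16 mm, PPI 2, ETL 12, NREP 900
#>   volume TR 2 s, acquisition 30.0 min

# displacement physics: one quarter of the shift under 4 shots
ph <- make_phantom(c(48, 48, 12), 6, 6, seed = 11)
fm <- make_fieldmap(ph, peak_hz = 450, width_mm = 3.5)
ss <- seq_params_ss(matrix = c(48, 48, 12), n_rep = 240)
ms <- seq_params_ms(matrix = c(48, 48, 12), n_rep = 120)
max(pe_displacement(fm, ss)$shift_vox) /
  max(pe_displacement(fm, ms)$shift_vox)
#> [1] 4

# sample size for a one-sample t test at alpha = 0.05, power 0.8
required_sample_size(d = 0.5)
#> [1] 34
required_sample_size(d = 1.0)
#> [1] 10

# the full two-arm experiment at desk scale (~1 min, one CPU)
rep <- run_experiment(default_experiment_config(),
                      stages = c("qc", "spatial", "connectome"))
rep$connectome$tests[, c("stratum", "p_two_sided", "ratio_a", "ratio_b")]
#>       stratum  p_two_sided   ratio_a   ratio_b
#> 1         all 7.547958e-11 0.8313497 0.5834195
#> 2    cortical 3.128227e-01 1.1086794 1.0081313
#> 3 subcortical 2.527986e-11 0.7381297 0.4429924
```

The table reads: across matched edges, the Fisher-z consistency
z-statistics of the 4-shot arm are right-shifted relative to single-shot
in the subcortical stratum (paired Wilcoxon p ≈ 3e-11; consistency ratio
0.74 vs 0.44) while the cortical stratum does not differ (p ≈ 0.31) —
segmentation recovers group-level connectivity statistics precisely in the
susceptibility-affected deep gray matter. The same report carries the
tSNR comparison (suprathreshold voxels confined to subcortical parcels),
Dice overlap and Jacobian tail masses.

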