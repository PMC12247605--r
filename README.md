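# dkiprep

Artifact correction and tensor estimation for clinical multi-shell
diffusion MRI, with ground-truth simulators for validating every step.

Clinical diffusion MRI is acquired fast and noisy: thermal noise biases the
magnitude signal (the Rician noise floor), finite and partial-Fourier
k-space sampling leaves Gibbs ringing at high-contrast edges, and two-series
protocols carry inter-series intensity offsets. All of that propagates into
diffusion tensor (DTI) and diffusion kurtosis (DKI) parameter maps as bias
and as physically impossible voxels (negative diffusivity, FA above 1,
kurtosis below −2). `dkiprep` implements the correction chain that targets
these artifacts, for researchers processing multi-shell dMRI or studying
the preprocessing steps themselves:

- **MPPCA denoising** — per-voxel patches (a local 5×5×5 box, or an
  adaptive bilateral selection of the 100 most similar voxels), with the
  number of signal components and the noise level σ estimated from the
  Marchenko–Pastur spectrum of the patch Casorati matrix; either hard
  truncation or optimal Frobenius singular-value shrinkage
  (`denoise_volume()`).
- **Rician bias correction** — method of moments,
  `sqrt(max(M² − σ², 0))`, using the denoiser's noise map
  (`rician_bias_correct()`).
- **Gibbs-ringing removal** — subvoxel shifts minimizing local total
  variation (`sushi_unring()`), extended to 6/8 and 7/8 partial-Fourier
  zero-filled reconstructions by a second pass on a resampled grid that
  maps the partial-Fourier ringing frequency onto Nyquist
  (`rpg_unring()`).
- **Two-series b0 normalization** (`b0_normalize()`) and CSF-excluded
  Gaussian smoothing as a comparison condition
  (`gaussian_smooth_csf_excluded()`).
- **WLLS DTI/DKI fitting** — two-pass weighted linear least squares on
  log-signals for the 22-parameter kurtosis model
  `ln S = ln S0 − b D(n) + (b²/6) MD² W(n)`, scalar maps MD/AD/RD/FA and
  MK/AK/RK, and physical-bounds outlier accounting (`wlls_fit()`,
  `scalar_maps()`, `outlier_stats()`).
- **Ground-truth phantoms and benchmarks** — a multi-shell brain-like noise
  phantom with the clinical protocol (5 b0, b = 250/1000/2000 s/mm² with
  4/20/60 directions) and Rician noise at controlled SNR
  (`make_multishell_phantom()`, `add_rician_noise()`); a Shepp-Logan
  diffusion phantom with simulated k-space truncation and partial-Fourier
  ringing (`make_shepp_logan_dmri()`); benchmark drivers reproducing the
  denoising and Gibbs comparisons (`run_denoise_benchmark()`,
  `run_gibbs_benchmark()`); and a quadratic age-association fitter
  (`quadratic_age_fit()`).
- **Pipeline orchestration** — `run_pipeline()` with presets `none`, `em`,
  `em-smooth`, `dv1` (local patch + plain subvoxel shifts), `dv2` (adaptive
  patch + shrinkage + partial-Fourier-aware Gibbs removal), enforcing the
  canonical step order and writing a JSON provenance report. External
  EPI-distortion/eddy/motion tools are integrated through a function hook,
  not reimplemented.

The methods vignette (`vignettes/preprocessing-methods.Rmd`) documents the
models, the estimators, all tunable parameters and the numerical choices.

## Worked example

Denoise a noisy phantom at SNR 20, correct the Rician bias, fit DKI, and
count physically implausible voxels in white matter:

```r
library(dkiprep)
ph    <- make_multishell_phantom()                     # 64 x 64 x 16 truth
noisy <- add_rician_noise(ph, noise_model(snr = 20, seed = 1))

dn   <- denoise_volume(noisy, patch_spec("adaptive"), shrink = TRUE)
corr <- rician_bias_correct(dn$denoised, dn$sigma_map)
maps <- scalar_maps(wlls_fit(corr))

median(dn$sigma_map[ph$wm_mask])          # estimated noise level
outlier_stats(scalar_maps(wlls_fit(noisy)), ph$wm_mask)$average
outlier_stats(maps, ph$wm_mask)$average
```

```
#> [1] 47.77834
#> [1] 0.3919861
#> [1] 0
```

The true σ here is 50 (WM b0 signal 1000 at SNR 20), so the noise map is
on target; denoising plus Rician correction removes the physically
implausible voxels that the raw fit produces (0.39% of WM on average
across the seven maps, mostly radial-kurtosis values below −2). The full
condition-by-condition comparison across SNR 10–60 is one call:
`run_denoise_benchmark()`.

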