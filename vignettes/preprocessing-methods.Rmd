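---
title: "Artifact correction and tensor estimation for multi-shell diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact correction and tensor estimation for multi-shell diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkiprep)
```

# Scope

`dkiprep` implements the artifact-correction chain used for clinical
multi-shell diffusion MRI — noise removal, Gibbs-ringing removal, intensity
harmonization, Rician bias correction — followed by diffusion tensor (DTI)
and diffusion kurtosis (DKI) estimation, together with ground-truth phantom
generators and a quantitative evaluation harness. The canonical step order
is: (a) MPPCA denoising with an adaptive patch and singular-value
shrinkage, (b) Gibbs removal (partial-Fourier aware), (c) a hook where
external EPI-distortion / eddy-current / motion tools run, (d) two-series
b0 normalization, (e) Rician bias correction, then the weighted
least-squares fit. EPI-distortion, eddy and motion correction themselves
are deliberately out of scope: established external tools do that work,
and `run_pipeline()` only exposes a function hook for them.

# The signal model

For a gradient direction $n$ and diffusion weighting $b$ (internally in
ms/µm² so diffusivities come out in µm²/ms), the log-signal is modeled as

$$\ln S(b, n) = \ln S_0 - b\, D(n) + \tfrac{b^2}{6}\, V(n), \qquad
V(n) = \mathrm{MD}^2 \sum_{ijkl} n_i n_j n_k n_l W_{ijkl},$$

with $D(n) = \sum_{ij} n_i n_j D_{ij}$. The 22 coefficients
($\ln S_0$, 6 tensor elements in the order xx, xy, xz, yy, yz, zz, and 15
kurtosis elements in lexicographic order) are estimated by two-pass
weighted linear least squares: an unweighted solve predicts the signals,
and the second pass weights each measurement by its squared predicted
signal. The kurtosis block is fitted in the $\mathrm{MD}^2 W$
parameterization, so the apparent kurtosis along $n$ is simply
$K(n) = V(n)/D(n)^2$ with no rescaling. Signals are floored at
$10^{-8}\times$ the voxel's mean b = 0 signal before the log; no positivity
constraints and no outlier rejection are applied during fitting — voxels
that go unphysical are deliberately left for the outlier statistic, which
counts values violating $D > 0$, $0 < \mathrm{FA} < 1$, $K > -2$.

Scalar maps come from the tensor eigensystem (eigenvalues descending): MD,
AD $= \lambda_1$, RD $= (\lambda_2+\lambda_3)/2$, FA by the standard closed
form; AK analytically along the principal axis; RK as the mean apparent
kurtosis over 64 equally spaced directions in the radial plane (a periodic
trapezoid rule, which converges exponentially for the smooth integrand);
and MK as the average over a 512-point spherical product quadrature
(16 Gauss–Legendre nodes in $\cos\theta$ × 32 azimuths). The product rule
was chosen over a similarly sized lattice because it integrates the smooth
$K(n)$ to ~$10^{-8}$ for physiological tensors, which keeps all scalar
maps equivariant under joint rotation of the gradient table and the object
— a property the test suite checks explicitly. For isotropic kurtosis the
quadrature is exact, which anchors the documented $10^{-3}$ MK tolerance.

# MPPCA denoising and eigenvalue shrinkage

Each voxel is denoised from the Casorati matrix $X$ (patch voxels ×
volumes) of its patch. With $M$ patch voxels, $N$ volumes and eigenvalues
$\lambda_1 \ge \dots \ge \lambda_N$ of $X^\top X / M$, the number of signal
components $P$ is the smallest leading count such that the trailing
eigenvalues are consistent with a pure-noise Marchenko–Pastur bulk: their
mean estimates $\hat\sigma^2$ and the next eigenvalue must fall below the
bulk edge $\hat\sigma^2 (1 + \sqrt{(N-P)/M})^2$. Hard truncation keeps the
top $P$ components. With shrinkage enabled, every singular value is instead
passed through the optimal Frobenius-loss shrinker at aspect
$\beta = N/M$: normalized singular values $y = s/(\hat\sigma\sqrt{M})$ map
to $0$ inside the bulk ($y \le 1+\sqrt\beta$) and to
$\sqrt{(y^2-\beta-1)^2 - 4\beta}\,/\,y$ above it.

Patch selection has two modes. The local mode uses a fixed 5×5×5 box. The
adaptive mode ranks all in-mask voxels within a half-width-7 search window
by an equally weighted bilateral score — spatial distance and mean absolute
signal difference over all volumes, each normalized by its in-window
maximum, ties broken by linear voxel index — and keeps the best 100. The
paper trail for this method states the two ranking criteria and the patch
size but not the weights or window; equal weights and half-width 7 are this
package's documented defaults. Each voxel's output is taken from the patch
centered on it (center-voxel writeback), which matches the adaptive-patch
semantics where every voxel owns a patch. The per-patch eigendecompositions
run in single precision — the estimator is statistical and this keeps a
64×64×16×89 volume within tens of seconds on one core — with an exact
identity short-circuit when the patch is noise-free.

Rician bias correction is the method-of-moments magnitude correction
$\sqrt{\max(M^2 - \hat\sigma^2, 0)}$ using the denoiser's noise map,
applied after denoising (and after b0 normalization in the full pipeline).
At zero underlying signal this reduces the expected squared magnitude from
$2\sigma^2$ to $2e^{-1/2}\sigma^2 \approx 1.21\sigma^2$ — not all the way
to $\sigma^2$, because the truncation at zero keeps the correction from
overshooting; the test suite freezes the analytic value.

# Gibbs-ringing removal

The subvoxel-shift corrector re-interpolates each line at the shift (out of
41 spanning ±½ voxel) that minimizes a one-sided total-variation measure
over the [k1, k2] = [1, 3] neighbor band, excluding the pair touching the
center sample; shifts are visited by increasing magnitude so the zero shift
wins ties and flat lines pass through untouched. The two in-plane axis
passes act on the complementary pair of spectrally weighted images, so each
pass only sees ringing oriented along its own axis. 3D and 4D inputs are
processed slice-wise in the plane spanned by the phase- and
frequency-encode axes.

One design choice departs from per-volume processing: the optimal shift
field is estimated once per slice from the TV measures summed over all
volumes, then applied to every volume. The ringing geometry is set by the
anatomy, which all diffusion volumes share; estimating shifts per volume
injects small cross-volume inconsistencies that the kurtosis fit reads as
curvature error, visibly biasing MK/RK in benchmark maps.

Zero-filled partial-Fourier reconstruction adds a second, lower-frequency
ringing: with fraction $p$ acquired, the asymmetric cutoff sits at
$(2p-1)\pi$, i.e. period 4 voxels for 6/8 and 8/3 voxels for 7/8. The
partial-Fourier corrector therefore runs a second pass on a grid whose
spacing maps that frequency onto Nyquist: for 6/8 the two
parity-interleaved subgrids along the phase-encode axis (spacing 2); for
7/8 a sinc ×3 upsampling followed by decimation by 4 (spacing 4/3), with
sinc resampling back. Only the phase-encode-oriented part of each image is
corrected in this pass, and the resulting correction is band-passed to the
frequencies just above the partial-Fourier cutoff, which is where that
ringing lives — the resampled pass's out-of-band interpolation noise is
discarded. A 5/8 fraction is rejected: at spacing 4 the correction smooths
far too aggressively to be useful. Two properties worth knowing: sharp
region boundaries keep being re-interpolated on repeated passes (the
filter split redistributes the edge each time), so the corrector is not
strictly idempotent at edges — successive changes decay but do not vanish
— and the image mean can move by up to ~0.15% through edge interpolation.

# Phantoms

Two generators define the simulation conditions.

The multi-shell noise phantom (default 64×64×16 at 2.5 mm, chosen as a
desk-scale version of a whole-brain matrix) is a brain-like label field:
central CSF, surrounding GM, and four thin white-matter tracts of varying
orientation — a commissural slab bordering the ventricle, two association
slabs, and a projection column — each only a few voxels thick, as real
tracts are at this resolution. Tracts are built from ~2-voxel blocks whose
fiber axis fans by ±15–25° along the tract; on top of that, tissue
parameters carry a smooth deterministic modulation (5–12%, gyral-scale
wavelengths) plus an independent per-voxel perturbation (3–8%, a few
degrees of orientation dither, from a fixed seed), and white-matter voxels
bordering the ventricle form a faster, less anisotropic peri-ventricular
rim, as partial volume produces in vivo. The texture matters: with
perfectly constant regions, patch matrices become exactly low-rank and
MPPCA denoising becomes essentially exact — unlike any real acquisition.
Every voxel is still an exact forward-model region (truth signal = DKI
model of its own parameters to machine precision, recorded in
`coef_true`), so truth maps and fits share one parameterization.
Region values (WM: $\lambda_\parallel \approx 1.7$,
$\lambda_\perp \approx 0.45$ µm²/ms, $K_\parallel \approx 0.7$,
$K_\perp \approx 1.8$; GM: 0.95 µm²/ms, K 0.8; CSF: 3.0 µm²/ms, K 0) are
literature-plausible for in-vivo brain at 3 T. The default protocol is the
clinical scheme: 5 b0, b = 250 s/mm² × 4, b = 1000 × 20, b = 2000 × 60
directions on deterministic golden-angle spirals.

Noise is added as
$S_m = \sqrt{(S_r + \sigma\epsilon_1)^2 + (\sigma\epsilon_2)^2}$ with
independent standard normal draws — a Rician magnitude with the imaginary
truth component zero. One global $\sigma$ is set from the target SNR as
(mean WM b0 signal)/SNR; the supported grid is SNR ∈ {10, 15, 20, 25, 30,
60}. Realizations are reproducible from integer seeds and leave the global
RNG untouched.

What this phantom does *not* emulate: spatially smooth parameter fields
(regions are blockwise constant), susceptibility/eddy/motion effects,
multi-coil noise correlation, or spatially varying noise. Passing
benchmarks here therefore demonstrates the correctness and the relative
ordering of the correction steps under controlled conditions, not absolute
in-vivo error levels.

The Gibbs phantom renders the classic ellipse head model (with per-ellipse
DKI parameters: an anisotropic bright rim, WM-like bulk with through-plane
axis, CSF-like ventricles and cistern, and small high-contrast features) at
4× resolution per volume, truncates k-space centrally to 128×128, zero
fills the negative-frequency side of the horizontal axis to the requested
partial-Fourier fraction, and returns the magnitude image alongside the
sharply rendered truth. Four rectangular ROIs are drawn, in fixed phantom
coordinates, where the uncorrected parameter-error maps show the strongest
partial-Fourier ringing: three tiling the band flanking the right lateral
high-contrast boundary and one at the left boundary, each offset from the
boundary voxels themselves. (Ringing strength is left/right asymmetric
because the zero-filled side of k-space is one-sided.)

# Evaluation harness

Percentage-error maps are signed, $100(\hat\theta - \theta)/\theta$, with
zero-truth voxels flagged invalid. Aggregation across noise realizations
uses the voxelwise median — not the mean — so that a single outlier
realization cannot dominate a low-SNR map; the reported ROI value is the
median over ROI voxels of that median map. Outlier percentages count
bound violations (non-finite fits count as violations) per map, plus the
average across the seven maps. The smoothing comparator is CSF-excluded
normalized masked convolution with FWHM = 1.2 × voxel size
($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$, truncated at 4σ): CSF voxels
neither contribute weight nor receive smoothed values. The two-series b0
normalization scales the second series by the ratio of the two smoothed
mean b0 images; the kernel is interpreted as an isotropic 3 mm standard
deviation truncated at 4σ (the source description of that kernel is
ambiguous between width and truncation, so the choice is surfaced as an
argument). The quadratic age-association fitter returns the OLS quadratic,
adjusted R², the model-vs-intercept F-test p-value, a ×28 Bonferroni
correction (7 parameters × 4 ROIs, capped at 1), and a vertex
classification: concave/convex with the inflection age when the vertex
falls inside the fitted age range, otherwise monotone.

`run_denoise_benchmark()` reproduces the simulation comparisons: conditions
`none`, `smooth`, `dv1` (local patch + Rician), `dv2` (adaptive + shrinkage
+ Rician), `dv2_noshrink`, `dv2_norician`, over the SNR grid with fixed
per-realization seeds. The three adaptive variants share one spectral
decomposition per realization, which keeps the with/without-shrinkage
comparison a paired one. `run_gibbs_benchmark()` compares `none` / `sushi`
/ `rpg` on the ringing phantom by mean |% error| per ROI and scalar, with
no noise added, so it is fully deterministic.

# Numerical and scale choices

Problem sizes were chosen so the full acceptance computation runs on one
desk core: the outlier comparison uses the 64×64×16 phantom with 50
realizations at SNR 20 (the condition count the simulations specify); the
MD-robustness sweep uses 11 realizations per SNR level, enough for a
stable voxelwise median; the test suite's benchmark checks run the same
64×64×16 phantom with 5 realizations per SNR, and unit tests use reduced
grids (16–24 voxels per side). Degenerate inputs are
handled conservatively: empty masks and non-finite images are errors;
fewer than 8 volumes triggers a reliability warning from the noise
estimator; rank-deficient per-voxel systems flag the voxel rather than
aborting the fit; a noise-free patch short-circuits to the identity.

# Known limitations

The external-tool hook is a pass-through: no distortion, eddy or motion
simulation or correction is provided. The Gibbs corrector assumes
zero-filled reconstruction (no homodyne/POCS) and corrects in image space.
Because every phantom voxel is an exact forward-model realization, the
patch-based denoiser compresses the phantom better than it compresses
measured data (whose reference maps carry embedded measurement noise that
no low-rank patch model can represent); absolute error levels and
residual-outlier percentages after denoising are therefore optimistic —
typically zero at SNR ≥ 20 — and orderings between conditions, not
absolute magnitudes, are the meaningful output of the noise benchmarks. Kurtosis scalars use numerical direction
averages with the documented quadrature tolerances rather than the
analytic closed forms.
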