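---
title: "Methods: linking DCE-MRI perfusion parameters to SPECT radiopeptide uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking DCE-MRI perfusion parameters to SPECT radiopeptide uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Radiolabeled somatostatin analogs (e.g. ^111^In-labeled octreotide) image and
treat neuroendocrine tumors, but their uptake is often strikingly
heterogeneous even when receptor expression is homogeneous. If that
heterogeneity is governed by vascular physiology — perfusion, vessel density,
capillary permeability — then DCE-MRI, which quantifies exactly those
properties, should spatially predict uptake. `dcespect` implements the full
analysis needed to test this voxel by voxel: DCE-MRI quantification
(semi-quantitative curve features and the standard Tofts compartment model),
mask-based registration between the MRI and SPECT-CT frames, and spatial
correlation statistics; plus a synthetic phantom that generates complete
studies with the statistical structure this analysis assumes, because the
original in-vivo datasets are not publicly deposited.

## Signal model and relaxometry

The pre-contrast T1 map is fitted per voxel from variable-TR, 90° flip
saturation-recovery calibration images,

$$S(TR) = S_0\,(1 - e^{-TR/T_1}),$$

with $S_0$ profiled out in closed form (the model is linear in it) and $T_1$
located by a log-spaced grid search over 50–5000 ms plus local refinement.
Voxels with all-zero signal, non-positive $S_0$, or a boundary solution (no
recovery curvature, e.g. constant signal) are flagged `fit_ok = FALSE`.

The dynamic series (TR 3.4 ms, 10° flip) uses the spoiled gradient-echo
steady state

$$S = M \sin\alpha\,\frac{1 - E_1}{1 - \cos\alpha\, E_1},\qquad
E_1 = e^{-TR \cdot R_1},$$

with the linear relaxivity model $R_1(t) = 1/T_{10} + r_1 C(t)$. The scale
$M$ is calibrated per voxel from the mean of the pre-contrast baseline frames
together with the fitted $T_{10}$, so the inversion to concentration needs no
absolute signal units. Frames whose signal leaves the invertible SPGR range
are marked missing; concentrations are floored at −0.05 mM (noise allowance)
and residual negatives set to zero. Choices the acquisition description does
not pin down, made once here: saturation-recovery for the 90° calibration
scans and SPGR for the dynamic series (they match the stated sequences);
$r_1 = 4.5\ \mathrm{mM^{-1}s^{-1}}$ (gadobutrol-class literature value; the
study names the agent but no relaxivity); baseline window = all frames before
the configured arrival for phantom data, first five frames otherwise; TE
effects neglected (TE = 1 ms).

## Semi-quantitative features

Six features of the enhancement curve $e(t) = S(t) - S_{\text{baseline}}$:
maximum enhancement (Smax), time-to-peak (TTP, referenced to the first
post-baseline frame; the first maximum wins ties), trapezoid areas AUC
(whole curve) and AUC60 (first 60 s, last sub-interval linearly
interpolated, window anchored at bolus start), wash-in (slope between the
first upward 10% and 90% crossings of Smax, linearly interpolated), and
wash-out (slope from the peak to the final time point, undefined when the
peak is the final frame). Enhancement is the absolute difference from
baseline, not a ratio — per-dataset min-max normalization
$x_{norm} = (x - x_{min})/(x_{max} - x_{min})$ removes the arbitrary MRI
scale anyway. TTP is never inverted in the statistics (the source analysis
inverted it only for display), so its correlations with uptake are expected
negative; reports carry $|\rho|$ alongside $\rho$.

## Pharmacokinetics

The standard (not extended) Tofts model,

$$C_t(t) = K^{trans} \int_0^t C_p(\tau)\, e^{-k_{ep}(t-\tau)}\, d\tau,$$

with a bi-exponential plasma input fitted per dataset to the averaged
femoral-artery concentration curve:
$C_p(t) = a_1 e^{-m_1 (t-t_0)} + a_2 e^{-m_2 (t-t_0)}$ for $t \ge t_0$,
arrival $t_0$ estimated as the first sample above 10% of the curve maximum,
log-parameterized multi-start least squares, terms ordered $m_1 > m_2$. For
this input the convolution has a closed form (differences of exponentials,
with the $(t-\tau)$-type limit when $k_{ep}$ meets a decay rate), evaluated
in a numerically stable `expm1`-based form and exercised against a
Romberg-refined trapezoid convolution in the tests. Per-voxel fitting is
bounded least squares on $(K^{trans}, k_{ep}) \in [0,1]^2\ \mathrm{s^{-1}}$
with analytic gradients and three multi-starts; ties break toward lower RSS,
then lower $K^{trans}$. The model is evaluated on the true non-uniform time
grid — no interpolation across the 60 s inter-acquisition gap.

Voxels with essentially no enhancement fit the Tofts model badly and can
return non-physiological values; they are zeroed ("gated"). A voxel is gated
when its unnormalized Smax falls below 8% of the robust (98th percentile)
in-mask Smax. The source text gives no number; 5% was the natural first
choice, but Smax is a maximum over 96 noisy frames, and its noise floor sits
near $4\sigma$ — measured against the phantom, a 5% gate (≈4σ) misses one or
two truly-zero voxels per dataset, while 8% (≳5.5σ) reliably contains them
at both the default noise and curve SNR 20. That measurement, not taste,
fixed the default.

## Registration

Tumor masks, not intensities, drive the registration (they are what the
original scheme registered), in two stages: (1) a rigid initialization from
mask moments — centroid plus principal axes, eigenvector signs disambiguated
by third-moment skewness along each axis, a leftover improper rotation
repaired by flipping the axis with the weakest skewness evidence; (2) a
12-parameter affine refinement maximizing soft Dice (trilinearly sampled
moving mask against the fixed mask) with restarted Nelder-Mead. Everything
works in world millimetres through the NIfTI affines. Resampling is
trilinear for continuous maps and nearest-neighbour for masks; a trilinear
sample is defined only when all eight neighbours are defined, so gated or
flagged voxels propagate as undefined. Non-rigid registration is
deliberately absent (the animal holder prevented deformation).

Two consequences discovered during implementation and now part of the
design: the fixed-frame masks live at CT-like (MRI-equal) resolution and the
SPECT volume is resampled onto that grid for the correlation — registering a
fine mask against a 2.5×-coarser staircase mask biases the overlap optimum
by ~0.5 mm (and that is also what the emulated acquisition did: masks were
drawn on CT, SPECT resampled to CT resolution). And the phantom tumor must
not be reflection- or rotation-symmetric, or the principal-axes frame (and
any mask-overlap criterion) cannot identify 180° flips; the phantom grows an
egg-shaped, distinct-semi-axes tumor for exactly this reason.

## Correlation statistics

Per dataset, over tumor voxels minus the feeding-vessel label, all eight
parameter maps on the identical voxel set: (1) Spearman $\rho$ from average
ranks with a two-sided t-approximation p-value; (2) bidirectional decile
summaries — rank-split one modality into ten equal-count bins (sizes
$\lceil n/10\rceil$ then $\lfloor n/10\rfloor$, stable on ties) and take
median/Q1/Q3 (type-7 quantiles) of the companion modality per bin; (3)
pooled regression — per dataset assign SPECT deciles, pool each decile's
voxels across datasets, regress the pooled median parameter value on the
decile index 1–10 by OLS. The index is the abscissa because absolute SPECT
scales differ between animals. Rank (equal-count) deciles implement
"sorting the range into deciles"; no multiple-testing correction is applied
(none was originally).

## The phantom: what it emulates, and what it does not

`phantom_config()` defaults *are* the emulated acquisition: 96 frames at
4.3 s in two equal blocks with a 60 s gap after frame 48; calibration at
TR = 200/400/800/1200/2400 ms; 10° flip, TR 3.4 ms; contrast arrival at 30 s
(injection timing relative to frame 1 is not stated; a fixed choice);
bi-exponential input (3.0, 0.01, 1.0, 0.001) in mM and s⁻¹. The working grid
is 32×32×16 voxels at 0.4 mm — a deliberate computational scale-down of the
0.195 mm acquisition grid giving ~3 800 tumor voxels (tests need ≥500); the
SPECT grid is 2.5× coarser with a 1.5 mm FWHM blur ("blooming") and Poisson
counting noise at 20 counts/kBq, displaced from the MRI frame by a known
rigid transform (3° about z, (1, −0.5, 0.5) mm).

Ground truth: smoothed-white-noise fields (Gaussian kernel, 4 voxels ≈
1.6 mm — mm-scale lobules; finer fields are annihilated by the 1.5 mm SPECT
blur in a way the original 15 mm tumors were not) with $K^{trans}$ scaled to
0–0.02 s⁻¹, $v_e$ to (0.15, 0.65), $T_{10}$ to 1200–1800 ms; one contiguous
pocket where $K^{trans}$ tapers smoothly to exactly zero; a feeding-vessel
rod (high $K^{trans}$, excluded from correlation); an artery sphere
supplying the input function; and receptor-free, well-vascularized
connective-tissue septa (8% of tumor voxels, high $v_e$) that stay *inside*
the analysis mask — the in-vivo data contained exactly such
high-enhancement/no-uptake regions without a visual clue to exclude them.

Uptake: delivery surrogate $d$ = noiseless AUC over the first 60 s of the
true tissue concentration, then Michaelis–Menten receptor saturation
$U = U_{max}\, d/(d + d_{50})$, times the receptor density (1 in vital
tumor, 0 on septa and vessels). $d_{50} = 45\ \mathrm{mM\,s}$ is calibrated
to the median tumor delivery — the injected peptide mass "partly saturates"
the receptors, so the median voxel sits at half saturation. The dynamic
noise default (SD 1, baseline SNR ≈ 25) is a free choice; the in-vivo SNR
was never stated. "Curve SNR" in the tests means baseline signal over noise
SD, the usual temporal-SNR definition for an SI curve.

What a green test does **not** establish: the phantom has no receptor-binding
kinetics, no tracer circulation time separate from the contrast bolus, no
anatomy, no motion, no B1 or T2* effects, and its uptake model is a
one-parameter saturation — green means the *pipeline* recovers what this
stated world encodes, not that the biology is settled. At this scale-down
the qualitative amount/exchange dissociation is also seed-sensitive: the
canonical four datasets (seeds 1–4, fixed a priori) reproduce it, but other
seed sets can blur it, because ten-bin medians over ~3 700 voxels are far
noisier than over the ~10⁵-voxel in-vivo tumors.

## Numerical and degenerate-input policy

Tofts convolution in `expm1`-stable form with series fallback when
$|k_{ep} - m_i|\,t < 10^{-8}$; T1 search bracketed in (50, 5000) ms with
boundary solutions flagged rather than returned; SPGR inversion marks
out-of-range frames missing instead of clamping them; all-zero artery curves
and empty masks are errors, all-zero tissue curves fit to
$K^{trans} = 0$ without error; constant maps refuse normalization by name;
coplanar masks degrade to centroid translation with a warning; decile code
requires $n \ge 10$ rows. Determinism: a study is bit-identical for a fixed
config + seed (the generator seeds and restores the RNG state), and the
analysis path contains no randomness.

## Known limitations

Per-voxel T1 precision at SNR 50 is bounded below by the Cramér–Rao limit of
the 5-TR design itself (~5–17% relative for T1 between 500 and 2000 ms); the
fitter sits at that bound, and no estimator can do better — the
corresponding acceptance expectation of 2% RMSE is therefore left failing by
design, with the analysis recorded alongside it. Registration accuracy is
limited by mask discretization, not by the optimizer. The pipeline assumes
co-registered calibration and dynamic volumes, one arterial region per
dataset, and axis-aligned grids in the phantom.
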