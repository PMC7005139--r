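---
title: "Methods: hierarchical Bayesian DOT and resting-state connectivity"
author: "hbdot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian DOT and resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package models

High-density functional near-infrared spectroscopy (fNIRS) measures
optical-density (OD) changes in source-detector channels laid on the
scalp. With two channel distances -- 13 mm pairs that sample mostly the
scalp and 29 mm pairs that reach the cortex -- and overlapping
measurements, the channel data can be inverted into a volumetric image
of absorption changes (diffuse optical tomography, DOT), unmixed into
oxy- and deoxy-hemoglobin, and summarized as resting-state functional
connectivity (RSFC) between cortical regions.

The central methodological question the package addresses is how the
choice of inverse algorithm affects RSFC estimates. Three solvers are
implemented:

* **MN** -- depth-compensated minimum norm. Tikhonov solution in
  column-rescaled variables, \(\hat x_t = L^{-1}\tilde S^\top
  (\tilde S\tilde S^\top + \alpha I)^{-1} y_t\) with
  \(\tilde S = S L^{-1}\), \(L_{vv} = \sqrt{\rho^2_v + \beta}\) and
  \(\rho^2_v\) the squared sensitivity column norm normalized by its
  maximum. MN sets \(\beta\) to the mean of \(\rho^2\) over voxels about
  20 mm deep (a very small number, hence aggressive depth
  compensation); its regularization \(\alpha\) is selected by type-II
  maximum likelihood (`evidence_alpha()`).
* **MN-WU** -- the same operator with the fixed spatially variant
  parameter \(\beta = 0.1\), the prevailing standard.
* **HB** -- a two-step hierarchical Bayesian solver. Step one is an MN
  reconstruction of the *unregressed* data; its per-voxel temporal mean
  squares become the prior variance centers \(\lambda_{0,v}\). Step two
  runs variational-Bayes automatic relevance determination (ARD) with
  the M-step
  \(\lambda_v \leftarrow (\sum_t\langle x_{v,t}^2\rangle +
  2\gamma_0\lambda_{0,v}) / (T + 2\gamma_0)\)
  for cortical voxels, while scalp activity lives on a smooth Gaussian
  basis with a fixed broad variance. The confidence \(\gamma_0\)
  (default \(0.1\,L\), with \(L\) the retained sample count)
  interpolates between the prior-dominated limit
  (\(\gamma_0\to\infty\): fixed-\(\lambda_0\) ridge) and the pure
  data-driven ARD rule (\(\gamma_0 = 0\)). HB therefore reconstructs
  scalp and cortex *simultaneously* and needs no short-channel
  regression.

The two minimum-norm branches instead receive data whose scalp
component has been removed by regressing out the global mean of the
good short channels -- the standard two-process approach, whose known
weakness is spatially inhomogeneous superficial interference.

# Forward model

The sensitivity matrix uses the Rytov (log-intensity) linearization in
base-10 OD convention,
\(S(ch, v) = G(r_s, r_v) G(r_v, r_d) / G(r_s, r_d) \times V_{vox}/\ln 10\),
with the analytic continuous-wave Green's function of the photon
diffusion equation in a homogeneous semi-infinite medium
(extrapolated-boundary image source, optodes represented one transport
mean free path below the surface). The default medium uses the
scalp/skull optical parameters of the standard head-tissue table
(`optical_parameters()`), shared by the three wavelengths (780, 805,
830 nm). This deterministic kernel replaces voxel-wise Monte-Carlo
photon transport; it preserves the banana-shaped channel kernels, the
depth dependence on source-detector separation, and source-detector
reciprocity -- the geometric properties the inverse solvers rely on --
at desk scale. What it does not model: curved scalp geometry, layered
heterogeneous optics, and subject-specific anatomy.

The reconstruction region is a 28-mm-deep cuboid slab under each
4x4 optode array (13-mm pitch), extended laterally by a factor 1.5, cut
into 4-mm voxels, and partitioned into tissue layers
(scalp/skull 0-11 mm, CSF 11-13 mm, gray below); the compartment split
(scalp vs cortex) drives the HB prior and all downstream masking.

# Preprocessing

The chain follows the standard resting-state recipe with exact
thresholds: (1) voltages to OD by \(-\log_{10}(V/\bar V)\); (2)
channel rejection when the coefficient of variation
(\(100\sigma/\mu\), population SD, raw voltages) strictly exceeds 15%
at any wavelength or the channel saturates (at the ADC ceiling for at
least 1% of samples -- the hardware criterion is not public, so the
ceiling and fraction are configurable); (3) Butterworth filtering,
high-pass order 3 at 0.009 Hz then low-pass order 7 at 0.08 Hz; (4)
optional global short-channel regression (minimum-norm branch only);
(5) removal of time points deviating more than 3 SD in any good short
channel, with the same index set dropped from every channel.

Numerical choices worth noting. The filters are implemented as
second-order sections designed analytically (prototype poles, bilinear
transform): at cutoffs two decades below Nyquist the expanded
polynomial recursion amplifies round-off by orders of magnitude, while
the biquad cascade keeps single-pass gains within 0.3% of the analytic
Butterworth magnitude and operator linearity at the 1e-11 level.
Zero-phase (forward-backward) filtering is the default since
connectivity is a correlation in time; single-pass mode exists for
analytic-gain verification. Step-(5) statistics are computed after
filtering; zero-variance channels never trigger removal; removed
samples are dropped, not interpolated.

# Connectivity

Cortical voxels whose normalized sensitivity exceeds 0.5 in every
subject are *sensitive*; regions with at least 10 sensitive voxels are
*available*. The normalized sensitivity is, by default, the column norm
of the depth-compensated operator \(S L^{-1}\) (\(\beta = 0.1\))
max-normalized over the cortical compartment: this is the sensitivity
of the operator actually applied during reconstruction, and its flatter
depth profile makes the 0.5 threshold select the well-sensed cortical
sheet. Raw column-norm normalization is available
(`normalized_sensitivity(method = "raw")`), but with the analytic
kernel it decays so steeply that the threshold retains only the single
best-seen voxel column, which cannot support a 19-region parcellation.

ROI time series are unweighted means over sensitive member voxels after
8-mm FWHM Gaussian smoothing (never across compartments). Connectivity
is the partial correlation from the inverse covariance,
\(pc_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}\), equal to the correlation of
residuals after regressing out all other ROIs. Two stabilizations are
exposed: short segments (\(T < 3R\)) engage a ridge automatically, and
the study pipeline applies a 0.05 ridge throughout because the
regularized inverse operator compresses high-order spatial modes --
the ROI covariance of reconstructed series can reach condition numbers
of \(10^7\), at which point an unridged precision matrix pins partial
correlations at \(\pm 1\).

# The synthetic study generator

`truth_spec()` / `simulate_study()` generate the study conditions the
comparison battery runs on: by default 20 subjects x 2 runs x 10 min at
18.5 Hz (the acceptance analyses use 5 subjects to keep a desk-scale
footprint; all sizes are spec fields), a two-array montage (96
channels, 48 short + 48 long), and 19 available ROIs.

* **Cortical signal.** ROI latents are band-limited (0.009-0.08 Hz)
  Gaussian processes with a known sparse SPD precision matrix. When ROI
  geometry is available the coupling graph is spatially organized --
  adjacent regions couple positively, long-range pairs have mixed
  sign -- which is how group-mean resting-state maps actually look.
  This matters beyond realism: the DOT point spread transmits smooth,
  spatially organized covariance and annihilates spatially random
  covariance, so a geometry-blind truth graph leaves nothing for *any*
  reconstruction to recover (verified on noise-free studies during
  design). Voxel series add independent band-limited noise
  (`voxel_snr`, default 2), synthesized exactly band-limited on the
  run's in-band Fourier modes (low rank, hence cheap at full sampling
  rate).
* **Scalp interference.** A global systemic mixture (0.01/0.04/0.1 Hz
  sinusoids plus a 1.1 Hz cardiac tone) and a spatially smooth
  inhomogeneous random field (Gaussian kernels, 40-mm correlation
  length) whose spatial pattern is redrawn every run -- run-specific
  interference is precisely what inter-run reproducibility must be
  limited by. Amplitudes are calibrated at the channel level: on long
  channels the cortical contribution has OD standard deviation
  `od_scale` (default 0.005) and the scalp contribution 1.5x that.
  Channel-level calibration replaced an earlier voxel-level scaling
  under which coherent scalp sheets outweighed the two-voxel-deep
  cortical signal thirty-fold at the channels, an implausible regime in
  which no algorithm retains any cortical information.
* **Noise and artifacts.** White measurement noise set by the in-band
  long-channel SNR (default 5) plus 1/f noise at half that amplitude;
  per run: 3 drifting channels whose CV is forced above 15%, one
  saturated channel, and Poisson-placed global motion spikes
  (0.05 events/s) that the 3-SD screen removes.
* **Reference modality.** ROI latents plus small independent noise,
  exported separately -- a noiseless-anatomy stand-in for a reference
  scan of the same connectivity.

Determinism: every run's RNG stream derives from the master seed
(`seed * 10000 + subject * 100 + run`), and regeneration is
bit-identical.

What passing tests on these data do *not* show about real recordings:
the generator shares one flat-slab geometry across subjects (no
anatomical variability, no coregistration error), draws signals from
the same model family the solvers assume, and omits serially correlated
physiology outside the three scalp components. Reliability values are
therefore optimistic relative to human recordings, and inter-run
reproducibility in particular carries a deterministic component common
to all algorithms (see the last section).

# Comparison battery

`compare_study()` mirrors the human-study evaluation: lower triangles
are Fisher-z transformed entrywise, similarity between two matrices is
the Pearson correlation of those vectors (itself Fisher-z transformed);
inter-run reproducibility uses the same similarity plus two-way
consistency intraclass correlations, ICC(C,1) and ICC(C,k), computed
from the ANOVA mean squares over items = ROI pairs and raters = runs
(ICC is computed on z-transformed connection values, consistent with
the r-based pipeline). Group differences among algorithms use one-way
ANOVA with Tukey-Kramer pairwise comparisons (runs pooled as
observations for similarity, 2 x 5 = 10 per algorithm at the acceptance
scale). `split_half_analysis()` implements the four half-run designs
(intra_run1, intra_run2, inter_FH, inter_SH; the first half receives
the extra sample at odd lengths) and compares intra-run against
half-length inter-run reproducibility with an unpaired two-sided
equal-variance t-test.

# Problem sizes and solver settings

The shipped analyses use: two 4x4 arrays (96 channels), 3150 voxels
(1350 scalp, 1800 cortex), 19 ROIs of 17-18 sensitive voxels, 10-min
runs preprocessed at 18.5 Hz and decimated by 25 before inversion
(the band ends at 0.08 Hz; the decimated Nyquist of 0.37 Hz leaves a
4.6x margin, so connectivity is unaffected while the solvers scale
accordingly). HB runs at most 100 iterations at tolerance 1e-4 on the
relative change of the prior variances; on study data it converges in
well under ten iterations because the noise variance is initialized
from the data scale and annealed by the EM update (mean squared
residual plus the posterior trace term tr(A Sigma A^T) evaluated in
channel space). Initializing the ARD iteration from the first-step
evidence noise estimate is deliberately avoided: on structured
high-SNR data the isotropic-prior evidence collapses toward the grid
floor and traps the iteration in an overfitted state. The evidence grid
for \(\alpha\) is `10^seq(-8, 2, length 61)`, ties resolved toward
less regularization; the variance floor is 1e-12; the scalp basis uses
20-mm FWHM kernels on a 10-mm lattice, wide enough to be smooth yet
fine enough that inhomogeneous interference is absorbed by the scalp
compartment rather than leaking into shallow cortex.

# Known limitations

* The similarity-to-truth levels reachable through a DOT chain are
  bounded well below 1 even without noise: cross-talk between
  point-spread-scale regions perturbs the ROI covariance
  deterministically. Values around 0.3-0.4 at the acceptance scale are
  in line with what reference-modality comparisons report on real
  recordings.
* Inter-run reproducibility on in-model synthetic data rewards
  spatially heavy regularization: the MN-WU variant's strongly
  smoothed estimates converge toward the run-independent expected
  connectivity and can be *more* reproducible than HB's adaptive
  estimates, a regime difference from human data (where run-specific
  contamination that global regression cannot remove dominates). The
  HB advantage on similarity and over MN is robust in simulation; the
  HB-vs-MN-WU reproducibility ordering is not, and the package reports
  it honestly rather than calibrating the generator until it flips.
* The evidence maximization for \(\alpha\) assumes an isotropic
  Gaussian prior and white noise; on band-limited, spatially structured
  data the selected \(\alpha\) can sit at a grid boundary. The grid is
  configurable.
* `fluence_green()` is a homogeneous half-space kernel; layered or
  curved geometries require an externally supplied sensitivity matrix
  (the reconstruction code accepts any channels x voxels operator).
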