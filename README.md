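# hbdot

Hierarchical Bayesian diffuse optical tomography (DOT) for
resting-state functional connectivity (RSFC).

High-density fNIRS montages with mixed 13-mm and 29-mm source-detector
channels can be inverted into volumetric images of oxy-/deoxy-hemoglobin
changes and summarized as connectivity between cortical regions — but
the result depends strongly on the inverse algorithm and on how scalp
hemodynamics are removed. `hbdot` implements and compares three
solvers under controlled, fully synthetic conditions with known ground
truth:

* **MN** — depth-compensated minimum norm,
  `x̂ = L⁻¹ S̃ᵀ (S̃S̃ᵀ + αI)⁻¹ y` with `S̃ = S L⁻¹`,
  `L_vv = √(ρ²_v + β)`, β from the ~20-mm-depth voxels, α by type-II
  maximum likelihood;
* **MN-WU** — the prevailing standard variant with β = 0.1;
* **HB** — a two-step hierarchical Bayesian solver: a first-step MN
  image sets per-voxel prior variance centers λ₀, then
  variational-Bayes ARD re-estimates voxel variances
  `λ_v ← (Σ_t⟨x²⟩ + 2γ₀λ₀_v)/(T + 2γ₀)` at confidence `γ₀ = 0.1·L`,
  with a sparse prior on cortex and a smooth Gaussian basis on the
  scalp — scalp and cortical activity are reconstructed
  simultaneously, so no short-channel regression is needed.

Around the solvers the package provides the full experimental chain:
an analytic photon-diffusion Rytov forward model, the standard fNIRS
preprocessing steps (log-ratio OD, CV > 15% channel rejection,
0.009–0.08 Hz Butterworth band, global short-channel regression for
the MN branch, 3-SD time-point removal), ROI partial-correlation
connectivity with sensitive-voxel/available-ROI rules, and the
comparison battery (Fisher-z matrix similarity, inter-run and
split-half reproducibility, ICC(C,1)/ICC(C,k), ANOVA with
Tukey–Kramer). A synthetic-study generator produces multi-subject,
two-run recordings with known ROI connectivity, inhomogeneous scalp
interference and realistic artifacts.

## Worked example

Simulate a small two-subject study, analyze it with all three
algorithms, and compare:

```r
library(hbdot)

spec  <- truth_spec(n_subjects = 2, duration = 300, seed = 7)
study <- simulate_study(spec)
an    <- analyze_study(study)        # HB, MN, MN_WU
cmp   <- compare_study(an)

aggregate(r_truth ~ algorithm + species, cmp$similarity, mean)
```

```
  algorithm species   r_truth
1        HB   deoxy 0.4729108
2        MN   deoxy 0.3071962
3     MN_WU   deoxy 0.4257035
4        HB     oxy 0.4963805
5        MN     oxy 0.3673689
6     MN_WU     oxy 0.4747316
```

`r_truth` is the Pearson correlation between the Fisher-z-transformed
lower triangle of the estimated partial-correlation matrix and that of
the generating (ground-truth) connectivity, averaged over subjects and
runs: under default scalp contamination the hierarchical solver tracks
the true connectivity more closely than either minimum-norm variant.
`cmp$reproducibility` tabulates the matching inter-run statistics
(r, ICC(C,1), ICC(C,k)) and `cmp$anova` the algorithm-wise ANOVA with
Tukey–Kramer pairwise comparisons.

The single pieces are exported individually (`probe_layout()`,
`build_sensitivity()`, `preprocess_run()`, `mn_reconstruct()`,
`hb_reconstruct()`, `partial_correlation()`, …); the methods vignette
(`vignettes/hbdot-methods.Rmd`) documents the model, the defaults and
their rationale, and the generator's scope.

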