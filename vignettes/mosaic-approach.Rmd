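---
title: "The mosaic approach to single-subject cortical atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mosaic approach to single-subject cortical atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mosaicmap)
```

## The problem

Cortical gray-matter atrophy is a clinically meaningful substrate of
neurodegenerative and neuroinflammatory disease — multiple sclerosis in
particular — but it is hard to quantify for an *individual* patient. A
cortical surface model carries tens of thousands of thickness estimates
(one per vertex, in mm), so a naive vertexwise comparison of one patient
against a reference cohort drowns in the multiple-comparisons problem, and
the common remedies (heavy smoothing, cluster-based corrections) each
introduce their own tuning choices.

The mosaic approach sidesteps this by changing the unit of inference: the
cortex is divided into a few hundred to a thousand parcels ("patches") of
a standard atlas-style parcellation, each patch is summarized by the
unweighted mean thickness of its vertices, and each patch is rated against
a healthy-control reference cohort. The primary output is a per-patch
binary map (thin / not thin) and one scalar, the **thin-patch fraction**:
the fraction of evaluable patches called significantly thin. That scalar
is the biomarker.

## The statistic

For patient $i$ and patch $k$, with reference cohort mean $\bar x_k$ and
sample standard deviation $s_k$ (denominator $n-1$) over the $n$ controls:

$$z_{ik} = \frac{x_{ik} - \bar x_k}{s_k}.$$

The z-score is converted to a p-value by an **exhaustive permutation**:
the patient is pooled with the $n$ controls, and each of the $n+1$ pooled
subjects in turn is treated as the singleton while the remaining $n$ form
the reference; the per-patch z is recomputed for every relabeling. This
is done per patch, so every patch has its own personalized null that
respects the physiological variation of thickness across the cortex. The
p-value is the tie-inclusive fraction of null z-scores at or below the
observed one,

$$p_k = \frac{\#\{r : z^{(r)}_k \le z_{ik}\}}{n+1},$$

so $p_k$ lives on the discrete grid $\{1/(n+1), \dots, 1\}$ and can never
undercut $1/(n+1)$ — with an 89-subject reference the smallest attainable
p is $1/90 \approx 0.011$, comfortably below the default $\alpha = .05$,
but the discreteness is a real limit of small reference cohorts and
`threshold_map()` warns when $\alpha$ falls below the attainable minimum.
Only abnormally *low* thickness is called (one-sided): the method looks
for atrophy, not hypertrophy. The whole pipeline is deterministic — the
permutation is exhaustive, so no random number is drawn anywhere.

Two thresholding modes are provided, because the choice between them is a
genuine interpretational fork: the per-patch mode calls patch $k$ thin
when $p_k \le \alpha$ (each patch against its own personalized null,
which is the literal reading of the procedure); the max-stat mode
additionally controls the family-wise error across patches by comparing
each observed z against the permutation distribution of the per-relabeling
*minimum* z. The two coincide exactly for a single patch. Per-patch is
the default; neither is asserted to be the only defensible reading.

Design choices worth stating explicitly:

* **Plain z-scores by default.** A Crawford–Howell-style scaling (divide
  by $s_k\sqrt{1 + 1/n}$) is available via `ch_correction = TRUE`; it
  rescales all z-scores by a common factor and therefore leaves the
  rank-based permutation p-values untouched. It matters only if the
  z-maps themselves are consumed.
* **No covariates by default.** An optional residualization of patch
  means on age and sex (coefficients fit on controls only) is available
  in `run_map_cohort()`.
* **Label 0 is sacrosanct.** Vertices labeled 0 (medial wall /
  unassigned) and vertices outside the cortical mask never enter any
  statistic. Patches emptied by masking carry `NA` and are excluded from
  both the numerator and the denominator of the thin-patch fraction.
* **Ties count as "less than or equal".** The observed relabeling always
  contributes to its own null, which is what guarantees validity
  ($P(p \le \alpha) \le \alpha$ up to grid rounding).

## The standard approaches, for comparison

`singleton_vs_group()` is the vertexwise prediction-interval GLM: control
thickness is regressed on intercept, age and sex, and the patient's
residual is scaled by the prediction standard error,
$t = r_0 / (s\sqrt{1 + x_0^\top(X^\top X)^{-1}x_0})$ with
$n - \mathrm{rank}$ degrees of freedom. With no covariates this reduces
exactly to the Crawford–Howell single-case test
$t = (x - \bar x)/(s\sqrt{1+1/n})$, and the test suite holds it to that
closed form at $10^{-10}$. Multiplicity is handled either by
Benjamini–Hochberg FDR on the one-sided p-map (`fdr_bh()`, delegating to
`stats::p.adjust`) or by max-statistic permutation FWE (`maxstat_fwe()`)
over the exhaustive leave-one-as-singleton relabelings. Cluster-based
enhancement methods are deliberately out of scope; max-stat permutation
fills the FWE slot of the comparison.

Smoothing (`smooth_on_mesh()`) is iterated symmetric neighbor diffusion
on the mesh: each edge carries weight $(1-w)/\mathrm{deg}_{\max}$ and the
remainder stays on the vertex. The operator is symmetric and doubly
stochastic, so constants are preserved exactly, the global mean is
conserved on any mesh, and variance contracts monotonically. The
iteration count is calibrated so the accumulated kernel variance
approximates $(\sigma/\text{edge length})^2$, with per-iteration variance
$(1-w)\,\text{edge}^2$; $\sigma = 0$ is the bit-exact identity. The usual
reporting convention $\mathrm{FWHM} = \sigma \cdot 2\sqrt{2\ln 2} \approx
2.3548\,\sigma$ is provided by `sigma_to_fwhm()`. This diffusion honors
the contract that downstream comparisons rely on (constant-preserving,
mean-conserving, variance-contracting, monotone in $\sigma$); it is not a
geodesic Gaussian on a real cortical surface, which would require full
mesh geometry.

## The evaluation layer

A strategy (a metric, a correction method, a smoothing level or patch
count) is judged by the Pearson correlation of its per-patient burden
fraction with two clinical variables: lesion volume (LV, mL, structural
burden) and the Expanded Disability Status Scale (EDSS, 0–10 in 0.5
steps, functional burden), both on their raw scales.
`compare_strategies()` then runs three one-way ANOVAs on the correlation
values — outcome (LV vs EDSS), approach (each metric as a level), and
smoothing/parcellation (none vs any) — with Tukey HSD follow-up where an
ANOVA is significant. The exact factor coding behind the source study's
printed F statistics cannot be reconstructed from its text, so those F
values are not reproduction targets; the implementation keeps each
hypothesis as a clean one-way design. `welch_t_from_summary()` and
`yates_chi2()` cover the demographic summary tests and agree with the
printed cohort-table statistics from the rounded summaries alone.

## What the simulator emulates — and what it does not

`simulate_cohort()` exists so that every pipeline stage can be exercised,
calibrated and stress-tested without patient data. Its defaults are the
study conditions the package targets:

| parameter | default | anchor |
|---|---|---|
| `n_controls` | 89 | reference cohort size |
| `n_patients` | 465 | patient cohort size |
| `base_mean` | 2.41 mm | control whole-brain mean thickness |
| `base_sd_between` | 0.11 mm | between-subject SD (global shift) |
| `patch_offset_sd` | 0.15 mm | fixed regional mean differences |
| `patch_sd_within` | 0.05 mm | subject-by-patch deviation |
| `vertex_noise_sd` | 0.25 mm | vertex-level measurement noise |
| `lv_mean`, `lv_sd` | 5.39, 8.41 mL | lesion-volume calibration |
| `atrophy_effect` | 6 | atrophy depth, reference-SD units |
| `atrophy_patch_fraction` | 0.1 | mean atrophic fraction |
| `clinical_coupling` | 0.6 | burden–LV Pearson target |
| `edss_coupling` | 0.35 | burden–EDSS target (weaker) |

Three generator decisions deserve justification:

* **Heterogeneous severity.** Each patient draws an individual atrophy
  propensity from a Beta distribution with mean `atrophy_patch_fraction`
  (shape controlled by `atrophy_heterogeneity`, default 2, i.e.
  Beta(2, 18) at the default mean), then each patch is independently
  atrophic with that propensity. Relapsing-remitting cohorts are strongly
  dispersed in burden — the lesion-volume calibration itself has a
  coefficient of variation of 1.56 — and a cohort in which every patient
  carried the same burden would make any burden-tracking biomarker
  meaningless by construction.
* **Injection in reference-SD units.** Atrophic patches are lowered by
  `atrophy_effect` times the *empirical* reference patch SD, so the
  injected effect is defined on exactly the scale the statistic measures.
* **Copula-coupled clinical variables.** LV is lognormal (calibrated to
  its mean/SD) and coupled to the realized burden through a Gaussian
  copula. Because a lognormal margin attenuates Pearson correlation by
  the closed-form factor $\sigma_{\log}/\sqrt{e^{\sigma_{\log}^2}-1}$,
  the latent correlation is inflated by that factor so that
  `clinical_coupling` is a target on the *observed* scale; couplings
  beyond the attainable cap raise an error rather than silently
  under-delivering. EDSS is generated the same way on the half-point
  grid (median near 1.5), always with the weaker coupling.

Reproducibility: one master seed; per-subject substreams are derived
deterministically from (seed, subject index), so individual subjects are
bit-stable when cohort sizes change.

What the simulator does **not** emulate: real cortical geometry and
lesion topography (patches are contiguous index blocks on a synthetic
grid mesh), spatial autocorrelation of atrophy, scanner and sequence
effects, and age/sex structure in thickness (covariates are generated but
thickness is not coupled to them unless you inject it). Passing tests on
this generator therefore demonstrate the statistical machinery —
calibration, recovery, ordering — not anatomical realism.

## Numerical choices and degenerate inputs

* Reference SDs of zero (identical controls) flag a patch *degenerate*:
  its z is `NA`, never an infinity, and it leaves the thin-patch-fraction
  denominator.
* Undefined null cells count as "not smaller" in the p-value, which is
  the conservative direction.
* The leave-one-out nulls are computed with the same column-mean/SD
  kernel as the reference fit, so the true patient's row of the null
  reproduces `zscore_patches()` bit-exactly and the tie-inclusive count
  is immune to floating-point asymmetry.
* Patch averaging conserves the masked global mean to $10^{-10}$
  (vertex-count-weighted), and is invariant under consistent vertex
  permutations.
* Group-level contrasts enumerate all label assignments exhaustively when
  the pooled cohort has at most 10 subjects (pure-ratio p-values);
  Monte-Carlo mode uses $+1$-smoothed p-values,
  $(1 + \#\{\text{null} \le \text{obs}\})/(B+1)$, for validity under
  sampling.

## Problem sizes used by the test suite

The packaged checks run at deliberately reduced scale, chosen as the
smallest sizes at which each property is still sharply testable: oracle
equivalence sweeps every pooled size up to 9 subjects and 5 patches
against naive enumeration; null calibration uses 2000 simulated null
patients against an 89-control reference with 100 patches (the 2-SE band
uses replicate-level cluster standard errors, since patches within a
replicate share one control draw); parameter recovery and the
strategy-comparison ordering use one simulated cohort of 89 controls and
100 patients on 4000 vertices and 1000 patches with the default atrophy
settings. The same computations, at the same sizes, are what
`scripts/acceptance.R` re-runs end to end.

## Known limitations

* With a small reference cohort the permutation p-values are discrete
  (grid $1/(n+1)$); at $n = 89$ the effective per-patch level of a
  nominal $\alpha = .05$ test is $4/90 \approx .044$.
* Healthy-range *global* thickness variation (the 0.11 mm between-subject
  SD) moves all of a subject's patches jointly across the discrete
  threshold, so part of the thin-patch fraction reflects diffuse
  position-in-the-healthy-range rather than focal patch atrophy. This is
  an inherent property of uncorrected single-subject normative
  comparison; it widens the seed-to-seed spread of recovery correlations
  and is the main reason a global-normalization or covariate layer may be
  worth adding for clinical use.
* The reference cohort is used as-is; age- and sex-matched reference
  subgrouping is out of scope (and not feasible at this reference size).
* Thickness is the only metric implemented; volumetric gray-matter
  metrics enter the comparison layer only as externally computed burden
  fractions.
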