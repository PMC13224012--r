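---
title: "mitoscreen: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoscreen: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `mitoscreen`, the
conventions its operators follow, the parameters that matter and why
their defaults are what they are, and the limits of what its synthetic
validation can show about real microscopy data.

## The measurement problem

Mitochondrial membrane potential (MMP, reported by TMRE-class dyes),
whole-cell reactive oxygen species (ROS, DCFH-DA-class) and
mitochondrial superoxide (mtROS, MitoSOX-class) are routinely read out
per cell in high-content screens. Beyond group means, the *coupling*
between MMP and (mt)ROS across single cells is itself a phenotype: in
healthy cells the electron transport chain links membrane potential to
superoxide production, so MMP and mtROS correlate strongly, while
whole-cell ROS is buffered and correlates less. Treatments can shift
levels, weaken coupling, or both, and comparing correlation strengths
requires normal-theory machinery (Fisher z) that in turn makes
distributional assumptions worth being explicit about.

## The latent generative model

Each cell of a treatment group carries a latent triple
$(M, R, S) = \exp(Z)$, $Z \sim N(\mu, D\rho D)$ with $D =
\mathrm{diag}(\sigma)$. A log-normal was chosen because fluorescence
intensities are strictly positive and right-skewed, and because it
makes the coupling parameter interpretable: $\rho$ is exactly the
correlation of log-intensities, the scale on which the coupling
statistics operate (below). Latents are sampled with `MASS::mvrnorm`;
an independent Cholesky construction serves as the oracle in tests.

Default group parameters encode the qualitative structure of the
study system, and are tunable per `group_spec()`:

* HPFC (normal fibroblasts): $\rho(M,S) = 0.75$, $\rho(M,R) = 0.35$;
* HeLa (tumor line): $\rho(M,S) = 0.60$, $\rho(M,R) = 0.30$;
* $\rho(R,S) = 0.40$ in both (total ROS partly reflects the
  mitochondrial pool); baseline $\mu = \log(3000, 1500, 2000)$ counts,
  $\sigma = 0.3$;
* cisplatin: depolarization with ROS flooding ($M\times0.4$,
  $R\times2$, $S\times2$) and halved off-diagonal correlations
  (uncoupling);
* G4-stabilizing ligands (Pt-ttpy, 360A, Phen-DC3): tumor-selective
  depolarization with mild ROS suppression ($M\times0.5$,
  $R\times0.85$, $S\times0.85$), applied in the tumor line only — the
  normal line keeps control parameters;
* EDL21 (the ligand scaffold without G4 binding): identical to
  control, serving as the inert-compound control.

Dose values are metadata only; the generator does not implement a
dose-response curve.

## Rendering

Cells are discs (radius 16–24 px) around non-overlapping nuclei
(radius 8–12 px); overlapping cytoplasm is split by normalized
distance, so touching cells exercise the watershed/propagation code
while nuclei stay cleanly separable — deliberately, since nuclei are
the segmentation seeds. Mitochondria are short random-walk filaments
confined to the cytoplasm. Channel composition: Hoechst on nuclei
(per-cell level log-normal around 5000 counts); ROS uniform over the
cell at amplitude $R$; MMP and mtROS at amplitude $M$ and $S$ on
mitochondrial pixels with an 8% cytoplasmic haze. Noise is Poisson
shot noise (gain 1 count/photon) followed by Gaussian read noise
(SD 2 counts), then rounding and clipping to 16 bits. With both noise
sources set to 0 the rendered field is the exact un-rounded
expectation, which the conservation and linearity tests exploit.

Background (100 counts), cell density (~30 cells per 512 px field) and
the intensity calibration are package defaults chosen to resemble
routine widefield HCS acquisition; no public calibration values exist
for the original acquisitions, and these defaults are stated as such.

What the simulation does **not** emulate: optics (PSF blur,
vignetting, chromatic shifts), autofluorescence gradients, cell-cycle
and morphological heterogeneity, segmentation-hostile confluent
monolayers, photobleaching, or plate-edge effects. Passing recovery
tests therefore demonstrates the *correctness of the computation*, not
robustness to every real-world artifact; on real plates the
segmentation parameters are the knobs to revisit first.

## Segmentation conventions

* Nuclei: Gaussian smoothing (σ = 2 px), Otsu threshold (fixed value
  configurable), area filter (≥ 50 px), watershed split on the
  distance transform. Touching-object splitting and all morphological
  primitives are EBImage's deterministic C implementations; identical
  inputs give identical label maps, which tests assert directly.
* Cells: CellProfiler-style seeded propagation
  (`EBImage::propagate`) over a guide channel (the whole-cell ROS
  stain), limited to `max_distance` (20 px) from the nucleus set and
  to guide foreground. Foreground defaults to a robust
  background-based cutoff (median + 3 MAD of the guide) rather than
  Otsu: with log-normal brightness the dimmest cells can fall below a
  global Otsu threshold, truncating exactly the cells whose latent
  values sit in one tail — a selection artifact that biases coupling
  estimates. The robust cutoff keeps dim cells; Otsu and fixed
  thresholds remain options.
* Mitochondria: white top-hat (disc radius 4 px) and a per-cell Otsu
  threshold, intersected with the parent cell and labeled by its
  label.
* Edge objects are kept by default (configurable); labels are
  renumbered contiguously after filtering; coordinates in exported
  tables are 0-based (row, column).

## Quantification conventions

Background is a per-field, per-channel scalar: the 5th percentile
(sort-based, type 1) of pixels outside all cells; the median is an
option, and a fixed value can be supplied. A rolling-ball alternative
was deliberately omitted to keep measurements deterministic and
auditable. Per cell: mean/median/integrated intensity over the cell
compartment per channel (`integrated = mean × area` exactly),
background-corrected means clipped at zero, nucleus-restricted Hoechst
mean, and mitochondria-restricted means for the MMP and mtROS
channels. The mito-restricted mean is the default MMP/mtROS readout
(the probes localize there); whole-cell means are always emitted too,
since either convention is defensible.

## The 541-feature catalogue

The catalogue is defined by `feature_manifest()` (and shipped as a
versioned CSV): shape 15 × 3 compartments = 45; intensity 13 × 3
compartments × 4 channels = 156; Haralick texture 13 × 3 × 4 = 156;
colocalization 3 metrics × 6 channel pairs × 2 compartments = 36;
granularity 16 radii × 4 channels = 64; radial distribution 3 × 4
bins × 4 channels = 48; neighbors 6 × 2 = 12; location 24. Total 541.
The manifest is the single source of truth: `extract_features()`
emits exactly its columns in order for any subset, and tests assert
the count and the family ledger.

Numerical conventions worth knowing:

* **Haralick.** Per-object min–max quantization to 64 gray levels
  (fixed-range quantization is the natural alternative when absolute
  intensities must remain comparable); symmetric normalized GLCMs at
  the four axial/diagonal offsets of length 3, averaged before the
  statistics. Sum variance is computed about the sum average (one of
  the two classical readings of the original definition; the
  brute-force oracle makes the same choice independently). On
  zero-variance regions contrast is 0, the inverse difference moment
  1, and the Haralick correlation **0 by convention** — the one
  deliberate exception to the "undefined means missing" rule, to
  avoid missing-value cascades on flat objects.
* **Shape.** Perimeter is the 8-connected boundary chain length
  (diagonal steps √2, isolated pixels 4), under which a digital
  disc's form factor $4\pi A/P^2$ lands near 1 with up to ~10%
  discretization overshoot. Axis lengths, eccentricity and
  orientation are moment-based; solidity is area over convex-hull
  area capped at 1 (hull from pixel centers).
* **Intensity.** Quantiles are type-7; SD is the sample SD; mass
  displacement is the distance between geometric and
  intensity-weighted centroids.
* **Granularity.** Normalized intensity loss under openings with disc
  radii 1–16; increments are clamped at 0 against the slight
  non-monotonicity of digital-disc granulometries; the spectrum sums
  to 1 when the largest opening removes all signal.
* **Radial.** Four equal-area annuli around the nucleus centroid
  scaled to the cell's maximal radius; radial CV over 8 angular
  wedges.
* Features undefined on a cell's geometry (e.g. texture of an empty
  mitochondrial mask) are `NA`, never silently 0; per-image profiles
  are missing-aware means over cells.

## Profiling

PCA operates on per-image mean profiles (the unit of analysis for
phenotype maps), z-scored per column with the population-SD
convention; zero-variance columns are dropped and reported.
Covariance PCA after z-scoring (equivalent to correlation PCA) via
SVD; an eigendecomposition of the covariance is the test oracle. Sign
convention: the largest-magnitude loading of each component is
positive. Family contributions are sums of squared loadings over
PC1–PC2 normalized across families. Hierarchical clustering defaults
to average linkage on the correlation distance (1 − Pearson between
rows) over per-group **median** profiles (median rather than mean to
resist outlier images; configurable), with ward/euclidean selectable;
constant rows are an error under correlation distance with a pointer
to the euclidean option.

## Coupling statistics

Pearson correlations are computed on `log1p`-transformed intensities
by default. Two reasons: (i) the latent model — and fluorescence
generally — is log-normal, and the Fisher z machinery
($\mathrm{var}(z_r) \approx 1/(n-3)$) assumes bivariate normality: in
simulation the two-sided comparison holds its nominal 5% type-I rate
on the log scale (~0.04) but inflates to ~0.065–0.07 on the linear
scale; (ii) it makes the pooled r directly comparable to the
generating latent ρ, which the recovery tests exploit. Raw-scale
correlations are available via `cor_scale = "linear"`.

Comparisons use the independent-sample Fisher z test throughout, also
for the within-group MMP–ROS vs MMP–mtROS contrast where the two
correlations share the MMP variable; this matches standard screening
practice, and the shared-variable caveat is flagged in the output's
`test` column. A dependent-correlation (Steiger) test is a noted
non-goal. One-sided p values are reported alongside two-sided ones
(both are stored). Confidence intervals are Fisher intervals
$z_r \pm 1.96/\sqrt{n-3}$, back-transformed. Both pooled and per-image
correlation scopes are computed; with unpublished underlying r and n
values for the original experiments, neither scope claims to
reproduce any printed test statistic — the package reproduces the
*procedure* and validates it on simulated ground truth.

## Group statistics and ΔΔCt

Group comparisons default to the classic equal-variance Student's t
(Welch via `var_equal = FALSE`); one-way ANOVA uses the standard
between/within decomposition and equals $t^2$ for two groups (tested
to 1e-10). No multiple-testing correction is applied by default, as
per-comparison stars are the screening convention; a Bonferroni pass
is a one-liner on the returned p values. Star codes: \*, \*\*, \*\*\*
at p < 0.05, 0.01, 0.001. Group summaries report both per-cell n and,
when an experiment column exists, the number of experiments — because
treating cells as independent replicates overstates power when
between-experiment variation matters.

ΔΔCt: $\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{reference}$ per
sample, centered on the **mean** control-group ΔCt (the per-sample
pairing alternative matters only for unbalanced designs), relative
level $2^{-\Delta\Delta Ct}$. Amplification-efficiency correction
(Pfaffl) is out of scope.

## Determinism and seeds

A single master seed is expanded into per-field child seeds by a
fixed linear-congruential mixing scheme (`child_seeds()`), so any
field can be re-rendered in isolation and full runs are byte-identical
(manifest hashes are compared in tests). All RNG use is wrapped so
library calls do not perturb the caller's RNG state.

## Problem sizes used in validation

The test suite validates at sizes chosen to exercise each property
meaningfully: latent-correlation convergence at n = 10⁴; the default
screen (12 groups × 8 fields × 30 cells, 2880 cells) for the
≥200-cells-per-group floor; coupling recovery through the full image
pipeline at ~1000 cells per replicate over 10 replicates
(ordering recovered in all replicates; pooled r within ±0.10 of the
generating ρ, a tolerance that budgets for measurement attenuation);
Fisher-test calibration over 1000 null replicates at n = 500 per
side; and the phenotype-separation property on a screen with the
default per-image cell density and two fields per well. Texture,
intensity, PCA and clustering code are checked against brute-force
oracles (100 random texture patches at 1e-10).

## Known limitations

* The feature catalogue is a reconstruction: it follows CellProfiler
  family conventions and fixes the membership by a published total
  (541) with intensity and texture as the dominant families, but it
  is not feature-for-feature identical to any specific CellProfiler
  project, and no numeric compatibility with CellProfiler output is
  claimed.
* The segmentation stage is functionally equivalent to, not
  byte-compatible with, Fiji-macro pipelines it stands in for.
* Silhouette thresholds in the profiling discrimination test (> 0.2
  tumor, < 0.1 normal) are acceptance choices for the synthetic
  screen, not values measured on real data.
* The simulator's realism limits (optics, heterogeneity, confluence)
  are listed above; claims validated on it transfer to real data only
  as far as those assumptions hold.
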