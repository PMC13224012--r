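# mitoscreen

High-content profiling of mitochondrial redox state from multichannel
live-cell fluorescence images.

`mitoscreen` is an R implementation of a high-content-screening (HCS)
analysis workflow for mitochondrial physiology. Cells are stained with
four dyes — Hoechst (nuclei), a whole-cell ROS probe (DCFH-DA-like), a
mitochondrial superoxide probe (MitoSOX-like) and a membrane-potential
probe (TMRE-like) — imaged in 96-well plates, and analyzed per cell:

1. **simulate** — a synthetic plate generator renders multichannel
   fields from a per-cell latent trivariate log-normal model of
   (MMP, ROS, mtROS), `log(M, R, S) ~ N(mu, D rho D)`, with exported
   ground-truth masks and latents for recovery testing;
2. **segment** — Otsu + watershed nuclei detection on the Hoechst
   channel, seeded propagation to cell bodies, white top-hat
   mitochondria extraction;
3. **quantify** — background-corrected per-cell intensities
   (whole-cell, nucleus- and mitochondria-restricted means);
4. **features** — a CellProfiler-style catalogue of exactly **541**
   morphological features per cell (shape 45, intensity 156, Haralick
   texture 156, cross-channel correlation 36, granularity 64, radial
   distribution 48, neighbors 12, location 24);
5. **profile** — per-image mean profiles, z-scoring, PCA with
   variance-explained and feature-family contributions, hierarchical
   clustering heatmaps;
6. **couple** — redox-coupling statistics: Pearson correlations of
   MMP vs ROS and MMP vs mtROS per group (pooled and per image),
   Fisher transforms `z_r = atanh(r)`, and two-sample z tests
   `Z = (z_r1 - z_r2) / sqrt(1/(n1-3) + 1/(n2-3))` comparing coupling
   strengths between pairs, cell lines and treatments;
7. **stats** — unpaired Student's t, one-way ANOVA, group summaries
   with SEM and star codes, and a ΔΔCt qPCR calculator
   (`rel = 2^-ΔΔCt`, `ΔCt = Ct(target) - Ct(reference)`).

It is aimed at imaging groups who want a scriptable, fully tested,
deterministic re-analysis pipeline for MMP/ROS coupling experiments —
including the ability to validate every stage against simulated ground
truth before touching real plates.

## Worked example

Simulate two baseline groups — normal fibroblasts (HPFC) with latent
coupling ρ(MMP, mtROS) = 0.75 and ρ(MMP, ROS) = 0.35, and a tumor line
(HeLa) with 0.60 / 0.30 — run the full imaging pipeline, and test
whether MMP–ROS coupling is weaker than MMP–mtROS coupling:

```r
library(mitoscreen)

gs_hpfc <- group_spec("HPFC", "control", 0,
                      rho = coupling_rho(0.35, 0.75, 0.40),
                      wells = c("A1", "A2"))
gs_hela <- group_spec("HeLa", "control", 0,
                      rho = coupling_rho(0.30, 0.60, 0.40),
                      wells = c("B1", "B2"))
layout <- plate_layout(list(gs_hpfc, gs_hela))

screen <- run_screen(layout, field_geometry(), seed = 1)
cp <- coupling_profile(screen$cells)
cp$results[, c("cell_line", "pair", "n", "r", "ci_lo", "ci_hi")]
#>   cell_line      pair   n     r  ci_lo ci_hi
#> 1      HeLa   MMP-ROS 240 0.197 0.0722 0.316
#> 2      HeLa MMP-mtROS 240 0.589 0.4992 0.666
#> 3      HPFC   MMP-ROS 240 0.293 0.1729 0.405
#> 4      HPFC MMP-mtROS 240 0.756 0.6965 0.806

subset(cp$comparisons, contrast == "within_group_pair")[,
       c("label1", "label2", "Z", "p_one_sided")]
#>                   label1                   label2      Z p_one_sided
#> 1 HeLa control 0 MMP-ROS HeLa control 0 MMP-mtROS -5.180   1.112e-07
#> 2 HPFC control 0 MMP-ROS HPFC control 0 MMP-mtROS -7.465   4.164e-14
```

Each `r` is a pooled Pearson correlation over ~240 single cells
measured from rendered images (not from the latents), with its Fisher
95% interval; the pooled MMP–mtROS coupling recovered from the images
(0.756 for HPFC, 0.589 for HeLa) sits on the generating latent values.
The negative `Z` statistics say the MMP–ROS coupling is significantly
weaker than the MMP–mtROS coupling in both lines, with the normal line
more tightly coupled than the tumor line.

The staged command-line workflow writes the same results as CSV
artifacts under a run directory:

```sh
Rscript inst/scripts/run_screen.R --stage all \
    --config inst/extdata/default_screen.yaml --out runs/demo
```

producing `cells.csv`, `features.csv` (541 feature columns),
`profiles.csv`, PCA/cluster outputs, `coupling.csv`,
`coupling_tests.csv`, group summaries and `report.md`.

## Layout

- `R/` — implementation (simulation, segmentation, quantification,
  features, profiling, coupling, statistics, staged CLI).
- `inst/extdata/feature_manifest_v1.csv` — the versioned 541-feature
  catalogue (kept in sync with `feature_manifest()` by a test).
- `inst/extdata/default_screen.yaml` — default screen configuration.
- `vignettes/mitoscreen-methods.Rmd` — model, assumptions, parameter
  choices and limitations.
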