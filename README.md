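# perfusim

Transport design and image quantification for microfluidic perfusion
stem-cell culture.

## The problem

Adherent stem cells condition their own medium: secreted autocrine and
paracrine factors accumulate near the monolayer and feed back on growth and
fate decisions. A perfused microfluidic chamber can break these loops by
carrying secreted ligand out of the chamber faster than it diffuses back to
— and rebinds — the cells. Whether a given design actually does so is a
transport question, and whether the resulting biology is measurable is an
image-quantification question. `perfusim` implements both sides for a
parallel-plate chamber design (reference geometry 250 µm × 1250 µm × 13 mm,
perfused at 33 µL/hr):

1. **Design calculator** (`design_summary()` and friends). For a chamber of
   height *h* perfused at mean velocity *v*, a ligand of diffusivity *D_L*,
   and floor cells with *N_R* receptors of association rate *k_on* over a
   disc of radius *r*:

   - Péclet number `Pe = v·h/D_L` (convection vs diffusion),
   - receptor areal density `ρ_R = N_R/(π r² N_A)`,
   - Damköhler number `Da = k_on·ρ_R·h/D_L` (binding vs diffusion),
   - `Pe/Da` (convection vs binding),
   - plane-Poiseuille wall shear `τ = 6µQ/(w h²)`,
   - surface-to-volume ratio and a transport-regime classification.

2. **Chamber simulator** (`solve_steady()`, `capture_fraction()`,
   `pe_sweep()`). A finite-volume steady advection–diffusion–reaction solver
   on the x–z cross-section with a reactive floor (secretion flux `qs`,
   first-order uptake `k_on·ρ_R`), upwind advection and a direct sparse
   solve. It reports the fraction of secreted ligand recaptured by the floor
   versus washed out, with exact mass bookkeeping, and is cross-checked
   against the plug-flow closed form `1 − exp(−k·L/(v·h))`.

3. **Synthetic micrographs** (`sample_scene()`, `grow_scene()`,
   `render_phase()`, `render_fluorescence()`). Colonies as wobbled ellipses
   with exact ground-truth masks, a bright phase halo, controllable growth
   folds and reporter-positive fractions — the test bed for the measurement
   pipeline.

4. **Quantification pipeline** (`segment_phase()`, `cell_area()`,
   `fold_increase()`, `sox1_fraction()`, `aggregate_condition()`,
   `ttest_unpaired_equal_var()`, `fit_standard_curve()`,
   `relative_expression()`). Bright-feature segmentation (white top-hat →
   contrast stretch → threshold → clean → fill holes), growth-area folds,
   reporter fractions, hierarchical condition aggregation with a
   pooled-variance t-test, and qPCR standard-curve quantification normalized
   to a reference gene and control condition.

## Worked example

```r
library(perfusim)
print(design_summary(v_mean_mm_s = 0.03))
```

```
Perfusion chamber transport summary
  mean velocity : 0.0300 mm/s
  Pe            : 75
  Da            : 0.132
  Pe/Da         : 568
  wall shear    : 7.04e-03 dyn/cm^2
  SA/V          : 4 /mm
  regime        : convection_dominated
```

With `Pe ≈ 75` convection beats diffusion across the chamber height, and
with `Pe/Da ≈ 568` it beats receptor binding by a larger margin still, at a
wall shear far below the ~1 dyn/cm² scale where shear phenotypes are
reported. The 2D simulator confirms the washout prediction:

```r
geom <- chamber_geometry(); lig <- ligand_spec(); rec <- receptor_spec()
g <- grid2d(geom)
fl <- floor_model(g, uptake_m_s = uptake_velocity(rec))
v <- mean_velocity(perfusion_setting(), geom)
capture_fraction(solve_steady(g, v, lig, fl))$capture_fraction
#> [1] 0.08617414
```

Only ~9% of secreted ligand is ever recaptured — ~91% is washed out —
against 8.9% from the plug-flow closed form. The numbered scripts under
`analysis/` run the full sequence (design table, transport simulation and
Péclet sweep, imaging-pipeline validation, statistics/qPCR demonstration,
end-to-end two-condition comparison) and write their tables under
`results/`.

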