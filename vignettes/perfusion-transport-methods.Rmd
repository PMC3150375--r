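---
title: "Transport design and quantification methods for perfused culture chambers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport design and quantification methods for perfused culture chambers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## The model

A shallow rectangular chamber (height $h$, width $w \gg h$, length $L$) is
perfused at volumetric rate $Q$, giving mean velocity $v = Q/(wh)$ and a
plane-Poiseuille profile $u(z) = 6v\,(z/h)(1-z/h)$. Cells on the floor
secrete a diffusible ligand (diffusivity $D_L$) at flux $q_s$ and recapture
it through surface receptors. Linearising the binding kinetics turns the
floor into a first-order sink with uptake velocity $k = k_{on}\rho_R$, where
$\rho_R = N_R/(\pi r^2 N_A)$ spreads one cell's $N_R$ receptors over its
projected disc of radius $r$ — a confluent-monolayer convention (a
sphere-membrane alternative, a factor 4 lower, is available via
`receptor_areal_density(..., "sphere")` but is off by default because
attached, spread cells present their footprint to the chamber).

Three dimensionless groups summarise the design:

* $Pe = vh/D_L$ — convection across the height vs diffusion;
* $Da = k h/D_L$ — floor binding vs diffusion;
* $Pe/Da = v/k$ — convection vs binding.

At the reference design point (250 µm height, 33 µL/hr, $D_L = 10^{-6}$
cm²/s, $k_{on} = 10^6\,\mathrm{M^{-1}s^{-1}}$, $10^4$ receptors over a 10 µm
disc) these are $Pe \approx 75$, $Da \approx 0.132$, $Pe/Da \approx 568$:
deep in the convection-dominated regime, where perfusion should sweep
secreted factors out of the chamber. Two conventions coexist for the
velocity: the exact $Q$-derived $v = 0.0293$ mm/s (giving $Pe = 73.3$) and
the rounded $0.03$ mm/s (giving $Pe = 75$); `design_summary()` computes the
former by default and accepts the latter as an override, which is what the
headline $Pe = 75$ uses.

The Damköhler expression deserves a note: it composes as
$Da = k_{on}\rho_R h / D_L$ with $k_{on}$ in m³·mol⁻¹·s⁻¹, which reproduces
the reference value 0.132 exactly from the stated receptor parameters; this
composition is locked by a regression test.

Wall shear is plane-Poiseuille, $\tau = 6\mu Q/(wh^2) = 7.0\times10^{-3}$
dyn/cm² uncorrected. Flow perturbation by attached cells modifies this by an
$O(1)$ factor that depends on cell shape; it is exposed as a multiplicative
`cell_factor` (default 1) rather than hard-coded, and every conclusion that
uses shear relies only on its order of magnitude (well below the
$\sim 1$ dyn/cm² scale of reported shear phenotypes).

Regime classification uses configurable thresholds ($Pe > 10$ and
$Pe/Da > 10$ for convection dominance, $Da$ vs 1 separating
diffusion-dominated from reaction-limited): the design criterion is
"$\gg 1$", and 10 is a conservative reading of "much greater" — the
reference point clears both thresholds by a factor of seven or more.

## The chamber simulator

`solve_steady()` discretises the steady advection–diffusion equation on the
x–z cross-section by node-centred finite volumes: first-order upwind
advection (unconditionally stable and monotone at $Pe \approx 75$ on coarse
grids), central diffusion, and the floor flux
$-D\,\partial c/\partial z = q_s - kc$ entering the floor control volumes
directly. The resulting sparse linear system (no time stepping; the problem
is linear and steady) is solved by sparse LU. Boundary conditions: fresh
medium at the inlet ($c = 0$), advective outflow with zero diffusive flux at
the outlet, no-flux ceiling. The default grid is 261 × 51 (dx = 50 µm,
dz = 5 µm); halving both spacings moves the design-point capture fraction by
about 1%, and the discrete mass balance (secretion = capture + outflow)
closes to machine precision, reported per solve as `mass_balance_error`.

No secretion rate is imposed: the problem is linear in $q_s$, so
concentrations are reported per unit $q_s$ and only the capture/washout
*fractions* are meaningful. Binding is irreversible and unsaturable (no
$k_{off}$, no receptor depletion) — a deliberate ceiling on recapture, so
the washout conclusion is conservative.

Two closed forms bracket the solver. A sealed, flow-free chamber must
recapture everything, with floor concentration $q_s/k$; the solver
reproduces both to well under 0.5% (`closed = TRUE`). In the opposite,
well-mixed limit, the depth-averaged balance gives capture
$1 - \exp(-kL/(vh)) \approx 0.089$ at the design point; the 2D solver gives
0.086, within 4% — at $Pe = 75$ vertical diffusion ($h^2/D \approx 625$ s)
is comparable to residence time ($L/v \approx 440$ s), so the cross-section
is only partially mixed and modest disagreement is expected. A Péclet sweep
(`pe_sweep()`) shows capture falling monotonically from 0.94 at $Pe = 0.1$
to 0.035 at $Pe = 750$.

One subtlety: with a Dirichlet inlet, the $Pe \to 0$ limit of the perfused
configuration is *not* capture $= 1$ — ligand still leaks out of the inlet
by diffusion, at a relative rate $\approx \sqrt{D_L h/k}/L \approx 5\%$ for
the reference parameters. The sweep's low-$Pe$ entries approach this open-inlet
limit, not the sealed-chamber one; the tests assert exactly that, with the
leak accounted in the washout bookkeeping.

## The synthetic-image generator

Scenes are lists of rotated ellipses with a low-order Fourier perturbation
of the boundary radius (amplitudes up to 0.05 on harmonics 2–4), matching
the lobed outline of adherent colonies without any cell-scale model.
Sampling places colonies uniformly (fully inside the frame) with lognormal
size variation (sdlog 0.3), then bisects a single global radius scale so the
realised union coverage lands within 10% of the target; the default target
of 7.5% emulates attachment coverage ~24 h after seeding. Growth rescales
all radii by one bisected factor to a target of fold × current coverage,
pulling centres inward so colonies stay in frame; coverage is capped at 0.95
(confluency), and growth saturates earlier when in-frame colonies cannot
cover the target — either limit sets a `capped` flag.

The phase render is "bright rim + textured interior": the segmentation that
consumes these images keys on bright morphological features, and the halo is
the feature phase-contrast actually provides. Ground truth is exact by
construction (the mask *is* the rendered geometry), reporter masks are
carved colony-by-colony to the requested fraction of cell area, and every
artifact is a pure function of (seed, parameters). Defaults are 512 × 512
16-bit images, ten fields per chamber and three chambers per condition.

What the generator does **not** emulate: optical point-spread, uneven
illumination, debris, colony merging/fragmentation textures, out-of-focus
halos, or any correlation between morphology and reporter state. Passing
recovery tests on these images therefore demonstrates the pipeline's
bookkeeping and robustness to additive noise — not performance on real
micrographs, whose segmentation difficulty is dominated by exactly the
artifacts excluded here.

## The measurement pipeline

`segment_phase()` runs, in fixed order: white top-hat (disc radius 15 px,
larger than the halo width so rims survive), percentile contrast stretch
(1–99.5%), Otsu threshold (a fixed threshold is available for cross-batch
reproducibility), removal of objects under 50 px, and hole filling, which
converts closed halo rings into solid colony masks. A constant image is
returned as an empty mask with a warning rather than an arbitrary split.

`sox1_fraction()` segments the fluorescence channel by stretch + threshold
(no top-hat — reporter regions are filled discs, not rings) and intersects
with the phase mask, guaranteeing a fraction in [0, 1]. Because a contrast
stretch maps even a signal-free image onto the full range, candidates must
also clear median + 6 MAD of the background estimated outside the phase
mask; this mirrors fixed-exposure imaging calibrated on reporter-negative
cells and makes the reporter-free case return 0 instead of thresholded
noise.

Aggregation follows the experimental hierarchy (image → chamber →
experiment → condition mean ± sd with $n-1$ denominator, $n$ =
experiments), and the condition contrast uses the unpaired two-tailed
pooled-variance t-test, written out from the textbook formula and checked
against `stats::t.test(var.equal = TRUE)` to $10^{-9}$. All areas are pixel
fractions: every readout of interest (fold increase, reporter fraction) is
a ratio, so µm calibration is unnecessary.

qPCR quantification is standard-curve based: $C_t = m\log_{10}(A) + b$ per
gene by least squares, efficiency $10^{-1/m} - 1$, curves rejected under
$r^2 = 0.98$ or non-negative slope; amounts $10^{(C_t-b)/m}$ are normalized
to the reference gene (Gapdh) within sample and to the control condition
across samples, making the result invariant to per-sample global $C_t$
shifts.

## Problem sizes and reproducibility

The shipped analyses and tests use the 261 × 51 solver grid, batteries of
~20 synthetic scenes spanning coverages 0.05–0.6 at noise σ ≤ 0.03, and an
end-to-end comparison of 3 experiments × 3 chambers × 2 images per
condition at 256 × 256 px — sizes at which every result in this vignette
recomputes in a few minutes on a laptop. All randomness flows through
explicit integer seeds; derived seeds are folded to stay within integer
range, and repeated runs are bit-identical.

## Known limitations

The solver is 2D (lateral gradients neglected, valid for $w \gg h$), steady,
and linear: no transient dynamics, receptor trafficking, saturation, or
extracellular-matrix binding competition — the last being a recognised
mechanism by which secreted factors can persist near cells even under flow.
The shear correction for attached-cell geometry is a free parameter, not a
prediction. The image generator's realism limits are listed above; the
segmentation defaults are tuned to its render model and would need
re-tuning, and validation against manual annotation, for real data.
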