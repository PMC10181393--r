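---
title: "Unit-cell fiber-volume, porosity and stiffness models for 3D woven scaffold preforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unit-cell fiber-volume, porosity and stiffness models for 3D woven scaffold preforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wovencell)
```

## The problem

Three-dimensional woven preforms of biodegradable polyglycolic-acid (PGA)
fiber are candidate temporary scaffolds for tissue regeneration: unlike
printed or electrospun mats they carry a true through-the-thickness yarn
(the z-yarn), along which cells can colonize the scaffold interior. How much
of a preform is fiber, how that fiber is split between the warp, filling and
z directions, and how much void space remains for cells and hydrogel are the
quantities that determine both the biological performance (porosity,
contact guidance) and the mechanical one (stiffness, strength).

`wovencell` implements the complete measurement-to-prediction chain for the
three standard architectures:

* **3DW-P-ZP** — 3D plain weave, warp-filling and warp-z both interlaced 1/1;
* **3DW-P-ZO** — semi-interlaced, plain in-plane, straight (orthogonal)
  z-yarns;
* **3DW-O-ZO** — fully orthogonal, all yarns straight except at the
  surfaces.

## Measurement reduction

Bench measurements per preform are structure dimensions $S_l, S_w, S_t$,
uncrimped yarn lengths $l_w, l_f, l_{zt}$, directional masses
$M_w, M_f, M_z$ and bulk density $\rho_p$. From these:

* crimp ratio per direction, e.g. $C_w = 100\,(l_w - S_l)/S_l$ — the
  percent excess of the straightened yarn over the span it crosses;
* total fiber volume fraction $V_{fp} = 100\,\rho_p/\rho_f$ with
  $\rho_f = 1.50$ g/cm³ for PGA fiber;
* directional fractions $V_{fw} = (M_w/M_p)\,100\,\rho_p/\rho_f$ (and
  likewise for filling and z), which sum to $V_{fp}$ when the directional
  masses account for the whole preform mass;
* total porosity $V_{tpr} = 100 - V_{fp}$, split equally over the three
  directions ($V_{tpr}/3$ each). No directional-porosity formula
  accompanies the unit-cell models; the equal split is the only rule
  consistent with the bundled reference tables, where the three directional
  porosity entries of every block are identical and sum to the total.

A negative crimp, which can arise from measurement noise, is reported with
a warning rather than raised, so batch reductions of noisy data never
abort. Bulk density exceeding the fiber density is a hard error (the
fraction would pass 100%).

```{r}
crimp_percent(51, 50)
measured_total_fraction(0.74, 1.50)
```

## The analytical unit cell

The repeat box of the weave is spanned by packing factors: thickness
$M d_w + (M{+}1) d_z$, width $N d_w + N d_f$ (orthogonal:
$N d_w + (N{+}1) d_f$), length $T d_f + (T{+}1) d_z$, where $N$, $M$ are
warp yarns per row and column, $T$ the weft density number, and $d$ the
yarn diameters. Each directional fiber volume is (yarn count) × (path
length) × (1 + crimp) × $\pi d^2/4$, divided by the cell volume:

* plain: all three families carry their crimp factor;
* semi-interlaced: the straight z-yarn carries none (its numerator is the
  plain one without $(1+C_z)$); a `semi_z_crimp = "apply"` switch restores
  the factor for users who consider the omission a transcription artifact,
  since measured z-crimp in this architecture is far from zero;
* orthogonal: no crimp factors at all.

Two conventions in the formula family deserve comment. The filling length
term $(M d_w + M d_z)$ is a thickness-like traverse although the filling
runs across the width; it is evaluated as printed in the source model
(a dimensionally consistent but physically odd choice we deliberately do
not "fix"). The orthogonal warp numerator is evaluated as
$N M (T d_f + (T{+}1)d_z)\,\pi d_w^2/4$, i.e. grouped exactly like the
plain and semi-interlaced warp numerators with the crimp factor dropped:
the ungrouped alternative reading is not extensive in the number of warp
yarns and contradicts the voxel model for any cell with more than one warp,
so parallelism across the three formula families decides the ambiguity.

Yarn diameters are rarely measured directly. `effective_yarn_diameter()`
reconstructs them from the yarn linear density (311 tex for the 50-ply PGA
yarn), the yarn material density (1.56 g/cm³) and a packing fraction
$\phi \in (0,1]$: $d = \sqrt{4T/(1000\pi\rho\phi)}$, giving 0.504 mm at
$\phi = 1$. $\phi$ is configurable; 1.0 is the default used throughout.

Identities guaranteed at machine precision: the three directional fractions
sum to the total; total fiber plus total porosity is 100; all fractions are
invariant under a common rescaling of the three diameters. Geometries whose
total exceeds 100% are flagged `non_physical` with a warning and reported
unclamped.

```{r}
p <- default_cell_params("3DW-P-ZP")
analytical_fractions("3DW-P-ZP", p)
```

The `default_cell_params()` repeat cell is $N = M = T = 2$ with all three
diameters at the derived 0.504 mm and the architecture's reference crimps.
A 2×2×2 cell is the smallest repeat in which every formula term (interior
and boundary allowances) is exercised; with these defaults the analytical
totals fall at 37–55%, inside the measured 36.7–49.3% range, which is what
a realistic parameterization should do. The exact cell parameterization
behind the bundled analytical reference block is not recoverable from the
source tables, and reproducing it is deliberately not attempted.

## The voxel unit cell

`build_unit_cell()` is the numerical counterpart: idealized yarn
centerlines are laid out in the same box, a cross-section (circle by
default; area-preserving ellipse and lenticular sections are available for
qualitative studies) is swept along each path, and the cell is rasterized
on a periodic voxel grid. `voxel_fractions()` then counts labels, so the
four fractions partition the grid exactly.

Design choices:

* **Inventory.** $N M$ warps, $T N$ fillings ($T(N{+}1)$ orthogonal),
  $T M$ z-yarns — the same counts the analytical numerators imply.
* **Straight families** (orthogonal cell) sit on the packing lattice the
  box factors imply, alternating with the gap allowances of the other
  families, so families are tangent rather than intersecting.
* **Interlaced paths** are sinusoids with amplitude
  $(d_\text{self}+d_\text{neighbor})/2$ and period twice the crossing-yarn
  pitch. All yarns of a family share one phase: the mean line crosses the
  other family's columns and the extremes dive into the free slots midway
  between them, which makes warp-filling crossings exactly tangent and
  keeps yarns of one family parallel. The z-yarn bend (plain only) cannot
  be tangent everywhere because the thickness lattice is not uniform; the
  overlap it causes is resolved by clipping.
* **Priority.** Overlap claims resolve as warp > filling > z-yarn; later
  families never overwrite, so clipping can only remove fiber volume,
  never create it.
* **Tilted slices.** A slice through a tilted tube is an ellipse; the
  rasterizer stretches the cross-section along the bend direction by the
  local slope factor $\sqrt{1+s^2}$, so the rasterized volume converges to
  arc length × area rather than span × area.
* **Crimp is emergent.** The path geometry fixes the arc length; the
  achieved arc-length crimp is reported in `achieved_crimps` so users can
  compare it with the measured crimps (the sinusoid registry gives ~32%
  warp crimp at the default plain cell — idealized interlacing bends far
  more than the real, compacted preform).
* **Determinism.** The builder has no randomness; the `seed` argument is
  reserved for future jitter studies.

Resolution is given in voxels/mm; at least 20 voxels across the smallest
diameter is recommended (a warning fires below that). At the default study
cell, 80 voxels/mm yields a ≈200³ grid and agrees with the analytical
orthogonal cell within 1.3 percentage points of total fiber fraction; the
difference has three understood sources: the ±$d_z$ length conventions of
the analytical numerators, tangency clipping, and voxelization error.

## Micromechanics

With fiber and matrix treated as a two-phase composite (the hydrogel
filling all pore space), every property follows the linear rule of
mixtures $P = P_f V_f + P_m (1 - V_f)$. Totals use the total fiber
fraction; each directional property (tensile modulus $E_{11}, E_{22},
E_{33}$, shear $G_{12}, G_{23}, G_{13}$, Poisson $\nu_{12}, \nu_{23},
\nu_{13}$, strength $\sigma_{11}, \sigma_{22}, \sigma_{33}$) uses its own
directional fiber fraction with the matrix taking the full complement —
the convention that reproduces the bundled mechanics table. Constituent
shear moduli default to the isotropic relation $G = E/(2(1+\nu))$, which
likewise reproduces every bundled shear entry; they can be overridden in
the materials YAML. Default constants: PGA fiber $E = 6.5$ GPa,
$\sigma = 79.85$ MPa, $\nu = 0.35$; hydrogel $E = 75\times10^{-6}$ GPa,
$\sigma = 25\times10^{-3}$ MPa, $\nu = 0.457$.

Interlacement stress concentration, residual strains and degradation
kinetics are outside the model: predictions are upper-bound, linear-elastic
mixtures.

```{r}
scaffold_mechanics(reference_fraction_set("3DW-O-ZO", "measured"))
```

## Synthetic data and what it validates

`generate_measurements()` draws measurement tables whose ground truth is
fully self-consistent: uncrimped lengths are $S(1+C)$, directional masses
come from the analytical fractions applied to the structure volume, and
bulk density is total mass over volume. Gaussian noise is then added per
quantity, with SDs defaulting to the stated instrument precisions (caliper
0.01 mm, flexible ruler 0.2 mm, balance 0.0001 g) and 0.01 g/cm³ for bulk
density, a value we chose since no precision is stated for the derived
density. Gaussian additive noise is a declared stand-in: the source
reports only instrument precisions, not an error model.

Because the generator uses the analytical model as its ground truth,
zero-noise closure (reduce ∘ generate = identity) validates the reduction
algebra and the plumbing — it does not validate the unit-cell model
against real preforms. Features of real data the generator does not
emulate: yarn cross-section flattening under inter-yarn pressure (the main
cause of model-measurement gaps), non-Gaussian and correlated measurement
errors, and within-preform heterogeneity. `recovery_experiment()` reports
bias and RMSE per recovered quantity; at instrument-precision noise the
recovery is unbiased and RMSE scales linearly with the noise SD.

## Numerical choices and degenerate inputs

* All internal arithmetic is unrounded; 2-decimal rounding happens only in
  CSV presentation (`run_pipeline(out=)`), with full precision in the JSON
  summary.
* Measured fraction sets may carry a bulk-density total that differs from
  the directional sum (the two are determined independently on the bench);
  such sets are marked `additive = FALSE` and both numbers are preserved.
* Comparison sign convention: `100 * (model - measured) / measured`;
  comparisons against a zero measured field are reported `NA`.
* Synthetic draws that would produce non-positive lengths or masses are
  redrawn with a warning, at most 100 times, then fail loudly.
* Voxel grids have at least 2 voxels per axis; grid pitch is recomputed
  per axis so the box is covered exactly.

## Problem sizes

The bundled tests and the acceptance script run the voxel comparison at a
≈200³ grid and the recovery experiments at 1000 replicates; both finish in
seconds on one core, and the voxel estimate changes by well under a
percentage point beyond that resolution.

## Known limitations

* The analytical formulas inherit the source model's conventions (filling
  traverse, $+d_z$ allowances); they are evaluated as printed, not
  re-derived.
* The voxel cell idealizes interlacing as tangent sinusoids; real yarns
  flatten and nest, so both models over-predict fiber fraction whenever
  compaction matters.
* Lenticular/elliptical cross-sections are qualitative options; no
  analytical correction for non-circular sections is provided.
* The rule of mixtures ignores shear coupling and stress concentration at
  interlacements; its directional values are iso-strain upper bounds.
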