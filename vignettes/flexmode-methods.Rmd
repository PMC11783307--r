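---
title: "Normal-mode flexible fitting: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-mode flexible fitting: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexmode)
```

## The problem

Predicted protein structures (e.g. AlphaFold2 models of single chains) are
sometimes globally wrong while locally right: secondary-structure elements
are well formed but their relative placement disagrees with the experimental
cryo-EM density of the assembly. flexmode refines such a model against a
density map by restricting its motion to the low-frequency normal modes of a
coarse-grained elastic network — a small set of smooth, collective
deformations — and optimizing the mode amplitudes so that a map simulated
from the deformed model correlates maximally with the target map.

## The elastic network and its modes

The network nodes are the model's C-alpha atoms. Every node pair within a
cutoff distance (default 12 Å, the standard choice for C-alpha networks) is
connected by a Hookean spring with a single uniform stiffness `k` (default 1;
frequencies are therefore in arbitrary units). At the energy minimum the
second-derivative (Hessian) matrix has the familiar pairwise block structure

$$H_{ij} = -\frac{k}{d_{ij}^2}\, r_{ij} r_{ij}^\mathsf{T}, \qquad
  H_{ii} = -\sum_{j \ne i} H_{ij},$$

with $r_{ij}$ the inter-node displacement. Unit masses are assumed — no
mass-weighting is applied — so eigenvalues are squared angular frequencies in
units of `k`.

A full symmetric eigendecomposition yields modes in ascending frequency
order. The first six eigenvalues of a connected, non-degenerate network are
numerically zero: they span rigid translations and rotations, which the
springs do not resist. Numerically these six vectors are an arbitrary
orthonormal basis of the null space; individual rigid eigenvectors carry no
meaning, only their span does, and both the tests and the mode-range
interface treat them as an indivisible block (modes 1–6). Zero modes are
identified by a relative threshold, `lambda < 1e-8 * max(lambda)`, because an
absolute threshold does not transfer across system sizes. Two further
numerical conventions make archives reproducible: eigenvector signs are fixed
by making the largest-magnitude component positive, and mode numbering is
1-based and inclusive everywhere user-facing (modes "1–12" are twelve modes;
mode 7 is the first internal mode).

Degenerate geometries are handled explicitly: a collinear node set has only a
5-dimensional rigid space (no rotation about its own axis resisted — a
two-atom dimer has eigenvalues $\{0 \times 5,\ 2k\}$), while more than six
zero modes (collinear or planar clusters, under-connected networks) triggers
a degeneracy warning.

Raw orthonormal eigenvectors are used as the deformation basis, with no
$1/\sqrt{\lambda}$ amplitude weighting; elongation coefficients therefore
have units of Å times a unit-norm field, and the ±9 coefficient bounds used
by the global optimizers bracket the amplitudes seen in practice.

## From C-alpha modes to all-atom deformations

Deforming a full atomic model requires per-atom displacements. Two
augmentation schemes are provided, and the choice is exposed rather than
fixed, because the interpolation kernel is genuinely an open design choice:

* **per-residue** (default): every atom inherits its residue's C-alpha
  displacement. This preserves residue-internal geometry exactly under the
  smooth, global motions that low-frequency modes describe, and conserves
  rigid motions exactly.
* **inverse-distance**: a 1/d-weighted average of all C-alpha displacements
  within an interpolation radius (default = the network cutoff, keeping one
  scale parameter), with the distance clamped at 1e-6 Å so atoms coincident
  with a node inherit its displacement exactly. Smoother across residue
  boundaries; each displacement is a convex combination of nearby node
  displacements.

Atoms in residues without a C-alpha (ligands, waters) fall back to the
nearest node with a warning, so they ride with their surroundings. Hydrogens
and heteroatoms are carried through deformation; nothing is stripped.

## Map simulation and the resolution convention

A model is lowered to a density map by depositing, for each atom, a 3D
Gaussian of width $\sigma = \texttt{sigma\_factor} \times \text{resolution}$
evaluated at voxel centers. The default `sigma_factor = 0.5` reads
"resolution" as $2\sigma$ (the Situs-style convention); the factor is a
parameter because kernel-width conventions differ between packages. The
kernel is truncated at 3σ per axis and **normalized over its discrete,
truncated support**, so an atom fully inside the grid contributes exactly its
weight to the map sum. (An analytically normalized but truncated kernel
would systematically lose 1–3% of each atom's mass at the default
truncation; discrete normalization removes that bookkeeping error, and the
correlation measures used for fitting are insensitive to the global scale
this choice affects.) Atoms are deposited by direct kernel evaluation on the
target lattice — the simulated map is generated directly on the (padded)
target grid, avoiding any resampling or interpolation bias in the objective.
A guard rejects $\sigma < 0.4 \times$ spacing, where the discretized
Gaussian would alias. Atom weights default to 1; mass weighting is optional
and immaterial to the correlation objectives.

## Similarity measures and zero-padding

Three measures are implemented over the common (padded) target lattice:

* **Pearson correlation** — centered and variance-normalized. Because
  centering involves the voxel count, Pearson is *not* invariant under
  zero-padding; when used as the fitting objective the target is padded once,
  before optimization, by a fixed margin (default 10 voxels) large enough to
  embed deformed intermediates.
* **Inner product** — $\sum_i x_i y_i$, uncentered and unnormalized; exactly
  invariant under padding, so no margin is needed (default 0) and any density
  the deformation pushes outside the scored volume simply stops contributing.
  This is the default objective: it is the cheapest and, in the recovery
  experiments, as effective as Pearson at locating the optimum. Its one
  caveat, visible in the synthetic experiments, is a mild bias: because the
  simulated-map norm varies with the deformation, slightly compacted
  conformations can out-score the ground truth by ~1%, leaving a residual
  C-alpha RMSD floor of roughly half a voxel that the centered, normalized
  Pearson objective does not have.
* **Situs-style correlation** — the inner product normalized by the
  uncentered norms; provided for reporting, scale-invariant and
  padding-invariant.

## The fitting engine

The objective is the negative similarity of the simulated map of the
deformed model against the target; optimizers minimize it. Four
derivative-free methods are available: Powell's conjugate-direction method
and Nelder–Mead (local, starting from the zero elongation vector), and
dual-annealing-style simulated annealing and differential evolution (global,
bounded to ±9 per coefficient, explicitly seeded — same seed, same result).
Powell and the two global methods are implemented in the package; Nelder–Mead
delegates to `stats::optim`. Defaults follow what works best in the recovery
experiments and at realistic scale: Powell, inner product, mode range 1–12,
masked maps.

Engine contracts worth knowing:

* every evaluation is recorded and the best-ever point is returned even on
  non-convergence or when the evaluation budget (default 10^4) runs out
  (status `"budget-exhausted"`);
* local optimizers stop at a relative objective tolerance of 1e-6; line
  searches bracket by doubling and refine with Brent's method;
* a degenerate evaluation (all simulated density off-grid, similarity
  undefined) scores +1 — the worst value — with a warning instead of
  erroring, so global searches survive pathological corners;
* the simulated map is regenerated from scratch at every evaluation;
  correctness is preferred over incremental-update cleverness, and a
  chain-scale fit costs seconds to minutes on one CPU;
* the reported `best_cc` is recomputed from the returned deformed model, so
  it cannot drift from the optimizer's bookkeeping.

## The synthetic test system

No experimental data ship with the package; every claim is exercised on
generated systems with known ground truth. The main fixture is an
antiparallel three-helix C-alpha bundle of 36 residues per helix
(~115 residues with linkers), mirroring the scale of the multi-helix chains
this method targets; segments are packed at a 4 Å gap and joined by short
linkers, and construction fails loudly if the network is disconnected at the
12 Å cutoff. A "true" structure is made by deforming the bundle along
internal modes 7–12 with amplitudes drawn once per seed, weighted
$\lambda^{-3/2}$ so smooth modes dominate (as in real collective
discrepancies) and rescaled to a stated C-alpha RMSD (2.2–3.6 Å in the
recovery suite; for orthonormal modes the RMSD is exactly
$\lVert a\rVert/\sqrt{N}$). Amplitudes that stretch any consecutive C-alpha
distance by more than 50% are rejected as unphysical. The target is the
truth's simulated 5 Å map (three of the four motivating systems are at 5 Å),
spacing 1 Å, either zone-masked to the truth (radius 5 Å, minimal bounds) or
contaminated with the fringe density of a neighboring copy clipped at the
box face — the decoy variant emulating box-cropped maps.

What these fixtures deliberately do not contain: side chains, B-factors,
experimental noise, map anisotropy, or model error beyond the imposed
deformation (fitting uses the same modes that generated the truth). Passing
the recovery suite therefore demonstrates the correctness and conditioning of
the machinery — not performance on experimental maps, where model
misspecification and map artifacts dominate.

Measured on these conditions (and recomputed by the test suite and
`scripts/acceptance.R` on every run): rigid-block-only fitting recovers a
2 Å translation to well under half a voxel; masked-map recovery reaches
final RMSD ≤ 20% of initial in at least 4 of 5 seeded cases; decoy fringe
density never makes the Powell result worse than the start; and the wide
mode range 1–12 fits a mixed rigid-plus-internal deformation at least as
well as the internal-only range 7–9.

## Numerical choices and limitations

* Dense eigendecomposition (`eigen(symmetric = TRUE)`) is used throughout;
  at single-chain scale (3N of a few hundred) this is fast and exact. Very
  large assemblies would need sparse or block methods, which are out of
  scope.
* Problem sizes in the shipped tests (clusters up to 50 nodes, bundles up to
  ~115 residues, grids up to ~60^3 voxels) were chosen so the full suite
  documents the method at realistic single-chain scale while running in a
  few minutes.
* Mode archives are a versioned plain-text format holding shapes,
  eigenvalues, coordinates and vectors at full double precision; round trips
  are exact, and corrupt or truncated archives are rejected with a clear
  error rather than read partially.
* MRC input accepts modes 0/1/2 with standard axis order and isotropic
  voxels only; the ORIGIN record takes precedence over `nstart` when both
  are present. Situs ASCII I/O is lossless at its 6-significant-digit
  precision.
* Large finite rotations are represented linearly by the rigid modes, so a
  big rotational misalignment is outside the model (as is any motion that
  forms or breaks contacts); an exhaustive rigid-body search should precede
  fitting in that regime.
* Stretching artifacts at extreme elongations are inherent to linear
  normal-mode deformation; the fixture generator's 50% bond-stretch
  rejection bounds them in tests, and downstream local regularization is the
  usual remedy on real structures.
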