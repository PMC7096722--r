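---
title: "Real-space model fitting, refinement and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-space model fitting, refinement and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfit)
```

## The problem

Interpreting a cryo-EM reconstruction usually starts from a homologous
model placed roughly into the map, not from de novo tracing. Getting from
"roughly placed" to "publishable" is a pipeline of local operations: blur
the map to widen the convergence radius, rigid-search a domain into
density, restrain the model to itself so it moves as a body, minimise a
combined geometry + density target, fit side chains one residue at a time,
and validate what came out. `rsfit` implements that pipeline headlessly:
every operation is a plain R function on two value types, an
`rs_structure` (chains → residues → atoms, with LINK records) and a
`density_map` (a 3D grid on an orthogonal cell).

The typical domain-fitting workflow is four calls:

```{r, eval = FALSE}
map_b <- sharpen_blur(map, B = 200)              # widen the funnel
fit   <- jiggle_fit(model, "//A", map_b)          # stochastic rigid search
rs    <- build_standard_restraints(fit$structure)
rs$gm <- generate_self_gm_restraints(fit$structure, limit = 6)
ref   <- refine_zone(fit$structure, "//A", rs, map)   # chain refine
```

## Map algebra

`sharpen_blur(m, B)` multiplies every Fourier coefficient by
$\exp(-B s^2/4)$, $s$ in 1/Å — the crystallographic temperature-factor
convention, so a blurred point source is a Gaussian of width
$\sigma^2 = B/(8\pi^2)$ and blur factors add:
blur(B) ∘ blur(B′) = blur(B+B′), and sharpen(−B) inverts blur(B) exactly
on a noise-free grid. The $s=0$ term is never scaled, so the map mean is
preserved. Positive $B$ (e.g. 200 Å², the value that works well before
rigid fitting) smooths; negative $B$ sharpens. `resample_factor` zero-pads
the spectrum, which is band-limited interpolation onto a finer grid over
the same box: values at original nodes are unchanged. Only orthogonal
cells are supported — cryo-EM maps are P1 orthogonal in practice, and this
avoids space-group machinery.

`synthesize_map()` builds test maps as one Gaussian per atom with
amplitude occupancy × atomic number and the same $\sigma^2 = B/(8\pi^2)$
width convention. This single-Gaussian atom is deliberately non-physical
(real scattering factors are multi-Gaussian); it is chosen because every
Fourier property above then has a closed form. One consequence worth
knowing: because atom amplitude (not integral) is normalised,
synthesize(B+ΔB) equals blur(synthesize(B), ΔB) only up to the analytic
factor $((B{+}\Delta B)/B)^{3/2}$; the test suite checks the identity with
that factor included. Defaults: 0.8 Å spacing and B = 40 Å², roughly the
appearance of a 3 Å reconstruction.

## The refinement target

`total_score()` is a weighted sum of restraint energies minus
`map_weight` × the density fit. Geometry terms are harmonic z-scores
against the monomer dictionary: bonds and angles with Engh–Huber-style
sigmas, periodic torsions (nearest periodic image), least-squares-plane
restraints, signed chiral volumes, and one-sided nonbonded contacts.
Gradients are analytic for every term; the plane gradient holds the
fitted plane fixed, which is exact by the envelope theorem because the
plane minimises the squared distances. All gradients are verified against
central finite differences to 1e-5 relative in the test suite.

Two numerical choices matter and are easy to miss:

* **Cubic density interpolation in the target.** The trilinear
  interpolant used for plain scoring is piecewise linear, so its maxima
  sit exactly on grid nodes; gradient refinement against it pins every
  atom to the nearest node (≈0.09 Å systematic error at 0.8 Å spacing).
  The refinement target therefore evaluates the map with a Catmull–Rom
  tricubic kernel, which is C¹ and has off-node maxima. `interpolate_density()`
  itself stays trilinear — it is the cheap scoring primitive used by the
  stochastic searches, where the bias is irrelevant.
* **Nonbonded exclusions.** Pairs at bonded-graph distance ≤ 3 and pairs
  within one residue are excluded (intra-residue geometry is governed by
  the dictionary's torsions and angles), and the contact target is 0.88 ×
  the vdW-radii sum, with 2.8 Å for N/O–N/O pairs that may hydrogen-bond.
  With these choices an ideal-geometry helix scores exactly zero, which
  the tests rely on.

`refine_zone()` minimises the target over the selected atoms with
L-BFGS-B in cycles, keeping the best model per cycle, so the reported
trace is non-increasing by construction. Atoms outside the zone are fixed
anchors that still contribute to boundary-spanning restraints.

## Self restraints and the robust estimator

`generate_self_gm_restraints()` emits one distance restraint per atom
pair within `limit` Å (4.2 Å classically; 6–7 Å when more restraints are
affordable, and side-chain-less models need the longer limits), excluding
1-2/1-3 bonded pairs, with the current distance as target. The loss is
the Geman–McClure function $z^2/(1+\alpha z^2)$, $z = (d - d_0)/\sigma$:
harmonic near the target, saturating at $1/\alpha$ so a badly wrong
restraint stops pulling. α defaults to 0.01.

The σ default is 0.8 Å, and the reasoning is worth recording. These
restraints exist to make neighbouring atoms move concertedly during large
rearrangements, not to freeze the starting model. A 20-residue model
carries several thousand such pairs; at σ = 0.1 Å their collective pull
dominates the dictionary + density optimum and refinement converges back
to the noisy start (0.26 Å residual error in the recovery experiment in
the test suite) instead of the 0.07 Å achieved at σ = 0.8 Å. 0.8 Å is in
the range of typical esds used for reference-model distance restraints at
low resolution. Both α and σ are arguments and CLI-visible configuration.

## Stochastic rigid fitting

`jiggle_fit()` draws random rigid transforms — rotation angle uniform in
[0, `max_rot_deg`] about a uniformly random axis through the fragment
centroid, translations uniform per component — scores them by
occupancy- and Z-weighted density sum, rigid-body refines the best few,
and replaces the fragment only on strict improvement. "Strict" uses a
0.1% relative margin: refined-score differences below the optimiser's
own tolerance are noise, and without the margin a fragment already at the
optimum would drift. Defaults (400 trials, 30°, 6 Å, keep 5) recover a
20-residue helix displaced by 4 Å + 20° on a 200 Å²-blurred map in 20/20
seeded repeats in the test suite. Everything is driven by one RNG seed,
and trials are scored independently of order, so the search could be
parallelised without changing results.

## Backrub side-chain fitting

For one residue, backbone hypotheses are rigid rotations of the residue's
atoms plus C,O of the previous and N of the next residue about the
Cα(i−1)→Cα(i+1) axis, followed by counter-rotations of the two flanking
peptide units about their own Cα–Cα vectors that restore O(i−1) and
N(i+1) toward their start positions. The full motion keeps the central
residue's τ (N–CA–C) exactly fixed — N, CA, C move as one body — and over
a ±10° sweep the median |Δτ| at the flanking residues is ≈1.6°; without
the peptide counter-rotations it would be ≈2.3°, which is why they are
part of the default motion rather than an optional stage. Side chains are
rebuilt per rotamer by internal coordinates (z-matrix bond lengths and
angles, rotamer χs), hypotheses are scored as density fit minus a clash
penalty (sum of squared overlaps against 0.85 × vdW contact radii;
symmetry mates are not considered), and the model is replaced only on
strict improvement (0.5% relative margin, same rationale as above).
Rotamer priors carry no secondary-structure dependence.

The rotamer library is a compact penultimate-style table (2–4 rotamers
per type with prior fractions), shipped both in code and as a TSV under
`inst/extdata/` so a fuller library can be swapped in.

## Dictionary and fixtures

The monomer dictionary is derived by measuring ideal-coordinate residue
templates built from an embedded z-matrix (Engh–Huber-style backbone
values). Deriving rather than transcribing guarantees that
`make_ideal_polypeptide()` output scores exactly zero against
`build_standard_restraints()` — fixtures and restraints cannot drift
apart. External dictionaries in the mmCIF chem_comp dialect
(`_chem_comp_bond` / `_angle` / `_tor` / `_plane_atom` / `_chir`) are
read by `read_restraint_dictionary()`. Metal coordination uses LINK
records: a LINK between a metal and an N/O/S ligand atom becomes a bond
restraint from a small element-pair table (Zn–N 2.05 Å, Mg–O 2.08 Å, …,
overridable), and the pair is dropped from nonbonded generation. This is
element-pair level only — full atom-type-specific targets are out of
scope and noticeably more accurate in dedicated tools.

What the synthetic fixtures do **not** emulate: solvent and noise in
maps, multi-Gaussian scattering, anisotropy, radiation damage, partial
occupancy disorder, or non-ideal starting geometry beyond Gaussian
coordinate noise and rigid displacement. Passing recovery tests on these
fixtures shows the algorithms and their numerics are sound, not that the
defaults are optimal on experimental reconstructions.

## Validation

Ramachandran classes follow the usual six-way split (all, general,
Ile/Val, Gly, Pro, pre-Pro), with pre-Pro taking precedence over Ile/Val
(an Ile before a Pro is classed pre-Pro). The probability tables are
synthesized as peak-normalised wrapped-Gaussian basin mixtures on a 5°
grid — published reference grids cannot be redistributed here, and the
qualitative geography (helix and strand basins, Gly symmetry, narrow Pro)
is what the package's checks need. Cutoffs default to 0.02 (preferred)
and 0.002 (allowed) of peak and are arguments, as is the grid step. Do
not compare absolute outlier percentages from these tables against
published statistics; within-model comparisons and the Kleywegt ranking
are the intended uses. Kleywegt comparisons pair residues by number when
the shared residues agree in type, falling back to sequence alignment,
and rank by the wrapped torus distance $\sqrt{\Delta\phi^2+\Delta\psi^2}$,
keeping the 50 most distant pairs by default. B-factor reports give both
mean and median because the median ignores a handful of absurd values
(one hot water shifts the mean of a hundred atoms from 20 to 21.8 and
the median not at all).

## Degenerate inputs and tie-breaks

Empty selections warn and return empty structures (not errors); residue
ranges are inclusive and 1-based (`//A/50-100` is 51 residues); fresh
chain ids on merge go A–Z, a–z, 0–9, then two-character ids (mmCIF only);
ligand merging uses minimum atom–atom distance with exact ties going to
the lexicographically smaller chain id; merged-ligand numbering is the
chain maximum plus a configurable gap (default 1); rotamer-distance ties
go to the lower-index (more probable) rotamer; torsion flips for a
period-1 torsion fall back to {180°} so every rotatable bond has a flip;
a blob walk that starts above the contour accumulates from the first
sample; register nudges leave zone-edge residues whose source falls
outside the zone as unchanged-type stubs, and insertions from alignments
are reported but never built (no de novo building anywhere in the
package).

## Problem sizes

The shipped tests and the acceptance script run on 3–100-residue
polypeptides and 16³–128³ grids: large enough that every code path
(boundary residues, periodic wrap, multi-chain bookkeeping) is exercised,
small enough that the whole suite completes in minutes on one CPU. The
same functions run unchanged on full-size chains and maps; only memory
for the O(n²) pair searches (bounded by the distance cutoffs) grows.
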