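---
title: "Rotation-invariant surface descriptors for antibody-antigen interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant surface descriptors for antibody-antigen interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whether an antibody binds a protein, a hapten, a carbohydrate or a nucleic
acid is written into the geometry and electrostatics of its combining site:
protein binders tend to present flat paratopes, small-molecule binders
concave pockets. zern3d quantifies this by turning a molecular surface
patch -- an antibody's combined CDR surface, an antigen epitope, or a decoy
patch -- into a compact vector of rotation- and translation-invariant
numbers, the 3D Zernike invariants, and by comparing patches through cosine
distances between those vectors. Because the invariants forget orientation,
two surfaces that fit each other like a hand and a glove produce nearly
identical vectors, which turns *complementarity* scoring into a *similarity*
computation that needs no superposition or docking.

## The descriptor model

A patch is described in three scalar channels on the unit ball: a binary
shape channel (voxels near the surface), and positive and negative
electrostatic channels (the signed per-residue surface potential split by
sign). Each channel $f(\mathbf{r})$ is expanded in the orthonormal 3D
Zernike basis $Z_{nlm} = R_{nl}(r)\,Y_{lm}(\theta,\varphi)$,

$$ C_{nlm} = \int_{|\mathbf{r}|\le 1} f(\mathbf{r})\,
   \overline{Z_{nlm}}(\mathbf{r})\, d\mathbf{r}, \qquad
   D_{nl} = \sqrt{\textstyle\sum_{m=-l}^{l} |C_{nlm}|^2}, $$

and the invariant vector collects the $D_{nl}$ in lexicographic $(n, l)$
order, $l \le n$, $n - l$ even. At the default maximum order $n = 20$ this
gives 121 invariants per channel; order 10 gives 36. The $D_{nl}$ are exact
rotation invariants of the underlying field; translation and scale are
removed beforehand by centring the patch at its centroid and scaling its
farthest point to radius 0.8 of the unit sphere.

Two patches are compared by the cosine distance
$D(x, y) = 1 - x \cdot y / (\lVert x\rVert\,\lVert y\rVert)$ between their
invariant vectors. *Similarity* averages same-sign electrostatic channels;
*complementarity* averages cross-sign channels (a positive surface facing a
negative one scores as matched), while for shape the two notions coincide
by the mold argument above.

## Pipeline parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| probe radius | 1.4 | Å | solvent probe for the accessible surface |
| points per atom | 256 | -- | deterministic spiral density of the SAS sampler |
| dielectric $\varepsilon$ | 80 | -- | screened-Coulomb residue potential |
| screening length $\lambda$ | 8 | Å | exponential damping of the potential |
| distance floor | 1 | Å | caps the self-term of the residue potential |
| fill | 0.8 | -- | fraction of the unit sphere the patch occupies |
| grid dimension | 64 (up to 128) | voxels/axis | voxelization resolution |
| reach | 1.7 | voxel edges | shape-channel neighbourhood radius |
| order $n_{max}$ | 20 | -- | expansion depth (121 invariants) |
| contact cutoff | 6 / 15 | Å | geometric / electrostatic epitope definition |
| neighbour fraction | 0.05 | -- | k-nearest-neighbour set of the classifier |

The reach is expressed in voxel edges, not Angstrom: after unit-sphere
normalisation an absolute length would mean different things for patches of
different physical size. The electrostatic voxel channels are binarized by
default (`es_mode = "binary"`); `"magnitude"` keeps the mean potential per
voxel instead, and the channels reconstruct the signed field exactly in
that mode.

The surface potential is a deliberately simple screened Coulomb sum
evaluated once per residue at its side-chain centroid and shared by all of
the residue's surface points (per-residue constancy is exact by
construction). Only the sign pattern of this value survives the binarized
channel split, so the method needs the potential's sign structure, not
accurate magnitudes; users with Poisson-Boltzmann or generalized-Born
outputs can attach them verbatim via
`assign_electrostatics(mode = "per_point_file")`. The 1 Å distance floor
exists because the bare sum is singular whenever a charge sits at the
evaluation point, which is the normal situation for the single-atom
pseudo-residues of the test fixtures; it also guarantees a residue's own
charges dominate its sign.

## Patch extraction

The antibody patch is the surface of all residues inside the six Chothia
CDR ranges (L1 24-34, L2 50-56, L3 89-97, H1 26-32, H2 52-56, H3 95-102),
one combined patch per antibody; the table is configurable. Paratope shells
take the fraction of CDR surface points nearest the interface centerpoint
*b*, the centroid of the 10 antibody atoms closest to the antigen, giving
nested sub-patches from the contact core out to the full CDR surface.

The native geometric (electrostatic) epitope is every antigen residue with
a minimum heavy-atom distance below 6 Å (15 Å) to the antibody. Decoy
epitopes are negative controls matched to the native epitope in solvent
accessibility: a pivot residue is drawn uniformly among residues with SASA
inside $0.48 \pm 0.5 \cdot 0.33$ nm² (the documented mean and spread of
native pivots), the patch grows by repeatedly adding the nearest
solvent-exposed residue (relative SASA > 0.2) until its summed SASA first
reaches the native value, and candidates overlapping more than 50% of the
native residues are rejected and resampled. "First crossing" is our
operationalisation of reaching "similar" SASA -- the alternative (closest
value) differs by at most one residue; overlap is counted as the fraction
of *native* residues shared. Decoy pivots may coincide with the native
pivot when the overlap cap allows it.

## Numerical design

Moments are not computed by evaluating the basis at every voxel. Each
$\overline{Z_{nlm}}$ is a polynomial in $(x, y, z)$ with closed-form
coefficients (radial part via Jacobi polynomials, angular part via solid
harmonics), so all moments up to order $n$ follow from one pass of
geometric moments $\sum_v f_v\, x^r y^s z^t$, computed by separable tensor
contractions. The coefficient tensor is cached per order; orders beyond 46
are refused (coefficient growth exhausts double precision). A literal
Riemann-sum oracle (`moments_oracle`) implements the defining integral
independently -- Jacobi recurrences and associated-Legendre recursions
evaluated pointwise -- and the test suite holds the two routes to agree to
better than 1e-6 relative error elementwise.

Numerical conventions worth knowing:

* Voxel $i$ (0-based) has its center at $-1 + (i + 0.5) \cdot 2/\mathrm{dim}$;
  voxel centers outside the unit ball are ignored by the expansion.
* Complex spherical harmonics carry the Condon-Shortley phase. This is
  invisible in $D_{nl}$ but matters if raw moments are compared across
  implementations.
* Patches are centred at the *centroid* of their points. A bounding-box
  center would be marginally closer to the letter of the usual bounding-box
  phrasing, but it is not rotation-covariant: rotating the input moves the
  box center relative to the patch and the resulting translation leaks into
  the invariants. With centroid centring, translation and scale invariance
  are exact and rotation leaves only voxelization noise (measured below 2%
  relative change at dim 64, order 20, against a 5% acceptance band).
* The electrostatic voxel value uses strict containment (points inside the
  voxel), not the reach neighbourhood; with per-residue-constant values the
  mean over enclosed points is then exact.
* Degenerate inputs fail loudly: single-point patches cannot be scaled,
  zero-norm descriptor channels (apolar patches) make cosine distances
  undefined, and both raise errors rather than returning NaN.
* Classifier distance ties are broken by entry id; the neighbour set size is
  $k = \lceil 0.05\,(N-1) \rceil$ with the entry itself excluded, and the
  protein/nonprotein decision thresholds the neighbour count strictly above
  $k \cdot N_{prot}/N_{tot}$, the expectation under uniformly distributed
  labels. The weighted score $\bar N_{pb} = A\,N_{pb}^{elec} +
  (1-A)\,N_{pb}^{shape}$ uses the same threshold, which is the affine
  combination of the two identical single-channel thresholds.
* Descriptors truncate exactly: the order-10 vector is the 36-entry prefix
  of the order-20 vector, so classifier sweeps over the expansion order
  reuse one order-20 computation.

One spec-level invariant was restated: the fraction of occupied voxels is
*not* stable under resolution doubling for a surface shell (the shell is a
fixed number of voxel edges thick, so the fraction scales like
$1/\mathrm{dim}$). The resolution-consistency property the pipeline
actually relies on -- and the one tested -- is that the invariant vector's
direction is stable, with cosine distance around 0.01 between dim 32 and
dim 64 descriptors of the same patch.

## What the synthetic generators emulate

All validation runs on generated data; nothing is downloaded. The
generators reproduce the *statistical structure* the method consumes:

* `make_patch` -- smooth curved patches (spherical caps, ellipsoid caps,
  Gaussian-bump fields) with 5-point pseudo-residues sharing one
  electrostatic value, mirroring per-residue constancy of computed
  surfaces.
* `make_complementary_pair` -- a bumpy patch and an independently sampled
  copy of the same height field offset by a gap, charges negated, under a
  random rigid motion: the surface/mold premise embodied, discoverable only
  through invariance.
* `make_classification_dataset` -- the flat-vs-concave prior: "protein"
  entries are shallow caps on a sphere of radius 14 Å (cap half-angle 25°),
  "nonprotein" entries deep cups on a sphere of radius 5.5 Å (half-angle
  75°), with dipolar versus positively-biased-random charge patterns.
* `make_toy_complex` -- a ~130-residue hollow-sphere antigen (single-atom
  residues sized and spaced so exposed-residue SASA clusters near 0.5 nm²,
  inside the decoy pivot window) plus a two-lobe antibody with
  Chothia-consistent CDR numbering hovering within the 6 Å contact
  distance.

What they deliberately do not emulate: real side-chain geometry, backbone
connectivity, amino-acid composition biases, crystallographic noise, or the
class-imbalance and within-class diversity of curated antibody sets.
Passing the synthetic benchmarks therefore demonstrates that the machinery
is correct and that the descriptors separate geometrically separable
classes at desk scale -- it does not certify the headline performance
figures obtainable on real antibody-antigen datasets, which require
hundreds of curated complexes.

## Problem sizes

The validation suite and the acceptance script use: random $32^3$ grids at
order 8 for oracle agreement; 20 bumpy patches at dim 64, order 20 for the
invariance measurements; 60 decoys (20 per seed, 3 seeds) on the toy
complex; 30 complementary pairs against 10 decoy patches each (330 scored
candidates) for the complementarity ROC; and 25 entries per class for the
classification benchmark. These sizes were chosen as the smallest at which
the measured properties are stable across seeds.

## Known limitations

* The screened-Coulomb surrogate is not a Poisson-Boltzmann potential; only
  its sign pattern is trusted, and patches whose true potential has
  near-zero values everywhere will produce empty electrostatic channels.
* Residue-level epitope selection cannot represent sub-residue contact
  footprints.
* The SAS sampler's spiral directions are fixed in the laboratory frame, so
  per-residue SASA fluctuates by a few percent under rotation of the input
  (total SASA is conserved much more tightly); decoy constraints are
  defined on the antigen in its given frame.
* HETATM (hapten) residues are excluded from CDR patches by default and the
  classifier is strictly two-class (protein vs non-protein).
* `generate_decoys` requires the antigen to be large enough to reach the
  native epitope's SASA outside the 50% overlap cap; tiny antigens fail
  with an explicit error rather than relaxing the constraints.
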