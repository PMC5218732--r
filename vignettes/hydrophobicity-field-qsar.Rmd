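---
title: "A hydrophobicity density field and interaction-fingerprint QSAR for ERa ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hydrophobicity density field and interaction-fingerprint QSAR for ERa ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroqsar)
```

## The model

Estrogen receptor alpha (ERa) binds a remarkably broad range of agonists
and antagonists in a large, flexible, predominantly hydrophobic ligand
binding pocket (LBP). Binding strength is dominated by two ingredients:
a small set of specific polar interactions (hydrogen bonds with Glu353,
His524 and Thr347, and for antagonists a salt bridge between a protonated
tertiary amine and Asp351) and a large, nonspecific hydrophobic contact
between the ligand body and the apolar pocket wall. `hydroqsar` scores
both ingredients from a 3D protein-ligand complex and combines them
linearly.

### Hydrophobicity density on the solvent-accessible surface

The ligand is wrapped in a grid on its solvent-accessible surface (SAS:
atomic spheres inflated by the probe radius). At each grid point $j$ a
hydrophobicity density is evaluated from the ligand's atoms:

$$
\log P_j \;=\; C_1\Bigl|\sum_i \frac{q_i}{r_{ij}^2}\Bigr|
  + C_2\sum_i \frac{q_i^2}{r_{ij}^3}
  + C_3\sum_i \frac{\alpha_i}{r_{ij}^3}
  + C_4\sum_i \frac{\alpha_i}{r_{ij}^6}
  + C_{cav},
$$

where $q_i$ is the net atomic charge, $\alpha_i$ the effective atomic
polarizability and $r_{ij}$ the atom-to-point distance. The first two
terms penalize electrostatically active surface (field and squared-charge
terms are hydrophilic, their coefficients negative), the polarizability
terms and the cavity constant describe the dispersion/cavity contribution.
The coefficients are solvation-model constants taken as printed
($C_1 = -8.85\times10^{-2}$, $C_2 = -1.45\times10^{-1}$,
$C_3 = 1.57\times10^{-2}$, $C_4 = -4.88\times10^{-1}$,
$C_{cav} = 2.34\times10^{-3}$); `hydroqsar` does not refit them. A point
is *hydrophobic* when $\log P_j > 0$.

The hydrophobic contact descriptor integrates the hydrophobic points that
touch the pocket: with $C_k$ the set of grid points inside the van der
Waals surface of the $k$-th hydrophobic pocket residue,

$$
\log P_C \;=\; \sum_k \sum_{j \in C_k,\ \log P_j > 0} \log P_j \, dA_j .
$$

Two reading choices deserve a note. First, the contact sum is printed in
the source literature as a bare sum over grid points; a bare sum scales
with grid density and is not reproducible across implementations, so this
package multiplies each point by its surface area element $dA_j$ by
default and offers `raw_sum = TRUE` for the literal reading. Second,
points lying inside two residues' surfaces contribute once per residue,
following the double sum; `unique_count = TRUE` restricts to once
overall.

### The interaction fingerprint and the linear model

Geometric detectors turn the complex into a six-slot fingerprint, in a
frozen order: FP1 salt bridge with Asp351 (binary), FP2 hydrogen bond
with Glu353 (binary, ligand donates), FP3 hydrogen bond with His524
(binary), FP4 hydrogen bond with Thr347 (binary), FP5 the number of
ligand-internal hydrogen bonds (integer), FP6 $= \log P_C$ (continuous).
Predicted affinity, as log relative binding affinity (RBA, percent scale
where estradiol $= 100$), is

$$\log \mathrm{RBA} = \sum_i c_i\,\mathrm{FP}_i + C,$$

with published coefficients $c_1 = 0.923$, $c_2 = 2.209$, $c_3 = 1.689$,
$c_4 = 1.487$, $c_5 = 0.614$, $c_6 = 3.861$ and intercept $C = -9.341$
(`published_model()`). The intercept is the affinity of a ligand making
no scored interaction at all, about $10^{-9}$ RBA; each binary
coefficient reads directly as a fold change ($10^{2.209} \approx 162$
for the Glu353 bond, and so on).

```{r}
print(published_model())
```

## Geometric criteria and their defaults

The exact numeric thresholds behind the detectors are supplementary
material not reproduced in the source text; the defaults here are
standard structural-biology geometry plus the distances that *are* stated
in the text, and every one of them is configurable through
`geometric_criteria()`:

| parameter | default | meaning |
|---|---|---|
| `hbond_max_dist` | 3.5 A | donor-acceptor heavy-atom distance |
| `hbond_min_angle` | 120 deg | donor-H...acceptor angle |
| `saltbridge_max_dist` | 4.0 A | amine N to carboxylate O |
| `ring_centroid_max_dist` | 5.5 A | T-stack / A-ring centroid separation |
| `ring_interplanar_range` | 60-90 deg | near-perpendicular window |
| `hydroxyl_pair_range` | 10-12 A | phenol-O to distal-OH-O (His524 reach) |
| `length_open_threshold` | 13 A | ligand length requiring the open pocket |

The hydroxyl-pair separation is measured oxygen-to-oxygen (the group
centroid alternative is not used); bounds are inclusive. Arg394 hydrogen-
bond acceptance is detected and reported as a candidate bit but excluded
from the default model, where its contribution is negligible; likewise
the Leu346 backbone-carbonyl bond is reported but unscored for lack of
training affinities.

### His524 conformational classes

His524 is the pocket's most mobile polar residue. Its side chain is
classified from the distance between the imidazole nitrogens and the
pocket anchor (the Glu353 carboxylate centroid): *closed* (hydrogen-bond
capable placement at the distal-hydroxyl site), *moved back* (retracted,
hydrophobic accommodation), *open* (swung out, extending the pocket for
ligands longer than 13 A). The closed boundary is
`hydroxyl_pair_range[2] + hbond_max_dist` = 15.5 A; the moved-back/open
boundary defaults to 18 A. These cutoffs are calibrated against this
package's constructed fixtures (which idealize the three classes), not
against crystal structures, and should be re-examined before use on real
receptors.

Docked poses are filtered through the class logic: the Glu353 bond (HB1)
is always required; on a closed receptor the ligand must fit the
unexpanded pocket and a distal hydroxyl in the 10-12 A window must
realize the His524 bond (HB2); a moved-back receptor demands nothing
further; an open receptor requires ligand length above the threshold.

## Per-atom parameters

The field needs $q_i$, $\alpha_i$ and van der Waals radii.

* **Charges** default to an iterative partial-equalization-of-orbital-
  electronegativity (PEOE) scheme: electronegativity
  $\chi(q) = a + bq + cq^2$ per element/hybridization, charge flowing
  across each bond with a damping factor $2^{-n}$ per iteration (eight
  iterations). The scheme is deterministic, conserves total charge to
  machine precision, and is pluggable (`assign_partial_charges(scheme=)`)
  for users with a preferred charge model.
* **Polarizabilities** come from an additive per-element (hybridization-
  aware for C, N, O) table in cubic Angstrom, swappable as a whole.
* **Radii** default to the Bondi set.

Because docking engines commonly merge non-polar hydrogens into heavy
atoms — which corrupts the surface field — ingestion rebuilds missing
hydrogens at standard bond lengths along directions chosen
deterministically to maximize separation from existing bonds
(`complete_hydrogens()`, automatic in `read_pdb_complex()` and
`load_poses()`).

## Numerical choices

* **Tessellation.** Deterministic Fibonacci point sets per atom sphere,
  buried points removed against all other SAS spheres; each surviving
  point carries `sphere area / points generated` as its area element, so
  weights sum to the SAS area (exact for an isolated sphere, within a
  few percent of the closed-form two-sphere area on overlapping
  geometries at the default density).
* **Canonical frame.** Grids are built in the ligand's principal-axis
  frame with a deterministic sign convention (positive third coordinate
  moment, right-handed) and mapped back, making $\log P_C$ invariant
  under rigid motion of the input to better than $10^{-6}$.
* **Density.** Default 2.0 points per square Angstrom with a 1.4 A water
  probe. On the package's estradiol-sized fixture, doubling the density
  changes $\log P_C$ by about 0.5%; the convergence is dominated by the
  contact-patch boundaries, so very small patches converge more slowly
  than the total.
* **Leave-one-out Q2** is computed through the exact OLS identity
  $e_{(i)} = e_i/(1-h_{ii})$, verified in the tests against an $n$-refit
  oracle to $10^{-12}$.
* **Greedy consensus clustering** orders poses by engine score (ties by
  run index and input position), seeds a cluster with the first
  unassigned pose, and joins later poses to the first cluster whose
  representative is within the RMSD threshold (1.0 A default); clusters
  with at least 3 members are bioactive-conformation candidates. RMSD is
  computed without superposition (poses share the receptor frame) and,
  by default, minimized over element-colored graph automorphisms so that
  symmetric ligands do not inflate their self-distance. The independent
  test oracle demands that the pairwise-RMSD graph decompose into
  disjoint cliques — on such unambiguous inputs any reasonable clustering
  has a unique answer, and the greedy result is checked against it; a
  full partition enumeration would add nothing on those inputs.
* **GA-MLR.** The genetic algorithm over feature masks uses fitness =
  leave-one-out Q2 with an infinitesimal parsimony penalty, tournament
  selection, uniform crossover (0.9), per-bit mutation (1/9), elitism 1,
  population 50, 100 generations, fixed seed. For the nine-bit candidate
  space this is deliberate overkill — `exhaustive_select()` scans all
  subsets and is used as the reference; the GA exists because the method
  being reproduced prescribes one. Whether the original fitness was Q2,
  R2 or an information criterion is not stated; Q2 was chosen because the
  model is validated by leave-one-out.
* **Degenerate inputs.** Zero-radius pockets score nothing and say so;
  rank-deficient designs error naming the collinear bits; censored
  (zero) RBA values must be excluded before fitting since their log is
  undefined.

## What the synthetic fixtures emulate — and what they do not

Everything in the test suite is generated in code.

* `make_toy_complex()` builds idealized binding situations: a phenolic
  A-ring held by the Phe404 pincer (always present — an aromatic ring is
  an absolute requirement of the pocket), pseudo-residues with correct
  donor/acceptor atoms, real residue names and ERa numbering, placed so
  that exactly the requested interactions satisfy the default criteria.
  The diol template puts its two hydroxyl oxygens 11 A apart, matching
  the separation that makes the His524 bond possible on a closed
  receptor.
* `make_synthetic_table()` draws fingerprint rows with Bernoulli binary
  bits, a small-integer internal-bond count and FP6 uniform on the
  published training range (0.80-2.44), with Gaussian noise on
  $y = C + \sum c_i \mathrm{FP}_i$. Bit prevalences (0.2/0.8/0.3/0.15)
  mirror the qualitative frequency of the features in the training
  complexes: the Glu353 bond is nearly universal, the Thr347 bond rare.
  With $n = 31$ and noise 0.3 log units the fitted $R^2$ typically lands
  in the mid-0.9s, consistent with the published self-consistency.
* `make_pose_set()` emulates repeated independent docking runs with
  planted consensus clusters (translational jitter around separated
  centers) and returns ground-truth labels.

The fixtures do **not** reproduce real ERa coordinates, real docking
noise (which is rotational and conformational, not just translational),
crystallographic disorder, or protonation ambiguity. Green tests
demonstrate that the machinery implements the stated model faithfully
and reproducibly — not that the model's absolute $\log P_C$ scale matches
the original on real complexes. That scale depends on grid density,
probe radius, the area-weighting choice and the charge scheme, none of
which are printed; all are exposed as knobs, and absolute reproduction
would require calibration against the original supplementary tables.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the estradiol-like fixture
(about 30 atoms, roughly 800 grid points at the default density, 16k at
the convergence check's doubled density), synthetic tables at the
training size $n = 31$, GA runs with populations of 20-50 over 25-100
generations, and consensus clustering over 500-1000 seeded random pose
sets of up to 9 poses. These sizes were chosen to exercise every code
path at the scale of the original study's training set.

## Known limitations

* Bond orders are perceived geometrically (rings by planarity); exotic
  aromatic systems may need explicit bond blocks via SDF input.
* Protonation is rule-based: aliphatic tertiary amines are treated as
  protonated, nothing else is; no pKa prediction.
* The His524 class cutoffs are fixture-calibrated stand-ins, as are the
  hydrogen-bond/stacking thresholds (supplementary values not available
  in the source text); both are configurable and recorded in every
  report.
* Docking itself is out of scope: poses are ingested from multi-model
  SDF or PDBQT files produced elsewhere (the expected contract is 10
  independent runs per complex).
* The structure reader performs no preparation beyond hydrogen
  completion — no minimization, no loop modeling, no altloc refinement
  beyond highest-occupancy selection.
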