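---
title: "Frontier bond-orbital screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontier bond-orbital screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbgap)
```

## The problem

Frontier molecular-orbital (FMO) theory rationalizes orbital-controlled
cycloadditions by the energy gap between the electron-rich partner's highest
occupied orbital and the electron-poor partner's lowest unoccupied orbital: a
smaller gap predicts a faster reaction. For polyfunctional molecules, however,
the *global* HOMO or LUMO often lives on a spectator group — an aromatic ring,
a remote carbonyl — and says nothing about the bond that actually reacts.
`orbgap` therefore works with *bond orbitals*: the highest occupied bond
orbital (HOBO) and lowest unoccupied bond orbital (LUBO), defined as the
frontier orbitals among those having at least a threshold fraction of their
density on a designated reacting fragment (for an enophile, its unsaturated
bond; for a cycloheptatriene substrate, the conjugated triene).

The package implements the full screening workflow: compute HOBO/LUBO labels
for a corpus of molecules with a surrogate quantum engine, train fingerprint
regression models on those labels, select the best descriptor/model
combination on a cross-validated accuracy grid, and rank candidate enophiles
by their predicted gap against a cycloheptatriene/norcaradiene (CHT/NCD)
reference.

## The surrogate oracle: a parameterized Hückel engine

Production pipelines of this kind label molecules with DFT. A desk-scale,
dependency-free package needs labels it can compute itself, so the quantum
stage is a Hückel-type π molecular-orbital model: for a conjugated system of
$n$ atoms, the Hamiltonian is the parameterized connectivity matrix

$$H_{ii} = \alpha + h_i\,\beta, \qquad H_{ij} = k_{ij}\,\beta$$

for π-bonded pairs, diagonalized exactly; the lowest $n_e/2$ orbitals are
doubly occupied. Energies are kept in β-scaled units with $\alpha = 0,
\beta = -1$ (every label carries a unit tag; an affine map to eV is
configurable but never invented silently). Heteroatom offsets $h$ and bond
factors $k$ follow the classical Streitwieser-style table shipped as an
editable plain-text file (`inst/extdata/huckel_default_params.txt`), with
carbon pinning the scale ($h_C = 0$, $k_{CC} = 1$ exactly). Nitroso groups
are parameterized as azo-type N plus carbonyl-type O. The parameter file's
checksum is recorded in every label, so labels are traceable to the table
that produced them.

What the Hückel level preserves — and all the package's qualitative claims
rest on — is the *ordering* of frontier levels across enophile classes:
electronegative heteroatoms in the π system lower the LUBO, so
N=N and N=O units (azo/triazolinedione, nitroso) sit below C=O, which sits
below isolated C=C/C≡C. What it cannot see: σ orbitals (hence arynes, whose
reactive orbital is in-plane, are accepted only with externally supplied
labels and flagged), electron correlation, substituent field effects beyond
the parameter table, and any 3D effect (sterics, strain, secondary orbital
interactions). Stereochemistry is parsed and preserved but ignored by the
oracle — Hückel energies are stereo-insensitive.

### Bond-orbital selection

The reacting fragment is located by substructure matching (a declared SMARTS
subset: element, charge, aromatic/aliphatic, ring membership, bond order —
anything else is a hard parse error). An orbital's *fragment weight* is the
sum of its squared coefficients over the matched atoms. The HOBO is the
highest-energy occupied orbital with weight ≥ threshold; the LUBO the
lowest-energy unoccupied one. The default threshold 0.3 is this package's
reproducible substitute for the visual orbital inspection such workflows
otherwise rely on: low enough that a two-atom fragment inside an
eight-atom π system can qualify (weights near $2/n$ scale), high enough to
reject spectator orbitals. Energy-degenerate candidates are resolved by
larger fragment weight, then lower orbital index — determinism over
aesthetics. If no orbital reaches the threshold the label errors out
("orbital not localized on fragment") rather than silently falling back to
the global frontier orbital; nitrosobenzene illustrates why, its global HOMO
being ring-dominated while the N=O bond orbital sits deeper in the occupied
stack.

## Molecular graphs

SMILES parsing, aromaticity perception (Hückel 4n+2 on rings of up to seven
atoms, kekulized input normalized), canonical atom ordering (iterative
neighborhood refinement with deterministic tie resolution), and a canonical
SMILES writer are implemented directly on the package's own attributed-graph
type, because every downstream contract — bit-identical fingerprints across
SMILES rewritings, input-order-independent spectra — is stated over that
graph. SDF files are read through ChemmineR's V2000 parser (formal charges
supplemented from `M CHG` property lines). Explicit hydrogens are folded
into per-atom counts; everything operates on the heavy-atom graph.

## Fingerprints

Two hashed families serve as the regression descriptors:

* **circular** (Morgan-style): for each atom and radius $r = 0..4$, the
  canonical encoding of the $r$-neighborhood (element, charge, degree, H
  count, aromaticity; bond orders; neighbor identifiers sorted) is hashed
  into the bit vector. Environments accumulate over radii, so the bit set at
  radius $r$ is a subset of the one at $r+1$.
* **path**: all simple paths of 1–7 bonds (plus bare atom tokens, so no
  molecule maps to the zero vector), each read in its lexicographically
  smaller direction.

Hashing is 32-bit FNV-1a with the published constants, never process-salted,
so fingerprints are bit-identical across runs and platforms; the hash
version tag travels with every feature matrix. The path family stands in for
the Avalon-type descriptor axis of the original workflow, whose exact bit
layout is not publicly specified; what the model-selection stage needs is
two structurally different descriptor families, not bit-level fidelity.
Bit sizes {512, 1024, 2048, 4096} span the published range, anchored by the
4096-bit winner reported there.

## The synthetic corpus

`generate_corpus()` *is* the study condition, not a test fixture: it
enumerates substituted scaffolds for five enophile classes — alkenes,
alkynes, carbonyls, nitroso compounds, azo/triazolinediones — labels each
with the oracle, and adds Gaussian noise (sd 0.05 β) to both energies. The
desk default of 30 molecules per class (150 total) keeps a full grid search
in minutes; `n_per_class = 110` approaches the 552-molecule scale of the
corpus it emulates. The noise level is a stated floor chosen to emulate the
reproducibility scatter of a DFT+visual-assignment labeling pipeline, small
against the ~1.5 β spread of the labels. Substituent enumeration order is
fixed, so the molecule list is deterministic and only the noise depends on
the seed. Arynes are excluded by construction (no oracle labels); the
screening panel carries them with synthetic stand-in external labels,
flagged as such.

What passing tests on this corpus do *not* show: performance on DFT-labeled
real data, where the fingerprint-to-energy map is less additive and
noisier. On Hückel labels the map is close to group-additive, which makes
regularized linear models unusually strong competitors — see the model
selection notes below.

## Models and model selection

Per the workflow's design, separate models are trained for the HOBO and the
LUBO energies (the gap is composed downstream against an arbitrary
reference), with three families:

* **elastic net** via glmnet: penalty
  $\lambda(\rho\|w\|_1 + \tfrac{1-\rho}{2}\|w\|_2^2)$; fitted along a short
  descending λ path for coordinate-descent stability, including the λ→0 OLS
  limit.
* **ε-SVR** via e1071 (linear and RBF kernels).
* **feed-forward neural network**, implemented in the package: 1–3 hidden
  layers, ReLU/tanh, full-batch Adam under a fixed seed (bit-reproducible,
  single-threaded), inputs centered, cosine learning-rate decay, L2 weight
  decay (default 3e-3), optional dropout on the first hidden layer, and
  stochastic weight averaging over the tail of the schedule. The trainer is
  hand-written because the installed alternative (nnet) supports a single
  hidden layer only. Numerical choices that matter at n ≈ 100–500: weight
  decay dominates all other regularizers here; a validation-split early
  stop was tried and rejected (it spends scarce training rows); weight
  averaging adds a small but consistent generalization gain.

`grid_search()` cross-validates every featurizer × model combination with
one *shared* stratified fold assignment (paired comparison across cells),
reports mean validation R² per cell — the accuracy heat map — and selects
the argmax, breaking ties toward the simpler family (elastic net < SVR <
neural net), then fewer hyperparameters. The desk grid (6 featurizers × 16
model configurations, ~100 cells per target) is a deliberate reduction of
the ~650,000-model sweep it mirrors; `default_grid(full = TRUE)` expands the
menus along the documented axes. A caveat stated openly: on the surrogate's
near-additive labels the neural network's advantage over the elastic net is
real but small (typically 0.005–0.01 R²), so at desk scale the selected
family can flip to the linear model for unlucky corpus/fold draws — a
faithful property of these study conditions, not a defect of the selection
machinery.

## Screening

`screen_candidates()` composes gaps, ranks ascending, and flags candidates
against a threshold. Because no numeric reactivity cutoff exists in the
source material, the threshold is anchored: a known-reactive compound (a
triazolinedione fixture by default) sets `threshold = anchor gap × (1 +
tolerance)`, tolerance 0.1 — and raising the tolerance can only flag more
candidates, never fewer. The shipped 42-entry panel of named common
enophiles deliberately includes captodative Michael acceptors (maleimide,
maleic anhydride, DMAD) whose individual LUBOs dip into the reactive
stratum; class-level summaries (medians) are what separate cleanly, with
azo/triazolinedione, aryne and nitroso classes below alkyne, carbonyl and
alkene classes — mirroring the published cluster picture, including its
blurred edges. Rank order is invariant under any consistent affine unit
change. Mode selectivity ([6+2] vs [4+2]) is explicitly out of scope: gap
ranking orders reactivity, not periselectivity.

## Reproducibility plumbing

One user-facing seed fans out to per-stage streams by hashing
(`derive_seed`), so stages are independently re-runnable; all RNG use is
wrapped to restore the caller's stream. Identical seed + config reproduces
corpus CSVs, grid tables and screening reports byte-for-byte. Every CLI run
writes a manifest (subcommand, options, input checksums, package version)
beside its output.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use: the 150-molecule desk corpus
(5 × 30), 5-fold cross-validation over the ~100-cell desk grid for one
target, a 500 × 2048 sparse-recovery design, 25 random conjugated graphs
(≤12 π atoms) for oracle equivalence, and 20 SMILES rewritings × 30 fixture
molecules × two fingerprint families for invariance — sizes chosen so the
whole battery completes in minutes while every check still exercises the
full code path.

## Known limitations

π-only orbital physics (no arynes without external labels, no σ effects, no
3D); a declared SMARTS subset rather than full SMARTS; heuristic canonical
ranking (exhaustive at the first ambiguity level — sufficient for the
chemical space here, not a graph-canonization proof); hashed fingerprints
collide by construction; the NN trainer is full-batch and CPU-bound, sized
for hundreds, not millions, of molecules.
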