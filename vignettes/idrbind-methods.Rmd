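---
title: "Methods: trajectory analysis of disordered-tail receptor–ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of disordered-tail receptor-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbind)
```

## Scope and data model

`idrbind` analyses replicate ensembles of coarse-grain (or atomistic)
trajectories of a membrane receptor whose intrinsically disordered
N-terminal tail is the first binding site of a diffusing protein ligand.
The pipeline covers five analyses — residue contact probability maps,
binding-event detection with time alignment, GROMOS conformational
clustering with 2D population landscapes, binding-mode fingerprints over
ligand structural elements, and chemical-shift-perturbation (CSP)
analysis — plus a synthetic-ensemble generator that plants every quantity
the analyses are supposed to recover.

Internal units are fixed: nm for coordinates and distances, ns for time,
ppm for shifts, amu for masses (PDB input is converted from Å on
ingestion). Residue numbering is 1-based. Frames are also indexed 1-based
throughout, the idiomatic R convention; reported binding *times* are in
ns and independent of that choice. A "residue" is whatever particle set
shares a residue index, so coarse-grain beads and atoms are handled
identically; the backbone/side-chain split is by particle-name convention
(`BB`/`CA`/`N`/`C`/`O` are backbone by default, configurable via
`options(idrbind.backbone_names=)`). Only orthorhombic periodic boxes are
supported; triclinic input is an explicit error.

## Contacts

Two residues are in contact in a frame when their minimum inter-particle
distance (distance of closest approach, minimum-image if periodic) is
within a cutoff. The boundary is inclusive (`d <= c`), which keeps
exact-boundary synthetic constructions stable; nothing in the analysed
systems sits on the boundary with measure > 0. Two cutoffs are in common
use for this system — 0.6 nm for contact maps and 0.5 nm for the binding
regime — so the cutoff is always an explicit parameter (default 0.6 nm
for maps) and is recorded on every result object.

The contact probability of a pair is the fraction of frames in contact,
computed *per replicate* (normalizing by that replicate's length) and
then averaged over replicates with equal weight, so replicates of unequal
length contribute equally. Intra-molecular maps are symmetric with the
diagonal fixed to 1 by convention and excluded from statistics. The
minimum-image convention is applied to inter-molecular distances by
default and off for intra-tail analysis, both overridable.

The per-residue partner profile takes, for each tail residue, the union
of frames in which it touches *any* partner residue — not the sum of
pairwise probabilities, which would double-count frames with multiple
partners. Side-chain centre-of-mass distances are mass-weighted; a
residue with no side-chain particle (e.g. a one-bead glycine) falls back
to all of its particles.

## Binding events and alignment

The time of binding (t = 0) is the earliest frame of a
ligand–receptor contact stretch (0.5 nm cutoff by default) that persists
to the end of the trajectory. The strict criterion takes "persists"
literally: no later frame may exceed the cutoff. Because real minimum
distances graze cutoffs, a tolerant mode is provided as a documented
extension: excursions above a separate dissociation cutoff are forgiven
if they last at most `max_unbound_frames` consecutive frames. With zero
tolerance and equal cutoffs the tolerant mode reduces exactly to strict,
which is tested.

Replicates are aligned by re-indexing each trace so its binding frame is
t = 0 — a pure re-indexing, no values change — and the ensemble is
truncated to the shortest post-binding span before averaging. Truncation
was chosen over padding so that every time point averages the same number
of replicates; with padding, late time points would mix replicate counts.
Replicates that never bind are excluded from aligned averages and counted
in a reported incidence statistic. Requesting a window longer than the
common span is an error naming the span, not a silent clip.

## Clustering and landscapes

Conformers are clustered with the GROMOS (Daura) algorithm on the
pairwise RMSD matrix: the frame with the most neighbours within the RMSD
cutoff becomes a cluster centre, it and its neighbours are removed, and
the scan repeats. Ties in neighbour count are broken toward the lowest
frame index; this makes the result deterministic where the original
leaves the order to the implementation. A consequence of the greedy
removal is that cluster sizes are non-increasing, so "ordered by
population" and "order of extraction" coincide.

Superposition is least-squares rigid-body fitting (proper rotations
only, via the quaternion method in `bio3d`); degenerate fit selections
(fewer than 3 particles, or collinear) are an error. For the tail
landscape the RMSD is fitted *on the tail backbone itself*, so the
coordinate measures internal conformation — consistent with pairing it
with the Met1–Asp26 end-to-end distance. Fitting on the receptor core
instead is available through the `fit_sel` argument.

The RMSD reference is the average structure of the top cluster: each
member is superposed onto the cluster centre and coordinates are
averaged. The 2D landscape bins (RMSD, Met1–Asp26 side-chain COM
distance) on half-open 0.1 nm bins `[k·0.1, (k+1)·0.1)` with origin 0 —
a value exactly on an edge falls in the higher bin. Densities are
normalized per replicate, averaged across replicates, and renormalized,
again so unequal replicate lengths cannot skew the average. Landscape
peaks are bins strictly greater than every neighbour within a Chebyshev
radius (1 bin by default); a flat plateau has no strict maxima by
definition.

## Binding modes

A binding mode is the exact boolean fingerprint of which ligand
structural elements (I: N-domain, II–IV: β-strands, V: α-helix) contact
the receptor group in a frame. Exact-identity modes (no Hamming-distance
merging) match the discrete interacting/non-interacting reading of such
fingerprints; frames before the replicate's binding event are excluded
because modes characterize the bound complex. Populations are bound-frame
fractions within replicate, then replicate-averaged. Element membership
is configuration-driven — the residue composition of the elements is a
property of the ligand, not of the method.

## Chemical shift perturbation

The per-residue CSP combines amide proton and nitrogen shift changes as

$$\Delta\delta = \sqrt{\tfrac{1}{2}\left[\Delta\delta_H^2 +
\left(\tfrac{\Delta\delta_N}{5}\right)^2\right]}$$

The nitrogen scaling (5) and the 1/2 normalization define the statistic
and are deliberately not configurable. Shifts are averaged over
replicates *within* each state first, then differenced, then combined —
the average-then-difference order; a per-replicate-CSP standard deviation
is additionally reported when replicate counts pair up. Prolines (and
optionally the chain-initial residue) have no amide proton and are
reported missing, never zero: a zero would masquerade as "no
perturbation". The hotspot threshold defaults to mean + 1 sd over
non-missing residues with strict inequality, and the numeric cutoff
actually applied is always echoed in the output.

Concordance between a contact profile and a CSP profile is summarized by
the Spearman rank correlation, the Jaccard overlap of top-k sets, and a
per-residue discordance flag (top quartile in one measure, bottom half in
the other). The package's central scientific point is testable here: when
shift perturbations are generated from contacts alone the rank
correlation is near 1, and when a conformational term dominates the
correlation collapses — CSP is then not a reporter of residue contacts.

## The synthetic generator

The generator emulates the statistical structure each analysis assumes,
not physics: there is no force field, no solvent, no PBC wrapping of the
ligand walk. It builds a static receptor core (a 16-bead ring whose
quadrants stand in for ECL1–3 and the lumen), a 37-residue two-bead
tail attached to it, a planar slab of lipid headgroup beads, and a rigid
15-bead ligand divided into elements I–V. The tail sequence defaults to
the human CXCR1 N-terminus (UniProt P25024, residues 1–37), which fixes
Met1/Asp26 as the landscape pair and provides prolines at 7, 21, 22 and
29 for the amide-less CSP path.

Planted features, all recorded in a machine-readable ground-truth object:

* **Two-state tail dynamics.** Frames follow a two-state Markov chain
  (membrane-bound template with residues 1–10 at the bilayer plane vs a
  receptor-contacted hairpin) with stationary occupancies 0.6/0.4 and
  mean dwell 25 frames by default; coordinates are the state template
  plus 0.02 nm Gaussian jitter. The planted landscape centroids are
  computed from the pure templates at generation time.
* **Binding.** The ligand–tail minimum distance is uniform in
  0.7–3.0 nm before the planted binding frame (with transient dips to
  0.4 nm emulating binding–unbinding events, and the frame before
  binding forced unbound), then Normal(0.35, 0.02) nm afterwards. A
  spike option raises a stated fraction of post-binding frames to a
  stated distance to exercise the tolerant criterion. Specs whose noise
  reaches the 0.5 nm detection cutoff (mean + 4 sd) are rejected at
  construction — recovery would be ill-posed, and the generator refuses
  rather than failing silently.
* **Intra-tail contacts.** A planted pair (default Met1–Asp26 at
  p = 0.7) is realized per frame by placing the second residue's
  side-chain bead at 0.45 nm from the first's; both templates keep the
  pair > 3.8 nm apart otherwise, so the per-frame Bernoulli draw is the
  contact indicator exactly. Planting a contact on the landscape pair
  necessarily pins that distance coordinate when engaged, splitting each
  conformational state into contact-on/off basins; landscape recovery
  runs therefore disable planted contacts, and the full-feature study
  run shows the expected four-basin structure.
* **Modes.** Per bound frame a fingerprint is drawn i.i.d. from the
  planted frequencies (default 0.4 I+V, 0.3 I+II+V, 0.2 I+IV+V, 0.1 I,
  the dominant patterns of this receptor–chemokine system); contacting
  elements hang below their anchor tail residues at the planted
  distances, non-contacting elements at 2 nm.
* **Shifts.** Apo amide shifts are baselines (δH ≈ 8.3, δN ≈ 120 ppm)
  plus Gaussian noise; bound shifts add α·contact(i) + β·conf(i) to the
  proton and five times that to the nitrogen, so both nuclei contribute
  equally after the 1/5 weighting.

Randomness derives from one master seed through fixed per-replicate
streams, recorded in the ground truth; the same spec is bit-identical
across runs. Generated trajectories are ordinary `trajectory` objects
and feed every module with no special-casing.

What the generator does **not** emulate — continuous diffusion, rugged
intra-state energy surfaces, correlated noise, realistic lipid dynamics —
bounds what green tests mean: they demonstrate that each stage recovers
what it is defined to measure under its own assumptions, not that those
assumptions hold for any particular real system.

## Problem sizes and numerical choices

Recovery tests run at sizes chosen to make sampling error small relative
to the stated tolerances: binding-time recovery uses 20 replicates of
700 frames; planted-contact probability 10 × 5000 frames (binomial sd
≈ 0.002 at p = 0.7) with the 20-seed ranking check at 3 × 1000 frames,
where a 0.7 contact against a ≤ 0.4 background is far from the decision
boundary; mode recovery ~5000 bound frames (multinomial sd ≈ 0.007);
landscape recovery 4 × 1500 frames with the pairwise-RMSD clustering on
an 80-frame subsample. The contact-ranking check considers
sequence-separated pairs (|i − j| ≥ 3), the standard non-local
definition — bonded neighbours of a connected chain are trivially in
permanent contact and carry no signal.

Other numerical conventions: distances compare with `<=` at cutoffs;
GROMOS ties go to the lowest frame index; landscape bins are half-open
with origin 0; superposition refuses degenerate selections rather than
returning an arbitrary frame; empty selections and zero-length windows
are errors, never silent empties; absence of a binding event is a value
(NULL), not an error.

## Known limitations

* XTC trajectories are not read (no reader available to R here); DCD and
  multi-model PDB are supported, and the generator writes multi-model
  PDB.
* Pairwise-RMSD clustering is O(n²) fits; cluster a subsample of frames
  (as the analysis scripts do) for long trajectories.
* Kinetic quantities (on/off rates, Markov state models) and free-energy
  conversion of landscape densities are out of scope.
* The tolerant binding criterion is a pragmatic extension; reported
  results default to the strict reading.
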