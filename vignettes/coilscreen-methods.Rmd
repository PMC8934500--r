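---
title: "Screening coiled-coil homodimers for stabilizing mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening coiled-coil homodimers for stabilizing mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilscreen)
```

`coilscreen` is a desk-scale re-creation of a structure-based screening
pipeline for dimer-stabilizing mutations in a two-chain parallel
coiled-coil homodimer, of the kind formed by the N-terminal dimerization
domain of the Siah-1-interacting protein (SIP/CacyBP). This vignette
explains the models behind each stage, the parameters that matter, and the
limits of what the synthetic benchmarks can show.

## The screening statistic

The core quantity is a variant-group comparison. A design run produces many
models; each model carries a designed sequence and three energies: the
complex energy (`total_score`), the energy of one monomer in its bound
conformation (`mono_score`), and the binding energy

$$\Delta G \;=\; E(\mathrm{complex}) - E(\mathrm{chain\ A}) - E(\mathrm{chain\ B}),$$

the rigid-separation (single-conformation) convention: the monomers are
scored in the conformation they have in the complex, so ΔG reduces to the
sum of inter-chain interaction terms. Models are grouped by their designed
sequence. Because the design step is allowed to re-introduce the native
residue, a wild-type-like group arises naturally and serves as the
reference:

$$\Delta\Delta G = \overline{\Delta G}_{\mathrm{variant}} -
  \overline{\Delta G}_{\mathrm{wt\text{-}like}},\qquad
  \Delta\mathrm{mono} = \overline{\mathrm{mono}}_{\mathrm{variant}} -
  \overline{\mathrm{mono}}_{\mathrm{wt\text{-}like}}.$$

A variant is selected when ΔΔG < 0 (more negative binding energy, i.e.
higher predicted dimerization propensity) and |Δmono| ≤ ε (monomer
stability unaffected). ε defaults to 0.5 energy units; it is a
configuration parameter because "close to zero" has no canonical value —
it should be set relative to the spread of `mono_score` in the reference
group.

The default screen geometry is a 44-position design window (residues 3–46
of each chain, applied symmetrically to both chains of the homodimer) for
single sites, and for pairs all in-window combinations separated by at
most four intervening residues — which over 44 positions gives
$\sum_{d=1}^{5}(44-d) = 205$ pairs. With a 100-member structure ensemble
and 20 designed models per (member, site) combination, the bookkeeping
identity |records| = |ensemble| × |sites| × |models| yields 88,000
single-site and 410,000 pair records. Designed residues are drawn
uniformly from the 20 standard amino acids (native included); with a
uniform draw the wild-type-like fraction is ≈ 1/20 per designed site,
which is ample for a stable reference at these ensemble sizes. An
energy-guided design engine would instead converge onto low-energy
residues (and a much larger wild-type fraction); the grouping statistic is
agnostic to how the samples were proposed.

## The energy model

Scoring is deliberately pluggable. The default is a residue-centroid
contact potential: each residue carries one side-chain centroid
pseudo-atom (`SC`), and

$$E = \sum_{\substack{\text{pairs } (i,j):\, d_{ij} \le r_c}} e(a_i, a_j)
    \;+\; P \cdot \#\{\text{pairs } d_{ij} \le r_{\mathrm{clash}}\},$$

summing over unordered residue pairs excluding self and sequence
neighbours (i, i±1) within a chain. Defaults: contact cutoff
$r_c = 8$ Å (centroid–centroid), clash distance 2.5 Å, clash penalty
+10 per pair. The shipped 20×20 matrix combines hydrophobic attraction
(−1.0), an aromatic stacking bonus (−0.5), opposite-charge attraction
(−1.5), like-charge repulsion (+1.0), and a weak polar–polar term (−0.2);
it is a plain whitespace-delimited text table and fully user-replaceable.
Energies are abstract units — the point of the pipeline is the *statistic*
(grouping, referencing, selection), not reproducing any physical energy
function, and none of the numeric energies here should be read as
kcal/mol. Under this pairwise-additive model the testable identity
$\Delta G = \mathrm{total} - 2\,\mathrm{mono}$ holds exactly for a
symmetric homodimer, and ΔG depends only on inter-chain terms.

## Synthetic structures

The structure generator places backbone N/CA/C/O atoms on a Crick-style
parameterization of a left-handed two-stranded coiled coil: superhelix
radius $R_0 = 4.9$ Å, minor-helix radius $R_1 = 2.26$ Å, 3.5 residues per
minor turn (102.857°/residue), pitch 140 Å, rise 1.51 Å/residue. The minor
circle lies in the plane normal to the superhelix tangent, which keeps
consecutive CA–CA distances essentially uniform (≈3.94 Å, within the
canonical 3.8 ± 0.3 Å band) and the CA radial distance inside
$[R_0-R_1,\,R_0+R_1]$. The two chains are related by an exact 2-fold
rotation about the superhelix axis (parallel orientation), and the default
minor phase (205.7°) points the heptad a/d seam at the partner chain, so
a/d side chains form the dimer interface as in natural coiled coils.

Side chains are reduced to a single `SC` pseudo-atom per residue on the
outward normal from the chain's own helical axis, at a per-residue-type
distance (a coarse size proxy, 0.5 Å for Gly up to 4.1 Å for Arg). This
single-centroid model is intentional: rotamers, packing and hydrogens are
irrelevant to the screening statistic under test, and a centroid model
keeps 88,000-model screens to a minute of CPU. In-silico mutation changes
the residue code and rescales the SC distance for the new type, leaving
the backbone bit-identical — mirroring the logic of fixed-backbone design.

The default demonstration sequence is a synthetic 46-residue idealized
heptad pattern, **not** the natural SIP sequence (which is not
redistributable here). It is constructed so the well-known variant names
remain meaningful: Lys21 (heptad g), Thr30 (b), Ser33 (e), and Glu34 (f) —
the salt-bridge partner for an introduced Arg30.

Ensembles emulate the practice of designing against multiple
representative conformations: member 1 is the unperturbed structure,
members 2..n add i.i.d. Gaussian coordinate noise (default σ = 0.3 Å).
Where an ensemble should come from a trajectory instead,
`cluster_representatives()` picks k-medoid frames (PAM on the pairwise
backbone-RMSD matrix); PAM was chosen over density- or linkage-based
alternatives because its BUILD+SWAP procedure is deterministic on a fixed
dissimilarity matrix, which makes representative selection exactly
reproducible.

## Synthetic trajectories and their analysis

`generate_trajectory()` produces frames as base coordinates plus isotropic
Gaussian noise — the simplest model with a controllable RMSD scale; there
is no integrator, solvent, or thermostat, and nothing kinetic should be
read into frame order. Its key feature is the *interaction schedule*: a
per-frame boolean vector attached to an atom-pair spec. After noise is
applied, the schedule's second atom is repositioned along the current
inter-atom direction to exactly the "present" distance (default 80% of
the cutoff) or the "absent" distance (250%). Occupancy analysis therefore
has exact ground truth, and the recovery is an identity, not an estimate:
a schedule marking 17 of 20 frames present yields occupancy 0.85 exactly.

Analysis mirrors standard MD post-processing at toy scale:

- **Windowing** keeps the equilibrated tail — by frame fraction (default
  0.5, the analogue of analysing the last 100 ns of a 200 ns run) or by a
  time span, in which case exactly the frames with time > t_end − span
  are kept.
- **Superposition** is the closed-form Kabsch solution via 3×3 SVD with a
  determinant guard enforcing a proper rotation; degenerate (<3 atoms or
  collinear) selections are refused rather than silently fitted. RMSD
  profiles use backbone atoms of both chains.
- **Occupancy** counts frames with selector-pair distance ≤ cutoff.
  Cutoff defaults (salt bridge 4.0 Å, stacking 5.5 Å, generic 8.0 Å) are
  configuration values on SC centroids, not literature atom-contact
  criteria; with centroid geometry only the *classification* convention is
  meaningful: an interaction is reported persistent when occupancy
  strictly exceeds its threshold (defaults 0.90 salt bridge, 0.85
  stacking).
- **Average structures** superpose every frame onto the first and take
  per-atom means. No energy minimization is applied afterwards — a
  deliberate deviation from the common "minimized average structure"
  practice, recorded in the output metadata (`minimized = FALSE`), since
  minimization would require the very force field this package avoids.
- **Binding energies** are computed per frame by the complex/receptor/
  ligand decomposition with the contact potential and aggregated as mean ±
  SEM; replicates (simulations differing only in their noise stream, the
  analogue of independent initial velocity draws) are pooled by
  concatenating per-frame values and recomputing both moments, with
  per-replicate means retained. The pooled mean necessarily lies between
  the replicate means.

## Sequence properties

`average_mass()` sums average isotopic residue masses plus one water
(18.01524 Da), and `isoelectric_point()` solves for zero net charge under
a Henderson–Hasselbalch model over D, E, C, Y side chains (negative), H,
K, R (positive) and both termini, with terminal pKa values depending on
the terminal residue. The constants are the Bjellqvist set used by the
ExPASy Compute pI/Mw tool — the only choice that can reproduce
ExPASy-printed two-decimal values. Net charge is strictly decreasing in
pH, so bisection on [0, 14] finds the unique root; iteration continues to
10⁻⁶ pH units (far below the 0.002 reporting tolerance) so the residual
charge at the returned pH is negligible even for long sequences. Reported
tables round MW and pI to two decimals, matching ExPASy conventions.

## Numerical and design choices

- *Pair separation.* "Separated by no more than four residues" is read as
  at most four intervening residues (index difference ≤ 5); over a
  44-position window this is the only reading that gives 205 pairs.
- *Residue numbering* is 1-based and contiguous within each chain in all
  generated structures; the design window 3–46 refers to this frame. The
  PDB reader, however, keeps `resSeq` verbatim, so externally numbered
  files are not silently renumbered.
- *Determinism.* Every generator is a pure function of (inputs, seed); the
  pipeline derives stage seeds from the single configured seed as
  `seed + 1000 × stage index`. RNG state is restored after each seeded
  operation so library calls do not perturb user sessions.
- *Degenerate inputs* fail loudly with classed conditions: empty
  structures, missing SC atoms, non-two-chain complexes for binding
  decomposition, zero-frame windows, collinear superposition selections,
  mismatched trajectory topologies, reference-group-free record sets.
- *Ties* in candidate ranking are broken lexicographically by signature so
  reports are stable across platforms.
- *PDB field width.* Coordinates with magnitude ≥ 10⁵ Å cannot be
  represented in fixed columns and are rejected rather than truncated.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the screens at the study's
native bookkeeping scale — a 100-member ensemble, 20 models per variant,
88,000 single-site records scored with the toy potential (about a minute
of CPU), and 410,000 pair records with scoring stubbed, which verifies the
count identity without the ~5× scoring cost. Trajectory checks use 20–200
frames; clustering oracles use 6-frame toys where exhaustive search is
feasible. These sizes were chosen so every check recomputes its quantity
from scratch in seconds to a minute on a single core.

## What the synthetic benchmarks do and do not show

The generators emulate the *shapes* of the real inputs — an idealized
dimer geometry, ensembles with controlled spread, trajectories with known
interaction truth — so that the statistics (grouping, referencing,
selection, occupancy, pooling) can be verified exactly against brute-force
oracles and planted ground truth. They do not emulate real conformational
dynamics, side-chain packing, solvation, or any physical energy scale.
Consequently, passing tests certify the correctness of the pipeline's
bookkeeping and mathematics, not the biological accuracy of any specific
candidate list: with the toy potential, the identity of selected variants
reflects the toy matrix and the centroid geometry, and recovering a
*planted* interface reward (the parameter-recovery benchmark) is the
appropriate correctness standard. Reproducing the published candidate
identities or energies for the natural SIP domain would require the
original all-atom scoring machinery, which is out of scope by design; the
published ExPASy MW/pI values of the natural variants are reproducible by
`seq_properties()` but only once the natural sequence is supplied by the
user (see the README note).
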