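---
title: "Geometric detection of interface bonds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric detection of interface bonds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interbond)
```

## The detection model

interbond treats bond prediction as a purely geometric decision problem
on a static structure. Three intermolecular interaction types are
detected independently between two user-declared interface groups (sets
of chains); a residue pair is only ever considered when its members lie
on opposite sides. The detectors share the same chemistry tables but no
state, so each can be audited in isolation and their outputs combined
freely.

**Hydrogen bonds** follow the classic donor/hydrogen/acceptor criteria:
donor–acceptor distance at most 3.9 Å, hydrogen–acceptor distance at
most 2.5 Å, donor–hydrogen–acceptor angle strictly greater than 90°, and
hydrogen–acceptor–antecedent and donor–acceptor–antecedent angles of at
least 90° for *every* covalent antecedent of the acceptor. The distance
pair (3.9/2.5) ensures the hydrogen points toward the acceptor; the
antecedent angles exclude approaches that would clash with the acceptor's
bonding framework. Donors, acceptors, antecedents and hydrogen counts are
tabulated per residue in a plain-text table under `extdata/`
(auditable and overridable via `IB_CHEMISTRY_DIR`); the backbone N
(except proline) donates and the backbone carbonyl O accepts for every
residue.

**Ionic bonds** require opposite formal charge at physiological pH —
arginine, histidine and lysine are taken as +1, aspartate and glutamate
as −1 — plus two distance conditions: whole-residue heavy-atom centroids
strictly closer than 5 Å, and the closest charged N···O pair within the
same cutoff. The centroid condition encodes "the residues as wholes are
close"; the charged-atom condition forces the side chains to actually
face each other. Because long-range electrostatic attraction is not
sharply bounded, 7.5 Å and 10 Å variants are provided as options; the
charged-atom cutoff follows the centroid cutoff unless set explicitly.

**Salt bridges** are the strict co-occurrence reading: side-chain charged
N···O within 4 Å. At that separation no water molecule fits between the
charged groups, so ionic character and hydrogen-bond compatibility are
both plausible. No centroid condition applies. The salt-bridge and ionic
detectors report independently: a ≤ 4 Å charged pair whose centroids are
far apart (long side chains reaching toward each other) is reported as a
salt bridge but not as an ionic bond, and this is intentional — the two
sets answer different questions and neither implies the other here.

### Hydrogen placement

Crystal structures usually lack hydrogens, so donors are protonated with
idealized geometry at a fixed 1.0 Å bond length: the backbone amide H in
the C–N–CA plane along the outer bisector, sp² NH₂ groups planar in
their amide/guanidinium plane, sp³ NH₃ staggered against the preceding
bond. Pre-existing hydrogens are kept untouched. Rotatable hydroxyls
(Ser OG, Thr OG1, Tyr OH) and the Cys thiol are not fixed; the detector
sweeps their X–O–H dihedral in 10° steps and accepts a bond if any
rotamer satisfies the hydrogen-dependent criteria, mirroring the
permissive treatment such donors receive in established hydrogen-bond
software. A donor whose defining neighbors are missing — most commonly
the backbone N of a chain-initial residue, which has no preceding
carbonyl — is flagged unplaceable and skipped with a warning rather than
guessed.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `da_cutoff` | 3.9 | Å | donor–acceptor distance (inclusive) |
| `ha_cutoff` | 2.5 | Å | hydrogen–acceptor distance (inclusive) |
| `dha_min_angle` | 90 | ° | D–H–A angle (exclusive) |
| `antecedent_min_angle` | 90 | ° | acceptor-antecedent angles (inclusive) |
| `ionic_centroid_cutoff` | 5.0 (7.5, 10) | Å | residue-centroid distance (exclusive) |
| `ionic_atom_cutoff` | = centroid cutoff | Å | charged N···O distance (inclusive) |
| `salt_cutoff` | 4.0 | Å | side-chain charged N···O (inclusive) |

Boundary semantics are deliberate: "less than" conditions are strict,
"within" conditions inclusive, evaluated in double precision with no
tolerance fudge. Real coordinates sit on a boundary with probability
zero, so the convention only matters for synthetic data — and the fixture
generator respects the same convention.

## Implementation notes

- **Neighbor search.** Candidate pairs come from uniform spatial binning
  with cell size equal to the cutoff, scanning all 27 neighbor cells.
  This is an invisible optimization: the contract, enforced by tests, is
  exact agreement with a quadratic all-pairs reference
  (`backend = "brute"`).
- **Centroid definition.** The residue centroid is the unweighted mean of
  all heavy atoms, backbone included. A side-chain-only centroid was the
  main alternative; whole-residue is the plainest reading of "amino acid
  centroid" and is applied uniformly. Borderline ionic calls can differ
  between the two conventions.
- **Histidine** is treated as protonated (+1, both ring nitrogens
  charged and donating, neither accepting). This matches the positive
  grouping used in the detection criteria; structures resolved at high pH
  would need a different table row.
- **Terminal groups** (N-terminal ammonium, C-terminal carboxylate) are
  *not* treated as charged: the criteria concern side-chain chemistry.
  HETATM records, waters and non-canonical residues are excluded at
  parse time; alternate locations resolve to the highest occupancy (ties
  toward altloc A); only the first MODEL of multi-model files is kept.
- **Disorder.** A charged residue missing any charged side-chain atom is
  skipped by the ionic/salt detectors with a warning — incomplete side
  chains are not rebuilt or inferred.
- **Degenerate inputs.** A residue with no heavy atoms has no centroid
  (error); an empty interface yields empty tables, not errors; unknown
  residue codes raise an unrecognized-residue error so the caller decides
  whether to skip.

## Free-energy computation

Equilibrium constants are interpreted as molar dissociation constants
and converted via ΔG = RT·ln(K_d) with R = 0.0019872 kcal/(mol·K) —
negative for sub-molar K_d, so larger ΔΔG = ΔG_mut − ΔG_wt means a
destabilizing mutation. Each record's experimental temperature enters
through RT (default 298.15 K when absent), which is the standard way to
make constants measured at different temperatures comparable on the
free-energy scale. ΔΔG is then min–max normalized within each complex to
[0, 1], preventing complexes with wide energy ranges from dominating
cross-complex comparisons; a complex whose records all share one value
(including singletons) maps to the uninformative midpoint 0.5. Group
summaries report the mean, a two-sided 95% *t* interval (only when
n ≥ 2; a single observation yields no interval), and the coefficient of
variation; empty groups are marked explicitly rather than dropped.

### Mutation bond-change classes

A wild-type bond touching the mutated residue through its *backbone*
atoms survives any point mutation ("intact") — chemically forced, since
substitution replaces only the side chain. Side-chain-mediated bonds are
"broken" when the mutant loses the required chemistry (for charged bond
types: no longer oppositely charged to the partner; for hydrogen bonds:
the mutant side chain cannot play the wild type's donor or acceptor
role) and "intact" otherwise. When no wild-type bond of a type touches
the site, "formed" requires two things: the mutation must *introduce*
the chemistry (a capability the wild type lacked — this keeps mutation
to the identical residue from ever being called "formed"), and a
compatible opposite-group partner must have relevant atoms within the
bond cutoff plus the mutant's side-chain reach of the site's Cβ (Cα for
glycine). Side-chain reach is measured on the idealized residue
templates as the Cβ-to-farthest-polar-atom distance. This reach
heuristic deliberately avoids modeling the mutant side-chain
conformation; it asks only whether the bond is geometrically possible,
which makes "formed" a permissive class.

## Evaluation conventions

Predictions are scored against curated reference bond lists on unordered
residue-pair identity plus bond type; atom-level detail is ignored
because references state residue pairs. A residue pair documented with
both a hydrogen bond and an ionic bond implies a salt-bridge reference
entry (added idempotently when absent). True negatives are reported as
"Unknown": no experimental survey exhaustively tests every residue pair,
so TN counts cannot be constructed, and reported precision is therefore
a lower bound (an unverified prediction counts as a false positive even
if it simply has not been tested yet). Precision and recall follow the
count arithmetic TP/(TP+FP) and TP/(TP+FN); zero denominators yield an
explicit undefined marker, never zero.

## What the synthetic fixtures emulate

The generator builds two-chain complexes from idealized residue
templates (Chemical Component Dictionary conformers) posed rigidly so
one controlled quantity — charged-atom distance, donor–acceptor
distance, or D–H–A angle — takes an exact requested value, then applies
a seeded random rigid motion. Plants are chosen so the default
geometries trigger exactly their own bond type: salt bridges use a
head-on Lys/Glu pair (single charged atom; every ammonium hydrogen ends
up outside the hydrogen-bond criteria), ionic bonds a side-by-side
Asp/His pair with the imidazole plane perpendicular to the separation so
no ring N–H points at the carboxylate, hydrogen bonds a Trp indole
N–H donating to a Gln carbonyl (a single fixed hydrogen gives full
control of the D–H–A angle). Decoys violate exactly one criterion each.
Truth tables are derived from the construction analytically — the
detectors are never consulted when writing truth. At charged-atom
distances of 4 Å or less an ionic plant necessarily also satisfies the
salt-bridge criterion, and the truth table says so.

Multi-pair complexes place plants on a 30 Å lattice (nearest atoms of
different plants stay > 12 Å apart, beyond every cutoff). Synthetic
mutation tables emulate the statistical structure of curated mutant
affinity data: bond-breaking mutations receive a +1.5 kcal/mol ΔΔG shift
(within-group SD 1.0 kcal/mol) and K_d values are back-computed at
298.15 K.

What the fixtures do **not** emulate: real backbone conformations,
packing, solvent, crystallographic noise, disorder, or correlated bond
networks. Passing the planted-recovery suite therefore demonstrates that
the criteria are implemented exactly as stated — not that the criteria
themselves are complete for real interfaces, where protonation
ambiguity, water-mediated bonds and coordinate error all blur the
picture. The bundled barnase–barstar-like example is likewise a labelled
synthetic stand-in (real residue identities and author numbering,
idealized coordinates), not the crystal structure.

## Problem sizes

The validation suite uses sweeps of ~200 planted single-pair complexes
(distances 2.6–4.95 Å in 0.05 Å steps; angles 95–180° in 5° steps), 50
random multi-pair complexes of up to ~1,700 atoms for the
neighbor-search equivalence check, and simulated mutation tables of
n = 200. These sizes give exact set comparisons and Monte-Carlo error
around ±0.2 kcal/mol on the recovered shift while keeping the whole
suite fast enough to run routinely.

## Known limitations

- Protonation is fixed (His⁺, Asp⁻/Glu⁻, neutral termini); no pKa
  calculation or pH dependence.
- π–cation, π–π, disulfide, hydrophobic and water-mediated interactions
  are out of scope, as are intramolecular bonds and any energy scoring.
- "Formed" classification uses the wild-type structure plus a reach
  bound, not mutant modeling; it can over-call formation where the real
  side chain would be sterically blocked.
- Reference-based precision inherits the incompleteness of curated bond
  lists; salt-bridge recall in particular is bounded by how strictly the
  4 Å criterion prunes genuine but looser pairings.
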