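# interbond

Detection and classification of intermolecular bonds — hydrogen bonds,
ionic bonds, and salt bridges — across protein–protein binding interfaces,
from atomic coordinates in PDB format.

## Who this is for

Structural biologists and protein engineers who want an explainable,
criteria-based inventory of the electrostatic interactions holding a
protein complex together: which residue pairs across the interface are
bonded, by which bond type, and what happens to those bonds when a residue
is mutated. Predictions are defined purely by textbook geometric and
chemical criteria evaluated on the crystal structure, so every call can be
traced back to a distance or an angle.

## The criteria

All detection is intermolecular: only residue pairs with one residue in
each interface group (sets of chains) are considered.

**Hydrogen bonds.** A donor D (heavy atom bearing a polar hydrogen H) and
acceptor A (lone-pair atom with covalent antecedents AA) are bonded when
all of the following hold:

- |D–A| ≤ 3.9 Å and |H–A| ≤ 2.5 Å,
- ∠(D,H,A) > 90°,
- ∠(H,A,AA) ≥ 90° and ∠(D,A,AA) ≥ 90° for every antecedent AA,
- D and A at least three covalent bonds apart (automatic across an
  interface).

Missing polar hydrogens are placed at 1.0 Å with idealized geometry;
rotatable hydroxyls (Ser/Thr/Tyr, and Cys thiols) are sampled over the O–H
dihedral in 10° steps and accepted if any rotamer qualifies.

**Ionic bonds.** Residues must be oppositely charged at physiological pH
(Arg/His/Lys positive; Asp/Glu negative), their whole-residue heavy-atom
centroids closer than 5 Å (strict), and their closest charged N···O atoms
within the same cutoff. Longer-range variants at 7.5 Å and 10 Å are
available through `--ionic-cutoff` / `detection_params()`.

**Salt bridges.** Oppositely charged residues whose side-chain charged
N···O atoms come within 4 Å — a stricter, hydrogen-bond-compatible variant
of the ionic criterion, with no centroid requirement.

**Mutation analysis.** Given SKEMPI-style measurements (wild-type and
mutant dissociation constants), the package computes ΔG = RT·ln(K_d),
ΔΔG = ΔG_mut − ΔG_wt (positive = destabilizing), min–max normalizes ΔΔG
within each complex to [0, 1], and classifies each mutation's effect on
every predicted bond as **broken** (required chemistry lost), **intact**
(e.g. charged → similarly charged, or backbone-mediated), or **formed**
(new chemistry within geometric reach of an opposite-group partner).
Predictions can be scored against curated reference bond lists with
TP/FP/FN counting (true negatives are unknowable in this setting and
reported as such), precision = TP/(TP+FP) and recall = TP/(TP+FN).

## Worked example

The repository ships a synthetic stand-in for the barnase–barstar
interface (real coordinates are not bundled): an arginine numbered 59 on
chain A facing a glutamate numbered 76 on chain D with a 3.0 Å N···O
contact, built by the fixture generator.

```r
library(interbond)
bb <- make_synthetic_barnase_barstar()
writeLines(bb$pdb, "synthetic_1brs_like.pdb")
cli_main(c("detect", "synthetic_1brs_like.pdb", "--groups", "A:D"))
```

```
[interbond] structure: synthetic_1brs_like, 60 atoms, 4 residues
[interbond] cutoffs: ionic 5 A, salt 4 A, D-A 3.9 A
[interbond] found 0 hydrogen, 0 ionic, 1 salt-bridge bond(s)
bond_type    chain1 resname1 resnum1 chain2 resname2 resnum2 atom1 atom2 role1 distance dha_angle centroid_distance
salt_bridge  A      ARG      59      D      GLU      76      NH1   OE1         3
```

Reading the row: the guanidinium NH1 of Arg59 sits 3.0 Å from the
carboxylate OE1 of Glu76 — inside the 4 Å salt-bridge cutoff — and the two
residues are oppositely charged, so a salt bridge is predicted. No ionic
bond is reported because the whole-residue centroids are farther than 5 Å
(the side chains reach toward each other), and no hydrogen bond because
every guanidinium H sits more than 2.5 Å from the acceptor.

The same classes drive mutation interpretation:

```r
wt  <- detect_all(bb$model, interface_spec("A", "D"))
mut <- data.frame(chain = "A", position = "59",
                  wt_residue = "ARG", mut_residue = "ALA")
classify_bond_change(wt, mut, bb$model, interface_spec("A", "D"))
#>     bond_type classification partner
#> 1    hydrogen           none    <NA>
#> 2       ionic           none    <NA>
#> 3 salt_bridge         broken    D:76
```

## Command line

```
interbond detect   <pdb> --groups A,B:C,D [--ionic-cutoff 5|7.5|10]
                   [--salt-cutoff 4] [--da-cutoff 3.9] [--ha-cutoff 2.5]
interbond ddg      <mutation-table.tsv> [--structure wt.pdb --groups ...]
interbond evaluate <pdb> --groups ... --reference bonds.tsv
interbond fixtures --dir out/ --seed 1
```

The wrapper script is installed under `inst/cli/interbond`; every
subcommand is also callable in-process via `cli_main()`.
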