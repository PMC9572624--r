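# shared helpers: quiet detection wrappers and small hand-built structures

ab_spec <- interbond::interface_spec("A", "B")

detect_quiet <- function(model, spec = ab_spec,
                         params = interbond::detection_params()) {
  suppressWarnings(interbond::detect_all(model, spec, params))
}

# counts per bond type as a named integer vector
bond_counts <- function(bonds) vapply(bonds, nrow, integer(1))

# assemble posed residue templates into a model (wraps internals)
build_model <- function(tpls, chains, resnos, resnames) {
  interbond:::.assemble(tpls, chains, resnos, resnames)
}

# a minimal hand-written PDB with two chains, waters, a HETATM ligand and
# an altloc pair on chain A SER OG
mini_pdb_lines <- function() {
  c(
    "ATOM      1  N   SER A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  SER A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   SER A   1      12.759   7.092  -4.973  1.00  0.00           C",
    "ATOM      4  O   SER A   1      13.164   7.763  -5.923  1.00  0.00           O",
    "ATOM      5  CB  SER A   1      10.521   6.316  -4.136  1.00  0.00           C",
    "ATOM      6  OG ASER A   1       9.533   5.316  -4.236  0.60  0.00           O",
    "ATOM      7  OG BSER A   1       9.433   5.416  -4.136  0.40  0.00           O",
    "ATOM      8  N   GLY B   1      14.000   2.000  -3.000  1.00  0.00           N",
    "ATOM      9  CA  GLY B   1      15.000   2.500  -2.200  1.00  0.00           C",
    "ATOM     10  C   GLY B   1      16.100   3.100  -3.000  1.00  0.00           C",
    "ATOM     11  O   GLY B   1      16.000   3.300  -4.200  1.00  0.00           O",
    "HETATM   12  O   HOH A 101       1.000   1.000   1.000  1.00  0.00           O",
    "HETATM   13 FE    FE A 102       2.000   2.000   2.000  1.00  0.00          FE",
    "END")
}
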