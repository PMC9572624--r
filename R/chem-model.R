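# Cached chemistry tables, loaded once per session from the auditable TSVs
# shipped under extdata. Users may point IB_CHEMISTRY_DIR at a directory
# containing replacement tables with the same layout.
.ib_cache <- new.env(parent = emptyenv())

.chem_dir <- function() {
  dir <- Sys.getenv("IB_CHEMISTRY_DIR", "")
  if (nzchar(dir)) dir else system.file("extdata", package = "interbond")
}

.load_tsv <- function(name) {
  key <- paste0("tsv_", name)
  if (!is.null(.ib_cache[[key]])) return(.ib_cache[[key]])
  path <- file.path(.chem_dir(), name)
  if (!file.exists(path)) {
    path <- system.file("extdata", name, package = "interbond")
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  .ib_cache[[key]] <- x
  x
}

.charge_table <- function() {
  x <- .load_tsv("residue_charges.tsv")
  data.frame(resname = x$resname,
             formal_charge = as.integer(x$formal_charge),
             sidechain_reach = as.numeric(x$sidechain_reach),
             stringsAsFactors = FALSE)
}

.chemistry_table <- function() .load_tsv("residue_chemistry.tsv")

#' Canonical amino-acid codes covered by the chemistry tables
#' @return Character vector of the 20 canonical 3-letter codes.
#' @export
canonical_residues <- function() .charge_table()$resname

# Normalize alternative protonation-state names to the canonical code.
.canon_resname <- function(resname) {
  up <- toupper(resname)
  up[up %in% c("HID", "HIE", "HIP", "HSD", "HSE", "HSP")] <- "HIS"
  up
}

.check_resname <- function(resname) {
  rn <- .canon_resname(resname)
  bad <- setdiff(unique(rn), canonical_residues())
  if (length(bad)) {
    stop("unrecognized residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rn
}

#' Formal charge of a residue side chain at physiological pH
#'
#' ARG, HIS and LYS are +1 (histidine is treated as protonated), ASP and
#' GLU are -1, the remaining canonical residues are 0.
#'
#' @param resname 3-letter residue code(s); HID/HIE/HIP variants are
#'   normalized to HIS.
#' @return Integer vector of formal charges in \{-1, 0, +1\}.
#' @export
#' @examples
#' formal_charge("ARG")  # +1
#' formal_charge(c("GLU", "GLY"))
formal_charge <- function(resname) {
  rn <- .check_resname(resname)
  tab <- .charge_table()
  tab$formal_charge[match(rn, tab$resname)]
}

#' Side-chain atoms carrying the formal charge
#'
#' Nitrogen atoms for basic residues (ARG: NE, NH1, NH2; LYS: NZ;
#' HIS: ND1, NE2), carboxylate oxygens for acidic residues (ASP: OD1, OD2;
#' GLU: OE1, OE2); empty for uncharged residues.
#'
#' @param resname a single 3-letter residue code.
#' @return Character vector of PDB atom names (possibly empty).
#' @export
charged_atoms <- function(resname) {
  rn <- .check_resname(resname)
  stopifnot(length(rn) == 1L)
  tab <- .chemistry_table()
  tab$atom[tab$resname == rn & tab$role == "charged"]
}

#' Hydrogen-bond donor and acceptor atoms of a residue
#'
#' Donors are heavy atoms bearing polar hydrogens (backbone N for all
#' residues except PRO, plus side-chain N/O/S per standard amino-acid
#' chemistry); acceptors are lone-pair-bearing atoms with their covalently
#' bonded antecedent atoms (backbone O with antecedent C for every
#' residue). Hydroxyl (and thiol) donors are flagged rotatable.
#'
#' @param resname a single 3-letter residue code.
#' @return A list with data frames \code{donors} (atom, hcount, rotatable)
#'   and \code{acceptors} (atom, antecedents as a comma-separated string).
#' @export
#' @examples
#' donor_acceptor_table("SER")
donor_acceptor_table <- function(resname) {
  rn <- .check_resname(resname)
  stopifnot(length(rn) == 1L)
  tab <- .chemistry_table()
  d <- tab[tab$resname == rn & tab$role == "donor", , drop = FALSE]
  a <- tab[tab$resname == rn & tab$role == "acceptor", , drop = FALSE]
  list(
    donors = data.frame(atom = d$atom,
                        hcount = as.integer(d$hcount),
                        rotatable = d$rotatable == "1",
                        stringsAsFactors = FALSE),
    acceptors = data.frame(atom = a$atom,
                           antecedents = a$antecedents,
                           stringsAsFactors = FALSE)
  )
}

#' Side-chain reach of a residue
#'
#' Distance from CB to the farthest charged (or, for uncharged polar
#' residues, polar) side-chain atom, measured on the idealized residue
#' templates. Used by the bond-formation heuristic for mutations.
#'
#' @param resname 3-letter residue code(s).
#' @return Numeric vector of distances in Angstrom (0 for residues with no
#'   charged/polar side chain).
#' @export
sidechain_reach <- function(resname) {
  rn <- .check_resname(resname)
  tab <- .charge_table()
  tab$sidechain_reach[match(rn, tab$resname)]
}
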