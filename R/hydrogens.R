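# Idealized polar-hydrogen placement. Donor N-H/O-H bond length is fixed
# at 1.0 Angstrom; geometry follows the hybridization of the donor:
# amide/backbone H in the peptide plane opposite the bisector, sp2 NH2
# planar, sp3 NH3 staggered. Hydroxyl/thiol donors (SER OG, THR OG1,
# TYR OH, CYS SG) are rotatable and handled at detection time by dihedral
# sampling rather than fixed placement.

.H_LEN <- 1.0

# coordinates of one named atom within a residue atom table (or NULL)
.atom_xyz <- function(res_atoms, name) {
  i <- which(res_atoms$name == name & !res_atoms$is_h)
  if (!length(i)) return(NULL)
  as.numeric(res_atoms[i[1], c("x", "y", "z")])
}

# hydrogens already attached to a heavy atom (within 1.3 A, same residue)
.attached_h <- function(res_atoms, xyz) {
  h <- res_atoms[res_atoms$is_h, , drop = FALSE]
  if (!nrow(h)) return(h)
  d <- sqrt((h$x - xyz[1])^2 + (h$y - xyz[2])^2 + (h$z - xyz[3])^2)
  h[d <= 1.3, , drop = FALSE]
}

# bisector-direction H: donor bonded to two heavy neighbors (sp2, 1 H)
.h_bisector <- function(d, n1, n2) {
  dir <- .unit(.unit(d - n1) + .unit(d - n2))
  d + .H_LEN * dir
}

# planar sp2 NH2: two H at +/-120 deg from the N->antecedent direction,
# rotating in the plane with normal defined by (p1 - ant) x (p2 - ant)
.h_sp2_pair <- function(d, ant, plane1, plane2) {
  n <- .unit(pracma::cross(plane1 - ant, plane2 - ant))
  u <- .unit(d - ant)
  list(d + .H_LEN * as.numeric(.rotmat(n, 120) %*% u),
       d + .H_LEN * as.numeric(.rotmat(n, -120) %*% u))
}

# sp3 NH3 staggered about the d->ant axis relative to reference atom
.h_sp3_triplet <- function(d, ant, ref) {
  u <- .unit(d - ant)
  p1 <- .unit((ref - ant) - sum((ref - ant) * u) * u)
  p2 <- pracma::cross(u, p1)
  ang <- 180 - 109.5
  lapply(c(60, 180, 300), function(phi) {
    dir <- cos(ang * pi / 180) * u +
      sin(ang * pi / 180) * (cos(phi * pi / 180) * p1 +
                             sin(phi * pi / 180) * p2)
    d + .H_LEN * .unit(dir)
  })
}

# per-donor placement geometry: list(fun(res_atoms, prev_c)) returning a
# list of H coordinates, or NULL when unplaceable
.place_donor_h <- function(resname, atom, res_atoms, prev_c) {
  g <- function(n) .atom_xyz(res_atoms, n)
  d <- g(atom)
  if (is.null(d)) return(NULL)
  if (atom == "N") {
    ca <- g("CA")
    if (is.null(ca) || is.null(prev_c)) return(NULL)
    return(list(.h_bisector(d, prev_c, ca)))
  }
  switch(paste(resname, atom),
    "ARG NE" = {
      cd <- g("CD"); cz <- g("CZ")
      if (is.null(cd) || is.null(cz)) return(NULL)
      list(.h_bisector(d, cd, cz))
    },
    "ARG NH1" = , "ARG NH2" = {
      cz <- g("CZ"); ne <- g("NE")
      other <- g(if (atom == "NH1") "NH2" else "NH1")
      if (is.null(cz) || is.null(ne)) return(NULL)
      if (is.null(other)) other <- d + c(1, 0, 0)
      .h_sp2_pair(d, cz, ne, d)
    },
    "LYS NZ" = {
      ce <- g("CE"); cd <- g("CD")
      if (is.null(ce) || is.null(cd)) return(NULL)
      .h_sp3_triplet(d, ce, cd)
    },
    "HIS ND1" = {
      cg <- g("CG"); ce1 <- g("CE1")
      if (is.null(cg) || is.null(ce1)) return(NULL)
      list(.h_bisector(d, cg, ce1))
    },
    "HIS NE2" = {
      cd2 <- g("CD2"); ce1 <- g("CE1")
      if (is.null(cd2) || is.null(ce1)) return(NULL)
      list(.h_bisector(d, cd2, ce1))
    },
    "ASN ND2" = {
      cg <- g("CG"); od1 <- g("OD1")
      if (is.null(cg) || is.null(od1)) return(NULL)
      .h_sp2_pair(d, cg, od1, d)
    },
    "GLN NE2" = {
      cd <- g("CD"); oe1 <- g("OE1")
      if (is.null(cd) || is.null(oe1)) return(NULL)
      .h_sp2_pair(d, cd, oe1, d)
    },
    "TRP NE1" = {
      cd1 <- g("CD1"); ce2 <- g("CE2")
      if (is.null(cd1) || is.null(ce2)) return(NULL)
      list(.h_bisector(d, cd1, ce2))
    },
    NULL)
}

# hydroxyl/thiol rotor definition: axis antecedent and dihedral reference
.ROTOR_REF <- list("SER OG" = c("CB", "CA"), "THR OG1" = c("CB", "CA"),
                   "TYR OH" = c("CZ", "CE1"), "CYS SG" = c("CB", "CA"))

# sampled H positions for a rotatable donor (10 degree dihedral steps);
# tetrahedral X-O-H angle. Returns a list of coordinates (possibly empty).
.rotor_h_samples <- function(resname, atom, res_atoms, step = 10) {
  ref <- .ROTOR_REF[[paste(resname, atom)]]
  if (is.null(ref)) return(list())
  d <- .atom_xyz(res_atoms, atom)
  ant <- .atom_xyz(res_atoms, ref[1])
  rr <- .atom_xyz(res_atoms, ref[2])
  if (is.null(d) || is.null(ant) || is.null(rr)) return(list())
  u <- .unit(d - ant)
  p1 <- (rr - ant) - sum((rr - ant) * u) * u
  p1 <- if (.vnorm(p1) < 1e-8) .perp_unit(u) else .unit(p1)
  p2 <- pracma::cross(u, p1)
  ang <- (180 - 109.5) * pi / 180
  lapply(seq(0, 359, by = step), function(phi) {
    phi <- phi * pi / 180
    dir <- cos(ang) * u + sin(ang) * (cos(phi) * p1 + sin(phi) * p2)
    d + .H_LEN * .unit(dir)
  })
}

.is_rotatable_donor <- function(resname, atom) {
  !is.null(.ROTOR_REF[[paste(resname, atom)]])
}

#' Place idealized polar hydrogens on donor atoms
#'
#' Adds missing hydrogens to every hydrogen-bond donor atom at 1.0
#' Angstrom using idealized geometry (backbone amide H in the
#' C-N-CA plane along the outer bisector; sp2 NH2 planar; sp3 NH3
#' staggered). Donors that already carry at least one hydrogen are left
#' untouched; rotatable hydroxyl/thiol donors (SER, THR, TYR, CYS) are
#' left bare and sampled at detection time; donors whose defining heavy
#' neighbors are absent (e.g. the backbone N of an N-terminal residue,
#' which lacks a preceding carbonyl C) are skipped with a warning.
#'
#' @param model an \code{ib_structure}.
#' @return The model with placed hydrogens appended to the atom table and
#'   attribute \code{hydrogens_placed} set.
#' @export
place_polar_hydrogens <- function(model) {
  stopifnot(inherits(model, "ib_structure"))
  atoms <- model$atoms
  rid <- residue_ids(atoms)
  new_rows <- list()
  skipped <- character()
  next_serial <- max(atoms$serial, 0) + 1L

  for (id in unique(rid)) {
    res_atoms <- atoms[rid == id, , drop = FALSE]
    resname <- res_atoms$resname[1]
    dat <- donor_acceptor_table(resname)
    if (!nrow(dat$donors)) next
    # preceding residue's carbonyl C (peptide bond within 1.8 A of N)
    prev_c <- NULL
    nxyz <- .atom_xyz(res_atoms, "N")
    if (!is.null(nxyz)) {
      cc <- atoms[atoms$name == "C" & !atoms$is_h &
                  atoms$chain == res_atoms$chain[1] & rid != id, ,
                  drop = FALSE]
      if (nrow(cc)) {
        dpc <- sqrt((cc$x - nxyz[1])^2 + (cc$y - nxyz[2])^2 +
                    (cc$z - nxyz[3])^2)
        if (min(dpc) <= 1.8) {
          prev_c <- as.numeric(cc[which.min(dpc), c("x", "y", "z")])
        }
      }
    }
    for (k in seq_len(nrow(dat$donors))) {
      atom <- dat$donors$atom[k]
      if (dat$donors$rotatable[k]) next  # rotatable: sampled at detection
      dxyz <- .atom_xyz(res_atoms, atom)
      if (is.null(dxyz)) next
      if (nrow(.attached_h(res_atoms, dxyz)) > 0L) next  # keep existing
      hpos <- .place_donor_h(resname, atom, res_atoms, prev_c)
      if (is.null(hpos)) {
        skipped <- c(skipped, paste0(id, "/", atom))
        next
      }
      base <- sub("^[NOS]", "H", atom)
      for (j in seq_along(hpos)) {
        hname <- if (length(hpos) == 1L) base else paste0(base, j)
        row <- res_atoms[1, , drop = FALSE]
        row$serial <- next_serial
        next_serial <- next_serial + 1L
        row$name <- hname
        row$x <- hpos[[j]][1]; row$y <- hpos[[j]][2]; row$z <- hpos[[j]][3]
        row$occ <- 1
        row$element <- "H"
        row$is_h <- TRUE
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
  }
  if (length(skipped)) {
    warning("hydrogen-unplaceable donor(s) skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(new_rows)) {
    model$atoms <- rbind(atoms, do.call(rbind, new_rows))
    rownames(model$atoms) <- NULL
  }
  attr(model, "hydrogens_placed") <- TRUE
  model
}
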