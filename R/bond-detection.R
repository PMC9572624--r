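# Interface bond detectors. All three detectors consider only residue
# pairs with one residue on each side of the interface, and evaluate their
# geometric criteria in double precision with the boundary semantics:
# strict < for the ionic centroid test, inclusive <= for atom-distance and
# angle-minimum tests, strict > for the donor-hydrogen-acceptor angle.

#' Detection parameters
#'
#' Geometric cutoffs for the three bond detectors. Defaults: donor-acceptor
#' distance 3.9 A, hydrogen-acceptor distance 2.5 A, D-H-A angle > 90
#' degrees, antecedent angles >= 90 degrees, ionic residue-centroid cutoff
#' 5 A (7.5 and 10 A variants for longer-range searches; the charged-atom
#' cutoff follows the centroid cutoff unless set explicitly), salt-bridge
#' charged-atom cutoff 4 A.
#'
#' @param da_cutoff donor-acceptor distance cutoff (A).
#' @param ha_cutoff hydrogen-acceptor distance cutoff (A).
#' @param dha_min_angle minimum D-H-A angle, exclusive (degrees).
#' @param antecedent_min_angle minimum donor/hydrogen-acceptor-antecedent
#'   angle, inclusive (degrees).
#' @param ionic_centroid_cutoff residue-centroid cutoff, exclusive (A).
#' @param ionic_atom_cutoff charged-atom cutoff for ionic bonds, inclusive
#'   (A); defaults to \code{ionic_centroid_cutoff}.
#' @param salt_cutoff side-chain charged N...O cutoff for salt bridges,
#'   inclusive (A).
#' @param backend neighbor-search backend, "cells" or "brute"; the two are
#'   exactly equivalent.
#' @return An object of class \code{detection_params}.
#' @export
detection_params <- function(da_cutoff = 3.9, ha_cutoff = 2.5,
                             dha_min_angle = 90, antecedent_min_angle = 90,
                             ionic_centroid_cutoff = 5.0,
                             ionic_atom_cutoff = NULL,
                             salt_cutoff = 4.0,
                             backend = c("cells", "brute")) {
  if (is.null(ionic_atom_cutoff)) ionic_atom_cutoff <- ionic_centroid_cutoff
  p <- list(da_cutoff = da_cutoff, ha_cutoff = ha_cutoff,
            dha_min_angle = dha_min_angle,
            antecedent_min_angle = antecedent_min_angle,
            ionic_centroid_cutoff = ionic_centroid_cutoff,
            ionic_atom_cutoff = ionic_atom_cutoff,
            salt_cutoff = salt_cutoff,
            backend = match.arg(backend))
  stopifnot(all(unlist(p[1:7]) > 0), p$salt_cutoff <= p$ionic_atom_cutoff)
  structure(p, class = "detection_params")
}

#' Centroid of a residue's heavy atoms
#'
#' Unweighted mean of the heavy-atom (non-hydrogen) coordinates of the
#' whole residue, backbone included.
#'
#' @param res_atoms atom table rows of one residue.
#' @return Numeric length-3 coordinate (A).
#' @export
residue_centroid <- function(res_atoms) {
  heavy <- res_atoms[!res_atoms$is_h, , drop = FALSE]
  if (!nrow(heavy)) stop("degenerate residue: no heavy atoms", call. = FALSE)
  c(mean(heavy$x), mean(heavy$y), mean(heavy$z))
}

# one row of a bond table
.bond_row <- function(type, r1, r2, atom1, atom2, role1 = NA_character_,
                      distance, dha = NA_real_, cdist = NA_real_) {
  data.frame(bond_type = type,
             chain1 = r1$chain, resname1 = r1$resname,
             resnum1 = paste0(r1$resno, r1$insert),
             chain2 = r2$chain, resname2 = r2$resname,
             resnum2 = paste0(r2$resno, r2$insert),
             atom1 = atom1, atom2 = atom2, role1 = role1,
             distance = distance, dha_angle = dha,
             centroid_distance = cdist, stringsAsFactors = FALSE)
}

# charged-residue inventory for one interface side: residue ids, first-row
# metadata, charge sign, charged-atom coordinates. Residues with missing
# charged atoms (side-chain disorder) are skipped with a warning.
.charged_residues <- function(atoms) {
  rid <- residue_ids(atoms)
  ids <- unique(rid)
  out <- list()
  skipped <- character()
  for (id in ids) {
    res_atoms <- atoms[rid == id, , drop = FALSE]
    resname <- res_atoms$resname[1]
    if (!(resname %in% canonical_residues())) next
    q <- formal_charge(resname)
    if (q == 0L) next
    want <- charged_atoms(resname)
    have <- res_atoms[match(want, res_atoms$name), , drop = FALSE]
    if (anyNA(have$name)) {
      skipped <- c(skipped, id)
      next
    }
    out[[id]] <- list(id = id, meta = res_atoms[1, , drop = FALSE],
                      charge = q, res_atoms = res_atoms,
                      atom_names = want,
                      xyz = as.matrix(have[, c("x", "y", "z")]))
  }
  if (length(skipped)) {
    warning("skipping charged residue(s) with missing side-chain atoms: ",
            paste(skipped, collapse = ", "))
  }
  out
}

#' Find intermolecular ionic bonds
#'
#' Reports residue pairs, one per interface side, that are oppositely
#' charged at physiological pH (ARG/HIS/LYS vs ASP/GLU), whose
#' whole-residue heavy-atom centroids are closer than the centroid cutoff
#' (strict), and whose closest charged N...O atom pair is within the
#' charged-atom cutoff (inclusive). One record per residue pair; the atom
#' pair and distance are the closest charged pair.
#'
#' @param model an \code{ib_structure}.
#' @param spec an \code{interface_spec}.
#' @param params a \code{detection_params}.
#' @return A bond table data frame.
#' @export
find_ionic_bonds <- function(model, spec, params = detection_params()) {
  sel <- select_interface(model, spec)
  g1 <- .charged_residues(sel$group1)
  g2 <- .charged_residues(sel$group2)
  if (!length(g1) || !length(g2)) return(empty_bonds())
  c1 <- t(vapply(g1, function(r) residue_centroid(r$res_atoms), numeric(3)))
  c2 <- t(vapply(g2, function(r) residue_centroid(r$res_atoms), numeric(3)))
  cand <- close_pairs(c1, c2, params$ionic_centroid_cutoff,
                      method = params$backend)
  cand <- cand[cand$d < params$ionic_centroid_cutoff, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    r1 <- g1[[cand$i[k]]]
    r2 <- g2[[cand$j[k]]]
    if (r1$charge * r2$charge >= 0L) next
    pp <- close_pairs_brute(r1$xyz, r2$xyz, params$ionic_atom_cutoff)
    if (!nrow(pp)) next
    best <- pp[which.min(pp$d), ]
    rows[[length(rows) + 1L]] <-
      .bond_row("ionic", r1$meta, r2$meta,
                r1$atom_names[best$i], r2$atom_names[best$j],
                distance = best$d, cdist = cand$d[k])
  }
  .finish_bonds(rows)
}

#' Find intermolecular salt bridges
#'
#' Reports oppositely charged residue pairs, one per interface side, whose
#' minimum side-chain charged N...O distance is within the salt cutoff
#' (4 A by default, inclusive). No centroid requirement; this is the
#' stricter, hydrogen-bond-compatible variant of the ionic criterion.
#'
#' @inheritParams find_ionic_bonds
#' @return A bond table data frame.
#' @export
find_salt_bridges <- function(model, spec, params = detection_params()) {
  sel <- select_interface(model, spec)
  g1 <- .charged_residues(sel$group1)
  g2 <- .charged_residues(sel$group2)
  if (!length(g1) || !length(g2)) return(empty_bonds())
  # flat charged-atom tables for the neighbor search
  flat <- function(g) {
    idx <- rep(seq_along(g), vapply(g, function(r) nrow(r$xyz), integer(1)))
    list(idx = idx,
         xyz = do.call(rbind, lapply(g, function(r) r$xyz)),
         an = unlist(lapply(g, function(r) r$atom_names)))
  }
  f1 <- flat(g1); f2 <- flat(g2)
  pp <- close_pairs(f1$xyz, f2$xyz, params$salt_cutoff,
                    method = params$backend)
  rows <- list()
  if (nrow(pp)) {
    pairkey <- paste(f1$idx[pp$i], f2$idx[pp$j])
    for (pk in unique(pairkey)) {
      sub <- pp[pairkey == pk, , drop = FALSE]
      best <- sub[which.min(sub$d), ]
      r1 <- g1[[f1$idx[best$i]]]
      r2 <- g2[[f2$idx[best$j]]]
      if (r1$charge * r2$charge >= 0L) next
      rows[[length(rows) + 1L]] <-
        .bond_row("salt_bridge", r1$meta, r2$meta,
                  f1$an[best$i], f2$an[best$j], distance = best$d)
    }
  }
  .finish_bonds(rows)
}

# donor/acceptor atom inventory for one interface side
.hb_inventory <- function(atoms) {
  rid <- residue_ids(atoms)
  donors <- list(); acceptors <- list()
  for (id in unique(rid)) {
    res_atoms <- atoms[rid == id, , drop = FALSE]
    resname <- res_atoms$resname[1]
    if (!(resname %in% canonical_residues())) next
    dat <- donor_acceptor_table(resname)
    for (k in seq_len(nrow(dat$donors))) {
      atom <- dat$donors$atom[k]
      dxyz <- .atom_xyz(res_atoms, atom)
      if (is.null(dxyz)) next
      rot <- dat$donors$rotatable[k]
      hs <- .attached_h(res_atoms, dxyz)
      hxyz <- lapply(seq_len(nrow(hs)),
                     function(j) as.numeric(hs[j, c("x", "y", "z")]))
      if (rot) {
        hxyz <- c(hxyz, .rotor_h_samples(resname, atom, res_atoms))
      }
      if (!length(hxyz)) next
      donors[[length(donors) + 1L]] <-
        list(meta = res_atoms[1, , drop = FALSE], id = id, atom = atom,
             xyz = dxyz, h = hxyz, rotatable = rot)
    }
    for (k in seq_len(nrow(dat$acceptors))) {
      atom <- dat$acceptors$atom[k]
      axyz <- .atom_xyz(res_atoms, atom)
      if (is.null(axyz)) next
      ants <- strsplit(dat$acceptors$antecedents[k], ",")[[1]]
      ant_xyz <- Filter(Negate(is.null),
                        lapply(ants, function(a) .atom_xyz(res_atoms, a)))
      acceptors[[length(acceptors) + 1L]] <-
        list(meta = res_atoms[1, , drop = FALSE], id = id, atom = atom,
             xyz = axyz, ants = ant_xyz)
    }
  }
  list(donors = donors, acceptors = acceptors)
}

# evaluate H-dependent criteria for one donor/acceptor pair; returns the
# best (largest) qualifying D-H-A angle or NA
.best_dha <- function(don, acc, params) {
  best <- NA_real_
  for (h in don$h) {
    if (.vnorm(h - acc$xyz) > params$ha_cutoff) next
    dha <- .angle3(don$xyz, h, acc$xyz)
    if (dha <= params$dha_min_angle) next
    ok <- TRUE
    for (aa in acc$ants) {
      if (.angle3(h, acc$xyz, aa) < params$antecedent_min_angle) {
        ok <- FALSE; break
      }
    }
    if (ok && (is.na(best) || dha > best)) best <- dha
  }
  best
}

#' Find intermolecular hydrogen bonds
#'
#' A donor-acceptor pair across the interface is reported when all of the
#' following hold: donor-acceptor distance <= 3.9 A; some donor hydrogen
#' within 2.5 A of the acceptor; D-H-A angle > 90 degrees; both the
#' hydrogen-acceptor-antecedent and donor-acceptor-antecedent angles >= 90
#' degrees for every antecedent of the acceptor; donor and acceptor at
#' least three covalent bonds apart (automatic for intermolecular pairs).
#' Rotatable hydroxyl/thiol donors are sampled over the O-H dihedral at 10
#' degree steps and accepted if any rotamer qualifies. One record per
#' donor/acceptor atom pair, keeping the largest qualifying D-H-A angle.
#' Missing polar hydrogens are placed first via
#' \code{\link{place_polar_hydrogens}}.
#'
#' @inheritParams find_ionic_bonds
#' @return A bond table data frame; \code{role1} says whether the group-1
#'   residue is the donor or the acceptor of the bond.
#' @export
find_hydrogen_bonds <- function(model, spec, params = detection_params()) {
  if (!isTRUE(attr(model, "hydrogens_placed"))) {
    model <- suppressWarnings(place_polar_hydrogens(model))
  }
  sel <- select_interface(model, spec)
  inv1 <- .hb_inventory(sel$group1)
  inv2 <- .hb_inventory(sel$group2)
  rows <- list()
  scan <- function(donors, acceptors, donor_is_group1) {
    if (!length(donors) || !length(acceptors)) return()
    dx <- t(vapply(donors, `[[`, numeric(3), "xyz"))
    ax <- t(vapply(acceptors, `[[`, numeric(3), "xyz"))
    cand <- close_pairs(dx, ax, params$da_cutoff, method = params$backend)
    for (k in seq_len(nrow(cand))) {
      don <- donors[[cand$i[k]]]
      acc <- acceptors[[cand$j[k]]]
      # donor-acceptor antecedent angle (H-independent)
      ok <- TRUE
      for (aa in acc$ants) {
        if (.angle3(don$xyz, acc$xyz, aa) < params$antecedent_min_angle) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      dha <- .best_dha(don, acc, params)
      if (is.na(dha)) next
      rows[[length(rows) + 1L]] <<- if (donor_is_group1) {
        .bond_row("hydrogen", don$meta, acc$meta, don$atom, acc$atom,
                  role1 = "donor", distance = cand$d[k], dha = dha)
      } else {
        .bond_row("hydrogen", acc$meta, don$meta, acc$atom, don$atom,
                  role1 = "acceptor", distance = cand$d[k], dha = dha)
      }
    }
  }
  scan(inv1$donors, inv2$acceptors, TRUE)
  scan(inv2$donors, inv1$acceptors, FALSE)
  .finish_bonds(rows)
}

.finish_bonds <- function(rows) {
  if (!length(rows)) return(empty_bonds())
  out <- do.call(rbind, rows)
  out <- out[order(out$bond_type, out$chain1,
                   as.integer(sub("[A-Za-z]+$", "", out$resnum1)),
                   out$atom1, out$chain2, out$resnum2, out$atom2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run all three bond detectors
#'
#' The detectors share no state and are run independently; the result is
#' simply their union keyed by type.
#'
#' @inheritParams find_ionic_bonds
#' @return A named list with bond tables \code{hydrogen}, \code{ionic} and
#'   \code{salt_bridge}.
#' @export
detect_all <- function(model, spec, params = detection_params()) {
  list(hydrogen = find_hydrogen_bonds(model, spec, params),
       ionic = find_ionic_bonds(model, spec, params),
       salt_bridge = find_salt_bridges(model, spec, params))
}
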