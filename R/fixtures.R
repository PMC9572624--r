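# Synthetic-structure generator. Residue pairs with idealized internal
# geometry (Chemical Component Dictionary templates) are posed rigidly so
# that a controlled quantity -- charged-atom distance, donor-acceptor
# distance, or donor-hydrogen-acceptor angle -- takes a requested value,
# then the whole complex is given a seeded random rigid orientation.
# Planted truth is derived from the construction analytically, never by
# running the detectors.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Idealized residue template
#'
#' Atom names, elements and idealized coordinates for one canonical
#' residue, from the vendored template table.
#'
#' @param resname 3-letter residue code.
#' @param hydrogens keep hydrogen atoms (default TRUE).
#' @return Data frame with columns name, element, x, y, z, is_h.
#' @export
residue_template <- function(resname, hydrogens = TRUE) {
  rn <- .check_resname(resname)
  tab <- .load_tsv("residue_templates.tsv")
  t0 <- tab[tab$resname == rn, , drop = FALSE]
  out <- data.frame(name = t0$atom, element = t0$element,
                    x = as.numeric(t0$x), y = as.numeric(t0$y),
                    z = as.numeric(t0$z), stringsAsFactors = FALSE)
  out$is_h <- out$element == "H"
  if (!hydrogens) out <- out[!out$is_h, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.tpl_xyz <- function(tpl) as.matrix(tpl[, c("x", "y", "z")])

.tpl_at <- function(tpl, name) {
  i <- which(tpl$name == name)
  if (!length(i)) stop("template lacks atom ", name, call. = FALSE)
  as.numeric(tpl[i[1], c("x", "y", "z")])
}

.apply_rt <- function(tpl, R, t) {
  m <- .tpl_xyz(tpl) %*% t(R)
  tpl$x <- m[, 1] + t[1]; tpl$y <- m[, 2] + t[2]; tpl$z <- m[, 3] + t[3]
  tpl
}

# rigidly pose a template: anchor atom at `point`, the anchor->axis_atom
# direction along `dir`; optional spin about `dir` putting spin_ref's
# perpendicular component along spin_target (or an explicit spin in deg)
.pose <- function(tpl, anchor, axis_atom, point, dir,
                  spin_ref = NULL, spin_target = NULL, spin_deg = NULL) {
  p0 <- .tpl_at(tpl, anchor)
  tpl <- .apply_rt(tpl, diag(3), -p0)
  u0 <- .unit(.tpl_at(tpl, axis_atom))
  R1 <- .rot_between(u0, dir)
  tpl <- .apply_rt(tpl, R1, c(0, 0, 0))
  if (!is.null(spin_ref)) {
    r <- .tpl_at(tpl, spin_ref)
    rp <- r - sum(r * dir) * dir
    if (.vnorm(rp) > 1e-8) {
      tgt <- spin_target - sum(spin_target * dir) * dir
      if (.vnorm(tgt) > 1e-8) {
        a <- .unit(rp); b <- .unit(tgt)
        ang <- atan2(sum(pracma::cross(a, b) * dir), sum(a * b)) * 180 / pi
        tpl <- .apply_rt(tpl, .rotmat(dir, ang), c(0, 0, 0))
      }
    }
  }
  if (!is.null(spin_deg)) tpl <- .apply_rt(tpl, .rotmat(dir, spin_deg),
                                           c(0, 0, 0))
  .apply_rt(tpl, diag(3), point)
}

# minimum cross distance over pairs that could realize an unintended
# hydrogen bond: donor atoms of one residue against acceptor atoms of the
# other (both directions), excluding the planted donor/acceptor pair.
# Donor-donor and acceptor-acceptor contacts cannot bond and are ignored.
.polar_clearance <- function(t1, t2, allowed1 = character(),
                             allowed2 = character(), res1 = NULL,
                             res2 = NULL) {
  if (is.null(res1) || is.null(res2)) {
    p1 <- t1[!t1$is_h & t1$element %in% c("N", "O", "S"), , drop = FALSE]
    p2 <- t2[!t2$is_h & t2$element %in% c("N", "O", "S"), , drop = FALSE]
    sets <- list(list(p1$name, p2$name))
  } else {
    d1 <- donor_acceptor_table(res1); d2 <- donor_acceptor_table(res2)
    # fixture residues are chain-initial: their backbone N has no amide
    # hydrogen (no preceding carbonyl), so it cannot donate
    sets <- list(list(setdiff(d1$donors$atom, "N"), d2$acceptors$atom),
                 list(d1$acceptors$atom, setdiff(d2$donors$atom, "N")))
  }
  best <- Inf
  for (s in sets) {
    p1 <- t1[t1$name %in% s[[1]], , drop = FALSE]
    p2 <- t2[t2$name %in% s[[2]], , drop = FALSE]
    for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
      if (p1$name[i] %in% allowed1 && p2$name[j] %in% allowed2) next
      d <- .vnorm(c(p1$x[i] - p2$x[j], p1$y[i] - p2$y[j],
                    p1$z[i] - p2$z[j]))
      if (d < best) best <- d
    }
  }
  best
}

.min_cross <- function(t1, t2, names1 = NULL, names2 = NULL, heavy = TRUE) {
  s1 <- t1[(!heavy | !t1$is_h) &
           (if (is.null(names1)) TRUE else t1$name %in% names1), ,
           drop = FALSE]
  s2 <- t2[(!heavy | !t2$is_h) &
           (if (is.null(names2)) TRUE else t2$name %in% names2), ,
           drop = FALSE]
  if (!nrow(s1) || !nrow(s2)) return(Inf)
  pp <- close_pairs_brute(.tpl_xyz(s1), .tpl_xyz(s2), Inf)
  min(pp$d)
}

.centroid_of <- function(tpl) {
  h <- tpl[!tpl$is_h, , drop = FALSE]
  c(mean(h$x), mean(h$y), mean(h$z))
}

# default partners per plant type: chosen so the default plants trigger
# exactly their own bond type (head-on LYS/GLU keeps every hydroxyl-free
# donor hydrogen >2.5 A or <=90 deg from the acceptor; ASP/HIS side-by-side
# keeps the imidazole plane perpendicular to the separation axis)
.PLANT_RES <- list(salt_bridge = c("LYS", "GLU"),
                   ionic = c("ASP", "HIS"),
                   hydrogen = c("TRP", "GLN"))
.CHARGED_ANCHOR <- c(ARG = "NH1", LYS = "NZ", HIS = "NE2",
                     ASP = "OD1", GLU = "OE1")
.CHARGED_AXIS <- c(ARG = "CZ", LYS = "CE", HIS = "CD2",
                   ASP = "CG", GLU = "CD")

# head-on pose: charged atoms face each other along +x at distance d;
# centroids end up far behind (used for salt-bridge plants and for
# ionic-centroid decoys)
.build_head_on <- function(res1, res2, d) {
  u <- c(1, 0, 0)
  a1 <- .CHARGED_ANCHOR[[res1]]; x1 <- .CHARGED_AXIS[[res1]]
  a2 <- .CHARGED_ANCHOR[[res2]]; x2 <- .CHARGED_AXIS[[res2]]
  t1 <- .pose(residue_template(res1), a1, x1, c(0, 0, 0), -u)
  t2 <- .pose(residue_template(res2), a2, x2, d * u, u)
  list(t1 = t1, t2 = t2)
}

# side-by-side pose: side chains parallel along +z, charged atoms offset
# mostly along +x at exact minimum distance d, centroids close; the
# translation direction is searched on a deterministic grid so the
# centroid distance constraint and clearance hold
.build_side_by_side <- function(res1, res2, d, centroid_max = NULL,
                                centroid_min = NULL, hb_screen = FALSE) {
  u <- c(1, 0, 0); v <- c(0, 1, 0); w <- c(0, 0, 1)
  a1 <- .CHARGED_ANCHOR[[res1]]; a2 <- .CHARGED_ANCHOR[[res2]]
  tpl1 <- residue_template(res1); tpl2 <- residue_template(res2)
  ch1 <- charged_atoms(res1); ch2 <- charged_atoms(res2)
  best <- NULL
  # tilt: angle between the CB->charged-atom axis and the vertical; at
  # short separations the side chains must lean toward each other for the
  # centroids to come close without backbone clashes
  for (alpha in c(0, 20, 40, 55, 70)) {
    ca <- cos(alpha * pi / 180); sa <- sin(alpha * pi / 180)
    e1 <- sa * u + ca * w          # res1 side chain leans toward +x
    e2 <- -sa * u + ca * w         # res2 leans back toward res1
    t1 <- .pose(tpl1, a1, "CB", c(0, 0, 0), -e1,
                spin_ref = "CA", spin_target = -v)
    t2_0 <- .pose(tpl2, a2, "CB", c(0, 0, 0), -e2,
                  spin_ref = if (res2 == "HIS") "ND1" else "CA",
                  spin_target = if (res2 == "HIS") v else -v)
    for (beta in seq(-0.8, 0.8, by = 0.1)) {
      for (gamma in seq(-0.4, 0.8, by = 0.2)) {
        tdir <- .unit(u + beta * v + gamma * w)
        t2 <- .apply_rt(t2_0, diag(3), d * tdir)
        if (abs(.min_cross(t1, t2, ch1, ch2) - d) > 1e-6) next
        if (.min_cross(t1, t2) < 2.4) next
        cd <- .vnorm(.centroid_of(t2) - .centroid_of(t1))
        if (!is.null(centroid_max) && cd >= centroid_max) next
        if (!is.null(centroid_min) && cd < centroid_min) next
        if (hb_screen &&
            .polar_clearance(t1, t2, ch1, ch2, res1 = res1,
                             res2 = res2) <= 3.95) next
        score <- .min_cross(t1, t2)
        if (is.null(best) || score > best$score) {
          best <- list(t1 = t1, t2 = t2, score = score, centroid = cd)
        }
      }
    }
    if (!is.null(best)) break  # prefer the most upright feasible tilt
  }
  if (is.null(best)) {
    stop("infeasible spec: no side-by-side pose satisfies the centroid ",
         "and clearance constraints", call. = FALSE)
  }
  best
}

# antiparallel pose for the ionic atom-distance decoy: centroids within
# `centroid` of each other while every charged-atom pair stays beyond
# `atom_min`
.build_antiparallel <- function(res1, res2, centroid, atom_min) {
  u <- c(1, 0, 0); v <- c(0, 1, 0); w <- c(0, 0, 1)
  t1 <- .pose(residue_template(res1), "CB", .CHARGED_ANCHOR[[res1]],
              c(0, 0, 0), -w)
  t2_0 <- .pose(residue_template(res2), "CB", .CHARGED_ANCHOR[[res2]],
                c(0, 0, 0), w)
  c1 <- .centroid_of(t1)
  ch1 <- charged_atoms(res1); ch2 <- charged_atoms(res2)
  for (phi in seq(0, 350, by = 10)) {
    tdir <- .unit(cos(phi * pi / 180) * u + sin(phi * pi / 180) * v)
    t2 <- t2_0
    c2 <- .centroid_of(t2)
    t2 <- .apply_rt(t2, diag(3), c1 - c2 + centroid * tdir)
    if (.min_cross(t1, t2) < 2.0) next
    if (.min_cross(t1, t2, ch1, ch2) <= atom_min) next
    if (.polar_clearance(t1, t2, res1 = res1, res2 = res2) <= 4.0) next
    return(list(t1 = t1, t2 = t2))
  }
  stop("infeasible spec: no antiparallel pose found", call. = FALSE)
}

# hydrogen-bond pose: TRP NE1 (donor; a single fixed indole hydrogen, so
# the D-H-A angle is fully controlled) against GLN OE1 (acceptor). D at
# origin, H along +x; the acceptor is placed at the exact D-A distance
# and D-H-A angle; the acceptor antecedent CD points along the A->(away
# from D) radial unless an explicit antecedent angle is requested.
.build_hbond <- function(d, theta, ant_angle = 180) {
  u <- c(1, 0, 0); v <- c(0, 1, 0); w <- c(0, 0, 1)
  asn <- .pose(residue_template("TRP"), "NE1", "HE1", c(0, 0, 0), u,
               spin_ref = "CE2", spin_target = -v)
  ct <- cos(theta * pi / 180); st <- sin(theta * pi / 180)
  disc <- ct^2 - 1 + d^2
  if (disc < 0) stop("infeasible spec: no H-A distance solves the triangle",
                     call. = FALSE)
  x <- ct + sqrt(disc)            # |H-A|
  # the indole ring lies in the x-y plane; offsetting the acceptor along
  # the ring normal keeps it clear of ring atoms at any D-H-A angle
  A <- u + x * (-ct * u + st * w) # acceptor position
  f0 <- .unit(A)                  # radial => angle(D, A, AA) = 180
  # rotate the antecedent direction in the u-v plane to the requested angle
  f <- if (ant_angle >= 179.99) f0 else {
    as.numeric(.rotmat(v, ant_angle - 180) %*% f0)
  }
  gln0 <- residue_template("GLN")
  best <- NULL
  for (spin in seq(0, 345, by = 15)) {
    gln <- .pose(gln0, "OE1", "CD", A, f, spin_deg = spin)
    clear <- .polar_clearance(asn, gln, c("NE1"), c("OE1"),
                              res1 = "TRP", res2 = "GLN")
    hclear <- .min_cross(asn, gln, NULL, NULL, heavy = FALSE)
    if (hclear < 1.5) next
    if (is.null(best) || clear > best$clear) {
      best <- list(t1 = asn, t2 = gln, clear = clear,
                   ha = x, acceptor = A)
    }
  }
  # any non-planted cross donor/acceptor pair must stay beyond the 3.9 A
  # donor-acceptor cutoff so no unintended hydrogen bond is possible
  if (is.null(best) || best$clear <= 3.95) {
    stop("infeasible spec: acceptor residue cannot be placed without ",
         "creating unintended polar contacts", call. = FALSE)
  }
  best
}

# assemble posed residues into an atom table / PDB text
.assemble <- function(tpls, chains, resnos, resnames, entry_id = "fixture") {
  rows <- list()
  serial <- 1L
  for (k in seq_along(tpls)) {
    t0 <- tpls[[k]]
    rows[[k]] <- data.frame(
      serial = seq.int(serial, length.out = nrow(t0)),
      name = t0$name, resname = resnames[k], chain = chains[k],
      resno = resnos[k], insert = "", x = round(t0$x, 3),
      y = round(t0$y, 3), z = round(t0$z, 3), occ = 1,
      element = t0$element, is_h = t0$is_h, stringsAsFactors = FALSE)
    serial <- serial + nrow(t0)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, atoms = atoms),
            class = "ib_structure")
}

#' Write a structure model as PDB text
#'
#' @param model an \code{ib_structure}.
#' @param path optional file path; when NULL the PDB lines are returned.
#' @return Character vector of PDB lines (invisibly when written).
#' @export
write_pdb_model <- function(model, path = NULL) {
  a <- model$atoms
  tmp <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  bio3d::write.pdb(file = tmp, xyz = as.numeric(t(as.matrix(
                     a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resname, eleno = a$serial, elety = a$name,
                   chain = a$chain, insert = a$insert, o = a$occ,
                   b = rep(0, nrow(a)), elesy = a$element)
  lines <- readLines(tmp, warn = FALSE)
  if (is.null(path)) unlink(tmp) else return(invisible(lines))
  lines
}

.truth_row <- function(type, chain1, resno1, res1, chain2, resno2, res2,
                       distance = NA_real_) {
  data.frame(bond_type = type, chain1 = chain1, resnum1 = as.character(resno1),
             resname1 = res1, chain2 = chain2, resnum2 = as.character(resno2),
             resname2 = res2, distance = distance, stringsAsFactors = FALSE)
}

.empty_truth <- function() {
  .truth_row("x", "A", 1, "ALA", "B", 1, "ALA")[0, ]
}

#' Generate a two-residue complex with planted bond geometry
#'
#' Builds one residue on chain A and one on chain B, posed so the
#' controlled quantity matches the request to within 0.01 A / 0.5 deg,
#' and applies a seeded random rigid rotation+translation to the whole
#' complex. \code{bond_type = "none"} builds a decoy violating exactly one
#' criterion (see \code{violated_criterion}). The returned truth table
#' lists the bonds of the planted type (plus, for short salt/ionic
#' distances, the other charge-mediated type when its criterion is
#' necessarily satisfied by the same geometry); it is derived analytically
#' from the construction, never from the detectors.
#'
#' @param bond_type "hydrogen", "ionic", "salt_bridge" or "none".
#' @param key_distance controlled distance (A): charged-atom N...O minimum
#'   for ionic/salt, donor-acceptor distance for hydrogen.
#' @param key_angle donor-hydrogen-acceptor angle in degrees (hydrogen
#'   plants only; default 150).
#' @param violated_criterion for decoys: one of "distance" (salt/hydrogen
#'   distance beyond cutoff), "centroid" (ionic centroid too far),
#'   "atom_distance" (ionic charged atoms too far), "charge" (like-charged
#'   pair), "dha_angle", "ha_distance", "antecedent_angle".
#' @param residues optional 2-vector of residue codes overriding the
#'   defaults (LYS/GLU salt, ASP/HIS ionic, ASN/GLN hydrogen).
#' @param seed integer seed for the rigid orientation.
#' @param resnos residue numbers for the two chains.
#' @param params detection parameters defining the thresholds the plant is
#'   built against.
#' @return A list with \code{model} (an \code{ib_structure}), \code{pdb}
#'   (PDB text lines) and \code{truth} (data frame of expected bonds of
#'   the planted type).
#' @export
make_pair_complex <- function(bond_type = c("salt_bridge", "ionic",
                                            "hydrogen", "none"),
                              key_distance = NULL, key_angle = 150,
                              violated_criterion = NULL, residues = NULL,
                              seed = 1, resnos = c(1, 1),
                              params = detection_params()) {
  bond_type <- match.arg(bond_type)
  if (bond_type != "none" && !is.null(violated_criterion)) {
    stop("violated_criterion is only valid for bond_type = \"none\"",
         call. = FALSE)
  }
  truth <- .empty_truth()

  if (bond_type == "salt_bridge") {
    if (is.null(key_distance)) key_distance <- 3.2
    if (key_distance > params$salt_cutoff) {
      stop("infeasible spec: salt-bridge distance beyond cutoff",
           call. = FALSE)
    }
    rr <- if (is.null(residues)) .PLANT_RES$salt_bridge else residues
    b <- .build_head_on(rr[1], rr[2], key_distance)
    truth <- .truth_row("salt_bridge", "A", resnos[1], rr[1], "B",
                        resnos[2], rr[2], key_distance)
  } else if (bond_type == "ionic") {
    if (is.null(key_distance)) key_distance <- 4.5
    if (key_distance > params$ionic_atom_cutoff) {
      stop("infeasible spec: charged-atom distance beyond cutoff",
           call. = FALSE)
    }
    rr <- if (is.null(residues)) .PLANT_RES$ionic else residues
    b <- .build_side_by_side(rr[1], rr[2], key_distance,
                             centroid_max = params$ionic_centroid_cutoff)
    truth <- .truth_row("ionic", "A", resnos[1], rr[1], "B", resnos[2],
                        rr[2], key_distance)
    if (key_distance <= params$salt_cutoff) {
      truth <- rbind(truth, .truth_row("salt_bridge", "A", resnos[1],
                                       rr[1], "B", resnos[2], rr[2],
                                       key_distance))
    }
  } else if (bond_type == "hydrogen") {
    if (is.null(key_distance)) key_distance <- 2.9
    ct <- cos(key_angle * pi / 180)
    disc <- ct^2 - 1 + key_distance^2
    ha <- if (disc >= 0) ct + sqrt(disc) else Inf
    if (key_distance > params$da_cutoff || ha > params$ha_cutoff ||
        key_angle <= params$dha_min_angle) {
      stop("infeasible spec: geometry violates a hydrogen-bond criterion",
           call. = FALSE)
    }
    b <- .build_hbond(key_distance, key_angle)
    truth <- .truth_row("hydrogen", "A", resnos[1], "TRP", "B", resnos[2],
                        "GLN", key_distance)
    rr <- c("TRP", "GLN")
  } else {
    vc <- match.arg(violated_criterion,
                    c("distance", "centroid", "atom_distance", "charge",
                      "dha_angle", "ha_distance", "antecedent_angle"))
    b <- switch(vc,
      distance = {
        dd <- if (is.null(key_distance)) 4.5 else key_distance
        if (dd > params$ionic_centroid_cutoff) {
          # long-range charged pair: centroids and charged atoms both
          # just beyond the default ionic cutoff (found at 7.5/10 A)
          rr <- c("ASP", "HIS")
          .build_side_by_side("ASP", "HIS", dd,
                              centroid_max = dd + 1.2,
                              centroid_min = params$ionic_centroid_cutoff)
        } else {
          # salt-bridge distance just beyond the 4 A cutoff
          rr <- c("LYS", "GLU")
          .build_head_on("LYS", "GLU", dd)
        }
      },
      centroid = {   # charged atoms close, centroids beyond the cutoff
        rr <- c("ARG", "GLU")
        .build_head_on("ARG", "GLU",
                       if (is.null(key_distance)) 4.5 else key_distance)
      },
      atom_distance = {  # centroids close, charged atoms far
        rr <- c("ARG", "GLU")
        .build_antiparallel("ARG", "GLU",
                            centroid = params$ionic_centroid_cutoff - 0.4,
                            atom_min = params$ionic_atom_cutoff)
      },
      charge = {     # like-charged pair at short range
        rr <- c("LYS", "ARG")
        .build_side_by_side("LYS", "ARG",
                            if (is.null(key_distance)) 3.5 else key_distance,
                            hb_screen = TRUE)
      },
      dha_angle = {  # D-H-A <= 90 with every other criterion satisfied
        rr <- c("TRP", "GLN")
        .build_hbond(2.5, if (is.null(key_angle) || key_angle > 90)
          80 else key_angle)
      },
      ha_distance = { # H too far while D-A and angles remain valid
        rr <- c("TRP", "GLN")
        .build_hbond(3.8, 95)
      },
      antecedent_angle = { # acceptor antecedent folded below 90 degrees
        rr <- c("TRP", "GLN")
        .build_hbond(2.9, 150, ant_angle = 70)
      })
  }

  tpls <- .with_seed(seed, {
    R <- .random_rotation()
    shift <- stats::runif(3, -5, 5)
    lapply(list(b$t1, b$t2), .apply_rt, R = R, t = shift)
  })
  model <- .assemble(tpls, chains = c("A", "B"), resnos = resnos,
                     resnames = rr,
                     entry_id = paste0("plant_", bond_type))
  list(model = model, pdb = write_pdb_model(model), truth = truth)
}

#' Generate a multi-pair interface complex with planted truth
#'
#' Builds \code{n_pairs} independent two-residue plants, spaced on a cubic
#' lattice so that no two plants come within 12 A of each other, and
#' merges them into one two-chain complex (all group-1 residues on chain
#' A, all partners on chain B, residue numbers 1..n).
#'
#' @param n_pairs number of planted interactions (>= 1).
#' @param bond_mix named proportions for types hydrogen/ionic/salt_bridge.
#' @param seed integer seed (per-plant orientations are derived from it).
#' @param params detection parameters.
#' @return A list with \code{model}, \code{pdb} and \code{truth}.
#' @export
make_interface_complex <- function(n_pairs,
                                   bond_mix = c(hydrogen = 1, ionic = 1,
                                                salt_bridge = 1),
                                   seed = 1,
                                   params = detection_params()) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  types <- rep(names(bond_mix), ceiling(n_pairs * bond_mix /
                                        sum(bond_mix)))[seq_len(n_pairs)]
  pitch <- 30  # plant extent <= ~18 A, so nearest atoms stay > 12 A apart
  side <- ceiling(n_pairs^(1/3))
  tpls <- list(); chains <- character(); resnos <- integer()
  resnames <- character()
  truth <- .empty_truth()
  for (i in seq_len(n_pairs)) {
    p <- make_pair_complex(types[i], seed = (seed %% 2000000L) * 1000L + i,
                           resnos = c(i, i), params = params)
    cell <- c((i - 1) %% side,
              ((i - 1) %/% side) %% side,
              (i - 1) %/% side^2) * pitch
    a <- p$model$atoms
    a$x <- a$x + cell[1]; a$y <- a$y + cell[2]; a$z <- a$z + cell[3]
    for (ch in c("A", "B")) {
      sub <- a[a$chain == ch, , drop = FALSE]
      t0 <- data.frame(name = sub$name, element = sub$element, x = sub$x,
                       y = sub$y, z = sub$z, is_h = sub$is_h,
                       stringsAsFactors = FALSE)
      tpls[[length(tpls) + 1L]] <- t0
      chains <- c(chains, ch)
      resnos <- c(resnos, i)
      resnames <- c(resnames, sub$resname[1])
    }
    truth <- rbind(truth, p$truth)
  }
  model <- .assemble(tpls, chains, resnos, resnames,
                     entry_id = sprintf("interface_%d", n_pairs))
  list(model = model, pdb = write_pdb_model(model), truth = truth)
}

#' Synthetic Barnase-Barstar-like worked example
#'
#' A synthetic stand-in for the barnase/barstar interface: chain A carries
#' an arginine numbered 59, chain D a glutamate numbered 76, posed with
#' their guanidinium/carboxylate groups facing at the given N...O
#' distance, plus spacer alanines on each chain away from the interface.
#' The coordinates are idealized and synthetic; only the residue
#' identities, author numbering and sub-4-A salt-bridge geometry mirror
#' the real complex.
#'
#' @param distance planted minimum charged N...O distance (A).
#' @param seed orientation seed.
#' @return A list with \code{model}, \code{pdb} and \code{truth}.
#' @export
make_synthetic_barnase_barstar <- function(distance = 3.0, seed = 1) {
  b <- .build_head_on("ARG", "GLU", distance)
  ala1 <- .pose(residue_template("ALA"), "CA", "CB", c(-14, 0, 0),
                c(0, 0, 1))
  ala2 <- .pose(residue_template("ALA"), "CA", "CB", c(distance + 14, 0, 0),
                c(0, 0, 1))
  tpls <- .with_seed(seed, {
    R <- .random_rotation()
    lapply(list(b$t1, ala1, b$t2, ala2), .apply_rt, R = R, t = c(0, 0, 0))
  })
  model <- .assemble(tpls, chains = c("A", "A", "D", "D"),
                     resnos = c(59, 60, 76, 77),
                     resnames = c("ARG", "ALA", "GLU", "ALA"),
                     entry_id = "synthetic_1brs_like")
  truth <- .truth_row("salt_bridge", "A", 59, "ARG", "D", 76, "GLU",
                      distance)
  list(model = model, pdb = write_pdb_model(model), truth = truth)
}

#' Synthetic SKEMPI-style mutation table with planted effect structure
#'
#' Emulates the statistical structure of curated mutant affinity data:
#' each record is a point mutation with wild-type and mutant equilibrium
#' dissociation constants. Under \code{effect_model = "broken_high_ddg"},
#' mutations labelled bond-breaking receive a binding free-energy penalty
#' shifted by \code{shift} kcal/mol relative to bond-preserving ones;
#' under \code{"null"} the two groups share one distribution. Keq values
#' are back-computed from the drawn ddG at the stated temperature.
#'
#' @param n_mutations number of rows (>= 2).
#' @param effect_model "broken_high_ddg" or "null".
#' @param seed integer seed.
#' @param shift planted ddG shift in kcal/mol (default +1.5).
#' @param sdev within-group ddG standard deviation (kcal/mol).
#' @param temperature experiment temperature in kelvin.
#' @return A list with \code{table} (complex_id, mutation, keq_wt,
#'   keq_mut, temperature) and \code{labels} ("broken"/"intact" per row).
#' @export
make_mutation_table <- function(n_mutations,
                                effect_model = c("broken_high_ddg", "null"),
                                seed = 1, shift = 1.5, sdev = 1.0,
                                temperature = 298.15) {
  effect_model <- match.arg(effect_model)
  if (n_mutations < 2) stop("n_mutations must be >= 2", call. = FALSE)
  .with_seed(seed, {
    complexes <- c("CPX1", "CPX2")
    cpx <- sample(complexes, n_mutations, replace = TRUE)
    lab <- sample(c("broken", "intact"), n_mutations, replace = TRUE)
    mu <- 0.5 + ifelse(effect_model == "broken_high_ddg" & lab == "broken",
                       shift, 0)
    ddg <- stats::rnorm(n_mutations, mean = mu, sd = sdev)
    keq_wt <- 10^stats::runif(n_mutations, -10, -6)
    RT <- 0.0019872 * temperature
    keq_mut <- keq_wt * exp(ddg / RT)
    wt_res <- ifelse(lab == "broken", sample(c("R", "K", "E", "D"),
                                             n_mutations, replace = TRUE),
                     sample(c("R", "K", "E", "D"), n_mutations,
                            replace = TRUE))
    mut_res <- ifelse(lab == "broken", "A",
                      vapply(wt_res, function(w) {
                        switch(w, R = "K", K = "R", E = "D", D = "E")
                      }, character(1)))
    pos <- sample(5:120, n_mutations, replace = TRUE)
    tab <- data.frame(
      complex_id = cpx,
      mutation = paste0(wt_res, "A", pos, mut_res),
      keq_wt = keq_wt, keq_mut = keq_mut,
      temperature = temperature, stringsAsFactors = FALSE)
    list(table = tab, labels = lab)
  })
}

#' Materialize a fixture suite into a directory
#'
#' Writes one PDB per default plant and decoy, the synthetic
#' barnase-barstar-like example, a combined truth table and a synthetic
#' mutation table.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, the vector of files written.
#' @export
write_fixture_suite <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  truth_all <- .empty_truth()
  plants <- list(
    salt_bridge = list(bond_type = "salt_bridge"),
    ionic = list(bond_type = "ionic"),
    hydrogen = list(bond_type = "hydrogen"))
  decoys <- c("distance", "centroid", "atom_distance", "charge",
              "dha_angle", "ha_distance", "antecedent_angle")
  k <- 0L
  for (nm in names(plants)) {
    k <- k + 1L
    p <- do.call(make_pair_complex, c(plants[[nm]], list(seed = seed + k)))
    f <- file.path(dir, paste0("plant_", nm, ".pdb"))
    writeLines(p$pdb, f)
    files <- c(files, f)
    tr <- p$truth; tr$file <- basename(f)
    truth_all <- rbind(truth_all, tr)
  }
  for (vc in decoys) {
    k <- k + 1L
    p <- make_pair_complex("none", violated_criterion = vc, seed = seed + k)
    f <- file.path(dir, paste0("decoy_", vc, ".pdb"))
    writeLines(p$pdb, f)
    files <- c(files, f)
  }
  bb <- make_synthetic_barnase_barstar(seed = seed)
  f <- file.path(dir, "synthetic_1brs_like.pdb")
  writeLines(bb$pdb, f)
  files <- c(files, f)
  tr <- bb$truth; tr$file <- basename(f)
  truth_all <- rbind(truth_all, tr)
  utils::write.table(truth_all, file.path(dir, "planted_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- make_mutation_table(200, "broken_high_ddg", seed = seed)
  out <- mt$table; out$label <- mt$labels
  utils::write.table(out, file.path(dir, "synthetic_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, file.path(dir, c("planted_truth.tsv",
                                     "synthetic_mutations.tsv")))
  invisible(files)
}
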