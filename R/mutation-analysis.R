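# Binding free-energy changes from equilibrium dissociation constants,
# per-complex normalization, and classification of each point mutation's
# effect on predicted interface bonds.

.R_KCAL <- 0.0019872  # gas constant, kcal/(mol K)

#' Binding free energy from an equilibrium dissociation constant
#'
#' dG = RT ln(Kd): negative for sub-molar Kd (favorable binding), larger
#' dG meaning weaker binding. Per-record experimental temperatures are
#' used when available so that Keq values measured at different
#' temperatures remain comparable on the free-energy scale.
#'
#' @param keq dissociation constant(s), molar; must be > 0.
#' @param temperature kelvin (default 298.15).
#' @return Free energy in kcal/mol.
#' @export
#' @examples
#' delta_g(1e-9)  # about -12.28 kcal/mol
delta_g <- function(keq, temperature = 298.15) {
  if (any(!is.finite(keq) | keq <= 0)) {
    stop("keq must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(temperature) | temperature <= 0)) {
    stop("temperature must be positive", call. = FALSE)
  }
  .R_KCAL * temperature * log(keq)
}

#' Change in binding free energy caused by a mutation
#'
#' ddG = dG(mutant) - dG(wild type); positive values are destabilizing
#' (the mutant binds more weakly). Only the Keq ratio matters, so
#' rescaling both constants by a common factor leaves ddG unchanged.
#'
#' @param records data frame with columns \code{keq_wt}, \code{keq_mut}
#'   and optionally \code{temperature} (kelvin; 298.15 where missing).
#' @return The input with columns \code{dg_wt}, \code{dg_mut} and
#'   \code{ddg} appended.
#' @export
compute_ddg <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("keq_wt", "keq_mut") %in% names(records)))
  temp <- if ("temperature" %in% names(records)) {
    ifelse(is.na(records$temperature), 298.15, records$temperature)
  } else rep(298.15, nrow(records))
  records$dg_wt <- delta_g(records$keq_wt, temp)
  records$dg_mut <- delta_g(records$keq_mut, temp)
  records$ddg <- records$dg_mut - records$dg_wt
  records
}

#' Min-max normalize ddG within each protein complex
#'
#' Maps ddG to [0, 1] separately per complex so that free-energy scales
#' are comparable across complexes; a complex whose records all share one
#' ddG value (including singletons) maps to 0.5.
#'
#' @param records data frame with columns \code{complex_id} and
#'   \code{ddg}.
#' @return The input with \code{ddg_normalized} appended.
#' @export
normalize_ddg <- function(records) {
  stopifnot(all(c("complex_id", "ddg") %in% names(records)))
  records$ddg_normalized <- NA_real_
  for (cx in unique(records$complex_id)) {
    i <- records$complex_id == cx
    v <- records$ddg[i]
    rng <- range(v)
    records$ddg_normalized[i] <- if (diff(rng) == 0) {
      rep(0.5, sum(i))
    } else (v - rng[1]) / diff(rng)
  }
  records
}

# one-letter -> three-letter residue codes
.AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Parse a compact mutation code
#'
#' Codes follow the curated-database convention wt + chain + position +
#' mutant, e.g. "RA59A" for Arg59 on chain A mutated to Ala; the position
#' may carry an insertion code letter (e.g. "RA100aA" style codes are not
#' supported -- insertion codes must be uppercase trailing the digits).
#'
#' @param code character vector of mutation codes.
#' @return Data frame with chain, position, wt_residue, mut_residue; rows
#'   that fail to parse are NA with a warning.
#' @export
parse_mutation_string <- function(code) {
  m <- regmatches(code, regexec("^([A-Z])([A-Za-z0-9])(\\d+[A-Z]?)([A-Z])$",
                                code))
  out <- data.frame(chain = NA_character_, position = NA_character_,
                    wt_residue = NA_character_, mut_residue = NA_character_,
                    stringsAsFactors = FALSE)[rep(1, length(code)), ,
                                              drop = FALSE]
  rownames(out) <- NULL
  bad <- character()
  for (i in seq_along(code)) {
    g <- m[[i]]
    if (length(g) != 5 || !(g[2] %in% names(.AA1)) ||
        !(g[5] %in% names(.AA1))) {
      bad <- c(bad, code[i])
      next
    }
    out$chain[i] <- g[3]
    out$position[i] <- g[4]
    out$wt_residue[i] <- .AA1[[g[2]]]
    out$mut_residue[i] <- .AA1[[g[5]]]
  }
  if (length(bad)) {
    warning("unparseable mutation code(s) skipped: ",
            paste(unique(bad), collapse = ", "))
  }
  out
}

#' Read a SKEMPI-style mutation table
#'
#' A delimited text file; the column mapping adapts header dialects. The
#' default mapping covers both this package's synthetic tables and
#' SKEMPI-2-style exports (\code{#Pdb}, \code{Mutation(s)_cleaned},
#' \code{Affinity_wt_parsed}, \code{Affinity_mut_parsed},
#' \code{Temperature}). Rows with unparseable mutation codes or
#' multi-point mutations (comma-separated codes) are skipped with a
#' warning; affinities are interpreted as molar dissociation constants.
#'
#' @param path file path.
#' @param mapping named list with entries complex_id, mutation, keq_wt,
#'   keq_mut, temperature giving candidate column names (first match
#'   wins).
#' @param sep field separator (default tab).
#' @return Data frame of mutation records: complex_id, chain, position,
#'   wt_residue, mut_residue, keq_wt, keq_mut, temperature.
#' @export
read_mutation_table <- function(path, mapping = skempi_mapping(),
                                sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(raw))
    if (!length(hit)) NULL else raw[[hit[1]]]
  }
  cpx <- pick(mapping$complex_id)
  mut <- pick(mapping$mutation)
  kwt <- pick(mapping$keq_wt)
  kmt <- pick(mapping$keq_mut)
  if (is.null(cpx) || is.null(mut) || is.null(kwt) || is.null(kmt)) {
    stop("mutation table lacks required columns under the given mapping",
         call. = FALSE)
  }
  temp <- pick(mapping$temperature)
  if (is.null(temp)) temp <- rep(NA_real_, nrow(raw))
  # strip qualifiers like "298(assumed)"
  temp <- suppressWarnings(as.numeric(sub("[^0-9.].*$", "",
                                          as.character(temp))))
  multi <- grepl(",", mut)
  if (any(multi)) {
    warning(sum(multi), " multi-point mutation record(s) skipped")
  }
  keep <- !multi
  parsed <- parse_mutation_string(mut[keep])
  out <- data.frame(complex_id = sub("_.*$", "", cpx[keep]),
                    parsed,
                    keq_wt = suppressWarnings(as.numeric(kwt[keep])),
                    keq_mut = suppressWarnings(as.numeric(kmt[keep])),
                    temperature = temp[keep],
                    stringsAsFactors = FALSE)
  bad <- is.na(out$chain) | is.na(out$keq_wt) | is.na(out$keq_mut)
  if (any(bad)) {
    warning(sum(bad), " unusable mutation record(s) dropped")
  }
  dup <- duplicated(out)
  if (any(dup)) warning(sum(dup), " duplicate mutation record(s) dropped")
  out <- out[!bad & !dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default column mapping for SKEMPI-style tables
#' @return Named list of candidate column names.
#' @export
skempi_mapping <- function() {
  list(complex_id = c("complex_id", "#Pdb", "Pdb"),
       mutation = c("mutation", "Mutation(s)_cleaned", "Mutation(s)_PDB",
                    "Mutations_cleaned"),
       keq_wt = c("keq_wt", "Affinity_wt_parsed", "Affinity_wt (M)"),
       keq_mut = c("keq_mut", "Affinity_mut_parsed", "Affinity_mut (M)"),
       temperature = c("temperature", "Temperature"))
}

# does this residue's side chain carry any H-bond capability?
.sidechain_hb_roles <- function(resname) {
  dat <- donor_acceptor_table(resname)
  list(donor = any(dat$donors$atom != "N"),
       acceptor = any(dat$acceptors$atom != "O"))
}

#' Classify a mutation's effect on each predicted bond type
#'
#' For each bond type, the mutation site is checked against the wild-type
#' bond predictions: a bond touching the site through side-chain atoms is
#' "broken" when the mutant residue loses the required chemistry (for
#' ionic/salt bridges: no longer oppositely charged to the partner; for
#' hydrogen bonds: the mutant side chain cannot play the role the
#' wild-type side chain played) and "intact" when it keeps it (e.g.
#' charged to similarly charged); bonds made through the site's backbone
#' atoms survive any point mutation and are "intact". If no wild-type
#' bond of the type touches the site, the result is "formed" when the
#' mutation introduces new chemistry (the wild type lacked it) and some
#' opposite-group residue with compatible atoms lies within the bond
#' cutoff plus the mutant's side-chain reach of the site's CB (CA for
#' glycine), else "none".
#'
#' @param wt_bonds output of \code{\link{detect_all}} on the wild-type
#'   structure.
#' @param mutation one row of a mutation-record data frame (chain,
#'   position, wt_residue, mut_residue).
#' @param model the wild-type \code{ib_structure}.
#' @param spec the \code{interface_spec} used for detection.
#' @param params the \code{detection_params} used for detection.
#' @return Data frame with one row per bond type: bond_type,
#'   classification ("broken", "intact", "formed", "none") and partner
#'   residue id (or NA).
#' @export
classify_bond_change <- function(wt_bonds, mutation, model, spec,
                                 params = detection_params()) {
  chain <- mutation$chain
  pos <- as.character(mutation$position)
  atoms <- model$atoms
  site <- atoms[atoms$chain == chain &
                paste0(atoms$resno, atoms$insert) == pos, , drop = FALSE]
  if (!nrow(site)) {
    stop("mutation site not found in structure: ", chain, ":", pos,
         call. = FALSE)
  }
  wt_res <- site$resname[1]
  if (!is.na(mutation$wt_residue) && wt_res != mutation$wt_residue) {
    warning("wild-type residue mismatch at ", chain, ":", pos, ": ",
            wt_res, " in structure, ", mutation$wt_residue, " in table")
  }
  mut_res <- mutation$mut_residue
  q_wt <- formal_charge(wt_res)
  q_mut <- formal_charge(mut_res)
  in_g1 <- chain %in% spec$group1
  opp_atoms <- if (in_g1) select_interface(model, spec)$group2 else
    select_interface(model, spec)$group1

  # anchor for the reach heuristic: CB, or CA for glycine
  anchor_name <- if (mut_res == "GLY" || !("CB" %in% site$name)) "CA" else "CB"
  anchor <- .atom_xyz(site, anchor_name)

  classify_type <- function(type) {
    b <- wt_bonds[[type]]
    hit <- b[(b$chain1 == chain & b$resnum1 == pos) |
             (b$chain2 == chain & b$resnum2 == pos), , drop = FALSE]
    if (nrow(hit)) {
      cls <- character(nrow(hit))
      partner <- character(nrow(hit))
      for (k in seq_len(nrow(hit))) {
        site_is_1 <- hit$chain1[k] == chain & hit$resnum1[k] == pos
        own_atom <- if (site_is_1) hit$atom1[k] else hit$atom2[k]
        partner[k] <- if (site_is_1) {
          paste0(hit$chain2[k], ":", hit$resnum2[k])
        } else paste0(hit$chain1[k], ":", hit$resnum1[k])
        partner_res <- if (site_is_1) hit$resname2[k] else hit$resname1[k]
        if (own_atom %in% c("N", "O")) {   # backbone-mediated
          cls[k] <- "intact"
        } else if (type %in% c("ionic", "salt_bridge")) {
          q_partner <- formal_charge(partner_res)
          cls[k] <- if (q_mut * q_partner < 0) "intact" else "broken"
        } else {                            # side-chain hydrogen bond
          role <- if (site_is_1) hit$role1[k] else
            c(donor = "acceptor", acceptor = "donor")[[hit$role1[k]]]
          cap <- .sidechain_hb_roles(mut_res)
          cls[k] <- if ((role == "donor" && cap$donor) ||
                        (role == "acceptor" && cap$acceptor)) {
            "intact"
          } else "broken"
        }
      }
      broken <- cls == "broken"
      return(data.frame(bond_type = type,
                        classification = if (any(broken)) "broken" else
                          "intact",
                        partner = partner[if (any(broken))
                          which(broken)[1] else 1L],
                        stringsAsFactors = FALSE))
    }
    # no wild-type bond: formed only if the mutation introduces chemistry
    formed <- FALSE; partner <- NA_character_
    if (type %in% c("ionic", "salt_bridge")) {
      cutoff <- if (type == "ionic") params$ionic_atom_cutoff else
        params$salt_cutoff
      if (q_mut != 0 && q_mut != q_wt && !is.null(anchor)) {
        reach <- sidechain_reach(mut_res)
        rid <- residue_ids(opp_atoms)
        for (id in unique(rid)) {
          ra <- opp_atoms[rid == id, , drop = FALSE]
          rn <- ra$resname[1]
          if (!(rn %in% canonical_residues())) next
          if (formal_charge(rn) * q_mut >= 0) next
          ca <- ra[ra$name %in% charged_atoms(rn), , drop = FALSE]
          if (!nrow(ca)) next
          dmin <- min(sqrt((ca$x - anchor[1])^2 + (ca$y - anchor[2])^2 +
                           (ca$z - anchor[3])^2))
          if (dmin <= cutoff + reach) {
            formed <- TRUE; partner <- id; break
          }
        }
      }
    } else {
      cap_mut <- .sidechain_hb_roles(mut_res)
      cap_wt <- .sidechain_hb_roles(wt_res)
      gains <- (cap_mut$donor && !cap_wt$donor) ||
        (cap_mut$acceptor && !cap_wt$acceptor)
      if (gains && !is.null(anchor)) {
        reach <- sidechain_reach(mut_res)
        rid <- residue_ids(opp_atoms)
        for (id in unique(rid)) {
          ra <- opp_atoms[rid == id, , drop = FALSE]
          rn <- ra$resname[1]
          if (!(rn %in% canonical_residues())) next
          dat <- donor_acceptor_table(rn)
          want <- character()
          if (cap_mut$donor && !cap_wt$donor) want <- dat$acceptors$atom
          if (cap_mut$acceptor && !cap_wt$acceptor) {
            want <- c(want, dat$donors$atom)
          }
          ra <- ra[ra$name %in% want, , drop = FALSE]
          if (!nrow(ra)) next
          dmin <- min(sqrt((ra$x - anchor[1])^2 + (ra$y - anchor[2])^2 +
                           (ra$z - anchor[3])^2))
          if (dmin <= params$da_cutoff + reach) {
            formed <- TRUE; partner <- id; break
          }
        }
      }
    }
    data.frame(bond_type = type,
               classification = if (formed) "formed" else "none",
               partner = partner, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("hydrogen", "ionic", "salt_bridge"),
                               classify_type))
  rownames(out) <- NULL
  out
}

#' Group summary statistics for normalized ddG (or any values)
#'
#' Mean, 95% two-sided t confidence interval (only when n >= 2), and
#' coefficient of variation (sample SD / mean) per group. Groups present
#' in the factor levels but empty in the data are reported with an
#' explicit empty marker and no statistics.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length; its levels
#'   define the reported groups.
#' @param conf confidence level (default 0.95).
#' @return Data frame: group, n, mean, sd, cv, ci_lo, ci_hi, empty.
#' @export
group_summary <- function(values, groups, conf = 0.95) {
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    v <- values[groups == g & !is.na(values)]
    n <- length(v)
    if (n == 0) {
      return(data.frame(group = g, n = 0L, mean = NA_real_, sd = NA_real_,
                        cv = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        empty = TRUE, stringsAsFactors = FALSE))
    }
    m <- mean(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    cv <- if (n >= 2 && m != 0) s / m else if (n >= 2) Inf else NA_real_
    if (n >= 2) {
      half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
      ci <- c(m - half, m + half)
    } else ci <- c(NA_real_, NA_real_)
    data.frame(group = g, n = n, mean = m, sd = s, cv = cv,
               ci_lo = ci[1], ci_hi = ci[2], empty = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
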