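# PDB input and table output. Parsing is delegated to bio3d::read.pdb;
# this layer applies the model conventions used throughout the package:
# first MODEL only, waters/HETATM excluded, non-canonical residues dropped
# with a warning, alternate locations resolved to the highest occupancy.

#' Parse a PDB file into a structure model
#'
#' Reads ATOM records of the first MODEL into a flat atom table. HETATM
#' records and waters are excluded; residues outside the 20 canonical
#' amino acids (e.g. MSE) are dropped with a warning. For alternate
#' locations the highest-occupancy copy is kept (ties resolved toward
#' altloc "A"). Hydrogens are retained and flagged.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param entry_id optional entry identifier; defaults to the file name.
#' @return An object of class \code{ib_structure}: a list with
#'   \code{entry_id} and \code{atoms}, a data frame with one row per atom
#'   (serial, name, resname, chain, resno, insert, x, y, z, occ, element,
#'   is_h).
#' @export
parse_pdb <- function(source, entry_id = NULL) {
  if (length(source) > 1L || grepl("\n", source[1]) ||
      !file.exists(source[1])) {
    if (length(source) == 1L) source <- strsplit(source, "\n")[[1]]
    path <- tempfile(fileext = ".pdb")
    writeLines(source, path)
    on.exit(unlink(path))
    if (is.null(entry_id)) entry_id <- "unnamed"
  } else {
    path <- source
    if (is.null(entry_id)) {
      entry_id <- tools::file_path_sans_ext(basename(path))
    }
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      lines <- readLines(path, warn = FALSE)
      atom_lines <- grep("^(ATOM|HETATM)", lines)
      for (ln in atom_lines) {
        xyz <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
        if (anyNA(suppressWarnings(as.numeric(xyz)))) {
          stop("PDB parse error at line ", ln, ": malformed coordinate field",
               call. = FALSE)
        }
      }
      stop("PDB parse error: ", conditionMessage(e), call. = FALSE)
    })
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid != "HOH", , drop = FALSE]
  if (!nrow(at)) stop("empty structure: no protein ATOM records", call. = FALSE)

  at$resid <- .canon_resname(at$resid)
  noncanon <- !(at$resid %in% canonical_residues())
  if (any(noncanon)) {
    warning("dropping ", length(unique(at$resid[noncanon])),
            " non-canonical residue type(s): ",
            paste(unique(at$resid[noncanon]), collapse = ", "))
    at <- at[!noncanon, , drop = FALSE]
  }
  if (!nrow(at)) stop("empty structure: no canonical protein residues",
                      call. = FALSE)

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc resolution: highest occupancy, ties toward "A" (then alphabetic)
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(akey)) {
    ord <- order(akey, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                                        at$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    resname = at$resid,
    chain = at$chain,
    resno = at$resno,
    insert = at$insert,
    x = at$x, y = at$y, z = at$z,
    occ = at$o,
    element = toupper(elem),
    stringsAsFactors = FALSE
  )
  atoms$is_h <- atoms$element == "H"
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("PDB parse error: non-finite coordinates", call. = FALSE)
  }
  structure(list(entry_id = entry_id, atoms = atoms),
            class = "ib_structure")
}

#' @export
print.ib_structure <- function(x, ...) {
  res <- unique(residue_ids(x$atoms))
  cat("<ib_structure>", x$entry_id, "-", nrow(x$atoms), "atoms,",
      length(res), "residues, chains:",
      paste(sort(unique(x$atoms$chain)), collapse = " "), "\n")
  invisible(x)
}

# residue identifier strings chain:resno[insert]
residue_ids <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno, atoms$insert)
}

#' Define the two sides of a binding interface
#'
#' @param group1,group2 character vectors of chain identifiers; the two
#'   groups must be disjoint and nonempty. Higher-order oligomers are
#'   handled by putting several chains in one group.
#' @return An object of class \code{interface_spec}.
#' @export
#' @examples
#' interface_spec("A", "D")
#' interface_spec(c("A", "B"), "C")
interface_spec <- function(group1, group2) {
  group1 <- as.character(group1)
  group2 <- as.character(group2)
  if (!length(group1) || !length(group2)) {
    stop("both interface groups must be nonempty", call. = FALSE)
  }
  if (length(intersect(group1, group2))) {
    stop("interface groups must be disjoint", call. = FALSE)
  }
  structure(list(group1 = group1, group2 = group2),
            class = "interface_spec")
}

#' Parse an interface group string such as "A,B:C,D"
#'
#' The colon separates the two sides; commas separate chains within a side.
#' @param text the group string.
#' @return An \code{interface_spec}.
#' @export
parse_groups <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("group spec must contain exactly one ':' (e.g. \"A:D\")",
         call. = FALSE)
  }
  sides <- lapply(parts, function(p) {
    ch <- trimws(strsplit(p, ",", fixed = TRUE)[[1]])
    ch[nzchar(ch)]
  })
  interface_spec(sides[[1]], sides[[2]])
}

#' Select the residues on each side of an interface
#'
#' @param model an \code{ib_structure}.
#' @param spec an \code{interface_spec}; every named chain must exist in
#'   the model.
#' @return A list with atom tables \code{group1} and \code{group2}.
#' @export
select_interface <- function(model, spec) {
  stopifnot(inherits(model, "ib_structure"), inherits(spec, "interface_spec"))
  chains <- unique(model$atoms$chain)
  missing <- setdiff(c(spec$group1, spec$group2), chains)
  if (length(missing)) {
    stop("chain(s) not present in structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(group1 = model$atoms[model$atoms$chain %in% spec$group1, , drop = FALSE],
       group2 = model$atoms[model$atoms$chain %in% spec$group2, , drop = FALSE])
}

# canonical empty bond table
empty_bonds <- function() {
  data.frame(bond_type = character(), chain1 = character(),
             resname1 = character(), resnum1 = character(),
             chain2 = character(), resname2 = character(),
             resnum2 = character(), atom1 = character(),
             atom2 = character(), role1 = character(),
             distance = numeric(), dha_angle = numeric(),
             centroid_distance = numeric(), stringsAsFactors = FALSE)
}

#' Combine per-type bond tables into one data frame
#' @param bonds a named list of bond tables as returned by
#'   \code{\link{detect_all}}, or a single bond table.
#' @return One bond table data frame.
#' @export
bind_bonds <- function(bonds) {
  if (is.data.frame(bonds)) return(bonds)
  out <- do.call(rbind, c(unname(bonds), list(empty_bonds())))
  rownames(out) <- NULL
  out
}

#' Serialize a bond table to TSV or JSON
#'
#' Rows are ordered deterministically (bond type, then chain and residue
#' number of the group-1 residue, then distance); distances and angles are
#' written with 3 decimals so repeated runs are byte-identical.
#'
#' @param bonds a bond table or a list of per-type bond tables.
#' @param format "tsv" or "json".
#' @param path optional output file; when NULL the text is returned.
#' @return The serialized text, invisibly when written to a file.
#' @export
write_bond_table <- function(bonds, format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  b <- bind_bonds(bonds)
  if (nrow(b)) {
    b <- b[order(b$bond_type, b$chain1, as.integer(sub("[A-Za-z]+$", "",
                                                       b$resnum1)),
                 b$distance), , drop = FALSE]
    for (col in c("distance", "dha_angle", "centroid_distance")) {
      b[[col]] <- round(b[[col]], 3)
    }
    rownames(b) <- NULL
  }
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(b, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    close(con)
    text <- paste0(paste(out, collapse = "\n"), "\n")
  } else {
    text <- as.character(jsonlite::toJSON(b, dataframe = "rows", na = "null",
                                          digits = NA, pretty = TRUE))
  }
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}
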