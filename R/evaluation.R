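# Scoring predicted bonds against a curated reference bond list.
# Matching is on unordered residue-pair identity plus bond type; atom
# detail is ignored because reference literature states residue pairs.
# True negatives are structurally unknowable (no study exhaustively tests
# every residue pair), so they are reported as "Unknown".

.pair_key <- function(chain1, resnum1, chain2, resnum2) {
  if (!length(chain1)) return(character())
  a <- paste0(chain1, ":", resnum1)
  b <- paste0(chain2, ":", resnum2)
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Read a reference bond list
#'
#' TSV with columns chain1, resnum1, resname1, chain2, resnum2, resname2,
#' bond_type, source.
#'
#' @param path file path.
#' @return Data frame of reference bonds.
#' @export
read_reference_bonds <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("chain1", "resnum1", "chain2", "resnum2", "bond_type")
  if (!all(need %in% names(x))) {
    stop("reference bond list lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  x
}

#' Add implied salt bridges to a reference bond list
#'
#' A residue pair documented with both a hydrogen bond and an ionic bond
#' implies a salt bridge; an explicit salt-bridge entry is added for such
#' pairs when absent. Idempotent.
#'
#' @param reference data frame of reference bonds.
#' @return The augmented reference list.
#' @export
infer_reference_salt_bridges <- function(reference) {
  key <- .pair_key(reference$chain1, reference$resnum1,
                   reference$chain2, reference$resnum2)
  has_h <- unique(key[reference$bond_type == "hydrogen"])
  has_i <- unique(key[reference$bond_type == "ionic"])
  has_s <- unique(key[reference$bond_type == "salt_bridge"])
  imply <- setdiff(intersect(has_h, has_i), has_s)
  if (!length(imply)) return(reference)
  add <- reference[match(imply, key), , drop = FALSE]
  add$bond_type <- "salt_bridge"
  if ("source" %in% names(add)) {
    add$source <- "implied by hydrogen + ionic entries"
  }
  out <- rbind(reference, add)
  rownames(out) <- NULL
  out
}

#' Score predicted bonds against the reference list
#'
#' TP: predicted residue pairs present in the reference with matching
#' bond type; FP: predicted pairs absent from the reference (including
#' pairs referenced only under a different type); FN: reference pairs of
#' the type that were not predicted. Pairs are unordered; duplicate
#' entries are collapsed with a warning.
#'
#' @param predicted a bond table (or list of tables) from the detectors.
#' @param reference a reference bond data frame.
#' @param bond_type which type to score.
#' @return An object of class \code{confusion_counts} with tp, fp, fn
#'   (tn is unknowable).
#' @export
score_predictions <- function(predicted, reference, bond_type) {
  pred <- bind_bonds(predicted)
  pred <- pred[pred$bond_type == bond_type, , drop = FALSE]
  ref <- reference[reference$bond_type == bond_type, , drop = FALSE]
  pk <- unique(.pair_key(pred$chain1, pred$resnum1, pred$chain2,
                         pred$resnum2))
  rk <- .pair_key(ref$chain1, ref$resnum1, ref$chain2, ref$resnum2)
  if (anyDuplicated(rk)) {
    warning("collapsing ", sum(duplicated(rk)),
            " duplicated reference entr(ies)")
    rk <- unique(rk)
  }
  structure(list(bond_type = bond_type,
                 tp = length(intersect(pk, rk)),
                 fp = length(setdiff(pk, rk)),
                 fn = length(setdiff(rk, pk)),
                 tn = NA_integer_),
            class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' @param tp,fp,fn non-negative integer counts; tn is unknowable and
#'   always recorded as NA.
#' @param bond_type optional label.
#' @return A \code{confusion_counts} object.
#' @export
confusion_counts <- function(tp, fp, fn, bond_type = NA_character_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(bond_type = bond_type, tp = as.integer(tp),
                 fp = as.integer(fp), fn = as.integer(fn),
                 tn = NA_integer_),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  pr <- precision_recall(x)
  cat("Confusion counts", if (!is.na(x$bond_type))
    paste0("(", x$bond_type, ")") else "", "\n")
  cat("  TP:", x$tp, " FP:", x$fp, " FN:", x$fn, " TN: Unknown\n")
  cat("  precision:", .fmt_pct(pr$precision),
      " recall:", .fmt_pct(pr$recall), "\n")
  invisible(x)
}

.fmt_pct <- function(p) if (is.na(p)) "undefined" else
  sprintf("%.1f%%", 100 * p)

#' Precision and recall from confusion counts
#'
#' precision = tp / (tp + fp); recall = tp / (tp + fn). A zero
#' denominator yields NA (undefined), never 0.
#'
#' @param counts a \code{confusion_counts} object.
#' @return List with \code{precision} and \code{recall} as fractions.
#' @export
precision_recall <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  list(precision = if (counts$tp + counts$fp > 0)
    counts$tp / (counts$tp + counts$fp) else NA_real_,
    recall = if (counts$tp + counts$fn > 0)
      counts$tp / (counts$tp + counts$fn) else NA_real_)
}

#' Per-type evaluation report
#'
#' Scores each bond type and lays the result out with one column per
#' type: TP/FP/FN counts, "Unknown" for TN, precision and recall as
#' percentages, and recomputed totals (total predictions = tp + fp,
#' total known bonds = tp + fn).
#'
#' @param predicted detector output (list of bond tables or one table).
#' @param reference reference bond data frame (salt-bridge implication is
#'   applied first).
#' @return Data frame with a metric column and one column per bond type.
#' @export
evaluation_report <- function(predicted, reference) {
  reference <- infer_reference_salt_bridges(reference)
  types <- c("ionic", "hydrogen", "salt_bridge")
  cols <- lapply(types, function(ty) {
    cc <- score_predictions(predicted, reference, ty)
    pr <- precision_recall(cc)
    c(cc$tp, cc$fp, cc$fn, "Unknown",
      .fmt_pct(pr$precision), .fmt_pct(pr$recall),
      cc$tp + cc$fn, cc$tp + cc$fp)
  })
  out <- data.frame(metric = c("True Positive", "False Positive",
                               "False Negative", "True Negative",
                               "Precision", "Recall",
                               "Total Known Bonds", "Total Predictions"),
                    stringsAsFactors = FALSE)
  for (k in seq_along(types)) out[[types[k]]] <- cols[[k]]
  out
}
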