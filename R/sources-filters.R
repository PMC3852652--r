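# Compound-source filters applied to ChEMBL/ChEBI/KEGG-style record
# tables before pooling, and the duplicate-removing union.

#' ChEMBL-style activity filter
#'
#' Keeps records that have a binding constant and whose IC50, when known,
#' is at most 100 nM ("more than 100 nM" is excluded, strictly).
#'
#' @param records compound-record data.frame (see
#'   \code{\link{readCompoundTable}}); all rows must carry source "chembl".
#' @param maxIC50nM IC50 threshold in nM (default 100).
#' @return the filtered records. Idempotent.
#' @export
filterChembl <- function(records, maxIC50nM = 100) {
  if (!nrow(records)) return(records)
  stopifnot(all(records$source == "chembl"))
  keep <- records$has_binding_constant &
    (is.na(records$ic50_nM) | records$ic50_nM <= maxIC50nM)
  records[keep, , drop = FALSE]
}

#' ChEBI-style size filter
#'
#' Excludes compounds with fewer than \code{minAtoms} atoms and/or a
#' molecular weight below \code{minWeight} Da. By default the atom count
#' includes hydrogens implicit by valence, so e.g. a 3-heavy-atom molecule
#' with one hydrogen passes the 4-atom rule; set
#' \code{countImplicitH = FALSE} to count heavy atoms only.
#'
#' @param records compound-record data.frame with source "chebi".
#' @param minAtoms minimum atom count (default 4).
#' @param minWeight minimum molecular weight in Da (default 50).
#' @param countImplicitH include implicit hydrogens in the atom count.
#' @return the filtered records. Idempotent.
#' @export
filterChebi <- function(records, minAtoms = 4, minWeight = 50,
                        countImplicitH = TRUE) {
  if (!nrow(records)) return(records)
  stopifnot(all(records$source == "chebi"))
  keep <- vapply(records$molecule, function(m) {
    p <- molProperties(m)
    atoms <- p$heavy_atoms + if (countImplicitH) p$n_implicit_h else 0L
    atoms >= minAtoms && p$mol_weight >= minWeight
  }, logical(1))
  records[keep, , drop = FALSE]
}

#' Union of compound collections with duplicate removal
#'
#' Records are considered duplicates when their molecular graphs are
#' identical (element- and bond-order-preserving isomorphism). On a
#' collision the record with the most metadata survives: a binding
#' constant beats a cross-reference count beats first-seen.
#'
#' @param ... compound-record data.frames.
#' @return the deduplicated union, in first-seen order.
#' @export
dedupUnion <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) {
    empty <- list(...)[[1]]
    return(empty)
  }
  all <- do.call(rbind, parts)
  rownames(all) <- NULL
  richness <- function(r)
    2 * isTRUE(all$has_binding_constant[r]) +
      1 * !is.na(all$xref_count[r])
  keptIdx <- integer()
  for (r in seq_len(nrow(all))) {
    dup <- NA_integer_
    for (k in keptIdx) {
      if (graphsIsomorphic(all$molecule[[r]], all$molecule[[k]])) {
        dup <- k
        break
      }
    }
    if (is.na(dup)) keptIdx <- c(keptIdx, r)
    else if (richness(r) > richness(dup))
      keptIdx[keptIdx == dup] <- r     # richer later copy replaces in place
  }
  out <- all[keptIdx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
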