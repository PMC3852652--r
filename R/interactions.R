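# Ligand-protein interaction detection and the conservation-weighted
# interaction score. Hydrogen bonds are distance-only polar (N/O/S)
# heavy-atom pairs (deposited structures rarely have hydrogens); contacts
# are any heavy-atom pairs, reduced to one per protein residue. Each
# interaction is weighted by how conserved the contacted residue is
# relative to the query: 3/2/1/-1 per hydrogen bond and 2/1/0/-1 per
# contacted residue for identical/similar/other/gap.

POLAR_ELEMENTS <- c("N", "O", "S")

interactionFrame <- function() {
  data.frame(kind = character(), ligandAtom = character(),
             chain = character(), resno = integer(), insert = character(),
             resType = character(), distance = numeric(),
             conservation = character(), weight = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect ligand-protein hydrogen bonds
#'
#' One record per (ligand polar atom, protein polar atom) pair within the
#' scheme's hydrogen-bond distance. Every such pair counts individually.
#'
#' @param protein a \linkS4class{ProteinStructure} in the same coordinate
#'   frame as the ligand.
#' @param ligand a \linkS4class{LigandInstance}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return data.frame of interaction records (kind "hbond"), conservation
#'   unclassified (NA) until \code{\link{classifyConservation}}.
#' @export
detectHBonds <- function(protein, ligand, scheme = ScoringScheme()) {
  pa <- protein@atoms[protein@atoms$element %in% POLAR_ELEMENTS, ,
                      drop = FALSE]
  la <- ligand@atoms[ligand@atoms$element %in% POLAR_ELEMENTS, ,
                     drop = FALSE]
  out <- interactionFrame()
  if (!nrow(pa) || !nrow(la)) return(out)
  d <- crossDist(la[, c("x", "y", "z")], pa[, c("x", "y", "z")])
  hit <- which(d <= scheme@hbondMaxDist, arr.ind = TRUE)
  if (!nrow(hit)) return(out)
  data.frame(kind = "hbond", ligandAtom = la$name[hit[, 1]],
             chain = pa$chain[hit[, 2]], resno = pa$resno[hit[, 2]],
             insert = pa$insert[hit[, 2]], resType = pa$resid[hit[, 2]],
             distance = d[hit], conservation = NA_character_,
             weight = NA_real_, stringsAsFactors = FALSE)
}

#' Detect nonbonded contacts
#'
#' Heavy-atom pairs within the scheme's contact distance, reduced to at
#' most one record per protein residue (the closest pair is kept).
#' Residues already contributing a hydrogen bond are excluded so a residue
#' never accrues both scores.
#'
#' @inheritParams detectHBonds
#' @param hbonds hydrogen-bond records from \code{\link{detectHBonds}} for
#'   the same pose, used for the exclusion rule; may be NULL.
#' @return data.frame of interaction records (kind "contact").
#' @export
detectContacts <- function(protein, ligand, scheme = ScoringScheme(),
                           hbonds = NULL) {
  pa <- protein@atoms[protein@atoms$element != "H", , drop = FALSE]
  la <- ligand@atoms[ligand@atoms$element != "H", , drop = FALSE]
  out <- interactionFrame()
  if (!nrow(pa) || !nrow(la)) return(out)
  d <- crossDist(la[, c("x", "y", "z")], pa[, c("x", "y", "z")])
  hit <- which(d <= scheme@contactMaxDist, arr.ind = TRUE)
  if (!nrow(hit)) return(out)
  rec <- data.frame(kind = "contact", ligandAtom = la$name[hit[, 1]],
                    chain = pa$chain[hit[, 2]], resno = pa$resno[hit[, 2]],
                    insert = pa$insert[hit[, 2]],
                    resType = pa$resid[hit[, 2]], distance = d[hit],
                    conservation = NA_character_, weight = NA_real_,
                    stringsAsFactors = FALSE)
  key <- paste(rec$chain, rec$resno, rec$insert)
  rec <- rec[order(key, rec$distance), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$chain, rec$resno, rec$insert)), ,
             drop = FALSE]
  if (!is.null(hbonds) && nrow(hbonds)) {
    hbKey <- unique(paste(hbonds$chain, hbonds$resno, hbonds$insert))
    rec <- rec[!(paste(rec$chain, rec$resno, rec$insert) %in% hbKey), ,
               drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Classify interaction conservation against the query
#'
#' For each record, finds the query residue aligned to the contacted hit
#' residue through the pairwise alignment: "gap" when the hit residue
#' aligns to no query position, "identical" when the query residue type
#' equals the hit's, "similar" when the substitution-matrix score is
#' positive, "other" otherwise.
#'
#' @param records interaction records from the detectors.
#' @param pair \linkS4class{AlignmentPair} of the query against the hit
#'   chain's sequence.
#' @param querySeq query sequence (character string).
#' @param hitPosOf function mapping a record's (chain, resno, insert) to
#'   the hit residue's 1-based sequence position; defaults to using resno
#'   directly (fixture convention: author numbering == sequence position).
#' @param matrix substitution matrix for the "similar" test.
#' @return the records with \code{conservation} filled in.
#' @export
classifyConservation <- function(records, pair, querySeq,
                                 hitPosOf = NULL, matrix = "BLOSUM62") {
  if (!nrow(records)) return(records)
  mat <- loadSubstitutionMatrix(matrix)
  cm <- pair@columns
  both <- !is.na(cm[, 1]) & !is.na(cm[, 2])
  qOfH <- integer()
  qOfH[cm[both, 2]] <- cm[both, 1]
  qchars <- strsplit(querySeq, "")[[1]]
  for (r in seq_len(nrow(records))) {
    hpos <- if (is.null(hitPosOf)) records$resno[r] else
      hitPosOf(records$chain[r], records$resno[r], records$insert[r])
    qpos <- if (!is.na(hpos) && hpos >= 1 && hpos <= length(qOfH))
      qOfH[hpos] else NA_integer_
    if (is.na(qpos) || qpos == 0L) {
      records$conservation[r] <- "gap"
      next
    }
    h1 <- aa321(records$resType[r])
    q1 <- qchars[qpos]
    records$conservation[r] <-
      if (q1 == h1) "identical"
      else if (h1 %in% rownames(mat) && q1 %in% colnames(mat) &&
               mat[h1, q1] > 0) "similar"
      else "other"
  }
  records
}

schemeWeight <- function(scheme, kind, conservation) {
  w <- ifelse(kind == "hbond",
    c(identical = scheme@hbIdentical, similar = scheme@hbSimilar,
      other = scheme@hbOther, gap = scheme@hbGap)[conservation],
    c(identical = scheme@nbIdentical, similar = scheme@nbSimilar,
      other = scheme@nbOther, gap = scheme@nbGap)[conservation])
  unname(w)
}

#' Score a ligand's interactions
#'
#' The achieved score sums the scheme weight of every hydrogen bond and
#' every (deduplicated) contacted residue by its conservation class. The
#' maximum is the ceiling the same interactions would reach were every
#' contacted residue identical to the query's.
#'
#' @param hbonds,contacts conservation-classified records.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param ligandKey named character identifying the ligand instance.
#' @return a \linkS4class{LigandScore} ("achieved/maximum").
#' @export
scoreLigand <- function(hbonds, contacts, scheme = ScoringScheme(),
                        ligandKey = c(structure_id = NA, het_code = NA,
                                      chain_id = NA, seq_num = NA)) {
  recs <- rbind(hbonds, contacts)
  if (nrow(recs) && anyNA(recs$conservation))
    stop("records must be conservation-classified before scoring")
  if (nrow(recs))
    recs$weight <- schemeWeight(scheme, recs$kind, recs$conservation)
  achieved <- if (nrow(recs)) sum(recs$weight) else 0
  maximum <- scheme@hbIdentical * NROW(hbonds) +
    scheme@nbIdentical * NROW(contacts)
  new("LigandScore", ligandKey = as.character(ligandKey),
      achieved = achieved, maximum = maximum, records = recs)
}

#' Merge per-domain scores for one ligand instance
#'
#' A ligand touching several domains is scored once per domain search;
#' this merges those results so each protein residue is counted once
#' (hydrogen-bond records preferred over contact records on collision,
#' duplicate hydrogen bonds deduplicated) and recomputes achieved/maximum
#' from the union.
#'
#' @param scores list of \linkS4class{LigandScore} for the same ligand
#'   instance (same structure, het code, chain and residue number).
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return the merged \linkS4class{LigandScore}.
#' @export
mergeDomainScores <- function(scores, scheme = ScoringScheme()) {
  stopifnot(length(scores) >= 1)
  keys <- unique(vapply(scores, function(s)
    paste(s@ligandKey, collapse = "|"), ""))
  if (length(keys) != 1)
    stop("cannot merge scores for different ligand instances")
  if (length(scores) == 1) return(scores[[1]])
  recs <- do.call(rbind, lapply(scores, function(s) s@records))
  # the same physical interaction seen from different domain searches
  # keeps its best conservation class (a residue aligns in the domain
  # that owns it and shows as a gap elsewhere)
  consRank <- c(identical = 1L, similar = 2L, other = 3L, gap = 4L)
  hb <- recs[recs$kind == "hbond", , drop = FALSE]
  hb <- hb[order(consRank[hb$conservation]), , drop = FALSE]
  hb <- hb[!duplicated(paste(hb$ligandAtom, hb$chain, hb$resno,
                             hb$insert)), , drop = FALSE]
  ct <- recs[recs$kind == "contact", , drop = FALSE]
  ct <- ct[order(consRank[ct$conservation], ct$distance), , drop = FALSE]
  ct <- ct[!duplicated(paste(ct$chain, ct$resno, ct$insert)), ,
           drop = FALSE]
  hbKey <- unique(paste(hb$chain, hb$resno, hb$insert))
  ct <- ct[!(paste(ct$chain, ct$resno, ct$insert) %in% hbKey), ,
           drop = FALSE]
  scoreLigand(hb, ct, scheme, ligandKey = scores[[1]]@ligandKey)
}
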