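# End-to-end workflow: sequence extraction, top-N homolog search, source
# filtering, domain partitioning, per-domain structure search and
# superposition, conservation-weighted ligand scoring with cross-domain
# merging, similarity clustering and ranking.

# ordered residues of one chain: sequence index -> (resno, insert)
chainResnoMap <- function(structure, chain) {
  a <- structure@atoms[structure@atoms$chain == chain, , drop = FALSE]
  res <- a[!duplicated(paste(a$resno, a$insert)), c("resno", "insert"),
           drop = FALSE]
  res$index <- seq_len(nrow(res))
  res
}

# map an entry-sequence position to a chain-sequence position: for a
# full-chain entry the identity; for a split-domain entry, through the
# concatenated segments
entryToChainPos <- function(entry, pos) {
  segs <- entry$segments[[1]]
  off <- 0L
  for (r in seq_len(nrow(segs))) {
    w <- segs$end[r] - segs$start[r] + 1L
    if (pos <= off + w) return(segs$start[r] + (pos - off - 1L))
    off <- off + w
  }
  NA_integer_
}

# inverse: chain-sequence position to entry position (NA outside segments)
chainToEntryPos <- function(entry, pos) {
  segs <- entry$segments[[1]]
  off <- 0L
  for (r in seq_len(nrow(segs))) {
    if (pos >= segs$start[r] && pos <= segs$end[r])
      return(off + pos - segs$start[r] + 1L)
    off <- off + (segs$end[r] - segs$start[r] + 1L)
  }
  NA_integer_
}

#' Rank clusters of candidate ligands
#'
#' Clusters containing structure-derived (PDB) ligands come first, sorted
#' by the highest achieved interaction score in the cluster (descending,
#' ties by cluster id). Clusters with no structure-derived member follow,
#' sorted by their highest member's associated-protein identity, then by
#' highest cross-reference count, then cluster id.
#'
#' @param members data.frame with one row per candidate: columns
#'   \code{cluster}, \code{is_pdb}, \code{achieved},
#'   \code{assoc_identity_pct}, \code{xref_count}.
#' @return data.frame mapping \code{cluster} to \code{cluster_rank}.
#' @export
rankClusters <- function(members) {
  stats <- do.call(rbind, lapply(split(members, members$cluster),
    function(m) data.frame(
      cluster = m$cluster[1],
      has_pdb = any(m$is_pdb),
      best = if (any(m$is_pdb)) max(m$achieved[m$is_pdb]) else -Inf,
      best_ident = suppressWarnings(max(c(m$assoc_identity_pct, -Inf),
                                        na.rm = TRUE)),
      best_xref = suppressWarnings(max(c(m$xref_count, -Inf),
                                       na.rm = TRUE)))))
  ord <- order(!stats$has_pdb, -stats$best, -stats$best_ident,
               -stats$best_xref, stats$cluster)
  data.frame(cluster = stats$cluster[ord],
             cluster_rank = seq_len(nrow(stats)))
}

#' Order candidates within one cluster
#'
#' Structure-derived ligands first, by achieved score (descending; ties by
#' maximum score descending, then ligand id); compound-source hits at the
#' end, in decreasing associated-protein identity, then decreasing
#' cross-reference count, then compound id.
#'
#' @param members data.frame of one cluster's candidates with columns
#'   \code{uid}, \code{is_pdb}, \code{achieved}, \code{maximum},
#'   \code{assoc_identity_pct}, \code{xref_count}.
#' @return the rows of \code{members} in display order.
#' @export
orderWithinCluster <- function(members) {
  pdb <- members[members$is_pdb, , drop = FALSE]
  src <- members[!members$is_pdb, , drop = FALSE]
  pdb <- pdb[order(-pdb$achieved, -pdb$maximum, pdb$uid), , drop = FALSE]
  ident <- ifelse(is.na(src$assoc_identity_pct), -Inf,
                  src$assoc_identity_pct)
  xref <- ifelse(is.na(src$xref_count), -Inf, src$xref_count)
  src <- src[order(-ident, -xref, src$uid), , drop = FALSE]
  rbind(pdb, src)
}

extractQuerySequence <- function(query) {
  if (methods::is(query, "ProteinStructure")) {
    s <- query@seqres[[1]]
    list(id = query@id, seq = s)
  } else if (methods::is(query, "XStringSet")) {
    list(id = if (!is.null(names(query))) names(query)[1] else "query",
         seq = as.character(query[[1]]))
  } else if (is.character(query) && length(query) == 1) {
    list(id = "query", seq = toupper(query))
  } else stop("unsupported query type")
}

#' Run the full candidate-ligand prediction workflow
#'
#' Extracts the query sequence, finds its top-N homolog chains in the
#' structure library, keeps compound-source records associated with those
#' homologs (ChEMBL/ChEBI filters applied, duplicates removed), partitions
#' the query into predicted domains from the homolog annotations, searches
#' each domain against the full-chain + domain sequence database, superposes
#' every hit structure onto the per-domain reference (best Smith-Waterman
#' score) by iterative outlier-trimmed fitting, scores every ligand of
#' every hit structure by conservation-weighted hydrogen bonds and
#' contacts, merges per-domain scores per ligand instance, pools all
#' candidates, clusters them by maximum-common-subgraph Tanimoto similarity
#' and ranks clusters and members.
#'
#' @param query a sequence (character or AAStringSet) or a
#'   \linkS4class{ProteinStructure} (sequence extracted).
#' @param structures list of \linkS4class{ProteinStructure}: the
#'   protein-ligand complex library.
#' @param annotations domain-annotation data.frame (see
#'   \code{\link{readDomainAnnotations}}) or NULL.
#' @param compounds compound-record data.frame (see
#'   \code{\link{readCompoundTable}}) or NULL.
#' @param config a \linkS4class{PipelineConfig}.
#' @return a \linkS4class{RankedResult}; its table is empty (with an
#'   explanatory log) when no hits are found anywhere.
#' @export
runPipeline <- function(query, structures, annotations = NULL,
                        compounds = NULL, config = PipelineConfig()) {
  q <- extractQuerySequence(query)
  if (nchar(q$seq) < config@minQueryLen)
    stop("query shorter than ", config@minQueryLen, " residues")
  checkAASeq(q$seq, q$id)
  if (methods::is(structures, "ProteinStructure"))
    structures <- list(structures)
  log <- sprintf("query %s: %d residues", q$id, nchar(q$seq))
  emptyResult <- function(log) {
    new("RankedResult",
        table = stats::setNames(
          data.frame(matrix(nrow = 0, ncol = length(RESULT_COLUMNS))),
          RESULT_COLUMNS),
        molecules = list(), queryId = q$id, log = log)
  }
  if (!length(structures) && (is.null(compounds) || !nrow(compounds)))
    stop("need a structure library or compound sources")

  db <- if (length(structures)) buildSequenceDb(structures, annotations)
        else NULL
  structById <- stats::setNames(structures,
    vapply(structures, structureId, ""))

  # --- top-N homolog chains ---------------------------------------------
  hits <- list()
  if (!is.null(db)) {
    fullDb <- db[db$kind == "full_chain", , drop = FALSE]
    hits <- rankHits(q$seq, fullDb, n = config@topN,
                     matrix = config@matrix, gapOpen = config@gapOpen,
                     gapExtend = config@gapExtend, queryId = q$id)
    hits <- Filter(function(p) p@score > 0, hits)
    log <- c(log, sprintf("homolog search: %d hits (top %d kept)",
                          length(hits), config@topN))
  }
  hitIds <- vapply(hits, function(p) p@hitId, "")
  hitIdent <- vapply(hits, identityPct, 0)
  hitStructOf <- function(eid) db$parent_structure_id[db$entry_id == eid][1]

  # --- compound sources -------------------------------------------------
  sourceRecs <- NULL
  if (!is.null(compounds) && nrow(compounds)) {
    protOfHit <- vapply(hitIds, hitStructOf, "")
    idx <- match(compounds$protein_id, protOfHit)
    idx2 <- match(compounds$protein_id, hitIds)
    idx[is.na(idx)] <- idx2[is.na(idx)]
    keep <- !is.na(idx)
    sourceRecs <- compounds[keep, , drop = FALSE]
    sourceRecs$assoc_identity_pct <- hitIdent[idx[keep]]
    log <- c(log, sprintf("sources: %d of %d records match a homolog",
                          nrow(sourceRecs), nrow(compounds)))
    ch <- sourceRecs[sourceRecs$source == "chembl", , drop = FALSE]
    cb <- sourceRecs[sourceRecs$source == "chebi", , drop = FALSE]
    kg <- sourceRecs[sourceRecs$source == "kegg", , drop = FALSE]
    ch <- filterChembl(ch)
    cb <- filterChebi(cb)
    sourceRecs <- dedupUnion(ch, cb, kg)
    log <- c(log, sprintf("sources after filters + dedup: %d records",
                          nrow(sourceRecs)))
  }
  if (!length(hits) && (is.null(sourceRecs) || !nrow(sourceRecs))) {
    log <- c(log, "no hits anywhere: empty result")
    return(emptyResult(log))
  }

  # --- domain partition -------------------------------------------------
  ranked <- list()
  if (!is.null(annotations) && nrow(annotations) && length(hits)) {
    for (p in hits) {
      sid <- hitStructOf(p@hitId)
      cid <- db$chain_id[db$entry_id == p@hitId][1]
      ann <- annotations[annotations$structure_id == sid &
                         annotations$chain_id == cid, , drop = FALSE]
      if (!nrow(ann)) next
      anns <- lapply(seq_len(nrow(ann)), function(r) list(
        domain_id = ann$domain_id[r], kind = ann$kind[r],
        segments = if ("segments_parsed" %in% names(ann))
          ann$segments_parsed[[r]] else parseSegments(ann$segments[r])))
      ranked[[length(ranked) + 1L]] <- list(pair = p, annotations = anns)
    }
  }
  partition <- partitionQuery(nchar(q$seq), ranked,
                              unknownDomainMin = config@unknownDomainMin,
                              minMapped = config@minMappedDomain)
  domLabels <- unique(partition$label)
  log <- c(log, sprintf("domain partition: %d domains (%s)",
                        length(domLabels),
                        paste(domLabels, collapse = ", ")))

  # --- per-domain structure search, superposition, scoring --------------
  perLigand <- list()     # uid -> list(scores = list, meta)
  if (!is.null(db) && nrow(db)) {
    for (lab in domLabels) {
      segs <- partition[partition$label == lab, , drop = FALSE]
      domSeq <- paste(substring(q$seq, segs$start, segs$end),
                      collapse = "")
      if (nchar(domSeq) < 3) next
      domHits <- rankHits(domSeq, db, n = config@topN,
                          matrix = config@matrix, gapOpen = config@gapOpen,
                          gapExtend = config@gapExtend,
                          queryId = paste0(q$id, ":", lab))
      domHits <- Filter(function(p) p@score > 0, domHits)
      if (!length(domHits)) next
      refEntry <- db[db$entry_id == domHits[[1]]@hitId, , drop = FALSE]
      refStruct <- structById[[refEntry$parent_structure_id[1]]]
      msa <- buildQueryAnchoredMSA(domHits, queryLen = nchar(domSeq))
      log <- c(log, sprintf("domain %s: %d hits, reference %s", lab,
                            length(domHits), refEntry$entry_id[1]))

      # superpose every non-reference hit structure onto the reference
      refRow <- msa$rows[[1]]
      refMap <- chainResnoMap(refStruct, refEntry$chain_id[1])
      supDone <- character()
      for (hi in seq_along(domHits)[-1]) {
        mobEntry <- db[db$entry_id == domHits[[hi]]@hitId, , drop = FALSE]
        mobStruct <- structById[[mobEntry$parent_structure_id[1]]]
        if (identical(mobStruct@id, refStruct@id)) next
        if (mobStruct@id %in% supDone) next
        supDone <- c(supDone, mobStruct@id)
        mobRow <- msa$rows[[hi]]
        qpos <- which(!is.na(refRow) & !is.na(mobRow))
        if (length(qpos) < 3) next
        mobMap <- chainResnoMap(mobStruct, mobEntry$chain_id[1])
        eq <- NULL
        for (qp in qpos) {
          rc <- entryToChainPos(refEntry, refRow[qp])
          mc <- entryToChainPos(mobEntry, mobRow[qp])
          ri <- match(rc, refMap$index)
          mi <- match(mc, mobMap$index)
          if (is.na(ri) || is.na(mi)) next
          eq <- rbind(eq, data.frame(
            ref_chain = refEntry$chain_id[1], ref_resno = refMap$resno[ri],
            ref_insert = refMap$insert[ri],
            mob_chain = mobEntry$chain_id[1], mob_resno = mobMap$resno[mi],
            mob_insert = mobMap$insert[mi]))
        }
        if (is.null(eq) || nrow(eq) < 3) next
        sup <- tryCatch(
          iterativeSuperpose(refStruct, mobStruct, eq,
                             cutoff = config@rmsdCutoff),
          error = function(e) NULL)
        if (!is.null(sup))
          log <- c(log, sprintf(
            "  superposed %s onto %s: rmsd %.2f A (%d pairs%s)",
            mobStruct@id, refStruct@id, sup@rmsd, nrow(sup@retained),
            if (sup@converged) "" else ", not converged"))
      }

      # score every ligand of every hit structure for this domain
      for (hi in seq_along(domHits)) {
        entry <- db[db$entry_id == domHits[[hi]]@hitId, , drop = FALSE]
        hstruct <- structById[[entry$parent_structure_id[1]]]
        if (is.null(hstruct) || !length(hstruct@ligands)) next
        cmap <- chainResnoMap(hstruct, entry$chain_id[1])
        posOf <- function(chain, resno, insert) {
          if (chain != entry$chain_id[1]) return(NA_integer_)
          i <- match(paste(resno, insert), paste(cmap$resno, cmap$insert))
          if (is.na(i)) return(NA_integer_)
          chainToEntryPos(entry, cmap$index[i])
        }
        for (lig in hstruct@ligands) {
          hb <- detectHBonds(hstruct, lig, config@scheme)
          ct <- detectContacts(hstruct, lig, config@scheme, hbonds = hb)
          if (!nrow(hb) && !nrow(ct)) next
          hb <- classifyConservation(hb, domHits[[hi]], domSeq,
                                     hitPosOf = posOf,
                                     matrix = config@matrix)
          ct <- classifyConservation(ct, domHits[[hi]], domSeq,
                                     hitPosOf = posOf,
                                     matrix = config@matrix)
          key <- c(structure_id = hstruct@id, het_code = lig@hetCode,
                   chain_id = lig@chainId,
                   seq_num = as.character(lig@seqNum))
          sc <- scoreLigand(hb, ct, config@scheme, ligandKey = key)
          uid <- paste(key, collapse = ":")
          if (is.null(perLigand[[uid]]))
            perLigand[[uid]] <- list(scores = list(), ligand = lig,
                                     structure_id = hstruct@id,
                                     chain_id = entry$chain_id[1],
                                     identity = identityPct(domHits[[hi]]))
          perLigand[[uid]]$scores <-
            c(perLigand[[uid]]$scores, list(sc))
          perLigand[[uid]]$identity <-
            max(perLigand[[uid]]$identity, identityPct(domHits[[hi]]))
        }
      }
    }
  }

  # --- candidate pool ---------------------------------------------------
  cand <- list()
  chainIdent <- stats::setNames(hitIdent, vapply(hitIds, hitStructOf, ""))
  for (uid in names(perLigand)) {
    pl <- perLigand[[uid]]
    merged <- mergeDomainScores(pl$scores, config@scheme)
    mol <- ligandMolecule(pl$ligand)
    props <- molProperties(mol)
    # report the structure's full-chain identity to the query when the
    # structure is among the top hits; fall back to the best domain hit
    if (pl$structure_id %in% names(chainIdent))
      pl$identity <- max(chainIdent[names(chainIdent) == pl$structure_id])
    cand[[uid]] <- list(uid = uid, is_pdb = TRUE,
      ligand_id = pl$ligand@hetCode, source = "pdb",
      achieved = achievedScore(merged), maximum = maximumScore(merged),
      structure_id = pl$structure_id, chain_id = pl$ligand@chainId,
      assoc_identity_pct = pl$identity, xref_count = NA_integer_,
      mol_weight = props$mol_weight, heavy_atoms = props$heavy_atoms,
      molecule = mol)
  }
  if (!is.null(sourceRecs) && nrow(sourceRecs)) {
    for (r in seq_len(nrow(sourceRecs))) {
      uid <- sourceRecs$compound_id[r]
      while (uid %in% names(cand)) uid <- paste0(uid, "+")
      props <- molProperties(sourceRecs$molecule[[r]])
      cand[[uid]] <- list(uid = uid, is_pdb = FALSE,
        ligand_id = sourceRecs$compound_id[r],
        source = sourceRecs$source[r], achieved = NA_real_,
        maximum = NA_real_, structure_id = NA_character_,
        chain_id = NA_character_,
        assoc_identity_pct = sourceRecs$assoc_identity_pct[r],
        xref_count = sourceRecs$xref_count[r],
        mol_weight = props$mol_weight, heavy_atoms = props$heavy_atoms,
        molecule = sourceRecs$molecule[[r]])
    }
  }
  if (!length(cand)) {
    log <- c(log, "no candidate ligands: empty result")
    return(emptyResult(log))
  }

  members <- data.frame(
    uid = vapply(cand, `[[`, "", "uid"),
    is_pdb = vapply(cand, `[[`, TRUE, "is_pdb"),
    ligand_id = vapply(cand, `[[`, "", "ligand_id"),
    source = vapply(cand, `[[`, "", "source"),
    achieved = vapply(cand, `[[`, 0, "achieved"),
    maximum = vapply(cand, `[[`, 0, "maximum"),
    structure_id = vapply(cand, `[[`, "", "structure_id"),
    chain_id = vapply(cand, `[[`, "", "chain_id"),
    assoc_identity_pct = vapply(cand, `[[`, 0, "assoc_identity_pct"),
    xref_count = vapply(cand, `[[`, 0L, "xref_count"),
    mol_weight = vapply(cand, `[[`, 0, "mol_weight"),
    heavy_atoms = vapply(cand, function(x)
      as.integer(x$heavy_atoms), 0L),
    stringsAsFactors = FALSE)
  rownames(members) <- NULL
  mols <- lapply(cand, `[[`, "molecule")

  # --- clustering and ranking -------------------------------------------
  S <- similarityMatrix(mols, ids = members$uid)
  cl <- clusterMolecules(similarities = S, cutoff = config@clusterCutoff)
  members$cluster <- cl$cluster[match(members$uid, cl$id)]
  log <- c(log, sprintf("clustering: %d candidates in %d clusters",
                        nrow(members), length(unique(members$cluster))))

  ranks <- rankClusters(members)
  tab <- NULL
  for (k in seq_len(nrow(ranks))) {
    m <- members[members$cluster == ranks$cluster[k], , drop = FALSE]
    m <- orderWithinCluster(m)
    m$cluster_rank <- ranks$cluster_rank[k]
    tab <- rbind(tab, m)
  }
  tab$cluster_id <- tab$cluster
  tab$score_achieved <- tab$achieved
  tab$score_max <- tab$maximum
  ordMols <- mols[match(tab$uid, members$uid)]
  out <- tab[, c(RESULT_COLUMNS, "uid")]
  rownames(out) <- NULL
  new("RankedResult", table = out, molecules = ordMols, queryId = q$id,
      log = log)
}

#' Compare a result against known cognate ligands
#'
#' For each cognate molecule, records the maximum similarity over all
#' returned candidates, and the number of other molecules in the same
#' cluster as the cognate (the cognate joins the cluster of its most
#' similar candidate when that similarity reaches the clustering cutoff).
#'
#' @param result a \linkS4class{RankedResult}.
#' @param cognates list of \linkS4class{MoleculeGraph}.
#' @param cutoff cluster-membership similarity cutoff (default 0.4).
#' @return list with \code{per_cognate} (data.frame: cognate_id,
#'   best_similarity, best_candidate, cluster, co_members) and
#'   \code{summary} (counts of cognates with best similarity >= 0.9, 0.8,
#'   0.7, and with at least one same-cluster co-member).
#' @export
evaluateAgainstCognates <- function(result, cognates, cutoff = 0.4) {
  stopifnot(length(cognates) >= 1)
  tab <- resultTable(result)
  per <- NULL
  for (i in seq_along(cognates)) {
    cg <- cognates[[i]]
    cid <- moleculeId(cg)
    if (is.na(cid)) cid <- paste0("cognate", i)
    best <- 0; bestIdx <- NA_integer_
    for (j in seq_along(result@molecules)) {
      v <- molSimilarity(cg, result@molecules[[j]])$value
      if (v > best) { best <- v; bestIdx <- j }
    }
    cluster <- NA_character_; co <- 0L
    if (!is.na(bestIdx) && best >= cutoff) {
      cluster <- tab$cluster_id[bestIdx]
      co <- sum(tab$cluster_id == cluster) - 1L
    }
    per <- rbind(per, data.frame(
      cognate_id = cid, best_similarity = best,
      best_candidate = if (is.na(bestIdx)) NA_character_
                       else tab$uid[bestIdx],
      cluster = cluster, co_members = co, stringsAsFactors = FALSE))
  }
  list(per_cognate = per,
       summary = list(
         n_cognates = nrow(per),
         n_ge_0.9 = sum(per$best_similarity >= 0.9),
         n_ge_0.8 = sum(per$best_similarity >= 0.8),
         n_ge_0.7 = sum(per$best_similarity >= 0.7),
         n_with_cluster_comember = sum(per$co_members > 0)))
}
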