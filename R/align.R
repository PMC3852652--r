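# Local sequence search layer: optimal Smith-Waterman alignment (via
# Biostrings), top-N hit ranking, the full-chain + domain sequence database,
# and the query-anchored multiple alignment derived from pairwise hits.

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman alignment under an affine gap model (a gap of length L
#' costs gapOpen + L * gapExtend, the BLAST convention). Percent identity
#' is computed over aligned (gap-free) columns.
#'
#' @param a,b amino-acid sequences (character strings).
#' @param matrix substitution matrix name, file or matrix (default
#'   BLOSUM62); see \code{\link{loadSubstitutionMatrix}}.
#' @param gapOpen,gapExtend positive gap penalties (defaults 11 and 1).
#' @param queryId,hitId identifiers stored on the result.
#' @return an \linkS4class{AlignmentPair}.
#' @examples
#' aln <- smithWaterman("MKVLLA", "MKVLLA")
#' identityPct(aln)  # 100
#' @export
smithWaterman <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                          gapExtend = 1, queryId = "query", hitId = "hit") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (gapOpen <= 0 || gapExtend <= 0) stop("gap penalties must be positive")
  mat <- loadSubstitutionMatrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local", substitutionMatrix = mat,
    gapOpening = gapOpen, gapExtension = gapExtend)
  qg <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  hg <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  cols <- matrix(NA_integer_, nrow = length(qg), ncol = 2,
                 dimnames = list(NULL, c("qpos", "hpos")))
  if (length(qg)) {
    qi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
    hi <- Biostrings::start(Biostrings::subject(aln)) - 1L
    for (k in seq_along(qg)) {
      if (qg[k] != "-") { qi <- qi + 1L; cols[k, 1] <- qi }
      if (hg[k] != "-") { hi <- hi + 1L; cols[k, 2] <- hi }
    }
  }
  both <- !is.na(cols[, 1]) & !is.na(cols[, 2])
  idpct <- if (any(both)) 100 * sum(qg[both] == hg[both]) / sum(both) else 0
  new("AlignmentPair", queryId = queryId, hitId = hitId,
      score = Biostrings::score(aln), columns = cols, identityPct = idpct)
}

dbAsSequences <- function(db) {
  if (is.data.frame(db)) stats::setNames(db$sequence, db$entry_id)
  else if (methods::is(db, "XStringSet"))
    stats::setNames(as.character(db), names(db))
  else unlist(db)
}

#' Rank database hits for a query
#'
#' Aligns the query against every database entry and returns the top
#' \code{n} hits sorted by Smith-Waterman score (descending), ties broken
#' by entry id (ascending) so the ranking is a stable total order.
#'
#' @param query query sequence (character string).
#' @param db a named character vector of sequences, an AAStringSet, or a
#'   sequence database data.frame from \code{\link{buildSequenceDb}}.
#' @param n maximum number of hits returned (default 20).
#' @param queryId identifier stored on the results.
#' @inheritParams smithWaterman
#' @return list of \linkS4class{AlignmentPair} in rank order.
#' @export
rankHits <- function(query, db, n = 20, matrix = "BLOSUM62", gapOpen = 11,
                     gapExtend = 1, queryId = "query") {
  stopifnot(n >= 1)
  seqs <- dbAsSequences(db)
  if (!length(seqs)) return(list())
  mat <- loadSubstitutionMatrix(matrix)
  pairs <- lapply(seq_along(seqs), function(i)
    smithWaterman(query, seqs[[i]], matrix = mat, gapOpen = gapOpen,
                  gapExtend = gapExtend, queryId = queryId,
                  hitId = names(seqs)[i]))
  scores <- vapply(pairs, alignmentScore, 0)
  ids <- vapply(pairs, function(p) p@hitId, "")
  ord <- order(-scores, ids)
  pairs[ord][seq_len(min(n, length(pairs)))]
}

parseSegments <- function(s) {
  parts <- strsplit(trimws(s), ",")[[1]]
  m <- do.call(rbind, lapply(parts, function(p) {
    se <- as.integer(strsplit(trimws(p), "-")[[1]])
    if (length(se) == 1) se <- c(se, se)
    se
  }))
  data.frame(start = m[, 1], end = m[, 2])
}

#' Read a domain-annotation table
#'
#' TSV with columns structure_id, chain_id, domain_id, segments (e.g.
#' "6-57,177-331"; 1-based inclusive intervals in the chain's sequence
#' coordinates) and optionally kind ("cath_like" or "pfam_like").
#'
#' @param x path or text of the TSV.
#' @return data.frame of annotations with parsed \code{segments} list-column.
#' @export
readDomainAnnotations <- function(x) {
  txt <- paste(asLines(x), collapse = "\n")
  df <- utils::read.delim(text = txt, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"kind" %in% names(df)) df$kind <- "cath_like"
  df$segments_parsed <- lapply(df$segments, parseSegments)
  df
}

#' Build the full-chain + domain sequence database
#'
#' One \code{full_chain} entry per polymer chain of every structure, plus
#' one \code{domain} entry per annotated domain. A split domain (segments
#' over several non-contiguous intervals) yields a single entry whose
#' sequence concatenates its segments in order, so split domains remain
#' findable by local search.
#'
#' @param structures list of \linkS4class{ProteinStructure} (or one).
#' @param annotations data.frame from \code{\link{readDomainAnnotations}},
#'   or NULL. Annotations naming unknown structures/chains, or segments
#'   outside the chain, are skipped with a warning.
#' @return data.frame with columns entry_id, parent_structure_id, chain_id,
#'   kind, sequence and a list-column \code{segments}.
#' @export
buildSequenceDb <- function(structures, annotations = NULL) {
  if (methods::is(structures, "ProteinStructure"))
    structures <- list(structures)
  entries <- list()
  seqOf <- list()
  for (s in structures) {
    for (ch in names(s@seqres)) {
      eid <- paste0(s@id, "_", ch)
      seqOf[[eid]] <- s@seqres[[ch]]
      entries[[length(entries) + 1L]] <- list(
        entry_id = eid, parent_structure_id = s@id, chain_id = ch,
        kind = "full_chain", sequence = s@seqres[[ch]],
        segments = data.frame(start = 1L, end = nchar(s@seqres[[ch]])))
    }
  }
  if (!is.null(annotations) && nrow(annotations)) {
    for (r in seq_len(nrow(annotations))) {
      eid <- paste0(annotations$structure_id[r], "_",
                    annotations$chain_id[r])
      segs <- if ("segments_parsed" %in% names(annotations))
        annotations$segments_parsed[[r]] else
        parseSegments(annotations$segments[r])
      if (is.null(seqOf[[eid]])) {
        warning("annotation ", annotations$domain_id[r],
                " references unknown chain ", eid, "; skipped")
        next
      }
      L <- nchar(seqOf[[eid]])
      if (any(segs$start < 1 | segs$end > L | segs$start > segs$end)) {
        warning("annotation ", annotations$domain_id[r],
                " has segments outside chain ", eid, "; skipped")
        next
      }
      seq <- paste(substring(seqOf[[eid]], segs$start, segs$end),
                   collapse = "")
      entries[[length(entries) + 1L]] <- list(
        entry_id = paste0(eid, ":", annotations$domain_id[r]),
        parent_structure_id = annotations$structure_id[r],
        chain_id = annotations$chain_id[r], kind = "domain",
        sequence = seq, segments = segs)
    }
  }
  out <- data.frame(
    entry_id = vapply(entries, `[[`, "", "entry_id"),
    parent_structure_id = vapply(entries, `[[`, "", "parent_structure_id"),
    chain_id = vapply(entries, `[[`, "", "chain_id"),
    kind = vapply(entries, `[[`, "", "kind"),
    sequence = vapply(entries, `[[`, "", "sequence"),
    stringsAsFactors = FALSE)
  out$segments <- lapply(entries, `[[`, "segments")
  out
}

#' Query-anchored multiple alignment
#'
#' Stacks pairwise alignments on the query: each row maps query positions to
#' hit positions using only that pair's aligned columns. Two hit residues
#' are equivalent iff they align to the same query position.
#'
#' @param pairs list of \linkS4class{AlignmentPair} sharing one query id.
#' @param queryLen query length; inferred from the pairs when NULL.
#' @return list with elements queryId, queryLen and \code{rows}, a named
#'   list (one per hit) of integer vectors of length queryLen giving the
#'   aligned hit position or NA at each query position.
#' @export
buildQueryAnchoredMSA <- function(pairs, queryLen = NULL) {
  if (!length(pairs)) stop("no alignment pairs given")
  qids <- unique(vapply(pairs, function(p) p@queryId, ""))
  if (length(qids) != 1)
    stop("all pairs must share the same query id; got: ",
         paste(qids, collapse = ", "))
  if (is.null(queryLen))
    queryLen <- max(vapply(pairs, function(p) {
      q <- p@columns[, "qpos"]
      if (all(is.na(q))) 0L else max(q, na.rm = TRUE)
    }, 0L))
  rows <- list()
  for (p in pairs) {
    v <- rep(NA_integer_, queryLen)
    cm <- p@columns
    both <- !is.na(cm[, 1]) & !is.na(cm[, 2])
    v[cm[both, 1]] <- cm[both, 2]
    nm <- p@hitId
    while (nm %in% names(rows)) nm <- paste0(nm, "+")
    rows[[nm]] <- v
  }
  list(queryId = qids, queryLen = as.integer(queryLen), rows = rows)
}
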