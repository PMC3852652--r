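# Partition the query sequence into predicted domains by transferring
# homolog domain annotations through the pairwise alignments, in hit-rank
# order, with a strict no-overlap rule; leftover runs are resolved by the
# 100-residue unknown-domain rule and the midpoint linker split.

#' Map a homolog domain onto the query
#'
#' For each annotation segment (in hit-sequence coordinates) takes the
#' minimal query interval covering every query position aligned to that
#' segment. Segments mapping fewer than \code{minMapped} query residues are
#' dropped as noise; NULL is returned when all segments drop.
#'
#' @param segments data.frame(start, end) of the domain's hit-coordinate
#'   segments (1-based inclusive).
#' @param pair the \linkS4class{AlignmentPair} of the query against the
#'   domain's source sequence.
#' @param minMapped minimum mapped query residues per segment (default 20).
#' @return data.frame(start, end) of query segments, or NULL.
#' @export
mapDomainToQuery <- function(segments, pair, minMapped = 20) {
  cm <- pair@columns
  both <- !is.na(cm[, 1]) & !is.na(cm[, 2])
  q <- cm[both, 1]; h <- cm[both, 2]
  out <- NULL
  for (r in seq_len(nrow(segments))) {
    inSeg <- h >= segments$start[r] & h <= segments$end[r]
    if (sum(inSeg) < minMapped) next
    out <- rbind(out, data.frame(start = min(q[inSeg]), end = max(q[inSeg])))
  }
  out
}

#' Partition the query into predicted domains
#'
#' Walks the ranked homologs from most to least similar, transferring each
#' of their annotated domains to the query and accepting a domain only if
#' none of its mapped segments overlaps a previously assigned residue.
#' Afterwards any unassigned run of more than \code{unknownDomainMin}
#' residues becomes a domain of unknown type; each remaining internal run
#' (a linker) is split at its midpoint with the halves merged into the
#' flanking domains (the extra residue of an odd linker goes to the
#' N-terminal side); terminal runs merge into their single neighbour. The
#' result always covers residues 1..queryLen exactly once.
#'
#' @param queryLen query length in residues.
#' @param ranked list, in hit-rank order, of elements
#'   \code{list(pair = AlignmentPair, annotations = list of
#'   list(domain_id =, kind =, segments = data.frame(start, end)))}.
#' @param unknownDomainMin run length above which an unassigned run becomes
#'   an unknown-type domain (default 100).
#' @param minMapped passed to \code{\link{mapDomainToQuery}}.
#' @return data.frame with columns label, kind, start, end, source; several
#'   rows may share a label (split domains).
#' @export
partitionQuery <- function(queryLen, ranked = list(), unknownDomainMin = 100,
                           minMapped = 20) {
  queryLen <- as.integer(queryLen)
  if (is.na(queryLen) || queryLen < 1) stop("queryLen must be >= 1")
  owner <- integer(queryLen)         # 0 = unassigned
  doms <- list()                     # idx -> list(label, kind, source)

  for (entry in ranked) {
    for (ann in entry$annotations) {
      segs <- mapDomainToQuery(ann$segments, entry$pair,
                               minMapped = minMapped)
      if (is.null(segs)) next
      pos <- unlist(mapply(seq, segs$start, segs$end, SIMPLIFY = FALSE))
      if (any(owner[pos] != 0L)) next          # strict no-overlap rule
      doms[[length(doms) + 1L]] <- list(
        label = ann$domain_id,
        kind = if (is.null(ann$kind)) "cath_like" else ann$kind,
        source = entry$pair@hitId)
      owner[pos] <- length(doms)
    }
  }

  # unassigned runs longer than the threshold become unknown-type domains
  runs <- trueRuns(owner == 0L)
  uidx <- 0L
  for (r in seq_len(nrow(runs))) {
    if (runs$end[r] - runs$start[r] + 1L > unknownDomainMin) {
      uidx <- uidx + 1L
      doms[[length(doms) + 1L]] <- list(label = paste0("U", uidx),
                                        kind = "unknown", source = NA)
      owner[runs$start[r]:runs$end[r]] <- length(doms)
    }
  }

  if (!length(doms)) {               # short query, nothing transferred
    doms[[1]] <- list(label = "U1", kind = "unknown", source = NA)
    owner[] <- 1L
  }

  # remaining runs: internal linkers split at midpoint, terminal runs merged
  runs <- trueRuns(owner == 0L)
  for (r in seq_len(nrow(runs))) {
    a <- runs$start[r]; b <- runs$end[r]
    left <- if (a > 1L) owner[a - 1L] else 0L
    right <- if (b < queryLen) owner[b + 1L] else 0L
    if (left && right) {
      L <- b - a + 1L
      nLeft <- ceiling(L / 2)        # odd linker: extra residue N-terminal
      owner[a:(a + nLeft - 1L)] <- left
      if (nLeft < L) owner[(a + nLeft):b] <- right
    } else if (left) owner[a:b] <- left
    else if (right) owner[a:b] <- right
  }

  out <- NULL
  r <- rle(owner)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    d <- doms[[r$values[k]]]
    out <- rbind(out, data.frame(label = d$label, kind = d$kind,
                                 start = starts[k], end = ends[k],
                                 source = if (is.null(d$source) ||
                                              is.na(d$source)) NA_character_
                                          else d$source,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
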