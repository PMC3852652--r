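# Small-molecule machinery: maximum common connected induced subgraph
# under element + bond-order matching, atom-count Tanimoto similarity,
# complete-linkage clustering at the 0.4 cutoff, and basic properties.

orderMatrix <- function(mol) {
  n <- length(mol@atoms)
  M <- matrix(0L, n, n)
  b <- mol@bonds
  if (nrow(b)) {
    M[cbind(b$i, b$j)] <- b$order
    M[cbind(b$j, b$i)] <- b$order
  }
  M
}

molToIgraph <- function(mol, elementLevels) {
  g <- igraph::make_empty_graph(length(mol@atoms), directed = FALSE)
  igraph::V(g)$color <- match(toupper(mol@atoms), elementLevels)
  if (nrow(mol@bonds)) {
    g <- igraph::add_edges(g, as.vector(t(mol@bonds[, c("i", "j")])))
    igraph::E(g)$color <- mol@bonds$order
  }
  g
}

#' Exact molecular-graph identity
#'
#' Element- and bond-order-preserving graph isomorphism, used as the
#' duplicate key when merging compound sources.
#'
#' @param a,b \linkS4class{MoleculeGraph}s.
#' @return TRUE when the two molecules are the same graph.
#' @export
graphsIsomorphic <- function(a, b) {
  if (length(a@atoms) != length(b@atoms) ||
      nrow(a@bonds) != nrow(b@bonds)) return(FALSE)
  ea <- sort(toupper(a@atoms)); eb <- sort(toupper(b@atoms))
  if (!identical(ea, eb)) return(FALSE)
  if (!identical(sort(a@bonds$order), sort(b@bonds$order))) return(FALSE)
  lev <- unique(c(ea, eb))
  igraph::isomorphic(molToIgraph(a, lev), molToIgraph(b, lev),
                     method = "vf2")
}

#' Maximum common subgraph of two molecules
#'
#' Branch-and-bound search for the maximum common *connected induced*
#' subgraph under element and bond-order matching (aromatic is its own
#' order; charge ignored). Pairs larger than \code{maxExact} heavy atoms,
#' or searches exceeding the node budget, fall back to the best mapping
#' found so far and are flagged non-exact.
#'
#' @param a,b \linkS4class{MoleculeGraph}s.
#' @param maxExact size limit for the exhaustive search (default 60).
#' @param nodeBudget search-tree node budget for the time-bounded fallback.
#' @return list with \code{size} (atom count of the common subgraph),
#'   \code{mapping} (2-column matrix of matched atom indices in a and b)
#'   and \code{exact} (FALSE when the budget was hit).
#' @export
mcs <- function(a, b, maxExact = 60, nodeBudget = 2e5) {
  na <- length(a@atoms); nb <- length(b@atoms)
  if (!na || !nb)
    return(list(size = 0L, mapping = matrix(integer(), 0, 2), exact = TRUE))
  exactMode <- max(na, nb) <= maxExact
  budget <- if (exactMode) Inf else nodeBudget
  A <- orderMatrix(a); B <- orderMatrix(b)
  ea <- toupper(a@atoms); eb <- toupper(b@atoms)

  st <- new.env()
  st$bestSize <- 0L
  st$bestMap <- matrix(integer(), 0, 2)
  st$nodes <- 0L
  st$truncated <- FALSE
  cap <- min(na, nb)

  extend <- function(mapA, mapB, seed) {
    st$nodes <- st$nodes + 1L
    if (st$nodes > budget) { st$truncated <- TRUE; return(invisible()) }
    k <- length(mapA)
    if (k > st$bestSize) {
      st$bestSize <- k
      st$bestMap <- cbind(mapA, mapB)
    }
    if (k + min(na - k, nb - k) <= st$bestSize) return(invisible())
    # candidate a-vertices: unmapped, >= seed, adjacent to the mapped set
    nbrs <- which(rowSums(A[, mapA, drop = FALSE] > 0) > 0)
    cand <- setdiff(nbrs[nbrs >= seed], mapA)
    for (u in cand) {
      for (v in setdiff(which(eb == ea[u]), mapB)) {
        if (all(A[u, mapA] == B[v, mapB]))
          extend(c(mapA, u), c(mapB, v), seed)
        if (st$truncated) return(invisible())
      }
    }
    invisible()
  }

  for (i in seq_len(na)) {
    if (st$bestSize >= cap || st$truncated) break
    # seed i is the smallest a-vertex of any mapping explored from it
    if (na - i + 1 <= st$bestSize) break
    for (j in which(eb == ea[i])) {
      extend(i, j, i)
      if (st$bestSize >= cap || st$truncated) break
    }
  }
  colnames(st$bestMap) <- c("a", "b")
  list(size = st$bestSize, mapping = st$bestMap,
       exact = exactMode && !st$truncated)
}

#' Maximum-common-subgraph Tanimoto similarity
#'
#' value = |MCS| / (|a| + |b| - |MCS|) over heavy atoms; 1 iff the two
#' (connected) graphs are isomorphic, 0 iff no atom can be matched.
#'
#' @inheritParams mcs
#' @return list with \code{value} in [0, 1], \code{mcsSize} and
#'   \code{exact}.
#' @export
molSimilarity <- function(a, b, maxExact = 60, nodeBudget = 2e5) {
  m <- mcs(a, b, maxExact = maxExact, nodeBudget = nodeBudget)
  na <- length(a@atoms); nb <- length(b@atoms)
  denom <- na + nb - m$size
  list(value = if (denom > 0) m$size / denom else 0,
       mcsSize = m$size, exact = m$exact)
}

#' All-by-all similarity matrix
#'
#' @param mols list of \linkS4class{MoleculeGraph}.
#' @param ids molecule identifiers (default taken from the graphs).
#' @inheritParams mcs
#' @return symmetric numeric matrix of Tanimoto similarities.
#' @export
similarityMatrix <- function(mols, ids = NULL, maxExact = 60,
                             nodeBudget = 2e5) {
  n <- length(mols)
  if (is.null(ids))
    ids <- vapply(seq_len(n), function(i) {
      id <- moleculeId(mols[[i]])
      if (is.na(id)) paste0("mol", i) else id
    }, "")
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      S[i, j] <- S[j, i] <- molSimilarity(mols[[i]], mols[[j]],
                                          maxExact, nodeBudget)$value
  S
}

#' Complete-linkage clustering of molecules
#'
#' Agglomerative clustering in which two clusters merge only while every
#' cross-pair similarity is at least \code{cutoff}, i.e. the similarity
#' between the most distant members of any emitted cluster is >= cutoff.
#' At each step the pair with the highest complete-linkage similarity is
#' merged; ties are broken by the lexicographically smallest sorted member
#' ids, making the clustering deterministic.
#'
#' @param mols list of \linkS4class{MoleculeGraph}; may be NULL when
#'   \code{similarities} is given.
#' @param cutoff minimum intra-cluster pairwise similarity (default 0.4).
#' @param similarities optional precomputed symmetric similarity matrix
#'   with dimnames as molecule ids.
#' @return data.frame with columns \code{id} and \code{cluster} (labels
#'   "C1", "C2", ... ordered by each cluster's smallest member id); the
#'   list of member-id vectors is attached as attribute \code{"clusters"}.
#' @export
clusterMolecules <- function(mols = NULL, cutoff = 0.4,
                             similarities = NULL) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (is.null(similarities)) {
    if (!length(mols))
      return(structure(data.frame(id = character(), cluster = character()),
                       clusters = list()))
    similarities <- similarityMatrix(mols)
  }
  S <- as.matrix(similarities)
  n <- nrow(S)
  ids <- rownames(S)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_len(n))
  clusters <- as.list(seq_len(n))       # member indices
  repeat {
    if (length(clusters) < 2) break
    bestSim <- -Inf; bestPair <- NULL; bestKey <- NULL
    for (p in 1:(length(clusters) - 1)) for (q in (p + 1):length(clusters)) {
      cl <- min(S[clusters[[p]], clusters[[q]]])
      if (cl < cutoff) next
      key <- paste(sort(ids[c(clusters[[p]], clusters[[q]])]),
                   collapse = "\r")
      if (cl > bestSim || (cl == bestSim && key < bestKey)) {
        bestSim <- cl; bestPair <- c(p, q); bestKey <- key
      }
    }
    if (is.null(bestPair)) break
    clusters[[bestPair[1]]] <- c(clusters[[bestPair[1]]],
                                 clusters[[bestPair[2]]])
    clusters[[bestPair[2]]] <- NULL
  }
  minId <- vapply(clusters, function(m) min(ids[m]), "")
  clusters <- clusters[order(minId)]
  members <- lapply(clusters, function(m) sort(ids[m]))
  names(members) <- paste0("C", seq_along(members))
  df <- data.frame(id = unlist(members),
                   cluster = rep(names(members),
                                 lengths(members)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df[order(match(df$id, ids)), , drop = FALSE],
            clusters = members)
}

implicitHCount <- function(mol) {
  el <- toupper(mol@atoms)
  bondSum <- numeric(length(el))
  if (nrow(mol@bonds)) {
    ord <- ifelse(mol@bonds$order == 4L, 1.5, mol@bonds$order)
    for (r in seq_len(nrow(mol@bonds))) {
      bondSum[mol@bonds$i[r]] <- bondSum[mol@bonds$i[r]] + ord[r]
      bondSum[mol@bonds$j[r]] <- bondSum[mol@bonds$j[r]] + ord[r]
    }
  }
  val <- DEFAULT_VALENCE[el]
  val[is.na(val)] <- 0
  pmax(0, floor(val - bondSum))
}

#' Basic molecular properties
#'
#' Molecular weight is summed over the heavy atoms plus hydrogens implicit
#' by standard valences (aromatic bonds count 1.5). logP and polar surface
#' area are delegated to OpenBabel (via \pkg{ChemmineOB}) when the package
#' is installed and the molecule carries a SMILES; otherwise NA.
#'
#' @param mol a \linkS4class{MoleculeGraph}.
#' @return list with mol_weight (Da), heavy_atoms, n_implicit_h, logP and
#'   polar_surface_area (Angstrom^2).
#' @export
molProperties <- function(mol) {
  el <- toupper(mol@atoms)
  unknown <- setdiff(el, names(ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  nh <- implicitHCount(mol)
  mw <- sum(ATOMIC_MASS[el]) + sum(nh) * ATOMIC_MASS[["H"]]
  logP <- NA_real_; psa <- NA_real_
  if (nzchar(mol@smiles) && requireNamespace("ChemmineOB", quietly = TRUE)) {
    props <- tryCatch(suppressWarnings({
      sdf <- ChemmineR::smiles2sdf(stats::setNames(mol@smiles, "m"))
      ChemmineR::propOB(sdf)
    }), error = function(e) NULL)
    if (!is.null(props)) {
      logP <- as.numeric(props$logP[1])
      psa <- as.numeric(props$TPSA[1])
    }
  }
  list(mol_weight = mw, heavy_atoms = length(mol@atoms),
       n_implicit_h = sum(nh), logP = logP, polar_surface_area = psa)
}

#' Derive a ligand's molecular graph from its coordinates
#'
#' HETATM groups carry no connection table, so bonds are inferred from
#' interatomic distances against single-bond covalent radii (pairs closer
#' than r1 + r2 + 0.45 Angstrom are bonded, order 1). Isolated metals and
#' ions yield single-atom graphs.
#'
#' @param ligand a \linkS4class{LigandInstance}.
#' @param tol bond-detection slack in Angstrom.
#' @return a \linkS4class{MoleculeGraph}.
#' @export
ligandMolecule <- function(ligand, tol = 0.45) {
  if (!is.null(ligand@molecule)) return(ligand@molecule)
  at <- ligand@atoms
  el <- toupper(at$element)
  r <- COVALENT_RADIUS[el]
  r[is.na(r)] <- 1.5
  n <- nrow(at)
  bonds <- NULL
  if (n > 1) {
    d <- crossDist(at[, c("x", "y", "z")], at[, c("x", "y", "z")])
    lim <- outer(r, r, "+") + tol
    hit <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit))
      bonds <- data.frame(i = hit[, 1], j = hit[, 2], order = 1L)
  }
  MoleculeGraph(el, bonds,
                id = paste(ligand@structureId, ligand@hetCode,
                           ligand@chainId, ligand@seqNum, sep = ":"))
}
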