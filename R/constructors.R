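#' Build a molecule graph
#'
#' @param atoms character vector of element symbols (heavy atoms only).
#' @param bonds data.frame or matrix with columns i, j, order (order 4 =
#'   aromatic). Edges are normalised to i < j.
#' @param id molecule identifier.
#' @param smiles optional SMILES kept for descriptor calculation.
#' @return a \linkS4class{MoleculeGraph}.
#' @examples
#' benzene <- MoleculeGraph(rep("C", 6),
#'   data.frame(i = 1:6, j = c(2:6, 1), order = 4), id = "benzene")
#' heavyAtomCount(benzene)
#' @export
MoleculeGraph <- function(atoms, bonds = NULL, id = NA_character_,
                          smiles = "") {
  if (is.null(bonds) || !NROW(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  bonds <- as.data.frame(bonds)
  names(bonds)[1:3] <- c("i", "j", "order")
  swap <- bonds$i > bonds$j
  if (any(swap)) {
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  }
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  new("MoleculeGraph", id = as.character(id), atoms = as.character(atoms),
      bonds = bonds, smiles = smiles)
}

#' Interaction scoring scheme constructor
#'
#' @param hbIdentical,hbSimilar,hbOther,hbGap hydrogen-bond weights
#'   (defaults 3, 2, 1, -1).
#' @param nbIdentical,nbSimilar,nbOther,nbGap nonbonded-contact weights
#'   (defaults 2, 1, 0, -1).
#' @param hbondMaxDist,contactMaxDist distance thresholds in Angstrom
#'   (defaults 3.35 and 3.9).
#' @return a \linkS4class{ScoringScheme}.
#' @export
ScoringScheme <- function(hbIdentical = 3, hbSimilar = 2, hbOther = 1,
                          hbGap = -1, nbIdentical = 2, nbSimilar = 1,
                          nbOther = 0, nbGap = -1, hbondMaxDist = 3.35,
                          contactMaxDist = 3.9) {
  new("ScoringScheme", hbIdentical = hbIdentical, hbSimilar = hbSimilar,
      hbOther = hbOther, hbGap = hbGap, nbIdentical = nbIdentical,
      nbSimilar = nbSimilar, nbOther = nbOther, nbGap = nbGap,
      hbondMaxDist = hbondMaxDist, contactMaxDist = contactMaxDist)
}

#' Pipeline configuration constructor
#'
#' Defaults are the workflow's published constants: top 20 hits, 12 Angstrom
#' RMSD cutoff, 0.4 similarity cutoff, 100-residue unknown-domain rule.
#'
#' @param topN hits retained by the sequence search.
#' @param rmsdCutoff superposition RMSD convergence cutoff (Angstrom).
#' @param clusterCutoff minimum intra-cluster similarity.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param gapOpen,gapExtend affine gap penalties.
#' @param matrix substitution matrix name.
#' @param unknownDomainMin,minMappedDomain,minQueryLen residue-count rules.
#' @param seed seed for stochastic fixture paths.
#' @return a \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(topN = 20, rmsdCutoff = 12, clusterCutoff = 0.4,
                           scheme = ScoringScheme(), gapOpen = 11,
                           gapExtend = 1, matrix = "BLOSUM62",
                           unknownDomainMin = 100, minMappedDomain = 20,
                           minQueryLen = 30, seed = 1) {
  new("PipelineConfig", topN = as.integer(topN), rmsdCutoff = rmsdCutoff,
      clusterCutoff = clusterCutoff, scheme = scheme, gapOpen = gapOpen,
      gapExtend = gapExtend, matrix = matrix,
      unknownDomainMin = as.integer(unknownDomainMin),
      minMappedDomain = as.integer(minMappedDomain),
      minQueryLen = as.integer(minQueryLen), seed = as.integer(seed))
}
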