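#' @import methods
NULL

PT_ELEMENTS <- c(
  "H","HE","LI","BE","B","C","N","O","F","NE","NA","MG","AL","SI","P","S",
  "CL","AR","K","CA","SC","TI","V","CR","MN","FE","CO","NI","CU","ZN","GA",
  "GE","AS","SE","BR","KR","RB","SR","Y","ZR","NB","MO","TC","RU","RH","PD",
  "AG","CD","IN","SN","SB","TE","I","XE","CS","BA","LA","CE","PR","ND","PM",
  "SM","EU","GD","TB","DY","HO","ER","TM","YB","LU","HF","TA","W","RE","OS",
  "IR","PT","AU","HG","TL","PB","BI","PO","AT","RN","U")

#' Small-molecule graph
#'
#' An element-labelled, bond-typed graph over heavy atoms only. Bond order is
#' coded 1, 2, 3 or 4 (aromatic), the SDF V2000 convention. Hydrogens are
#' implicit and inferred by valence where a property needs them.
#'
#' @slot id molecule identifier.
#' @slot atoms character vector of element symbols, one per heavy atom.
#' @slot bonds data.frame with integer columns \code{i}, \code{j},
#'   \code{order}; \code{i < j}, no self-loops, no duplicate edges.
#' @slot smiles optional SMILES string carried along for descriptor
#'   calculation; empty when unknown.
#' @exportClass MoleculeGraph
setClass("MoleculeGraph",
  representation(id = "character", atoms = "character", bonds = "data.frame",
                 smiles = "character"),
  prototype(id = NA_character_, atoms = character(),
            bonds = data.frame(i = integer(), j = integer(),
                               order = integer()),
            smiles = ""))

setValidity("MoleculeGraph", function(object) {
  b <- object@bonds
  n <- length(object@atoms)
  msg <- character()
  if (!all(c("i", "j", "order") %in% names(b)))
    msg <- c(msg, "bonds must have columns i, j, order")
  else if (nrow(b)) {
    if (any(b$i < 1 | b$j < 1 | b$i > n | b$j > n))
      msg <- c(msg, "bond endpoints out of range")
    if (any(b$i == b$j)) msg <- c(msg, "self-loops not allowed")
    if (any(b$i > b$j)) msg <- c(msg, "bonds must be stored with i < j")
    if (anyDuplicated(b[, c("i", "j")])) msg <- c(msg, "duplicate bonds")
    if (!all(b$order %in% 1:4)) msg <- c(msg, "bond order must be 1..4")
  }
  if (n && !all(toupper(object@atoms) %in% PT_ELEMENTS))
    msg <- c(msg, "unknown element symbol")
  if (length(msg)) msg else TRUE
})

#' One ligand occurrence in a structure
#'
#' A maximal group of HETATM records sharing het code, chain and residue
#' number. Waters (HOH) are never represented as ligand instances; single
#' metals and ions are.
#'
#' @slot hetCode chemical-component identifier, e.g. "TMP".
#' @slot chainId one-character chain label.
#' @slot seqNum author residue number of the het group.
#' @slot structureId id of the parent structure.
#' @slot atoms data.frame with columns serial, name, element, x, y, z.
#' @slot molecule a \linkS4class{MoleculeGraph} or NULL when connectivity has
#'   not been derived yet.
#' @exportClass LigandInstance
setClass("LigandInstance",
  representation(hetCode = "character", chainId = "character",
                 seqNum = "integer", structureId = "character",
                 atoms = "data.frame", molecule = "ANY"),
  prototype(molecule = NULL))

setValidity("LigandInstance", function(object) {
  msg <- character()
  if (!nzchar(object@hetCode)) msg <- c(msg, "het code must be non-empty")
  if (!nrow(object@atoms)) msg <- c(msg, "ligand must have at least one atom")
  need <- c("serial", "name", "element", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns serial, name, element, x, y, z")
  else if (!all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "atom coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Parsed protein structure
#'
#' Polymer chains (ATOM records, author numbering, insertion codes honoured)
#' plus the non-water HETATM ligand instances. Per-chain one-letter sequences
#' come from SEQRES when present, else are derived from the ATOM residues.
#'
#' @slot id structure identifier (e.g. a 4-character PDB code).
#' @slot atoms polymer atom table: serial, name, element, resid (3-letter),
#'   chain, resno, insert, x, y, z.
#' @slot seqres named character vector, one-letter sequence per chain.
#' @slot ligands list of \linkS4class{LigandInstance}.
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame",
                 seqres = "character", ligands = "list"))

setValidity("ProteinStructure", function(object) {
  msg <- character()
  if (!length(object@seqres) || any(nchar(object@seqres) < 1))
    msg <- c(msg, "every chain sequence must have length >= 1")
  keys <- unique(object@atoms[, c("chain", "resno", "insert")])
  if (anyDuplicated(keys))
    msg <- c(msg, "(chain, resno, insert) must be unique in the polymer")
  bad <- vapply(object@ligands, function(l)
    !is(l, "LigandInstance") || !identical(l@structureId, object@id),
    logical(1))
  if (any(bad))
    msg <- c(msg, "all ligands must reference this structure's id")
  if (length(msg)) msg else TRUE
})

#' Pairwise local alignment
#'
#' Optimal Smith-Waterman local alignment of a query against a database
#' entry under an affine gap model.
#'
#' @slot queryId,hitId sequence identifiers.
#' @slot score alignment score in substitution-matrix units.
#' @slot columns integer matrix with columns \code{qpos}, \code{hpos}; one
#'   row per alignment column, NA marking a gap on that side. Non-NA values
#'   strictly increase down each column.
#' @slot identityPct 100 x identical columns / aligned (gap-free) columns.
#' @exportClass AlignmentPair
setClass("AlignmentPair",
  representation(queryId = "character", hitId = "character",
                 score = "numeric", columns = "matrix",
                 identityPct = "numeric"))

setValidity("AlignmentPair", function(object) {
  msg <- character()
  cm <- object@columns
  if (ncol(cm) != 2L || !identical(colnames(cm), c("qpos", "hpos")))
    msg <- c(msg, "columns must be a 2-column matrix (qpos, hpos)")
  else {
    for (k in 1:2) {
      v <- cm[, k][!is.na(cm[, k])]
      if (length(v) > 1 && any(diff(v) <= 0))
        msg <- c(msg, "positions must strictly increase on each side")
    }
  }
  if (!is.na(object@identityPct) &&
      (object@identityPct < 0 || object@identityPct > 100))
    msg <- c(msg, "identityPct must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Rigid-body superposition result
#'
#' @slot rotation 3x3 proper rotation applied to the mobile coordinates.
#' @slot translation length-3 translation (Angstrom).
#' @slot rmsd RMSD over the retained equivalences after the transform.
#' @slot retained data.frame of residue equivalences used in the final fit.
#' @slot removed data.frame of residue equivalences discarded by the
#'   iterative trimming.
#' @slot converged TRUE when the RMSD cutoff was met before running out of
#'   equivalences.
#' @slot iterations number of fit iterations performed.
#' @exportClass Superposition
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", retained = "data.frame",
                 removed = "data.frame", converged = "logical",
                 iterations = "integer"),
  prototype(removed = data.frame(), converged = TRUE, iterations = 1L))

setValidity("Superposition", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3x3")
  else if (abs(det(R) - 1) > 1e-6)
    msg <- c(msg, "rotation must be proper (det = +1)")
  if (length(object@translation) != 3)
    msg <- c(msg, "translation must have length 3")
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (!nrow(object@retained)) msg <- c(msg, "retained set must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Conservation-weighted interaction scoring scheme
#'
#' Weights for hydrogen bonds and nonbonded contacts by the conservation
#' class of the contacted protein residue relative to the query: 3/2/1/-1
#' for hydrogen bonds to identical/similar/other residues or a gap, and
#' 2/1/0/-1 for nonbonded contacts. Interactions are geometric: polar
#' (N/O/S) heavy-atom pairs within \code{hbondMaxDist} count as hydrogen
#' bonds, any heavy-atom pair within \code{contactMaxDist} as a contact.
#'
#' @slot hbIdentical,hbSimilar,hbOther,hbGap hydrogen-bond weights.
#' @slot nbIdentical,nbSimilar,nbOther,nbGap nonbonded-contact weights.
#' @slot hbondMaxDist hydrogen-bond distance threshold (Angstrom).
#' @slot contactMaxDist contact distance threshold (Angstrom).
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(hbIdentical = "numeric", hbSimilar = "numeric",
                 hbOther = "numeric", hbGap = "numeric",
                 nbIdentical = "numeric", nbSimilar = "numeric",
                 nbOther = "numeric", nbGap = "numeric",
                 hbondMaxDist = "numeric", contactMaxDist = "numeric"),
  prototype(hbIdentical = 3, hbSimilar = 2, hbOther = 1, hbGap = -1,
            nbIdentical = 2, nbSimilar = 1, nbOther = 0, nbGap = -1,
            hbondMaxDist = 3.35, contactMaxDist = 3.9))

setValidity("ScoringScheme", function(object) {
  ok <- object@hbIdentical > object@hbSimilar &&
    object@hbSimilar > object@hbOther && object@hbOther > object@hbGap &&
    object@nbIdentical > object@nbSimilar &&
    object@nbSimilar > object@nbOther && object@nbOther > object@nbGap
  if (!ok) return("weights must strictly decrease identical > similar > other > gap")
  if (object@hbondMaxDist <= 0 || object@contactMaxDist <= 0)
    return("distance thresholds must be positive")
  TRUE
})

#' Ligand interaction score
#'
#' The achieved score sums the scheme weights over the ligand's hydrogen
#' bonds and (residue-deduplicated) contacts by conservation class; the
#' maximum is the ceiling the same interactions would reach if every
#' contacted residue were identical to the query's.
#'
#' @slot ligandKey named character identifying the scored ligand instance
#'   (structure_id, het_code, chain_id, seq_num).
#' @slot achieved,maximum score points.
#' @slot records per-interaction breakdown: kind, chain, resno, insert,
#'   resType, ligandAtom, distance, conservation, weight.
#' @exportClass LigandScore
setClass("LigandScore",
  representation(ligandKey = "character", achieved = "numeric",
                 maximum = "numeric", records = "data.frame"))

setValidity("LigandScore", function(object) {
  msg <- character()
  if (object@maximum < 0) msg <- c(msg, "maximum must be >= 0")
  if (object@achieved > object@maximum + 1e-9)
    msg <- c(msg, "achieved must not exceed maximum")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Houses the workflow constants: top-20 homolog hits, 12 Angstrom
#' superposition RMSD cutoff, 0.4 clustering cutoff, the 100-residue
#' unknown-domain rule and the 20-residue minimum mapped domain fragment,
#' plus alignment parameters (BLOSUM62, gap open 11, extend 1).
#'
#' @slot topN number of sequence hits retained.
#' @slot rmsdCutoff superposition convergence cutoff (Angstrom).
#' @slot clusterCutoff minimum intra-cluster pairwise similarity.
#' @slot scheme a \linkS4class{ScoringScheme}.
#' @slot gapOpen,gapExtend affine gap penalties (positive).
#' @slot matrix substitution matrix name (e.g. "BLOSUM62").
#' @slot unknownDomainMin unassigned run length above which a run becomes an
#'   unknown-type domain.
#' @slot minMappedDomain minimum mapped query residues for a transferred
#'   domain segment.
#' @slot minQueryLen minimum accepted query length.
#' @slot seed seed for any stochastic fixture paths.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(topN = "integer", rmsdCutoff = "numeric",
                 clusterCutoff = "numeric", scheme = "ScoringScheme",
                 gapOpen = "numeric", gapExtend = "numeric",
                 matrix = "character", unknownDomainMin = "integer",
                 minMappedDomain = "integer", minQueryLen = "integer",
                 seed = "integer"),
  prototype(topN = 20L, rmsdCutoff = 12, clusterCutoff = 0.4,
            gapOpen = 11, gapExtend = 1, matrix = "BLOSUM62",
            unknownDomainMin = 100L, minMappedDomain = 20L,
            minQueryLen = 30L, seed = 1L))

setValidity("PipelineConfig", function(object) {
  vals <- c(object@topN, object@rmsdCutoff, object@clusterCutoff,
            object@gapOpen, object@gapExtend, object@unknownDomainMin,
            object@minMappedDomain, object@minQueryLen)
  if (any(vals <= 0)) return("all thresholds must be positive")
  if (object@clusterCutoff > 1) return("clusterCutoff must be <= 1")
  TRUE
})

#' Ranked candidate-ligand result
#'
#' Clusters of candidate ligands with cluster-level and within-cluster
#' ordering. \code{table} holds one row per candidate in ranked order with
#' the columns written to the results TSV; \code{molecules} keeps the
#' corresponding \linkS4class{MoleculeGraph}s for downstream evaluation.
#'
#' @slot table ranked candidate table.
#' @slot molecules list of MoleculeGraph, parallel to \code{table} rows.
#' @slot queryId query identifier.
#' @slot log per-stage provenance messages.
#' @exportClass RankedResult
setClass("RankedResult",
  representation(table = "data.frame", molecules = "list",
                 queryId = "character", log = "character"),
  prototype(queryId = NA_character_, log = character()))
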