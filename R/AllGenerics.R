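#' @rdname ProteinStructure-class
#' @param object,x an object.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("chainSequences", function(x) standardGeneric("chainSequences"))

#' @rdname LigandInstance-class
#' @export
setGeneric("hetCode", function(x) standardGeneric("hetCode"))

#' @rdname LigandInstance-class
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))

#' @rdname MoleculeGraph-class
#' @export
setGeneric("heavyAtomCount", function(x) standardGeneric("heavyAtomCount"))

#' @rdname MoleculeGraph-class
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))

#' @rdname AlignmentPair-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname AlignmentPair-class
#' @export
setGeneric("identityPct", function(x) standardGeneric("identityPct"))

#' @rdname AlignmentPair-class
#' @export
setGeneric("alignedColumns", function(x) standardGeneric("alignedColumns"))

#' @rdname LigandScore-class
#' @export
setGeneric("achievedScore", function(x) standardGeneric("achievedScore"))

#' @rdname LigandScore-class
#' @export
setGeneric("maximumScore", function(x) standardGeneric("maximumScore"))

#' @rdname RankedResult-class
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

setMethod("structureId", "ProteinStructure", function(x) x@id)
setMethod("ligands", "ProteinStructure", function(x) x@ligands)
setMethod("chainSequences", "ProteinStructure", function(x) x@seqres)
setMethod("hetCode", "LigandInstance", function(x) x@hetCode)
setMethod("ligandAtoms", "LigandInstance", function(x) x@atoms)
setMethod("heavyAtomCount", "MoleculeGraph", function(x) length(x@atoms))
setMethod("moleculeId", "MoleculeGraph", function(x) x@id)
setMethod("alignmentScore", "AlignmentPair", function(x) x@score)
setMethod("identityPct", "AlignmentPair", function(x) x@identityPct)
setMethod("alignedColumns", "AlignmentPair", function(x) x@columns)
setMethod("achievedScore", "LigandScore", function(x) x@achieved)
setMethod("maximumScore", "LigandScore", function(x) x@maximum)
setMethod("resultTable", "RankedResult", function(x) x@table)

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure", object@id, "\n",
      " chains: ", paste0(names(object@seqres), " (", nchar(object@seqres),
                          " aa)", collapse = ", "), "\n",
      " polymer atoms: ", nrow(object@atoms),
      "; ligands: ", length(object@ligands), "\n", sep = "")
})

setMethod("show", "LigandInstance", function(object) {
  cat("LigandInstance ", object@hetCode, " [", object@structureId, " ",
      object@chainId, " ", object@seqNum, "], ", nrow(object@atoms),
      " atoms\n", sep = "")
})

setMethod("show", "MoleculeGraph", function(object) {
  cat("MoleculeGraph ", object@id, ": ", length(object@atoms),
      " heavy atoms, ", nrow(object@bonds), " bonds\n", sep = "")
})

setMethod("show", "AlignmentPair", function(object) {
  cat("AlignmentPair ", object@queryId, " vs ", object@hitId,
      ": score ", object@score, ", identity ",
      formatC(object@identityPct, format = "f", digits = 1), "%, ",
      nrow(object@columns), " columns\n", sep = "")
})

setMethod("show", "Superposition", function(object) {
  cat("Superposition: rmsd ", formatC(object@rmsd, format = "f", digits = 3),
      " A over ", nrow(object@retained), " residue pairs (",
      nrow(object@removed), " removed, ", object@iterations,
      " iterations, ", if (object@converged) "converged" else "NOT converged",
      ")\n", sep = "")
})

setMethod("show", "LigandScore", function(object) {
  cat("LigandScore ", paste(object@ligandKey, collapse = " "), ": ",
      object@achieved, "/", object@maximum, " over ",
      nrow(object@records), " interactions\n", sep = "")
})

setMethod("show", "RankedResult", function(object) {
  nc <- length(unique(object@table$cluster_id))
  cat("RankedResult for ", object@queryId, ": ", nrow(object@table),
      " candidates in ", nc, " clusters\n", sep = "")
})
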