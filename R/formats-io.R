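# Readers and writers for the standard formats the pipeline touches.
# PDB parsing is delegated to bio3d; this layer adds strict record
# validation, occupancy-based altloc selection and HETATM -> ligand grouping.

asLines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) readLines(x)
  else unlist(strsplit(x, "\n", fixed = TRUE))
}

#' Read a PDB-format structure
#'
#' Polymer residues are built from ATOM records; each maximal group of
#' HETATM records sharing (het code, chain, residue number) becomes one
#' \linkS4class{LigandInstance}. Waters (HOH) are excluded from the ligand
#' list; single metals and ions are kept. When alternate locations are
#' present the highest-occupancy conformer is kept (ties: first seen).
#' Sequences come from SEQRES records when present, otherwise from the ATOM
#' residues. Only the first NMR model is read.
#'
#' @param x path to a PDB file, or PDB-format text (single string with
#'   newlines, or a character vector of lines).
#' @param id structure identifier; defaults to the HEADER idCode when
#'   present, else the file base name, else "struct".
#' @return a \linkS4class{ProteinStructure}.
#' @export
readPDB <- function(x, id = NULL) {
  lines <- asLines(x)
  isRec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isRec))
    stop("no ATOM or HETATM records found")
  for (ln in which(isRec)) {
    l <- lines[ln]
    coords <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54))))
    if (nchar(l) < 54 || anyNA(coords) || any(!is.finite(coords)))
      stop("malformed fixed-column record at line ", ln)
  }
  if (!any(grepl("^ATOM  ", lines)))
    stop("empty structure: no ATOM records")

  if (is.null(id)) {
    hdr <- lines[grepl("^HEADER", lines)]
    if (length(hdr) && nchar(hdr[1]) >= 66 &&
        nzchar(trimws(substr(hdr[1], 63, 66))))
      id <- trimws(substr(hdr[1], 63, 66))
    else if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
      id <- tools::file_path_sans_ext(basename(x))
    else id <- "struct"
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, rm.alt = FALSE, multi = FALSE, verbose = FALSE)
  at <- p$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                    substr(trimws(at$elety), 1, 1),
                                    at$elesy)))

  # altloc: keep highest occupancy per (type, chain, resno, insert, name)
  key <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety,
               sep = "|")
  ord <- order(-at$o)          # stable: first-seen wins ties
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), , drop = FALSE]

  pol <- at[at$type == "ATOM", , drop = FALSE]
  atoms <- data.frame(serial = pol$eleno, name = trimws(pol$elety),
                      element = pol$elesy, resid = pol$resid,
                      chain = pol$chain, resno = pol$resno,
                      insert = pol$insert, x = pol$x, y = pol$y, z = pol$z,
                      stringsAsFactors = FALSE)

  het <- at[at$type == "HETATM" & at$resid != "HOH", , drop = FALSE]
  ligs <- list()
  if (nrow(het)) {
    grp <- paste(het$resid, het$chain, het$resno, sep = "|")
    for (g in unique(grp)) {
      h <- het[grp == g, , drop = FALSE]
      ligs[[length(ligs) + 1L]] <- new("LigandInstance",
        hetCode = h$resid[1], chainId = h$chain[1],
        seqNum = as.integer(h$resno[1]), structureId = id,
        atoms = data.frame(serial = h$eleno, name = trimws(h$elety),
                           element = h$elesy, x = h$x, y = h$y, z = h$z,
                           stringsAsFactors = FALSE),
        molecule = NULL)
    }
  }

  seqres <- character()
  if (!is.null(p$seqres) && length(p$seqres)) {
    for (ch in unique(names(p$seqres)))
      seqres[ch] <- paste(aa321(p$seqres[names(p$seqres) == ch]),
                          collapse = "")
  } else {
    res <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert)), ]
    for (ch in unique(res$chain))
      seqres[ch] <- paste(aa321(res$resid[res$chain == ch]), collapse = "")
  }

  new("ProteinStructure", id = id, atoms = atoms, seqres = seqres,
      ligands = ligs)
}

#' Serialize a structure to PDB-format text
#'
#' Emits SEQRES, ATOM, TER and HETATM records in fixed-column format.
#' Round-trips through \code{\link{readPDB}} preserve residue counts,
#' ligand grouping and coordinates to 1e-3 Angstrom.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @return character vector of PDB lines.
#' @export
writePDB <- function(structure) {
  out <- sprintf("HEADER    %-40s%9s   %4s", "SYNTHETIC COMPLEX", "",
                 substr(structure@id, 1, 4))
  for (ch in names(structure@seqres)) {
    res3 <- AA1TO3[strsplit(structure@seqres[[ch]], "")[[1]]]
    res3[is.na(res3)] <- "UNK"
    n <- length(res3)
    for (k in seq_len(ceiling(n / 13))) {
      chunk <- res3[((k - 1) * 13 + 1):min(k * 13, n)]
      out <- c(out, sprintf("SEQRES %3d %1s %4d  %s", k, ch, n,
                            paste(sprintf("%3s", chunk), collapse = " ")))
    }
  }
  fmtAtom <- function(recname, serial, name, resid, chain, resno, insert,
                      x, y, z, element) {
    nm <- if (nchar(name) >= 4) substr(name, 1, 4) else
      sprintf(" %-3s", name)
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            recname, serial, nm, "", resid, chain, resno,
            substr(paste0(insert, " "), 1, 1), x, y, z, 1, 0, element)
  }
  a <- structure@atoms
  for (r in seq_len(nrow(a)))
    out <- c(out, fmtAtom("ATOM", a$serial[r], a$name[r], a$resid[r],
                          a$chain[r], a$resno[r], a$insert[r],
                          a$x[r], a$y[r], a$z[r], a$element[r]))
  out <- c(out, "TER")
  for (lig in structure@ligands) {
    la <- lig@atoms
    for (r in seq_len(nrow(la)))
      out <- c(out, fmtAtom("HETATM", la$serial[r], la$name[r], lig@hetCode,
                            lig@chainId, lig@seqNum, "", la$x[r], la$y[r],
                            la$z[r], la$element[r]))
  }
  c(out, "END")
}

#' Read FASTA amino-acid sequences
#'
#' @param x path to a FASTA file or FASTA-format text.
#' @return a named \link[Biostrings]{AAStringSet}; sequences are uppercased
#'   and validated against the 20 amino acids plus X.
#' @export
readFastaSeqs <- function(x) {
  lines <- asLines(x)
  if (!length(lines) || !any(nzchar(lines)))
    stop("empty FASTA input")
  # validate raw residue characters first: readAAStringSet silently drops
  # invalid codes, which would mask bad input
  body <- toupper(gsub("\\s", "", lines[!grepl("^>", lines)]))
  checkAASeq(paste(body, collapse = ""), "FASTA input")
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  ss <- Biostrings::readAAStringSet(tf)
  Biostrings::AAStringSet(toupper(as.character(ss)))
}

# convert one ChemmineR SDF object to a MoleculeGraph (heavy atoms only)
sdfToGraph <- function(sdf, id = NA_character_, smiles = "") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- toupper(sub("_.*$", "", rownames(ab)))
  keep <- elements != "H"
  idx <- cumsum(keep)
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (NROW(bb)) {
    b <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    b <- b[keep[b$i] & keep[b$j], , drop = FALSE]
    if (nrow(b)) bonds <- data.frame(i = idx[b$i], j = idx[b$j],
                                     order = b$order)
  }
  MoleculeGraph(elements[keep], bonds, id = id, smiles = smiles)
}

smilesToGraph <- function(smiles, id = NA_character_) {
  # single-atom SMILES ("O", "[Fe]", "[Cl-]") come back from the SDF
  # round-trip with no bond block, which ChemmineR flags invalid
  m <- regmatches(smiles,
    regexec("^\\[?([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*)?\\]?$", smiles))[[1]]
  if (length(m) && toupper(m[2]) %in% PT_ELEMENTS)
    return(MoleculeGraph(m[2], NULL, id = id, smiles = smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smiles, id)))
  sdfToGraph(sdf[[1]], id = id, smiles = smiles)
}

#' Read a compound-source table
#'
#' Accepts either a TSV with columns \code{id}, \code{smiles},
#' \code{ic50_nM}, \code{xref_count}, \code{protein_id}, \code{source}
#' (extra columns ignored, an optional \code{has_binding_constant} column
#' honoured) or an SDF V2000 file whose data fields carry the same keys.
#' Records whose molecule cannot be parsed are skipped with a warning; the
#' number skipped is recorded in the \code{"skipped"} attribute.
#'
#' @param x path or text of the table.
#' @param dialect "tsv" or "sdf".
#' @param defaultSource source label used when the table has none; one of
#'   "chembl", "chebi", "kegg".
#' @return data.frame with columns compound_id, source, ic50_nM,
#'   has_binding_constant, xref_count, protein_id, assoc_identity_pct and a
#'   list-column \code{molecule} of \linkS4class{MoleculeGraph}.
#' @export
readCompoundTable <- function(x, dialect = c("tsv", "sdf"),
                              defaultSource = "chebi") {
  dialect <- match.arg(dialect)
  skipped <- 0L
  rows <- list()
  if (dialect == "tsv") {
    txt <- paste(asLines(x), collapse = "\n")
    df <- utils::read.delim(text = txt, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(df))) {
      mol <- tryCatch(smilesToGraph(df$smiles[r], id = as.character(df$id[r])),
                      error = function(e) NULL)
      if (is.null(mol)) {
        warning("skipping compound ", df$id[r], ": unparsable molecule")
        skipped <- skipped + 1L
        next
      }
      ic50 <- if ("ic50_nM" %in% names(df))
        suppressWarnings(as.numeric(df$ic50_nM[r])) else NA_real_
      hasbc <- if ("has_binding_constant" %in% names(df))
        isTRUE(as.logical(df$has_binding_constant[r])) else !is.na(ic50)
      rows[[length(rows) + 1L]] <- list(
        compound_id = as.character(df$id[r]),
        source = if ("source" %in% names(df)) tolower(df$source[r])
                 else defaultSource,
        ic50_nM = ic50, has_binding_constant = hasbc,
        xref_count = if ("xref_count" %in% names(df))
          suppressWarnings(as.integer(df$xref_count[r])) else NA_integer_,
        protein_id = if ("protein_id" %in% names(df))
          as.character(df$protein_id[r]) else NA_character_,
        molecule = mol)
    }
  } else {
    tf <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) x else {
      tmp <- tempfile(fileext = ".sdf"); writeLines(asLines(x), tmp); tmp
    }
    sdfs <- ChemmineR::read.SDFset(tf)
    for (r in seq_along(sdfs)) {
      cid <- ChemmineR::sdfid(sdfs[[r]])
      mol <- tryCatch(sdfToGraph(sdfs[[r]], id = cid),
                      error = function(e) NULL)
      if (is.null(mol) || !heavyAtomCount(mol)) {
        warning("skipping SDF record ", r, ": unparsable connection table")
        skipped <- skipped + 1L
        next
      }
      db <- ChemmineR::datablock(sdfs[[r]])
      getf <- function(k) if (k %in% names(db)) db[[k]] else NA
      ic50 <- suppressWarnings(as.numeric(getf("ic50_nM")))
      rows[[length(rows) + 1L]] <- list(
        compound_id = cid,
        source = if (!is.na(getf("source"))) tolower(getf("source"))
                 else defaultSource,
        ic50_nM = ic50,
        has_binding_constant = !is.na(ic50),
        xref_count = suppressWarnings(as.integer(getf("xref_count"))),
        protein_id = as.character(getf("protein_id")),
        molecule = mol)
    }
  }
  out <- data.frame(
    compound_id = vapply(rows, `[[`, "", "compound_id"),
    source = vapply(rows, `[[`, "", "source"),
    ic50_nM = vapply(rows, `[[`, 0, "ic50_nM"),
    has_binding_constant = vapply(rows, `[[`, TRUE, "has_binding_constant"),
    xref_count = vapply(rows, `[[`, 0L, "xref_count"),
    protein_id = vapply(rows, `[[`, "", "protein_id"),
    assoc_identity_pct = rep(NA_real_, length(rows)),
    stringsAsFactors = FALSE)
  out$molecule <- lapply(rows, `[[`, "molecule")
  attr(out, "skipped") <- skipped
  out
}

RESULT_COLUMNS <- c("cluster_rank", "cluster_id", "ligand_id", "source",
                    "score_achieved", "score_max", "structure_id",
                    "chain_id", "assoc_identity_pct", "xref_count",
                    "mol_weight", "heavy_atoms")

#' Write a ranked result as TSV
#'
#' One row per candidate ligand in ranked order, header row first.
#'
#' @param result a \linkS4class{RankedResult}.
#' @param path destination file.
#' @return invisibly, the data.frame written.
#' @export
writeResultsTSV <- function(result, path) {
  tab <- resultTable(result)
  miss <- setdiff(RESULT_COLUMNS, names(tab))
  for (m in miss) tab[[m]] <- NA
  tab <- tab[, RESULT_COLUMNS, drop = FALSE]
  if ("assoc_identity_pct" %in% names(tab))
    tab$assoc_identity_pct <- round(tab$assoc_identity_pct, 1)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(tab)
}
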