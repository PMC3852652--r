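# Synthetic-input generators with known ground truth: idealized
# extended-chain complexes with planted hydrogen bonds and contacts,
# homologs at controlled percent identity with conserved binding sites,
# and molecule series with controlled pairwise similarity. Realism is
# deliberately minimal - only distances, residue labels and graph
# structure matter to the scored method.

randomRotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

randomAASequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(AA1TO3), n, replace = TRUE), collapse = "")
}

#' Build a synthetic protein-ligand complex
#'
#' An idealized extended chain (3.8 Angstrom CA spacing; N, C, O at fixed
#' offsets) with ligand atoms placed to realize each planted interaction
#' at its stated distance: a ligand oxygen above the backbone carbonyl
#' oxygen of an hbond residue, a ligand carbon above that of a contact
#' residue. Planted residues should be distinct; interactions planted at
#' different residues never interfere (the geometry keeps all other
#' protein atoms outside both thresholds).
#'
#' @param spec list with elements: \code{id} (structure id), \code{chain}
#'   (default "A"), \code{sequence} (or \code{n_residues} + \code{seed}
#'   for a random one), \code{hbonds} and \code{contacts}
#'   (data.frames with columns resno, dist), \code{het_code} (default
#'   "LIG"), \code{ligand_graph} (optional \linkS4class{MoleculeGraph}
#'   attached as the ligand's molecule), \code{rotation}/\code{translation}
#'   (optional rigid motion applied to the whole complex), \code{seed}.
#' @return list with \code{structure} (\linkS4class{ProteinStructure}),
#'   \code{pdb} (PDB-format text) and \code{truth} (the planted
#'   interactions and the applied motion).
#' @export
makeComplex <- function(spec) {
  chain <- if (is.null(spec$chain)) "A" else spec$chain
  id <- if (is.null(spec$id)) "SYN1" else spec$id
  hetCode <- if (is.null(spec$het_code)) "LIG" else spec$het_code
  seq <- if (!is.null(spec$sequence)) toupper(spec$sequence) else {
    if (is.null(spec$n_residues)) stop("need sequence or n_residues")
    randomAASequence(spec$n_residues, seed = spec$seed)
  }
  n <- nchar(seq)
  if (n < 10) stop("need at least 10 residues")
  hb <- if (is.null(spec$hbonds))
    data.frame(resno = integer(), dist = numeric()) else spec$hbonds
  ct <- if (is.null(spec$contacts))
    data.frame(resno = integer(), dist = numeric()) else spec$contacts
  if (any(c(hb$resno, ct$resno) > n) || any(c(hb$resno, ct$resno) < 1))
    stop("infeasible geometry: planted residue outside the chain")
  if (anyDuplicated(c(hb$resno, ct$resno)))
    stop("infeasible geometry: one residue planted twice")

  aa <- strsplit(seq, "")[[1]]
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    x <- 3.8 * i
    res3 <- AA1TO3[[aa[i]]]
    for (at in list(c("N", "N", -0.5, -0.8, 0), c("CA", "C", 0, 0, 0),
                    c("C", "C", 0.5, 0.8, 0), c("O", "O", 0.6, 1.9, 0))) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(serial = serial, name = at[1],
        element = at[2], resid = res3, chain = chain, resno = i,
        insert = "", x = x + as.numeric(at[3]), y = as.numeric(at[4]),
        z = as.numeric(at[5]), stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)

  lrows <- list()
  k <- 0L
  for (r in seq_len(nrow(hb))) {
    k <- k + 1L
    lrows[[k]] <- data.frame(serial = serial + k,
      name = paste0("O", k), element = "O",
      x = 3.8 * hb$resno[r] + 0.6, y = 1.9, z = hb$dist[r],
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(ct))) {
    k <- k + 1L
    lrows[[k]] <- data.frame(serial = serial + k,
      name = paste0("C", k), element = "C",
      x = 3.8 * ct$resno[r] + 0.6, y = 1.9, z = ct$dist[r],
      stringsAsFactors = FALSE)
  }
  ligAtoms <- if (k) do.call(rbind, lrows) else
    data.frame(serial = serial + 1L, name = "C1", element = "C",
               x = 0, y = 10, z = 10, stringsAsFactors = FALSE)

  R <- if (is.null(spec$rotation)) diag(3) else spec$rotation
  tv <- if (is.null(spec$translation)) c(0, 0, 0) else spec$translation
  moveDf <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + tv[1]; df$y <- xyz[, 2] + tv[2]
    df$z <- xyz[, 3] + tv[3]
    df
  }
  atoms <- moveDf(atoms); ligAtoms <- moveDf(ligAtoms)

  lig <- new("LigandInstance", hetCode = hetCode, chainId = chain,
             seqNum = 501L, structureId = id, atoms = ligAtoms,
             molecule = spec$ligand_graph)
  st <- new("ProteinStructure", id = id, atoms = atoms,
            seqres = stats::setNames(seq, chain), ligands = list(lig))
  list(structure = st, pdb = writePDB(st),
       truth = list(hbonds = hb, contacts = ct, rotation = R,
                    translation = tv, sequence = seq))
}

#' Mutate a sequence to a target percent identity
#'
#' Random substitutions outside the conserved positions until the realized
#' identity is within 2 points of the target. Each substitution is chosen
#' with a known substitution-matrix sign so the planted conservation class
#' ("similar": BLOSUM62 score > 0 and not identical; "other": score <= 0)
#' is part of the ground truth.
#'
#' @param sequence source amino-acid sequence.
#' @param identityTarget target percent identity in (0, 100].
#' @param conserved 1-based positions never mutated.
#' @param seed RNG seed (same seed, same mutant).
#' @param simFrac fraction of substitutions drawn from the "similar" class
#'   (default 0.5).
#' @return the mutated sequence, with attributes \code{positions} and
#'   \code{classes} recording the substitutions.
#' @export
makeHomolog <- function(sequence, identityTarget, conserved = integer(),
                        seed = 1, simFrac = 0.5) {
  stopifnot(identityTarget > 0, identityTarget <= 100)
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  nSub <- round(L * (1 - identityTarget / 100))
  free <- setdiff(seq_len(L), conserved)
  if (nSub > length(free))
    stop("identity target unreachable while honouring conserved positions")
  if (!nSub) {
    out <- sequence
    attr(out, "positions") <- integer()
    attr(out, "classes") <- character()
    return(out)
  }
  set.seed(seed)
  pos <- sort(sample(free, nSub))
  mat <- loadSubstitutionMatrix("BLOSUM62")
  std <- names(AA1TO3)
  classes <- character(nSub)
  for (k in seq_along(pos)) {
    orig <- aa[pos[k]]
    simCands <- std[std != orig & mat[std, orig] > 0]
    othCands <- std[std != orig & mat[std, orig] <= 0]
    wantSim <- stats::runif(1) < simFrac
    if (wantSim && length(simCands)) {
      aa[pos[k]] <- sample(simCands, 1); classes[k] <- "similar"
    } else {
      aa[pos[k]] <- sample(othCands, 1); classes[k] <- "other"
    }
  }
  out <- paste(aa, collapse = "")
  attr(out, "positions") <- pos
  attr(out, "classes") <- classes
  out
}

#' Molecule series with controlled similarity
#'
#' Starting from a base graph, deletes one removable (non-articulation)
#' atom per step, so the k-th member is a connected induced subgraph of
#' the base and its Tanimoto similarity to the base is (n - k) / n,
#' strictly decreasing along the series.
#'
#' @param base a connected \linkS4class{MoleculeGraph} (n atoms).
#' @param edits number of successive deletions (< n).
#' @return list of \code{edits + 1} graphs, the base first.
#' @export
makeMoleculeSeries <- function(base, edits) {
  n <- length(base@atoms)
  stopifnot(edits < n)
  out <- list(base)
  cur <- base
  for (k in seq_len(edits)) {
    m <- length(cur@atoms)
    deletable <- NA_integer_
    for (v in rev(seq_len(m))) {        # prefer the highest index
      keep <- setdiff(seq_len(m), v)
      b <- cur@bonds[cur@bonds$i != v & cur@bonds$j != v, , drop = FALSE]
      if (length(keep) == 1 ||
          igraph::is_connected(igraph::graph_from_data_frame(
            d = data.frame(from = match(b$i, keep),
                           to = match(b$j, keep)),
            directed = FALSE,
            vertices = data.frame(name = seq_along(keep))))) {
        deletable <- v
        break
      }
    }
    keep <- setdiff(seq_len(length(cur@atoms)), deletable)
    b <- cur@bonds[cur@bonds$i != deletable & cur@bonds$j != deletable, ,
                   drop = FALSE]
    cur <- MoleculeGraph(cur@atoms[keep],
      data.frame(i = match(b$i, keep), j = match(b$j, keep),
                 order = b$order),
      id = paste0(base@id, "-d", k))
    out[[k + 1L]] <- cur
  }
  out
}

#' Assemble a complete synthetic study set
#'
#' The study conditions used throughout the tests and the acceptance
#' script: a 120-residue query with two annotated 60-residue domains;
#' homolog complexes at 90, 60 and 30 percent identity sharing a conserved
#' binding site (hydrogen bonds at residues 20 and 24, contacts at 28 and
#' 32, plus one hydrogen bond at 80 in the second domain), each carrying
#' the same 10-atom ligand graph; one homolog rigid-body transformed and
#' one annotated with a split domain; and a compound table mixing chembl,
#' chebi and kegg records (a molecule series around the ligand plus
#' decoys, one cross-source duplicate).
#'
#' @param seed RNG seed controlling the query sequence and mutations.
#' @param includeSelf also include a complex whose sequence is the query
#'   itself (the self-hit scenario).
#' @return list with query (character), structures (list of
#'   \linkS4class{ProteinStructure}), annotations (data.frame), compounds
#'   (data.frame), cognates (list of \linkS4class{MoleculeGraph}) and
#'   truth (per-structure planted facts).
#' @export
makeStudySet <- function(seed = 1, includeSelf = TRUE) {
  L <- 120L
  query <- randomAASequence(L, seed = seed)
  site <- c(20L, 24L, 28L, 32L, 80L)
  hb <- data.frame(resno = c(20L, 24L, 80L), dist = c(3.0, 3.1, 2.9))
  ct <- data.frame(resno = c(28L, 32L), dist = c(3.6, 3.7))

  # a thymidine-like abstract scaffold: 10 heavy atoms, ring + tail
  base <- MoleculeGraph(c("C", "N", "C", "N", "C", "C", "O", "C", "O", "P"),
    data.frame(i = c(1, 2, 3, 4, 5, 6, 5, 6, 8, 9),
               j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10),
               order = c(1, 1, 1, 1, 1, 1, 2, 1, 1, 1)),
    id = "LIG")
  series <- makeMoleculeSeries(base, 4)

  idents <- c(h90 = 90, h60 = 60, h30 = 30)
  structures <- list()
  truth <- list()
  homologSeqs <- character()
  k <- 0L
  for (nm in names(idents)) {
    k <- k + 1L
    hseq <- makeHomolog(query, idents[[nm]], conserved = site,
                        seed = seed + k)
    homologSeqs[nm] <- as.character(hseq)
    cx <- makeComplex(list(id = nm, sequence = as.character(hseq),
      hbonds = hb, contacts = ct, het_code = "LIG",
      ligand_graph = base,
      rotation = if (nm == "h60") randomRotation(seed + 10) else NULL,
      translation = if (nm == "h60") c(5, -3, 8) else NULL))
    structures[[nm]] <- cx$structure
    truth[[nm]] <- cx$truth
  }
  if (includeSelf) {
    cx <- makeComplex(list(id = "self", sequence = query, hbonds = hb,
                           contacts = ct, het_code = "LIG",
                           ligand_graph = base))
    structures[["self"]] <- cx$structure
    truth[["self"]] <- cx$truth
  }

  annRows <- list()
  for (nm in names(structures)) {
    if (nm == "h60") {      # split domain over two segments + the middle
      annRows[[length(annRows) + 1L]] <- data.frame(structure_id = nm,
        chain_id = "A", domain_id = paste0(nm, "_Dsplit"),
        segments = "1-30,91-120", kind = "cath_like")
      annRows[[length(annRows) + 1L]] <- data.frame(structure_id = nm,
        chain_id = "A", domain_id = paste0(nm, "_Dmid"),
        segments = "31-90", kind = "cath_like")
    } else {
      annRows[[length(annRows) + 1L]] <- data.frame(structure_id = nm,
        chain_id = "A", domain_id = paste0(nm, "_D1"), segments = "1-60",
        kind = "cath_like")
      annRows[[length(annRows) + 1L]] <- data.frame(structure_id = nm,
        chain_id = "A", domain_id = paste0(nm, "_D2"),
        segments = "61-120", kind = "pfam_like")
    }
  }
  annotations <- do.call(rbind, annRows)
  annotations$segments_parsed <- lapply(annotations$segments,
                                        parseSegments)

  compounds <- data.frame(
    compound_id = c("cmp_near1", "cmp_near2", "cmp_far", "cmp_dup",
                    "cmp_weak", "cmp_small"),
    source = c("chembl", "chebi", "kegg", "chebi", "chembl", "chebi"),
    ic50_nM = c(50, NA, NA, NA, 500, NA),
    has_binding_constant = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    xref_count = c(12L, 3L, 1L, 7L, 2L, 5L),
    protein_id = c("h90", "h90", "h60", "h30", "h90", "h60"),
    assoc_identity_pct = NA_real_,
    stringsAsFactors = FALSE)
  benz <- MoleculeGraph(rep("C", 6),
    data.frame(i = 1:6, j = c(2:6, 1), order = 4), id = "cmp_far")
  small <- MoleculeGraph("O", NULL, id = "cmp_small")   # water: < 50 Da
  # near1/near2: base minus one/two atoms; dup duplicates near2 across
  # sources; weak is a distant series member; small is sub-50 Da
  compounds$molecule <- list(series[[2]], series[[3]], benz, series[[3]],
                             series[[5]], small)
  smis <- c("C1NCNC(=O)C1CO", "C1NCNC(=O)C1C", "c1ccccc1",
            "C1NCNC(=O)C1C", "C1NCNC(=O)C1", "O")
  for (i in seq_along(compounds$molecule)) {
    m <- compounds$molecule[[i]]
    m@id <- compounds$compound_id[i]
    m@smiles <- smis[i]
    compounds$molecule[[i]] <- m
  }

  list(query = query, structures = structures, annotations = annotations,
       compounds = compounds, cognates = list(base, series[[2]]),
       truth = truth, homologs = homologSeqs, bindingSite = site,
       ligandGraph = base)
}
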