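# shared lookup tables and small helpers

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_LETTERS <- c(names(AA1TO3), "X")

aa321 <- function(res3) {
  out <- AA3TO1[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

# standard atomic weights (most abundant usage, 4 sf)
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, CL = 35.45, BR = 79.904, I = 126.90, B = 10.81,
  SI = 28.085, SE = 78.971, "NA" = 22.990, K = 39.098, MG = 24.305,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, LI = 6.94, AL = 26.982, AS = 74.922)

# default valences for implicit-hydrogen counting; absent => 0 implicit H
DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1,
                     BR = 1, I = 1, B = 3, SI = 4, SE = 2)

# single-bond covalent radii (Angstrom) for distance-based connectivity
COVALENT_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, CL = 1.02, BR = 1.2, I = 1.39, B = 0.84, SI = 1.11,
  SE = 1.2, "NA" = 1.66, K = 2.03, MG = 1.41, CA = 1.76, MN = 1.39,
  FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32, ZN = 1.22)

#' Load a substitution matrix
#'
#' Returns a built-in matrix from \pkg{Biostrings} by name (e.g.
#' "BLOSUM62", "PAM250") or parses an NCBI-format matrix text file.
#'
#' @param x matrix name, path to an NCBI-format matrix file, or an already
#'   constructed numeric matrix (returned as is).
#' @return numeric substitution matrix with amino-acid dimnames.
#' @export
loadSubstitutionMatrix <- function(x = "BLOSUM62") {
  if (is.matrix(x)) return(x)
  stopifnot(is.character(x), length(x) == 1)
  if (file.exists(x)) {
    lines <- readLines(x)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    body <- do.call(rbind, lapply(lines[-1], function(l)
      strsplit(trimws(l), "\\s+")[[1]]))
    m <- apply(body[, -1, drop = FALSE], 2, as.numeric)
    rownames(m) <- body[, 1]
    colnames(m) <- cols
    return(m)
  }
  env <- new.env()
  utils::data(list = x, package = "Biostrings", envir = env)
  get(x, envir = env)
}

# pairwise Euclidean distances between rows of two n x 3 matrices
crossDist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}

# contiguous runs of TRUE in a logical vector -> data.frame(start, end)
trueRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# validate an amino-acid sequence string
checkAASeq <- function(s, id = "sequence") {
  bad <- setdiff(strsplit(s, "")[[1]], AA_LETTERS)
  if (length(bad))
    stop("invalid characters in ", id, ": ", paste(unique(bad), collapse = ""))
  invisible(TRUE)
}
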