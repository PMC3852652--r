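# Independent oracles used to check the package's own implementations.
# These deliberately use the slowest, most transparent formulation.

# Local alignment by exhaustive dynamic programming without the affine
# (Gotoh) optimization: every gap length is tried explicitly, a gap of
# length L costing open + L * ext.
swOracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    diag <- H[i, j] + mat[A[i], B[j]]
    up <- max(vapply(seq_len(i), function(k)
      H[i + 1 - k, j + 1] - (open + k * ext), 0))
    left <- max(vapply(seq_len(j), function(k)
      H[i + 1, j + 1 - k] - (open + k * ext), 0))
    H[i + 1, j + 1] <- max(0, diag, up, left)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

randomAA <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# Maximum common connected induced subgraph by exhaustive enumeration:
# every connected vertex subset of a is tested for an element- and
# bond-order-preserving induced embedding into b.
mcsOracle <- function(a, b) {
  na <- length(a@atoms); nb <- length(b@atoms)
  if (!na || !nb) return(0L)
  A <- matrix(0L, na, na); B <- matrix(0L, nb, nb)
  if (nrow(a@bonds)) {
    A[cbind(a@bonds$i, a@bonds$j)] <- a@bonds$order
    A[cbind(a@bonds$j, a@bonds$i)] <- a@bonds$order
  }
  if (nrow(b@bonds)) {
    B[cbind(b@bonds$i, b@bonds$j)] <- b@bonds$order
    B[cbind(b@bonds$j, b@bonds$i)] <- b@bonds$order
  }
  ea <- toupper(a@atoms); eb <- toupper(b@atoms)
  isConnected <- function(vs) {
    if (length(vs) == 1) return(TRUE)
    seen <- vs[1]; frontier <- vs[1]
    while (length(frontier)) {
      nxt <- setdiff(vs[colSums(A[frontier, vs, drop = FALSE] > 0) > 0],
                     seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(vs)
  }
  embeds <- function(vs) {
    rec <- function(k, mapped) {
      if (k > length(vs)) return(TRUE)
      u <- vs[k]
      for (v in setdiff(which(eb == ea[u]), mapped)) {
        ok <- TRUE
        for (t in seq_len(k - 1))
          if (A[u, vs[t]] != B[v, mapped[t]]) { ok <- FALSE; break }
        if (ok && rec(k + 1, c(mapped, v))) return(TRUE)
      }
      FALSE
    }
    rec(1, integer())
  }
  best <- 0L
  for (mask in seq_len(2^na - 1)) {
    vs <- which(bitwAnd(mask, 2^(seq_len(na) - 1)) > 0)
    if (length(vs) <= best) next
    if (!isConnected(vs)) next
    if (embeds(vs)) best <- length(vs)
  }
  best
}

# random connected molecule graph: spanning tree plus optional extra edges
randomMolecule <- function(n, id = "rnd", extraEdges = 1) {
  el <- sample(c("C", "C", "N", "O"), n, replace = TRUE)
  bonds <- NULL
  if (n > 1) {
    for (v in 2:n)
      bonds <- rbind(bonds,
                     data.frame(i = sample(v - 1, 1), j = v,
                                order = sample(1:2, 1)))
    for (e in seq_len(extraEdges)) {
      if (n < 3) break
      pair <- sort(sample(n, 2))
      if (!any(bonds$i == pair[1] & bonds$j == pair[2]))
        bonds <- rbind(bonds, data.frame(i = pair[1], j = pair[2],
                                         order = sample(1:2, 1)))
    }
  }
  MoleculeGraph(el, bonds, id = id)
}

benzeneGraph <- function(id = "benzene")
  MoleculeGraph(rep("C", 6), data.frame(i = 1:6, j = c(2:6, 1), order = 4),
                id = id)

# minimal two-residue, one-ligand PDB fixture used by the io tests
toyPDBText <- function() {
  c(sprintf("HEADER    %-52s%4s", "SYNTHETIC COMPLEX", "TOY1"),
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.685   7.192  -5.004  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      12.500   8.300  -5.500  1.00  0.00           O",
    "ATOM      5  CA  GLY A   2      14.800   7.900  -4.100  1.00  0.00           C",
    "TER",
    "HETATM  101  P   TMP A 201       1.000   2.000   3.000  1.00  0.00           P",
    "HETATM  102  O1  TMP A 201       2.000   2.000   3.000  1.00  0.00           O",
    "HETATM  103  O2  TMP A 201       1.000   3.000   3.000  1.00  0.00           O",
    "HETATM  104  S   SO4 A 301       9.000   9.000   9.000  1.00  0.00           S",
    "HETATM  105  O   HOH A 302       9.000   9.000   5.000  1.00  0.00           O",
    "END")
}
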