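# Rigid-body superposition: a Kabsch least-squares kernel plus the
# iterative outlier-trimming loop that refits until the RMSD drops below
# the configured cutoff (default 12 Angstrom), removing the worst residue
# equivalences at each round.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of the
#' mobile points onto the fixed points.
#'
#' @param fixed,mobile n x 3 coordinate matrices, n >= 3, paired row-wise.
#' @return a \linkS4class{Superposition}; \code{rotation} and
#'   \code{translation} map mobile coordinates as \code{x R^T + t}.
#' @export
kabsch <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (nrow(fixed) != nrow(mobile)) stop("point sets must be paired")
  if (nrow(fixed) < 3) stop("degenerate input: need at least 3 points")
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)                       # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cf - as.vector(R %*% cm)
  moved <- tcrossprod(mobile, R) + matrix(t, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  new("Superposition", rotation = R, translation = t, rmsd = rmsd,
      retained = data.frame(point = seq_len(nrow(fixed))),
      converged = TRUE, iterations = 1L)
}

#' Apply a superposition to coordinates
#'
#' @param sup a \linkS4class{Superposition}.
#' @param coords n x 3 matrix (or data.frame with x, y, z columns).
#' @return transformed coordinates, same shape as the input.
#' @export
applyTransform <- function(sup, coords) {
  isDf <- is.data.frame(coords)
  xyz <- if (isDf) as.matrix(coords[, c("x", "y", "z")]) else
    as.matrix(coords)
  moved <- tcrossprod(xyz, sup@rotation) +
    matrix(sup@translation, nrow(xyz), 3, byrow = TRUE)
  if (isDf) { coords[, c("x", "y", "z")] <- moved; coords } else moved
}

mainChainCoords <- function(structure, chain, resno, insert = "") {
  a <- structure@atoms
  sel <- a$chain == chain & a$resno == resno & a$insert == insert &
    a$name %in% c("N", "CA", "C", "O")
  m <- a[sel, c("name", "x", "y", "z")]
  rownames(m) <- m$name
  m
}

#' Iterative superposition with outlier trimming
#'
#' Fits the mobile structure onto the reference over the main-chain atoms
#' (N, CA, C, O; a missing O is tolerated) of the given residue
#' equivalences. While the RMSD is at or above \code{cutoff}, the worst 10
#' percent of residue pairs (at least one) by per-residue deviation are
#' removed and the fit repeated; the loop fails when fewer than 3 pairs
#' remain. The RMSD is non-increasing across iterations.
#'
#' @param reference,mobile \linkS4class{ProteinStructure}s.
#' @param equivalences data.frame with columns ref_chain, ref_resno,
#'   mob_chain, mob_resno (optional ref_insert, mob_insert). Pairs whose
#'   main-chain atoms are entirely missing on either side are skipped with
#'   a warning.
#' @param cutoff RMSD convergence cutoff in Angstrom (default 12).
#' @param trimFrac fraction of pairs removed per iteration (default 0.1).
#' @return a \linkS4class{Superposition}; \code{converged} is FALSE when
#'   the pair floor was reached first. Apply it to the mobile structure's
#'   ligand atoms with \code{\link{applyTransform}}.
#' @export
iterativeSuperpose <- function(reference, mobile, equivalences, cutoff = 12,
                               trimFrac = 0.1) {
  stopifnot(cutoff > 0)
  if (!"ref_insert" %in% names(equivalences)) equivalences$ref_insert <- ""
  if (!"mob_insert" %in% names(equivalences)) equivalences$mob_insert <- ""
  if (nrow(equivalences) < 3)
    stop("need at least 3 residue equivalences")

  pairAtoms <- list()
  for (r in seq_len(nrow(equivalences))) {
    fa <- mainChainCoords(reference, equivalences$ref_chain[r],
                          equivalences$ref_resno[r],
                          equivalences$ref_insert[r])
    ma <- mainChainCoords(mobile, equivalences$mob_chain[r],
                          equivalences$mob_resno[r],
                          equivalences$mob_insert[r])
    common <- intersect(rownames(fa), rownames(ma))
    if (!length(common)) {
      warning("equivalence ", r, " has no shared main-chain atoms; skipped")
      next
    }
    pairAtoms[[length(pairAtoms) + 1L]] <- list(
      row = r, fixed = as.matrix(fa[common, c("x", "y", "z")]),
      mobile = as.matrix(ma[common, c("x", "y", "z")]))
  }
  if (length(pairAtoms) < 3)
    stop("fewer than 3 usable equivalences after atom matching")

  retained <- seq_along(pairAtoms)
  removed <- integer()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fx <- do.call(rbind, lapply(pairAtoms[retained], `[[`, "fixed"))
    mb <- do.call(rbind, lapply(pairAtoms[retained], `[[`, "mobile"))
    fit <- kabsch(fx, mb)
    if (fit@rmsd < cutoff) {
      converged <- TRUE
      break
    }
    dev <- vapply(retained, function(i) {
      moved <- applyTransform(fit, pairAtoms[[i]]$mobile)
      sqrt(mean(rowSums((moved - pairAtoms[[i]]$fixed)^2)))
    }, 0)
    nDrop <- max(1L, ceiling(trimFrac * length(retained)))
    drop <- retained[order(-dev)][seq_len(nDrop)]
    removed <- c(removed, drop)
    retained <- setdiff(retained, drop)
    if (length(retained) < 3) {
      converged <- FALSE
      break
    }
  }
  eqRows <- function(idx) {
    if (!length(idx)) return(data.frame())
    equivalences[vapply(pairAtoms[idx], `[[`, 0L, "row"), , drop = FALSE]
  }
  new("Superposition", rotation = fit@rotation,
      translation = fit@translation, rmsd = fit@rmsd,
      retained = eqRows(retained), removed = eqRows(removed),
      converged = converged, iterations = iter)
}
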