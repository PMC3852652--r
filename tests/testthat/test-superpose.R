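test_that("kabsch recovers exact rigid motions", {
  set.seed(1)
  X <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
  # identical sets: zero rmsd, identity rotation
  s0 <- kabsch(X, X)
  expect_lt(s0@rmsd, 1e-9)
  expect_equal(s0@rotation, diag(3), tolerance = 1e-9)
  # known rotation + translation: recovered inverse to 1e-6
  R <- ligscout:::randomRotation(99)
  Y <- X %*% t(R) + matrix(c(3, -7, 12), 30, 3, byrow = TRUE)
  s1 <- kabsch(X, Y)
  expect_lt(s1@rmsd, 1e-8)
  expect_equal(s1@rotation, t(R), tolerance = 1e-6)
  expect_error(kabsch(X[1:2, ], Y[1:2, ]), "degenerate")
})

test_that("kabsch rmsd equals the independent fitting oracle on noisy data", {
  set.seed(2)
  for (k in 1:25) {
    X <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
    R <- ligscout:::randomRotation(k)
    Y <- X %*% t(R) + matrix(rnorm(3), 30, 3, byrow = TRUE) +
      matrix(rnorm(30 * 3, sd = 0.5), ncol = 3)
    mine <- kabsch(X, Y)@rmsd
    # bio3d::rmsd reports to 3 decimals; compare at that precision
    oracle <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
    expect_lt(abs(mine - oracle), 5e-4)
  }
})

test_that("already-superposed structures converge in one iteration", {
  cx <- makeComplex(list(id = "SP1", n_residues = 40, seed = 3))
  eq <- data.frame(ref_chain = "A", ref_resno = 1:40,
                   mob_chain = "A", mob_resno = 1:40)
  s <- iterativeSuperpose(cx$structure, cx$structure, eq, cutoff = 12)
  expect_equal(s@iterations, 1L)
  expect_equal(nrow(s@removed), 0)
  expect_lt(s@rmsd, 1e-9)
  expect_true(s@converged)
})

test_that("a planted 50 A outlier is trimmed away", {
  cx <- makeComplex(list(id = "SP2", n_residues = 41, seed = 4))
  mob <- cx$structure
  # displace one residue's atoms by 50 A
  sel <- mob@atoms$resno == 21
  mob@atoms$z[sel] <- mob@atoms$z[sel] + 50
  eq <- data.frame(ref_chain = "A", ref_resno = 1:41,
                   mob_chain = "A", mob_resno = 1:41)
  s <- iterativeSuperpose(cx$structure, mob, eq, cutoff = 0.5)
  expect_true(s@converged)
  expect_lt(s@rmsd, 0.01)
  expect_true(21 %in% s@removed$mob_resno)
  expect_false(21 %in% s@retained$mob_resno)
})

test_that("planted rigid motions are recovered through the full structure path", {
  R <- ligscout:::randomRotation(17)
  tv <- c(4, -2, 9)
  base <- makeComplex(list(id = "SP3", n_residues = 35, seed = 5,
                           hbonds = data.frame(resno = 10, dist = 3.0)))
  moved <- makeComplex(list(id = "SP4",
                            sequence = base$truth$sequence,
                            hbonds = data.frame(resno = 10, dist = 3.0),
                            rotation = R, translation = tv))
  eq <- data.frame(ref_chain = "A", ref_resno = 1:35,
                   mob_chain = "A", mob_resno = 1:35)
  s <- iterativeSuperpose(base$structure, moved$structure, eq)
  expect_lt(s@rmsd, 0.01)
  expect_equal(s@rotation, t(R), tolerance = 1e-6)
  # the transform carries the mobile ligand into the reference frame
  ligMoved <- applyTransform(s, ligandAtoms(ligands(moved$structure)[[1]]))
  ligRef <- ligandAtoms(ligands(base$structure)[[1]])
  expect_equal(as.matrix(ligMoved[, c("x", "y", "z")]),
               as.matrix(ligRef[, c("x", "y", "z")]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("rigid transforms preserve intra-ligand distances", {
  cx <- makeComplex(list(id = "SP5", n_residues = 30, seed = 6,
                         hbonds = data.frame(resno = c(5, 9), dist = c(3, 3.2)),
                         contacts = data.frame(resno = 14, dist = 3.6)))
  lig <- ligandAtoms(ligands(cx$structure)[[1]])
  s <- kabsch(matrix(rnorm(9), 3), matrix(rnorm(9), 3))
  before <- dist(as.matrix(lig[, c("x", "y", "z")]))
  after <- dist(as.matrix(applyTransform(s, lig)[, c("x", "y", "z")]))
  expect_equal(as.vector(before), as.vector(after), tolerance = 1e-6)
})

test_that("rmsd never increases across trimming iterations", {
  # instrument by reproducing the loop on noisy equivalences
  set.seed(30)
  cx <- makeComplex(list(id = "SP6", n_residues = 50, seed = 7))
  mob <- cx$structure
  noise <- matrix(rnorm(nrow(mob@atoms) * 3, sd = 4), ncol = 3)
  mob@atoms$x <- mob@atoms$x + noise[, 1]
  mob@atoms$y <- mob@atoms$y + noise[, 2]
  mob@atoms$z <- mob@atoms$z + noise[, 3]
  eq <- data.frame(ref_chain = "A", ref_resno = 1:50,
                   mob_chain = "A", mob_resno = 1:50)
  rmsds <- c()
  keep <- eq
  for (it in 1:10) {
    if (nrow(keep) < 3) break
    s <- iterativeSuperpose(cx$structure, mob, keep, cutoff = 1e-6)
    rmsds <- c(rmsds, s@rmsd)
    if (nrow(s@retained) >= 3) keep <- s@retained else break
  }
  # successive refits on trimmed sets: monotone non-increasing
  expect_true(all(diff(rmsds) <= 1e-9))
})

test_that("mutually inconsistent coordinates terminate with a failure flag", {
  set.seed(31)
  cx <- makeComplex(list(id = "SP7", n_residues = 30, seed = 8))
  mob <- cx$structure
  mob@atoms$x <- rnorm(nrow(mob@atoms), sd = 30)
  mob@atoms$y <- rnorm(nrow(mob@atoms), sd = 30)
  mob@atoms$z <- rnorm(nrow(mob@atoms), sd = 30)
  eq <- data.frame(ref_chain = "A", ref_resno = 1:30,
                   mob_chain = "A", mob_resno = 1:30)
  s <- iterativeSuperpose(cx$structure, mob, eq, cutoff = 0.001)
  expect_false(s@converged)
})
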