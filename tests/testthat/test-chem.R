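test_that("MCS handles the self, disjoint and hand-checked cases", {
  benz <- benzeneGraph()
  expect_equal(mcs(benz, benz)$size, 6)
  one_c <- MoleculeGraph("C", NULL, id = "c1")
  one_o <- MoleculeGraph("O", NULL, id = "o1")
  expect_equal(mcs(one_c, one_o)$size, 0)
  expect_equal(mcs(one_c, one_c)$size, 1)
  # bond order must match: aromatic ring vs single-bond ring share no edge,
  # so only a single atom can be mapped
  ring1 <- MoleculeGraph(rep("C", 6),
                         data.frame(i = 1:6, j = c(2:6, 1), order = 1))
  expect_equal(mcs(benz, ring1)$size, 1)
})

test_that("MCS equals the exhaustive enumeration oracle on random small graphs", {
  set.seed(77)
  for (k in 1:60) {
    a <- randomMolecule(sample(3:8, 1))
    b <- randomMolecule(sample(3:8, 1))
    got <- mcs(a, b)
    expect_true(got$exact)
    expect_equal(got$size, mcsOracle(a, b), info = paste("trial", k))
  }
})

test_that("similarity is the atom-count Tanimoto with its boundary cases", {
  benz <- benzeneGraph()
  expect_equal(molSimilarity(benz, benz)$value, 1)
  a <- MoleculeGraph(c("C", "C"), data.frame(i = 1, j = 2, order = 1))
  b <- MoleculeGraph(c("N", "N"), data.frame(i = 1, j = 2, order = 1))
  expect_equal(molSimilarity(a, b)$value, 0)
  # |a| = 6, |b| = 8, mcs = 4 gives 4/10
  chain6 <- MoleculeGraph(rep("C", 6),
                          data.frame(i = 1:5, j = 2:6, order = 1))
  chain4N4 <- MoleculeGraph(c(rep("C", 4), rep("N", 4)),
                            data.frame(i = 1:7, j = 2:8, order = 1))
  s <- molSimilarity(chain6, chain4N4)
  expect_equal(s$mcsSize, 4)
  expect_equal(s$value, 0.4)
})

test_that("similarity is symmetric and bounded on random pairs", {
  set.seed(78)
  for (k in 1:15) {
    a <- randomMolecule(sample(2:7, 1))
    b <- randomMolecule(sample(2:7, 1))
    sab <- molSimilarity(a, b)$value
    sba <- molSimilarity(b, a)$value
    expect_equal(sab, sba)
    expect_gte(sab, 0); expect_lte(sab, 1)
    expect_equal(molSimilarity(a, a)$value, 1)
  }
})

test_that("complete-linkage clustering honours the worked example and cutoff", {
  S <- matrix(c(1, .9, .3, .9, 1, .3, .3, .3, 1), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- clusterMolecules(similarities = S, cutoff = 0.4)
  expect_equal(attr(cl, "clusters"),
               list(C1 = c("A", "B"), C2 = "C"))
  # single molecule: one singleton
  cl1 <- clusterMolecules(list(benzeneGraph()))
  expect_equal(nrow(cl1), 1)
  # n copies of one molecule: one cluster of n
  copies <- lapply(1:4, function(i) {
    m <- benzeneGraph(); m@id <- paste0("b", i); m
  })
  cln <- clusterMolecules(copies)
  expect_equal(length(attr(cln, "clusters")), 1)
  expect_equal(lengths(attr(cln, "clusters")), c(C1 = 4L))
})

test_that("every emitted cluster satisfies the min-similarity criterion", {
  set.seed(80)
  for (trial in 1:5) {
    n <- 25
    S <- matrix(runif(n * n), n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(sprintf("m%02d", 1:n), sprintf("m%02d", 1:n))
    cl <- clusterMolecules(similarities = S, cutoff = 0.4)
    for (members in attr(cl, "clusters")) {
      if (length(members) > 1)
        expect_gte(min(S[members, members]), 0.4)
    }
    # deterministic under re-run
    cl2 <- clusterMolecules(similarities = S, cutoff = 0.4)
    expect_identical(cl, cl2)
  }
})

test_that("clustering agrees with hclust complete linkage on cluster count", {
  set.seed(81)
  n <- 20
  S <- matrix(runif(n * n), n); S <- (S + t(S)) / 2; diag(S) <- 1
  dimnames(S) <- list(sprintf("m%02d", 1:n), sprintf("m%02d", 1:n))
  cl <- clusterMolecules(similarities = S, cutoff = 0.4)
  hc <- stats::hclust(stats::as.dist(1 - S), method = "complete")
  ref <- stats::cutree(hc, h = 1 - 0.4)
  # both are greedy complete-linkage algorithms; with random (tie-free)
  # similarities the partitions coincide
  expect_equal(length(attr(cl, "clusters")), length(unique(ref)))
  refSets <- unname(split(names(ref), ref))
  mySets <- unname(attr(cl, "clusters"))
  expect_setequal(lapply(mySets, sort), lapply(refSets, sort))
})

test_that("molecular properties use implicit hydrogens and atomic masses", {
  water <- MoleculeGraph("O", NULL, id = "w")
  expect_equal(molProperties(water)$mol_weight, 18.02, tolerance = 1e-3)
  benz <- benzeneGraph()
  p <- molProperties(benz)
  expect_equal(p$heavy_atoms, 6)
  expect_equal(p$mol_weight, 78.11, tolerance = 1e-3)   # C6H6
  etoh <- MoleculeGraph(c("C", "C", "O"),
                        data.frame(i = 1:2, j = 2:3, order = 1), id = "e")
  expect_equal(molProperties(etoh)$mol_weight, 46.07, tolerance = 1e-3)
  bad <- MoleculeGraph("U", NULL, id = "u")
  expect_error(molProperties(bad), "unknown element")
})

test_that("molecular weight matches the OpenBabel oracle on varied molecules", {
  skip_if_not_installed("ChemmineOB")
  smis <- c("CCO", "c1ccccc1", "CC(=O)O", "O=P(O)(O)O", "CCN(CC)CC",
            "C1CCCCC1", "O=C(N)C", "CSC", "FC(F)F", "OCC(O)CO")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smis, paste0("m", seq_along(smis)))))
  ob <- ChemmineR::propOB(sdf)
  for (i in seq_along(smis)) {
    mol <- ligscout:::smilesToGraph(smis[i], id = paste0("m", i))
    expect_equal(molProperties(mol)$mol_weight, ob$MW[i], tolerance = 0.01,
                 info = smis[i])
  }
})

test_that("ligand connectivity is recovered from coordinates by covalent radii", {
  # a glycine-like fragment: N-CA(1.47), CA-C(1.53), C=O(1.23)
  at <- data.frame(serial = 1:4, name = c("N", "CA", "C", "O"),
                   element = c("N", "C", "C", "O"),
                   x = c(0, 1.47, 2.4, 2.4), y = c(0, 0, 1.2, 2.43),
                   z = 0, stringsAsFactors = FALSE)
  lig <- new("LigandInstance", hetCode = "FRG", chainId = "A",
             seqNum = 1L, structureId = "x", atoms = at, molecule = NULL)
  mol <- ligandMolecule(lig)
  expect_equal(heavyAtomCount(mol), 4)
  expect_equal(nrow(mol@bonds), 3)
  # a lone magnesium is a single-atom graph
  mg <- new("LigandInstance", hetCode = "MG", chainId = "A", seqNum = 2L,
            structureId = "x",
            atoms = data.frame(serial = 1, name = "MG", element = "MG",
                               x = 0, y = 0, z = 0), molecule = NULL)
  expect_equal(heavyAtomCount(ligandMolecule(mg)), 1)
})
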