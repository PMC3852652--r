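# distance helper for the dedup check
crossDistToRes <- function(st, lig, resno) {
  pa <- st@atoms[st@atoms$resno == resno, c("x", "y", "z")]
  la <- ligandAtoms(lig)[, c("x", "y", "z")]
  as.vector(ligscout:::crossDist(as.matrix(la), as.matrix(pa)))
}

# helper: classify every record as a fixed class without an alignment
forceClass <- function(records, classes) {
  records$conservation <- rep_len(classes, nrow(records))
  records
}

test_that("hydrogen bonds are polar-polar pairs within threshold", {
  cx <- makeComplex(list(id = "IX1", n_residues = 30, seed = 1,
                         hbonds = data.frame(resno = c(5, 12), dist = c(3.0, 3.1))))
  hb <- detectHBonds(cx$structure, ligands(cx$structure)[[1]])
  expect_equal(nrow(hb), 2)
  expect_setequal(hb$resno, c(5, 12))
  expect_true(all(hb$distance <= 3.35))
  # a carbon at hydrogen-bond distance is not an hbond
  cx2 <- makeComplex(list(id = "IX2", n_residues = 30, seed = 2,
                          contacts = data.frame(resno = 7, dist = 3.0)))
  expect_equal(nrow(detectHBonds(cx2$structure,
                                 ligands(cx2$structure)[[1]])), 0)
})

test_that("planted interactions are recovered exactly, none invented", {
  set.seed(33)
  for (k in 1:5) {
    nHB <- sample(1:4, 1)
    resn <- sample(seq(5, 56, by = 4), nHB + 1)
    cx <- makeComplex(list(id = "IX3", n_residues = 60, seed = k,
      hbonds = data.frame(resno = resn[seq_len(nHB)],
                          dist = runif(nHB, 2.8, 3.2)),
      contacts = data.frame(resno = resn[nHB + 1], dist = 3.7)))
    st <- cx$structure; lig <- ligands(st)[[1]]
    hb <- detectHBonds(st, lig)
    ct <- detectContacts(st, lig, hbonds = hb)
    expect_setequal(hb$resno, cx$truth$hbonds$resno)
    expect_setequal(ct$resno, cx$truth$contacts$resno)
  }
})

test_that("contacts deduplicate per residue and defer to hydrogen bonds", {
  # one residue, several atoms within contact range: one record, closest kept
  cx <- makeComplex(list(id = "IX4", n_residues = 30, seed = 3,
                         contacts = data.frame(resno = 9, dist = 3.5)))
  st <- cx$structure; lig <- ligands(st)[[1]]
  ct <- detectContacts(st, lig)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$resno, 9)
  expect_equal(ct$distance, min(crossDistToRes(st, lig, 9)),
               tolerance = 1e-9)
  # hbond residue: its contacts are suppressed
  cx2 <- makeComplex(list(id = "IX5", n_residues = 30, seed = 4,
                          hbonds = data.frame(resno = 11, dist = 3.0)))
  st2 <- cx2$structure; lig2 <- ligands(st2)[[1]]
  hb2 <- detectHBonds(st2, lig2)
  ct2 <- detectContacts(st2, lig2, hbonds = hb2)
  expect_false(11 %in% ct2$resno)
  # far ligand: nothing
  cx3 <- makeComplex(list(id = "IX6", n_residues = 12, seed = 5))
  expect_equal(nrow(detectContacts(cx3$structure,
                                   ligands(cx3$structure)[[1]])), 0)
})

test_that("conservation classes follow the alignment and the matrix", {
  q <- "ARNDCQEGHILKMFPWSTYV"
  q <- paste0(q, q)  # length 40
  pair <- smithWaterman(q, q)
  rec <- data.frame(kind = "hbond", ligandAtom = "O1", chain = "A",
                    resno = 2L, insert = "", resType = "ARG",
                    distance = 3.0, conservation = NA_character_,
                    weight = NA_real_, stringsAsFactors = FALSE)
  expect_equal(classifyConservation(rec, pair, q)$conservation, "identical")
  # hit LYS aligned to query ARG: BLOSUM62 R/K = +2, similar
  rec$resType <- "LYS"
  expect_equal(classifyConservation(rec, pair, q)$conservation, "similar")
  # hit ASP aligned to query ARG: score -2, other
  rec$resType <- "ASP"
  expect_equal(classifyConservation(rec, pair, q)$conservation, "other")
  # hit residue beyond the alignment: gap
  rec$resno <- 200L
  expect_equal(classifyConservation(rec, pair, q)$conservation, "gap")
})

test_that("achieved/maximum follow the quoted weights exactly", {
  cx <- makeComplex(list(id = "IX7", n_residues = 60, seed = 6,
    hbonds = data.frame(resno = c(5, 10, 15), dist = c(3, 3, 3)),
    contacts = data.frame(resno = c(20, 25), dist = c(3.6, 3.6))))
  st <- cx$structure; lig <- ligands(st)[[1]]
  hb <- forceClass(detectHBonds(st, lig),
                   c("identical", "similar", "gap"))
  ct <- forceClass(detectContacts(st, lig, hbonds = hb),
                   c("identical", "gap"))
  sc <- scoreLigand(hb, ct)
  # 3 + 2 - 1 + 2 - 1 = 5 over a ceiling of 3*3 + 2*2 = 13
  expect_equal(achievedScore(sc), 5)
  expect_equal(maximumScore(sc), 13)
  # no interactions: 0/0
  sc0 <- scoreLigand(hb[0, ], ct[0, ])
  expect_equal(achievedScore(sc0), 0)
  expect_equal(maximumScore(sc0), 0)
  # unclassified records are refused
  expect_error(scoreLigand(detectHBonds(st, lig), ct), "classified")
})

test_that("a self-hit achieves its maximum for any planted interaction set", {
  set.seed(44)
  for (k in 1:5) {
    resn <- sample(seq(4, 57, by = 3), 5)
    cx <- makeComplex(list(id = "IX8", n_residues = 60, seed = 10 + k,
      hbonds = data.frame(resno = resn[1:3], dist = runif(3, 2.8, 3.3)),
      contacts = data.frame(resno = resn[4:5], dist = runif(2, 3.5, 3.8))))
    st <- cx$structure; lig <- ligands(st)[[1]]
    pair <- smithWaterman(cx$truth$sequence, cx$truth$sequence)
    hb <- classifyConservation(detectHBonds(st, lig), pair,
                               cx$truth$sequence)
    ct <- classifyConservation(detectContacts(st, lig, hbonds = hb), pair,
                               cx$truth$sequence)
    sc <- scoreLigand(hb, ct)
    expect_equal(achievedScore(sc), maximumScore(sc))
    expect_true(all(hb$conservation == "identical"))
  }
})

test_that("upgrading a conservation class never decreases the score", {
  classes <- c("gap", "other", "similar", "identical")
  cx <- makeComplex(list(id = "IX9", n_residues = 30, seed = 20,
    hbonds = data.frame(resno = 5, dist = 3.0),
    contacts = data.frame(resno = 10, dist = 3.6)))
  st <- cx$structure; lig <- ligands(st)[[1]]
  hb <- detectHBonds(st, lig)
  ct <- detectContacts(st, lig, hbonds = hb)
  prevH <- -Inf; prevC <- -Inf
  for (cl in classes) {
    sH <- achievedScore(scoreLigand(forceClass(hb, cl), forceClass(ct, "gap")))
    sC <- achievedScore(scoreLigand(forceClass(hb, "gap"), forceClass(ct, cl)))
    expect_gte(sH, prevH); expect_gte(sC, prevC)
    prevH <- sH; prevC <- sC
    expect_lte(sH, maximumScore(scoreLigand(forceClass(hb, cl),
                                            forceClass(ct, "gap"))))
  }
})

test_that("the score is invariant under rigid transformation of the complex", {
  spec <- list(id = "IXA", n_residues = 40, seed = 21,
               hbonds = data.frame(resno = c(6, 14), dist = c(3.0, 3.2)),
               contacts = data.frame(resno = 22, dist = 3.7))
  cx <- makeComplex(spec)
  spec$rotation <- ligscout:::randomRotation(5)
  spec$translation <- c(-4, 11, 2)
  cxR <- makeComplex(spec)
  scoreOf <- function(cx) {
    st <- cx$structure; lig <- ligands(st)[[1]]
    pair <- smithWaterman(cx$truth$sequence, cx$truth$sequence)
    hb <- classifyConservation(detectHBonds(st, lig), pair,
                               cx$truth$sequence)
    ct <- classifyConservation(detectContacts(st, lig, hbonds = hb), pair,
                               cx$truth$sequence)
    sc <- scoreLigand(hb, ct)
    c(achievedScore(sc), maximumScore(sc))
  }
  expect_equal(scoreOf(cx), scoreOf(cxR))
})

test_that("cross-domain merge counts each residue once with union arithmetic", {
  cx <- makeComplex(list(id = "IXB", n_residues = 60, seed = 22,
    hbonds = data.frame(resno = c(5, 10, 15, 40), dist = c(3, 3, 3, 3)),
    contacts = data.frame(resno = c(20, 25, 45), dist = c(3.6, 3.6, 3.6))))
  st <- cx$structure; lig <- ligands(st)[[1]]
  hb <- detectHBonds(st, lig)
  ct <- detectContacts(st, lig, hbonds = hb)
  key <- c(structure_id = "IXB", het_code = "LIG", chain_id = "A",
           seq_num = "501")
  # domain 1 sees residues <= 30 (others gap): 3 hbonds + 2 contacts
  d1h <- forceClass(hb, ifelse(hb$resno <= 30, "identical", "gap"))
  d1c <- forceClass(ct, ifelse(ct$resno <= 30, "identical", "gap"))
  s1 <- scoreLigand(d1h, d1c, ligandKey = key)   # 3*3+2*2 -1-1 = 11 of 18
  # domain 2 sees residues > 30
  d2h <- forceClass(hb, ifelse(hb$resno > 30, "identical", "gap"))
  d2c <- forceClass(ct, ifelse(ct$resno > 30, "identical", "gap"))
  s2 <- scoreLigand(d2h, d2c, ligandKey = key)
  m <- mergeDomainScores(list(s1, s2))
  expect_equal(maximumScore(m), 3 * 4 + 2 * 3)
  expect_equal(achievedScore(m), maximumScore(m))  # best class survives
  # single-domain input unchanged
  expect_equal(achievedScore(mergeDomainScores(list(s1))),
               achievedScore(s1))
  # disjoint unions add: 5/13 + 4/5 = 9/18 style arithmetic
  sA <- scoreLigand(forceClass(hb[1:3, ], c("identical", "similar", "gap")),
                    forceClass(ct[1:2, ], c("identical", "gap")),
                    ligandKey = key)
  sB <- scoreLigand(hb[0, ], forceClass(ct[3, , drop = FALSE], "similar"),
                    ligandKey = key)
  mm <- mergeDomainScores(list(sA, sB))
  expect_equal(achievedScore(mm), 5 + 1)
  expect_equal(maximumScore(mm), 13 + 2)
  # mixed ligand identities are refused
  s3 <- scoreLigand(d1h, d1c, ligandKey = replace(key, 1, "OTHER"))
  expect_error(mergeDomainScores(list(s1, s3)), "different ligand")
})
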