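test_that("self-alignment is perfect and all-mismatch alignment is empty", {
  aln <- smithWaterman("MKVLLA", "MKVLLA")
  expect_equal(identityPct(aln), 100)
  cm <- alignedColumns(aln)
  expect_equal(cm[, "qpos"], 1:6, ignore_attr = TRUE)
  expect_equal(cm[, "hpos"], 1:6, ignore_attr = TRUE)
  # no positive-scoring residue pair: empty local alignment
  aln2 <- smithWaterman("AAAA", "CCCC")
  expect_equal(alignmentScore(aln2), 0)
  expect_equal(nrow(alignedColumns(aln2)), 0)
  expect_error(smithWaterman("", "MKV"), "non-empty")
  expect_error(smithWaterman("MKV", "MKV", gapOpen = -1), "positive")
})

test_that("identityPct(a, a) is 100 for random sequences", {
  set.seed(42)
  for (k in 1:10) {
    s <- randomAA(sample(5:40, 1))
    expect_equal(identityPct(smithWaterman(s, s)), 100)
  }
})

test_that("alignment score matches the brute-force DP oracle on random 12-mers", {
  mat <- loadSubstitutionMatrix("BLOSUM62")
  set.seed(7)
  for (k in 1:30) {
    a <- randomAA(12); b <- randomAA(12)
    expect_equal(smithWaterman(a, b)@score, swOracle(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("hit ranking is a stable total order with the query first", {
  set.seed(11)
  q <- randomAA(60)
  db <- c(self = q, other = randomAA(60), third = randomAA(60))
  hits <- rankHits(q, db, n = 20)
  expect_equal(hits[[1]]@hitId, "self")
  expect_equal(length(hits), 3)           # n larger than db: all returned
  expect_equal(length(rankHits(q, db, n = 2)), 2)
  expect_equal(length(rankHits(q, character(0))), 0)
  # re-running yields an identical ranking (ties broken by id)
  ids1 <- vapply(hits, function(p) p@hitId, "")
  ids2 <- vapply(rankHits(q, db, n = 20), function(p) p@hitId, "")
  expect_identical(ids1, ids2)
})

test_that("planted identity gradient ranks homologs in identity order", {
  set.seed(5)
  q <- randomAA(100)
  db <- c(h90 = as.character(makeHomolog(q, 90, seed = 1)),
          h60 = as.character(makeHomolog(q, 60, seed = 2)),
          h30 = as.character(makeHomolog(q, 30, seed = 3)))
  hits <- rankHits(q, db)
  expect_equal(vapply(hits, function(p) p@hitId, ""),
               c("h90", "h60", "h30"))
  idents <- vapply(hits, identityPct, 0)
  expect_true(all(diff(idents) < 0))
})

test_that("sequence database holds full chains plus (split) domain entries", {
  seq <- randomAA(331)
  st <- makeComplex(list(id = "sdb1", sequence = seq))$structure
  ann <- data.frame(structure_id = "sdb1", chain_id = "A",
                    domain_id = c("D1", "D2"),
                    segments = c("6-57,177-331", "58-176"),
                    kind = "cath_like", stringsAsFactors = FALSE)
  db <- buildSequenceDb(st, ann)
  expect_equal(db$kind, c("full_chain", "domain", "domain"))
  # split domain concatenates its two segments: 52 + 155 = 207 residues
  expect_equal(nchar(db$sequence[db$entry_id == "sdb1_A:D1"]), 207)
  expect_equal(nchar(db$sequence[db$entry_id == "sdb1_A:D2"]), 119)
  expect_true(sum(nchar(db$sequence[db$kind == "domain"])) <=
                nchar(db$sequence[db$kind == "full_chain"]))
  # no annotations: full-chain entry only
  expect_equal(buildSequenceDb(st)$kind, "full_chain")
  # unknown chain skipped with warning
  bad <- data.frame(structure_id = "sdb1", chain_id = "Z",
                    domain_id = "DX", segments = "1-10", kind = "cath_like")
  expect_warning(db2 <- buildSequenceDb(st, bad), "unknown chain")
  expect_equal(nrow(db2), 1)
})

test_that("query-anchored MSA stacks pairwise alignments on the query", {
  set.seed(9)
  q <- randomAA(80)
  p1 <- smithWaterman(q, q, queryId = "q", hitId = "h1")
  p2 <- smithWaterman(q, q, queryId = "q", hitId = "h2")
  msa <- buildQueryAnchoredMSA(list(p1, p2), queryLen = 80)
  expect_identical(msa$rows$h1, msa$rows$h2)   # identical hits, same rows
  expect_equal(msa$rows$h1, 1:80)
  # single pair: row equals the pairwise mapping
  one <- buildQueryAnchoredMSA(list(p1), queryLen = 80)
  expect_equal(one$rows$h1, 1:80)
  bad <- smithWaterman(q, q, queryId = "other", hitId = "h3")
  expect_error(buildQueryAnchoredMSA(list(p1, bad)), "same query id")
})

test_that("homolog rows agree with the planted ungapped correspondence", {
  set.seed(13)
  q <- randomAA(120)
  hitIds <- c("m90", "m75", "m60")
  pairs <- list()
  for (k in seq_along(hitIds)) {
    h <- as.character(makeHomolog(q, c(90, 75, 60)[k], seed = k))
    pairs[[k]] <- smithWaterman(q, h, queryId = "q", hitId = hitIds[k])
  }
  msa <- buildQueryAnchoredMSA(pairs, queryLen = 120)
  # homologs are ungapped mutants: the true correspondence is identity
  for (row in msa$rows) {
    mapped <- !is.na(row)
    expect_gte(mean(row[mapped] == which(mapped)), 0.95)
  }
})

test_that("NCBI-format matrix files load with correct values", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# tiny demo matrix", "   A  R  N",
               "A  4 -1 -2", "R -1  5  0", "N -2  0  6"), tf)
  m <- loadSubstitutionMatrix(tf)
  expect_equal(m["A", "A"], 4)
  expect_equal(m["R", "N"], 0)
  expect_equal(m["N", "N"], 6)
})
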