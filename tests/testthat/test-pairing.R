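test_that("identical sequences give one full-length perfect hit", {
  set.seed(1)
  s <- randSeq(1000)
  h <- allVsAllHits(c(a = s), c(b = s))
  expect_identical(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$alignedLength, 1000L)
  expect_equal(h$score, 1000)
  expect_equal(c(h$qstart, h$qend), c(1L, 1000L))
})

test_that("sequences with no shared 11-mer produce no hit", {
  a <- c(x = strrep("A", 300))
  b <- c(y = strrep("CT", 150))
  expect_identical(nrow(allVsAllHits(a, b, minSeeds = 1L)), 0L)
  expect_error(allVsAllHits(a, Biostrings::DNAStringSet()), "empty")
})

test_that("planted mismatches give the Smith-Waterman identity", {
  set.seed(2)
  s <- randSeq(1000)
  ch <- strsplit(s, "")[[1]]
  at <- sort(sample(50:950, 10))
  for (p in at) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  m <- paste(ch, collapse = "")
  h <- allVsAllHits(c(a = s), c(b = m))
  expect_identical(nrow(h), 1L)
  expect_equal(h$identity, 99.0, tolerance = 0.001)
  # independent check against the C Smith-Waterman in Biostrings (a
  # different code path from the package's seed-and-extend scan)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s), Biostrings::DNAString(m), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      1, -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  expect_equal(h$score, Biostrings::score(pa))
  expect_equal(h$identity, Biostrings::pid(pa, type = "PID1"),
               tolerance = 1e-6)
})

test_that("reciprocal-best selection follows the toy score matrix", {
  # c1's best is s1, but s1's best is c2: c1 must stay unpaired
  hitsAB <- data.frame(
    query_id = c("c1", "c2"), subject_id = c("s1", "s1"),
    score = c(50, 80), identity = c(95, 99), alignedLength = c(500, 500),
    qstart = 1, qend = 500, sstart = 1, send = 500)
  hitsBA <- data.frame(
    query_id = "s1", subject_id = "c2",
    score = 80, identity = 99, alignedLength = 500,
    qstart = 1, qend = 500, sstart = 1, send = 500)
  rb <- reciprocalBestPairs(hitsAB, hitsBA)
  expect_identical(rb$a_id, "c2")
  expect_identical(rb$b_id, "s1")
  # brute-force RBH over the explicit matrix agrees
  best_c1 <- "s1"; best_s1 <- "c2"
  expect_false(best_s1 == "c1" && best_c1 == "s1")
})

test_that("best-hit tie-breaking is score, length, identity, then id", {
  base <- data.frame(qstart = 1, qend = 10, sstart = 1, send = 10)
  h <- cbind(data.frame(
    query_id = "q", subject_id = c("sB", "sA", "sC"),
    score = c(50, 50, 50), identity = c(90, 90, 95),
    alignedLength = c(400, 400, 300)), base)
  b <- hybridASE:::.bestHits(h)
  # equal score and length: higher identity only matters at equal length;
  # here sB/sA tie on everything, so lexicographic id wins among them,
  # but sC has shorter length so the 400-bp hits rank first
  expect_identical(b$subject_id, "sA")
})

test_that("pairing recovers all true pairs and is one-to-one", {
  cfg <- SimConfig(seed = 6, nGenes = 10, lengthRange = c(500L, 1500L))
  sim <- simulateTranscriptomes(cfg)
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  pi <- pairInfo(tp)
  expect_identical(nrow(pi), 10L)
  expect_identical(sub("^cave_", "", pi$cave_id),
                   sub("^surf_", "", pi$surface_id))
  expect_false(anyDuplicated(pi$cave_id) > 0)
  expect_false(anyDuplicated(pi$surface_id) > 0)
  # label symmetry: swapping the input roles yields the same matching
  tp2 <- makeTranscriptPairs(sim$surface, sim$cave)
  pi2 <- pairInfo(tp2)
  expect_setequal(paste(pi$cave_id, pi$surface_id),
                  paste(pi2$surface_id, pi2$cave_id))
})

test_that("transcripts present in only one transcriptome drop out", {
  cfg <- SimConfig(seed = 14, nGenes = 10, unpairedFraction = 0.3)
  sim <- simulateTranscriptomes(cfg)
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  unpaired <- sim$truth@genes$gene_id[!sim$truth@genes$paired]
  expect_gt(length(unpaired), 0)
  expect_identical(nrow(pairInfo(tp)),
                   sum(sim$truth@genes$paired))
  expect_false(any(paste0("surf_", unpaired) %in% pairInfo(tp)$pair_id))
})

test_that("trimming cuts unaligned extensions and offsets the map", {
  set.seed(4)
  core <- randSeq(600)
  ext <- randSeq(200)
  tr <- trimToAlignment(paste0(ext, core), core, minLength = 400L)
  expect_identical(tr$caveStart, 201L)
  expect_identical(tr$surfStart, 1L)
  expect_identical(tr$caveTrimmed, core)
  m <- tr$map
  expect_true(all(diff(m[, "cave"]) > 0))
  expect_true(all(diff(m[, "surface"]) > 0))
  # identity trim when sequences are identical
  tr2 <- trimToAlignment(core, core, minLength = 400L)
  expect_identical(tr2$caveTrimmed, core)
  expect_identical(tr2$caveStart, 1L)
})

test_that("short aligned regions are rejected at the 400 bp threshold", {
  set.seed(5)
  s <- randSeq(350)
  expect_warning(tr <- trimToAlignment(s, s), "pair rejected")
  expect_null(tr)
})

test_that("coordinate maps skip deleted positions, matching a DP oracle", {
  set.seed(16)
  a <- randSeq(450)
  bch <- strsplit(a, "")[[1]]
  b <- paste(bch[-(201:203)], collapse = "")   # 3-bp deletion
  tr <- trimToAlignment(a, b, minLength = 400L)
  m <- tr$map
  # positions after the deletion are shifted by 3 on the deleted side
  expect_true(all(m[m[, "cave"] <= 200, "cave"] ==
                    m[m[, "cave"] <= 200, "surface"]))
  hi <- m[m[, "cave"] >= 204, , drop = FALSE]
  expect_true(all(hi[, "cave"] == hi[, "surface"] + 3))
  orc <- swOracle(a, b)
  expect_equal(tr$score, orc$score)
  keep <- m[, "cave"] <= 200 | m[, "cave"] >= 204
  expect_true(all(paste(m[keep, 1], m[keep, 2]) %in%
                    paste(orc$map[, "a"], orc$map[, "b"])))
})

test_that("self-similarity filter removes planted duplicates only", {
  cfg <- SimConfig(seed = 23, nGenes = 8, duplicatedFraction = 0.15)
  sim <- simulateTranscriptomes(cfg)
  dup <- sim$truth@duplicates
  expect_gt(nrow(dup), 0)
  side <- dup$side[1]
  seqs <- if (side == "cave") sim$cave else sim$surface
  res <- selfSimilarityFilter(seqs)
  flagged <- sub("^(cave|surf)_", "", res$removed$id)
  flagged <- sub("_dup$", "", sub("^(cave|surf)_", "", flagged))
  expect_true(all(flagged %in% dup$gene_id))
  expect_true(any(sub("^(cave|surf)_", "", res$removed$id) %in%
                    dup$gene_id))
  # a short (< 150 bp) high-identity overlap does not trigger removal
  set.seed(9)
  s1 <- randSeq(600); s2 <- randSeq(600)
  frag <- substr(s1, 1, 100)
  s2 <- paste0(frag, substr(s2, 101, 600))
  res2 <- selfSimilarityFilter(c(g1 = s1, g2 = s2), minSeeds = 1L)
  expect_identical(nrow(res2$removed), 0L)
})

test_that("copy-number filter applies the more-than-9 rule per side", {
  ann <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    annotation_id = c("X", "Y", NA, "Z"),
    copiesCave = c(10L, 9L, 1L, 2L),
    copiesSurface = c(1L, 9L, 1L, 12L))
  res <- copyNumberFilter(c("a", "b", "c", "d"), ann)
  expect_setequal(res$kept, c("b", "c"))     # 9 copies is the boundary
  expect_setequal(res$removed$gene_id, c("a", "d"))
})

test_that("external outfmt-6 hit tables are ingested", {
  f <- tempfile(fileext = ".tsv")
  writeLines("c1\ts1\t99.5\t800\t1\t800\t5\t804\t780", f)
  h <- readHitsTable(f)
  expect_identical(h$query_id, "c1")
  expect_equal(h$score, 780)
  expect_equal(h$sstart, 5L)
  rb <- reciprocalBestPairs(h, data.frame(
    query_id = "s1", subject_id = "c1", score = 780, identity = 99.5,
    alignedLength = 800, qstart = 5, qend = 804, sstart = 1, send = 800))
  expect_identical(nrow(rb), 1L)
})

test_that("combined reference FASTA carries both alleles per pair", {
  cfg <- SimConfig(seed = 33, nGenes = 3)
  sim <- simulateTranscriptomes(cfg)
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  f <- tempfile(fileext = ".fasta")
  n <- writeCombinedFasta(tp, f)
  expect_identical(n, 6L)
  back <- Biostrings::readDNAStringSet(f)
  expect_setequal(names(back),
                  c(paste0(pairIds(tp), "|cave"),
                    paste0(pairIds(tp), "|surface")))
})
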