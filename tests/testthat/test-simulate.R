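test_that("zero-SNP genes yield identical cave and surface transcripts", {
  cfg <- SimConfig(seed = 5, nGenes = 1, snpRange = c(0L, 0L),
                   lengthRange = c(500L, 600L))
  sim <- simulateTranscriptomes(cfg)
  expect_identical(as.character(sim$cave[[1]]),
                   as.character(sim$surface[[1]]))
  expect_equal(nrow(sim$truth@snps), 0L)
})

test_that("the seed fully determines transcriptomes and reads", {
  cfg <- SimConfig(seed = 42, nGenes = 5, meanDepth = 100)
  s1 <- simulateTranscriptomes(cfg)
  s2 <- simulateTranscriptomes(cfg)
  expect_identical(as.character(s1$cave), as.character(s2$cave))
  expect_identical(as.character(s1$surface), as.character(s2$surface))
  expect_identical(s1$truth@snps, s2$truth@snps)
  t1 <- simulateF2Cohort(cfg, s1$truth)
  t2 <- simulateF2Cohort(cfg, s2$truth)
  expect_identical(t1@f2$geneGenotypes, t2@f2$geneGenotypes)
  sam <- sampleSheet(cfg, t1)[1, ]
  r1 <- simulateSampleReads(cfg, t1, sam)
  r2 <- simulateSampleReads(cfg, t2, sam)
  expect_identical(r1$genes, r2$genes)
})

test_that("planted SNP counts respect the configured range", {
  cfg <- SimConfig(seed = 9, nGenes = 50, snpRange = c(3L, 12L))
  sim <- simulateTranscriptomes(cfg)
  perGene <- table(factor(sim$truth@snps$gene_id,
                          levels = sim$truth@genes$gene_id))
  expect_true(all(perGene >= 3 & perGene <= 12))
  # planted bases really differ at every SNP
  sn <- sim$truth@snps
  expect_true(all(sn$caveBase != sn$surfaceBase))
})

test_that("F1 allele shares concentrate around the planted fraction", {
  cfg <- SimConfig(seed = 7, nGenes = 1, lengthRange = c(900L, 1000L),
                   snpRange = c(8L, 8L), meanDepth = 10000,
                   dispersion = 0, errorRate = 0,
                   aseGenes = data.frame(gene = 1, caveFraction = 0.8))
  sim <- simulateTranscriptomes(cfg)
  truth <- simulateF2Cohort(cfg, sim$truth)
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  gm <- stats::setNames(list(truth@genes$gene_id[1]),
                        pairInfo(tp)$pair_id[1])
  sl <- studySiteList(tp, gm)
  reads <- simulateSampleReads(cfg, truth, list(sample_id = "F1_1",
                                                generation = "F1",
                                                stage = "late"))
  ab <- quantifySample(reads, sl)$abundance
  share <- ab$zCave / (ab$zCave + ab$zSurface)
  expect_lt(abs(share - 0.8), 0.02)
})

test_that("error-free F2 homozygotes emit no opposite-allele fragments", {
  cfg <- SimConfig(seed = 13, nGenes = 3, lengthRange = c(500L, 700L),
                   meanDepth = 300, errorRate = 0,
                   linkedBlocks = list(list(phenotype = "unpigmented",
                                            genes = 1:3, marker = "M")),
                   f2PhenotypeSpec = c(unpigmented = 2L), nF2 = 6L)
  sim <- simulateTranscriptomes(cfg)
  truth <- simulateF2Cohort(cfg, sim$truth)
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  pg <- stats::setNames(truth@genes$gene_id,
                        paste0("surf_", truth@genes$gene_id))
  gm <- as.list(pg[pairInfo(tp)$pair_id])
  names(gm) <- pairInfo(tp)$pair_id
  sl <- studySiteList(tp, gm)
  cc <- truth@f2$individuals[truth@f2$blockGenotypes["unpigmented", ] ==
                               "CC"][1]
  reads <- simulateSampleReads(cfg, truth,
    list(sample_id = cc, generation = "F2", stage = "adult",
         individual_id = cc))
  ab <- quantifySample(reads, sl)$abundance
  expect_true(all(ab$zSurface == 0))
  expect_true(all(ab$zCave > 0))
})

test_that("unconditioned F2 block genotypes segregate 1:2:1", {
  cfg <- SimConfig(seed = 3, nGenes = 1, nF2 = 100000L,
                   linkedBlocks = list(list(phenotype = "trait",
                                            genes = 1, marker = "M")))
  sim <- simulateTranscriptomes(cfg)
  truth <- simulateF2Cohort(cfg, sim$truth)
  g <- truth@f2$blockGenotypes["trait", ]
  expect_lt(abs(mean(g == "CC") - 0.25), 0.005)
  expect_lt(abs(mean(g == "SC") - 0.50), 0.006)
})

test_that("phenotype conditioning fixes the CC count exactly", {
  for (seed in c(1, 2, 3, 17, 99)) {
    cfg <- SimConfig(seed = seed, nGenes = 2,
                     linkedBlocks = list(list(phenotype = "unpigmented",
                                              genes = 1:2, marker = "M")),
                     f2PhenotypeSpec = c(unpigmented = 3L), nF2 = 15L)
    truth <- simulateF2Cohort(cfg, simulateTranscriptomes(cfg)$truth)
    expect_identical(
      sum(truth@f2$blockGenotypes["unpigmented", ] == "CC"), 3L)
    expect_identical(
      sum(truth@f2$phenotypes$pigment_class == "unpigmented"), 3L)
  }
})

test_that("genes of one block share every individual's genotype", {
  cfg <- SimConfig(seed = 21, nGenes = 4,
                   linkedBlocks = list(list(phenotype = "trait",
                                            genes = c(2, 4),
                                            marker = "M")))
  truth <- simulateF2Cohort(cfg, simulateTranscriptomes(cfg)$truth)
  gg <- truth@f2$geneGenotypes
  expect_identical(gg["g0002", ], gg["g0004", ])
})

test_that("infeasible phenotype specs are rejected", {
  cfg <- SimConfig(seed = 1, nGenes = 1,
                   linkedBlocks = list(list(phenotype = "unpigmented",
                                            genes = 1, marker = "M")),
                   f2PhenotypeSpec = c(unpigmented = 3L), nF2 = 5L)
  cfg2 <- cfg
  cfg2@f2PhenotypeSpec <- c(unpigmented = 6L)
  expect_error(validObject(cfg2), "more CC individuals")
  expect_error(simulateSampleReads(cfg,
    simulateF2Cohort(cfg, simulateTranscriptomes(cfg)$truth),
    list(sample_id = "x", generation = "F3", stage = "late")),
    "unknown sample generation")
})

test_that("sequence mode materialises reads consistent with the alleles", {
  cfg <- SimConfig(seed = 31, nGenes = 2, lengthRange = c(500L, 600L),
                   meanDepth = 50, errorRate = 0)
  sim <- simulateTranscriptomes(cfg)
  truth <- simulateF2Cohort(cfg, sim$truth)
  registerAlleleSeqs(sim)
  reads <- simulateSampleReads(cfg, truth,
    list(sample_id = "cave_late_1", generation = "P_cave",
         stage = "late"), mode = "sequence")
  g <- names(reads$genes)[1]
  rec <- reads$genes[[g]]
  cave <- as.character(sim$cave[[paste0("cave_", g)]])
  # error-free cave-parental reads are exact substrings of the cave allele
  ok <- vapply(seq_len(rec$n), function(i)
    substr(cave, rec$starts[i], rec$starts[i] + 99L) == rec$seqs[i],
    logical(1))
  expect_true(all(ok))
  fq <- tempfile(fileext = ".fastq")
  n <- writeSampleFastq(reads, fq)
  lines <- readLines(fq)
  expect_identical(length(lines), 4L * n)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
})

test_that("site-mode and sequence-mode quantification agree", {
  cfg <- SimConfig(seed = 8, nGenes = 3, lengthRange = c(500L, 700L),
                   meanDepth = 400, errorRate = 0.002,
                   aseGenes = data.frame(gene = 1, caveFraction = 0.8))
  sim <- simulateTranscriptomes(cfg)
  truth <- simulateF2Cohort(cfg, sim$truth)
  registerAlleleSeqs(sim)
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  pg <- stats::setNames(truth@genes$gene_id,
                        paste0("surf_", truth@genes$gene_id))
  gm <- as.list(pg[pairInfo(tp)$pair_id])
  names(gm) <- pairInfo(tp)$pair_id
  sl <- studySiteList(tp, gm)
  sam <- list(sample_id = "F1_1", generation = "F1", stage = "late")
  rSites <- simulateSampleReads(cfg, truth, sam, mode = "sites")
  rSeq <- simulateSampleReads(cfg, truth, sam, mode = "sequence")
  aSites <- quantifySample(rSites, sl)$abundance
  gmRev <- as.list(stats::setNames(pairInfo(tp)$pair_id, unlist(gm)))
  aSeq <- quantifySampleSeq(rSeq, tp, gmRev)$abundance
  # same RNG seed: identical fragment starts and allele draws, so the
  # two representations must classify identically
  aSeq <- aSeq[match(aSites$gene, aSeq$gene), ]
  expect_equal(aSites$nCave, aSeq$nCave)
  expect_equal(aSites$nSurface, aSeq$nSurface)
  expect_equal(aSites$zCave, aSeq$zCave)
})
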