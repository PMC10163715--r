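test_that("fixed-SNP calling applies the 100%-frequency / >=5 rules", {
  mkSites <- function(cCounts, sCounts, refC, refS) {
    s <- data.frame(posCave = seq_along(refC), posSurface = seq_along(refC),
                    refCave = refC, refSurface = refS)
    cbind(s, stats::setNames(as.data.frame(cCounts),
                             paste0("c", c("A", "C", "G", "T"))),
          stats::setNames(as.data.frame(sCounts),
                          paste0("s", c("A", "C", "G", "T"))))
  }
  # site 1: 7C cave / 9T surface -> diagnostic
  # site 2: 4C cave (support < 5) but surface-fixed 9T -> kept through
  #         the surface side (the defining side carries the support rule)
  # site 3: both populations fixed for the same base -> shared, removed
  # site 4: neither population unanimous -> rejected
  cC <- rbind(c(0, 7, 0, 0), c(0, 4, 0, 0), c(8, 0, 0, 0),
              c(0, 6, 1, 0))
  sC <- rbind(c(0, 0, 0, 9), c(0, 0, 0, 9), c(8, 0, 0, 0),
              c(1, 0, 0, 6))
  sites <- mkSites(cC, sC, refC = c("C", "C", "A", "C"),
                   refS = c("T", "T", "G", "T"))
  out <- callFixedSNPs(sites)
  expect_identical(out$posCave, c(1L, 2L))
  expect_identical(out$caveBase, c("C", "C"))
  expect_identical(out$surfaceBase, c("T", "T"))
  # with the surface side below support too, site 2 disappears (4C
  # cave support stays below the 5-observation rule)
  sites2 <- sites
  sites2[2, paste0("s", c("A", "C", "G", "T"))] <- c(0, 0, 0, 4)
  expect_identical(callFixedSNPs(sites2)$posCave, 1L)
  # boundary: exactly 5 observations qualify ("five or more")
  sites3 <- sites[1, , drop = FALSE]
  sites3[1, paste0("c", c("A", "C", "G", "T"))] <- c(0, 5, 0, 0)
  expect_identical(nrow(callFixedSNPs(sites3)), 1L)
})

test_that("planted SNPs are recovered exactly from error-free pileups", {
  cfg <- SimConfig(seed = 41, nGenes = 1, lengthRange = c(600L, 700L),
                   snpRange = c(6L, 6L), meanDepth = 400, errorRate = 0,
                   dispersion = 0)
  sim <- simulateTranscriptomes(cfg)
  truth <- simulateF2Cohort(cfg, sim$truth)
  registerAlleleSeqs(sim)
  g <- truth@genes$gene_id[1]
  L <- truth@genes$length[1]
  mkPile <- function(gen) {
    reads <- simulateSampleReads(cfg, truth,
      list(sample_id = paste0(gen, "_r"), generation = gen,
           stage = "late"), mode = "sequence")
    rec <- reads$genes[[g]]
    pileupCounts(rec$seqs, rec$starts, L)
  }
  sites <- pileupSiteTable(mkPile("P_cave"), mkPile("P_surface"),
                           as.character(sim$cave[[paste0("cave_", g)]]),
                           as.character(sim$surface[[paste0("surf_", g)]]))
  out <- callFixedSNPs(sites)
  planted <- truth@snps[truth@snps$gene_id == g, ]
  expect_identical(sort(out$posCave), sort(planted$posCave))
  m <- match(out$posCave, planted$posCave)
  expect_identical(out$caveBase, planted$caveBase[m])
  expect_identical(out$surfaceBase, planted$surfaceBase[m])
})

test_that("spanning-SNP selection maximizes positional spread", {
  # three SNPs: all retained
  expect_identical(selectSpanningSNPs(c(10, 50, 90)), 1:3)
  # ten evenly spaced SNPs on [0, 900]: first, last, and the quantile
  # neighbours (ties broken leftmost: 450 -> 400)
  pos <- seq(0, 900, by = 100)[1:10]
  sel <- selectSpanningSNPs(pos)
  expect_identical(pos[sel], c(0, 200, 400, 700, 900))
  # a single SNP is kept (the gene is flagged downstream)
  expect_identical(selectSpanningSNPs(42), 1L)
  expect_error(selectSpanningSNPs(numeric()), "at least one")
  # unsorted input comes back in positional order
  expect_identical(selectSpanningSNPs(c(90, 10, 50)), c(2L, 3L, 1L))
})

test_that("allele counting partitions reads by observed base", {
  snps <- data.frame(posCave = 5L, posSurface = 5L,
                     caveBase = "A", surfaceBase = "G")
  seqs <- c(rep("AAAAA", 30), rep("AAAAG", 10), rep("AAAAT", 2))
  out <- countAlleles(seqs, rep(1L, 42), snps, "cave")
  expect_identical(out$nCave, 30L)
  expect_identical(out$nSurface, 10L)
  expect_identical(out$nOther, 2L)       # third-allele bases excluded
  # positions beyond the reference are skipped with a warning
  snps2 <- rbind(snps, data.frame(posCave = 99L, posSurface = 99L,
                                  caveBase = "A", surfaceBase = "G"))
  expect_warning(out2 <- countAlleles(seqs, rep(1L, 42), snps2, "cave",
                                      L = 10L), "outside")
  expect_identical(nrow(out2), 1L)
})

test_that("dual-reference counts agree on indel-free data", {
  cfg <- SimConfig(seed = 43, nGenes = 2, meanDepth = 200,
                   aseGenes = data.frame(gene = 1:2, caveFraction = 0.5))
  sim <- simulateTranscriptomes(cfg)
  truth <- simulateF2Cohort(cfg, sim$truth)
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  pg <- stats::setNames(truth@genes$gene_id,
                        paste0("surf_", truth@genes$gene_id))
  gm <- as.list(pg[pairInfo(tp)$pair_id])
  names(gm) <- pairInfo(tp)$pair_id
  sl <- studySiteList(tp, gm)
  reads <- simulateSampleReads(cfg, truth,
    list(sample_id = "F1_1", generation = "F1", stage = "late"))
  q <- quantifySample(reads, sl)
  g <- truth@genes$gene_id[1]
  planted <- truth@snps[truth@snps$gene_id == g, ]
  snps <- data.frame(posCave = planted$posCave,
                     posSurface = planted$posSurface,
                     caveBase = planted$caveBase,
                     surfaceBase = planted$surfaceBase)
  cc <- siteAlleleCounts(q$siteCounts, g, snps, "cave")
  cs <- siteAlleleCounts(q$siteCounts, g, snps, "surface")
  expect_identical(cc$nCave, cs$nCave)
  expect_identical(cc$nSurface, cs$nSurface)
})

test_that("exact binomial p-values match the closed forms", {
  p <- hybridASE:::.binomTwoSided
  expect_equal(p(20, 20), 2 * 0.5^20)
  expect_equal(p(10, 20), 1)
  expect_equal(p(18, 20), 422 / 1048576)
  expect_equal(p(0, 0), 1)
  # agreement with stats::binom.test across a grid
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:80, 1); x <- sample(0:n, 1)
    expect_equal(p(x, n), binom.test(x, n, 0.5)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the gene decision needs two SNPs significant everywhere", {
  mk <- function(gene, snp, sample, ref, nc, ns)
    data.frame(gene = gene, snp = snp, sample = sample, reference = ref,
               nCave = nc, nSurface = ns)
  grid <- expand.grid(snp = c(100, 200), sample = paste0("F1_", 1:3),
                      reference = c("cave", "surface"))
  good <- mk("gA", grid$snp, grid$sample, grid$reference, 55, 5)
  res <- binomialDecision(good)
  expect_true(res$decisions$confirmed)
  expect_identical(res$decisions$nSigSNPs, 2L)
  # one hybrid balanced at one SNP: that SNP no longer counts
  bad <- good
  bad[bad$snp == 100 & bad$sample == "F1_2" & bad$reference == "cave",
      c("nCave", "nSurface")] <- c(30, 30)
  res2 <- binomialDecision(bad)
  expect_false(res2$decisions$confirmed)
  expect_identical(res2$decisions$nSigSNPs, 1L)
  # single-SNP genes are flagged, not confirmed
  single <- mk("gB", 100, paste0("F1_", 1:3), "cave", 60, 0)
  res3 <- binomialDecision(single)
  expect_false(res3$decisions$confirmed)
  expect_match(res3$decisions$reason, "fewer than 2")
})

test_that("per-SNP rejection is conservative under balanced alleles", {
  set.seed(11)
  n <- 10000
  x <- rbinom(n, 60, 0.5)
  p <- hybridASE:::.binomTwoSided(x, rep(60L, n))
  expect_lte(mean(p < 0.05), 0.05)
})
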