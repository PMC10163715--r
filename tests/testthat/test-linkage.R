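test_that("genotype calls follow the strict ratio cutoffs", {
  ratio <- matrix(c(0.2, 0.5, 1.4, 0, Inf, NaN), 1,
                  dimnames = list("g", paste0("i", 1:6)))
  calls <- callGenotypes(ratio)
  expect_identical(unname(calls[1, ]),
                   c("CC", NA, "S_", "CC", "S_", NA))
  # tighter cutoffs only widen the NA band
  c2 <- callGenotypes(ratio, 0.3, 0.7)
  expect_identical(unname(c2[1, 2]), NA_character_)
  expect_identical(unname(c2[1, 1]), "CC")
  expect_error(callGenotypes(ratio, 0.7, 0.3))
  # from an AlleleCounts object the ratio is surface over cave
  ac <- makeAC(matrix(c(100, 10), 1, dimnames = list("g", c("a", "b"))),
               matrix(c(20, 100), 1, dimnames = list("g", c("a", "b"))),
               c("F2", "F2"))
  expect_identical(unname(callGenotypes(ac)[1, ]), c("CC", "S_"))
})

test_that("pattern scan demands the exact genotype pattern", {
  ids <- sprintf("i%02d", 1:15)
  calls <- matrix("S_", 3, 15, dimnames = list(paste0("g", 1:3), ids))
  cc <- ids[1:3]
  calls["g1", cc] <- "CC"
  calls["g2", cc[1:2]] <- "CC"            # 2 of 3 only
  calls["g3", ] <- "S_"; calls["g3", cc] <- "CC"
  calls["g3", ids[10]] <- NA              # NA blocks the match
  pat <- list(phenotype = "p", cc = cc, s = setdiff(ids, cc),
              excluded = character())
  expect_identical(patternScan(calls, pat), "g1")
  expect_error(patternScan(calls, list(phenotype = "p", cc = "zz",
                                       s = ids, excluded = character())),
               "unknown individuals")
})

test_that("the exhaustive null enumerates every assignment", {
  ids <- sprintf("i%02d", 1:15)
  calls <- matrix("S_", 2, 15, dimnames = list(c("g1", "g2"), ids))
  null <- permutationNull(calls, 3, ids)
  expect_identical(length(null$counts), 455L)
  expect_equal(length(null$counts), choose(15, 3))
  expect_identical(dim(null$assignments), c(3L, 455L))
  expect_identical(length(permutationNull(calls, 1, ids[1:2])$counts), 2L)
  expect_error(permutationNull(calls, 15, ids), "smaller")
  expect_error(permutationNull(calls, 7, ids, cap = 100), "cap")
})

test_that("scan and null agree at the observed assignment", {
  set.seed(5)
  ids <- sprintf("i%02d", 1:10)
  calls <- matrix(sample(c("CC", "S_", NA), 200, TRUE,
                         prob = c(0.3, 0.6, 0.1)),
                  20, 10, dimnames = list(paste0("g", 1:20), ids))
  cc <- ids[c(2, 5, 8)]
  pat <- list(phenotype = "p", cc = cc, s = setdiff(ids, cc),
              excluded = character())
  null <- permutationNull(calls, 3, ids)
  idx <- observedIndex(null, cc)
  expect_identical(null$counts[idx], length(patternScan(calls, pat)))
})

test_that("permutation counts match a brute-force re-implementation", {
  set.seed(6)
  for (rep in 1:3) {
    nInd <- sample(4:6, 1); nGenes <- sample(5:20, 1)
    k <- sample(1:(nInd - 1), 1)
    ids <- sprintf("i%02d", seq_len(nInd))
    calls <- matrix(sample(c("CC", "S_", NA), nInd * nGenes, TRUE,
                           prob = c(0.35, 0.55, 0.10)),
                    nGenes, nInd,
                    dimnames = list(paste0("g", seq_len(nGenes)), ids))
    null <- permutationNull(calls, k, ids)
    expect_identical(null$counts, bruteForceNull(calls, k, ids))
  }
})

test_that("the signed-rank comparison matches an independent formula", {
  set.seed(7)
  counts <- rpois(455, 2)
  counts[1] <- 25
  cmp <- wilcoxonCompare(counts, 25)
  expect_equal(cmp$wilcoxonP, signedRankOracle(counts, 25),
               tolerance = 1e-10)
  expect_equal(cmp$empiricalP, mean(counts >= 25))
  # maximal separation: all permutations at zero
  z <- rep(0L, 455)
  cmp2 <- wilcoxonCompare(z, 300)
  expect_lt(cmp2$wilcoxonP, 1e-10)
  expect_equal(cmp2$empiricalP, 0)
  # observed at the median leaves the test non-significant
  sym <- c(rep(0, 200), rep(10, 200), rep(5, 55))
  cmp3 <- wilcoxonCompare(sym, 5)
  expect_gt(cmp3$wilcoxonP, 0.5)
  expect_warning(cmp4 <- wilcoxonCompare(rep(3, 10), 3), "degenerate|equal")
  expect_equal(cmp4$wilcoxonP, 1)
})

test_that("pattern probabilities follow (1/4)^k (3/4)^m", {
  expect_equal(patternProbability(0, 0), 1)
  expect_equal(patternProbability(1, 0), 0.25)
  expect_equal(patternProbability(0, 1), 0.75)
  expect_equal(patternProbability(2, 3), 0.25^2 * 0.75^3)
  expect_error(patternProbability(-1, 2), "non-negative")
})

test_that("candidate post-filter keeps annotated single-copy genes", {
  genes <- c(paste0("u", 1:25), "na1", "na2", "na3", "d1", "d2")
  ann <- data.frame(
    gene_id = genes,
    annotation_id = c(paste0("A", 1:25), NA, NA, NA, "DUP", "DUP"))
  out <- postfilterCandidates(genes, ann)
  expect_identical(length(out$kept), 25L)
  expect_setequal(out$removed$gene_id[out$removed$reason ==
                                        "unannotated"],
                  c("na1", "na2", "na3"))
  expect_setequal(out$removed$gene_id[grepl("not unique",
                                            out$removed$reason)],
                  c("d1", "d2"))
})

test_that("candidates are placed next to their best-agreeing marker", {
  ids <- sprintf("i%02d", 1:36)
  set.seed(8)
  m1 <- sample(c("CC", "S_"), 36, TRUE, prob = c(0.25, 0.75))
  markers <- rbind(M1 = m1,
                   M2 = sample(c("CC", "S_"), 36, TRUE))
  colnames(markers) <- ids
  cand <- stats::setNames(m1, ids)
  res <- assignToMarker(cand, markers)
  expect_identical(res$best, "M1")
  expect_identical(res$agreement, 36L)
  # 10% recombination still recovers the true marker
  flip <- sample(36, 3)
  cand2 <- cand
  cand2[flip] <- ifelse(cand[flip] == "CC", "S_", "CC")
  expect_identical(assignToMarker(cand2, markers)$best, "M1")
  expect_error(assignToMarker(stats::setNames(rep(NA_character_, 36),
                                              ids), markers),
               "no overlapping")
})

test_that("stricter cutoffs only shrink the matched gene set", {
  set.seed(9)
  ids <- sprintf("i%02d", 1:15)
  ratio <- matrix(rlnorm(100 * 15, 0, 1.5), 100, 15,
                  dimnames = list(paste0("g", 1:100), ids))
  cc <- ids[1:3]
  pat <- list(phenotype = "p", cc = cc, s = setdiff(ids, cc),
              excluded = character())
  cuts <- list(c(0.5, 0.5), c(0.4, 0.6), c(0.3, 0.7))
  sets <- lapply(cuts, function(ct)
    patternScan(callGenotypes(ratio, ct[1], ct[2]), pat))
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("phenotype patterns respect exclusions and class boundaries", {
  ph <- data.frame(
    individual_id = sprintf("MP%02d", 1:15),
    pigment_class = c(rep("unpigmented", 3), rep("orange", 5),
                      rep("brown", 7)),
    eye = c(rep("eyeless", 4), rep("eyed", 10), "fragment"))
  pats <- phenotypePatterns(ph)
  expect_identical(length(pats$unpigmented$cc), 3L)
  expect_identical(length(pats$unpigmented$s), 12L)
  expect_identical(length(pats$orange$cc), 5L)
  expect_identical(length(pats$orange$s), 10L)
  expect_identical(length(pats$eyeless$cc), 4L)
  expect_identical(length(pats$eyeless$s), 10L)
  expect_identical(pats$eyeless$excluded, "MP15")
})
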