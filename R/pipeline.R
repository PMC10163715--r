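#' Diagnostic-site list of a simulated study, in read coordinates
#'
#' Collects each pair's difference sites and shifts them from trimmed to
#' full-transcript coordinates (indel-free data), keyed by gene id, for
#' use with [quantifySample()] on simulated reads.
#'
#' @param tp a [TranscriptPairSet-class].
#' @param geneMap named character: pair id -> gene id.
#' @return named list (by gene) of data.frames pos, caveBase,
#'   surfaceBase.
#' @export
studySiteList <- function(tp, geneMap) {
  diffs <- pairDiffSites(tp)
  info <- tp@pairs
  out <- list()
  for (i in seq_len(nrow(info))) {
    pid_ <- info$pair_id[i]
    g <- geneMap[[pid_]]
    if (is.null(g) || is.na(g)) next
    d <- diffs[[pid_]]
    out[[g]] <- data.frame(pos = d$posCave + info$caveStart[i] - 1L,
                           caveBase = d$caveBase,
                           surfaceBase = d$surfaceBase,
                           stringsAsFactors = FALSE)
  }
  out
}

# accumulate per-site ACGT counts over a set of samples
.sumSiteCounts <- function(quantList, sampleIds) {
  if (!length(sampleIds)) return(NULL)
  all <- do.call(rbind, lapply(sampleIds, function(s)
    quantList[[s]]$siteCounts))
  if (is.null(all) || !nrow(all)) return(NULL)
  key <- paste(all$gene, all$pos, sep = "#")
  agg <- rowsum(all[, c("A", "C", "G", "T")], key)
  parts <- do.call(rbind, strsplit(rownames(agg), "#"))
  data.frame(gene = parts[, 1], pos = as.integer(parts[, 2]),
             A = agg$A, C = agg$C, G = agg$G, T = agg$T,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full synthetic study pipeline
#'
#' Simulates the study described by `config` and pushes it through every
#' analysis stage: transcriptome pairing (reciprocal best hits, trimming,
#' 400 bp filter), per-sample fragment quantification against the allele
#' pairs, dual-reference concordant differential expression with the
#' paralog and copy-number filters, the parental-fidelity and F1
#' allele-bias screen intersected with differential expression, fixed-SNP
#' discovery with spanning-SNP selection and the dual-reference exact
#' binomial confirmation, and the F2 cosegregation scan with its
#' exhaustive permutation null, pattern probabilities and marker
#' placement.  Ground-truth recovery is summarized at the end.
#'
#' @param config a [SimConfig-class]; [defaultStudyConfig()] reproduces
#'   the full study design.
#' @param deStage parental stage used for differential expression.
#' @param biasFactor allele-bias ratio threshold (default 3.3).
#' @param alpha adjusted-p / binomial significance threshold.
#' @param lfcThreshold log2 fold-change magnitude threshold.
#' @param cutoffs F2 genotype ratio cutoffs `c(ccMax, sMin)`.
#' @param tol fragment mismatch tolerance.
#' @param verbose print stage progress.
#' @return a list of class `studyPipeline` with elements truth, pairs,
#'   samples, counts ([AlleleCounts-class]), de, deGenes (filtered biased
#'   genes), fidelity, ase, aseDE, snps, binomial, linkage, recovery.
#' @export
runStudyPipeline <- function(config, deStage = "late", biasFactor = 3.3,
                             alpha = 0.05, lfcThreshold = 2,
                             cutoffs = c(0.5, 0.5), tol = 3L,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating transcriptomes")
  sim <- simulateTranscriptomes(config)
  truth <- simulateF2Cohort(config, sim$truth)
  ann <- annotationTable(truth)

  say("pairing transcriptomes")
  tp <- makeTranscriptPairs(sim$cave, sim$surface)
  pairGene <- stats::setNames(truth@genes$gene_id,
                              paste0("surf_", truth@genes$gene_id))
  geneMap <- as.list(pairGene[tp@pairs$pair_id])
  names(geneMap) <- tp@pairs$pair_id
  siteList <- studySiteList(tp, geneMap)

  say("simulating and quantifying samples")
  samples <- sampleSheet(config, truth)
  quantList <- list()
  for (i in seq_len(nrow(samples))) {
    reads <- simulateSampleReads(config, truth, samples[i, ])
    quantList[[samples$sample_id[i]]] <- quantifySample(reads, siteList,
                                                        tol)
  }
  ac <- abundanceMatrix(quantList, samples)

  say("differential expression")
  de <- differentialExpression(ac, stage = deStage, alpha = alpha,
                               lfcThreshold = lfcThreshold)
  biased <- de$result$gene[de$result$bias != "none"]
  ssC <- selfSimilarityFilter(sim$cave,
    intersect(paste0("cave_", biased), names(sim$cave)))
  ssS <- selfSimilarityFilter(sim$surface,
    intersect(paste0("surf_", biased), names(sim$surface)))
  dropSS <- unique(c(sub("^cave_", "", ssC$removed$id),
                     sub("^surf_", "", ssS$removed$id)))
  cn <- copyNumberFilter(setdiff(biased, dropSS), ann, maxCopies = 9L)
  deGenes <- cn$kept

  say("allele-specific expression screen")
  fid <- parentalFidelityFilter(ac, biasFactor = biasFactor)
  ase <- hybridBias(ac, biasFactor = biasFactor,
                    genes = fid$gene[fid$passedFidelity],
                    annotations = ann)
  aseDE <- intersectWithDE(ase, de$result)

  say("fixed-SNP discovery and binomial confirmation")
  caveP <- samples$sample_id[samples$generation == "P_cave"]
  surfP <- samples$sample_id[samples$generation == "P_surface"]
  f1 <- samples$sample_id[samples$generation == "F1"]
  cavePile <- .sumSiteCounts(quantList, caveP)
  surfPile <- .sumSiteCounts(quantList, surfP)
  targets <- aseDE$gene[aseDE$intersectsDE]
  snps <- list()
  rows <- list()
  for (g in targets) {
    sl <- siteList[[g]]
    if (is.null(sl) || !nrow(sl)) next
    getCounts <- function(pile) {
      sub <- pile[pile$gene == g, , drop = FALSE]
      m <- match(sl$pos, sub$pos)
      cbind(A = ifelse(is.na(m), 0L, sub$A[m]),
            C = ifelse(is.na(m), 0L, sub$C[m]),
            G = ifelse(is.na(m), 0L, sub$G[m]),
            T = ifelse(is.na(m), 0L, sub$T[m]))
    }
    cm <- getCounts(cavePile); sm <- getCounts(surfPile)
    sites <- data.frame(posCave = sl$pos, posSurface = sl$pos,
                        refCave = sl$caveBase, refSurface = sl$surfaceBase,
                        cA = cm[, "A"], cC = cm[, "C"], cG = cm[, "G"],
                        cT = cm[, "T"], sA = sm[, "A"], sC = sm[, "C"],
                        sG = sm[, "G"], sT = sm[, "T"],
                        stringsAsFactors = FALSE)
    called <- callFixedSNPs(sites, minSupport = 5L)
    if (!nrow(called)) next
    sel <- called[selectSpanningSNPs(called$posCave), , drop = FALSE]
    snps[[g]] <- sel
    for (s in f1)
      for (ref in c("cave", "surface")) {
        cnts <- siteAlleleCounts(quantList[[s]]$siteCounts, g, sel, ref)
        if (nrow(cnts))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, snp = cnts$pos, sample = s, reference = ref,
            nCave = cnts$nCave, nSurface = cnts$nSurface,
            stringsAsFactors = FALSE)
      }
  }
  binom <- if (length(rows))
    binomialDecision(do.call(rbind, rows), alpha = alpha)
  else list(decisions = data.frame(gene = character(), nSNPs = integer(),
                                   nSigSNPs = integer(),
                                   confirmed = logical(),
                                   reason = character()),
            pvalues = NULL)

  say("F2 linkage scan")
  bg <- truth@f2$blockGenotypes
  markers <- NULL
  if (length(truth@blocks)) {
    markers <- matrix(ifelse(bg == "CC", "CC", "S_"), nrow(bg),
                      dimnames = dimnames(bg))
    rownames(markers) <- vapply(truth@blocks, `[[`, "", "marker")
  }
  linkage <- linkageScan(ac, truth@f2$phenotypes, cutoffs = cutoffs,
                         annotations = ann, markers = markers)

  out <- list(config = config, truth = truth, pairs = tp,
              samples = samples, counts = ac, de = de, deGenes = deGenes,
              deRemoved = list(selfSimilarity = rbind(ssC$removed,
                                                      ssS$removed),
                               copyNumber = cn$removed),
              fidelity = fid, ase = ase, aseDE = aseDE, snps = snps,
              binomial = binom, linkage = linkage)
  out$recovery <- compareToTruth(out)
  class(out) <- "studyPipeline"
  out
}

#' Score a pipeline run against its ground truth
#'
#' @param result a `studyPipeline` list ([runStudyPipeline()]).
#' @return list with per-class recall and false positives: `de`, `ase`,
#'   and one entry per linked phenotype.
#' @export
compareToTruth <- function(result) {
  truth <- result$truth
  out <- list()

  planted <- truth@de$gene_id
  wantCave <- truth@de$gene_id[truth@de$log2fc > 0]
  deTab <- result$de$result
  calledBias <- stats::setNames(as.character(deTab$bias), deTab$gene)
  called <- result$deGenes
  good <- called[(called %in% wantCave & calledBias[called] == "cave") |
                 (called %in% setdiff(planted, wantCave) &
                    calledBias[called] == "surface")]
  out$de <- list(planted = planted, recovered = good,
                 recall = if (length(planted))
                   length(good) / length(planted) else NA,
                 falsePositives = setdiff(called, planted))

  plantedA <- truth@ase$gene_id
  wantCaveA <- truth@ase$gene_id[truth@ase$caveFraction > 0.5]
  aseDir <- stats::setNames(as.character(result$ase$direction),
                            result$ase$gene)
  goodA <- names(aseDir)[(names(aseDir) %in% wantCaveA &
                            aseDir == "cave_allele") |
                         (names(aseDir) %in% setdiff(plantedA, wantCaveA) &
                            aseDir == "surface_allele")]
  out$ase <- list(planted = plantedA, recovered = goodA,
                  recall = if (length(plantedA))
                    length(goodA) / length(plantedA) else NA,
                  falsePositives = setdiff(result$ase$gene, plantedA))

  for (b in truth@blocks) {
    ph <- b$phenotype
    if (is.null(result$linkage[[ph]])) next
    matched <- result$linkage[[ph]]$matched
    rec <- intersect(matched, b$gene_ids)
    out[[ph]] <- list(planted = b$gene_ids, recovered = rec,
                      recall = length(rec) / length(b$gene_ids),
                      falsePositives = setdiff(matched, b$gene_ids))
  }
  out
}

#' @export
print.studyPipeline <- function(x, ...) {
  cat("studyPipeline:", nrow(x$truth@genes), "genes,",
      nrow(x$samples), "samples,", length(x$pairs@pairs$pair_id),
      "allele pairs\n")
  cat("  DE biased genes (filtered):", length(x$deGenes), "\n")
  cat("  ASE calls:", nrow(x$ase),
      sprintf("(%d cave_allele, %d surface_allele)",
              sum(x$ase$direction == "cave_allele"),
              sum(x$ase$direction == "surface_allele")), "\n")
  cat("  binomial-confirmed genes:",
      sum(x$binomial$decisions$confirmed), "\n")
  for (nm in names(x$linkage))
    cat(sprintf("  %s: %d matched, empirical p %.3g, wilcoxon p %.3g\n",
                nm, x$linkage[[nm]]$nMatched, x$linkage[[nm]]$empiricalP,
                x$linkage[[nm]]$wilcoxonP))
  r <- x$recovery
  if (!is.null(r$de$recall))
    cat(sprintf("  recovery: DE %.0f%%, ASE %.0f%%\n",
                100 * r$de$recall, 100 * r$ase$recall))
  invisible(x)
}
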