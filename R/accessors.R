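#' Construct a SimConfig
#'
#' Bare constructor for the synthetic-study configuration.  The defaults
#' describe a small neutral study with no planted signals; use
#' [defaultStudyConfig()] for the full cave x surface study layout.
#'
#' @param seed master RNG seed (a single positive integer).
#' @param nGenes number of cave/surface gene pairs.
#' @param lengthRange transcript length range (bp).
#' @param snpRange number of fixed SNPs per gene (range).
#' @param nParentalReps parental biological replicates per ecomorph per stage.
#' @param stages embryonic stages with parental samples
#'   (subset of `c("mid","late")`).
#' @param nF1 number of F1 hybrid samples.
#' @param nF2 number of F2 individuals.
#' @param readLength single-end fragment length (bp).
#' @param meanDepth mean fragments per transcript per sample.
#' @param errorRate per-base substitution error probability.
#' @param dispersion negative-binomial dispersion of depth across
#'   biological replicates.
#' @param aseGenes data.frame(gene, caveFraction) of allele-biased genes.
#' @param deGenes data.frame(gene, log2fc, stage) of differentially
#'   expressed genes (log2fc of cave relative to surface).
#' @param linkedBlocks list of `list(phenotype=, genes=, marker=)`.
#' @param f2PhenotypeSpec named counts of CC individuals per phenotype, or
#'   NULL for unconditioned Mendelian sampling.
#' @param nEyeFragment eyed F2 individuals relabelled "fragment".
#' @param duplicatedFraction fraction of genes with a near-identical extra
#'   copy in one transcriptome.
#' @param unpairedFraction fraction of genes present in one transcriptome
#'   only.
#' @param unannotatedFraction fraction of genes without an annotation id.
#' @param indelRate per-gene probability of a short deletion in the cave
#'   transcript.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(seed = 1, nGenes = 5, meanDepth = 100)
#' @export
SimConfig <- function(seed = 1L, nGenes = 50L,
                      lengthRange = c(500L, 3000L),
                      snpRange = c(3L, 12L),
                      nParentalReps = 3L,
                      stages = c("mid", "late"),
                      nF1 = 3L, nF2 = 15L,
                      readLength = 100L,
                      meanDepth = 5000,
                      errorRate = 0.001,
                      dispersion = 0.05,
                      aseGenes = NULL,
                      deGenes = NULL,
                      linkedBlocks = list(),
                      f2PhenotypeSpec = NULL,
                      nEyeFragment = 0L,
                      duplicatedFraction = 0,
                      unpairedFraction = 0,
                      unannotatedFraction = 0,
                      indelRate = 0) {
  if (is.null(aseGenes))
    aseGenes <- data.frame(gene = integer(), caveFraction = numeric())
  if (is.null(deGenes))
    deGenes <- data.frame(gene = integer(), log2fc = numeric(),
                          stage = character())
  if (!"stage" %in% names(deGenes) && nrow(deGenes))
    deGenes$stage <- "both"
  if (!is.null(f2PhenotypeSpec))
    f2PhenotypeSpec <- stats::setNames(as.integer(f2PhenotypeSpec),
                                       names(f2PhenotypeSpec))
  new("SimConfig",
      seed = as.integer(seed), nGenes = as.integer(nGenes),
      lengthRange = as.integer(lengthRange), snpRange = as.integer(snpRange),
      nParentalReps = as.integer(nParentalReps), stages = stages,
      nF1 = as.integer(nF1), nF2 = as.integer(nF2),
      readLength = as.integer(readLength), meanDepth = meanDepth,
      errorRate = errorRate, dispersion = dispersion,
      aseGenes = aseGenes, deGenes = deGenes, linkedBlocks = linkedBlocks,
      f2PhenotypeSpec = f2PhenotypeSpec,
      nEyeFragment = as.integer(nEyeFragment),
      duplicatedFraction = duplicatedFraction,
      unpairedFraction = unpairedFraction,
      unannotatedFraction = unannotatedFraction,
      indelRate = indelRate)
}

#' The default cave x surface study configuration
#'
#' Returns the configuration emulating the full study design: 500 genes,
#' three parental replicates per ecomorph at each of two embryonic stages,
#' three F1 hybrids and fifteen F2 individuals; 10 planted allele-biased
#' genes (cave-allele fraction 0.8, also cave-biased in parental
#' expression so they flow into the allele-count confirmation stage), 20
#' planted differentially expressed genes in total
#' (|log2FC| = 3, both directions), and three perfectly linked gene
#' blocks of 25, 15 and 20 genes tied to the recessive unpigmented, orange
#' and eyeless phenotypes (3, 5 and 4 affected F2 individuals, plus one
#' eyed individual carrying eye fragments that the eye scan excludes).
#'
#' @param seed master RNG seed.
#' @param nGenes total number of genes (>= 250 so the planted indices fit).
#' @param meanDepth mean fragments per transcript per sample.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- defaultStudyConfig(seed = 7)
#' @export
defaultStudyConfig <- function(seed = 1L, nGenes = 500L, meanDepth = 5000) {
  stopifnot(nGenes >= 250L)
  SimConfig(
    seed = seed, nGenes = nGenes, meanDepth = meanDepth,
    aseGenes = data.frame(gene = 1:10, caveFraction = 0.8),
    # the allele-biased genes are also differentially expressed between
    # the parental forms, in the concordant direction -- the
    # cis-regulatory expectation, and what routes them into the
    # allele-count confirmation stage (which targets ASE-and-DE genes)
    deGenes = data.frame(gene = c(1:10, 21:30),
                         log2fc = rep(c(3, -3), each = 10),
                         stage = "both"),
    linkedBlocks = list(
      list(phenotype = "unpigmented", genes = 101:125, marker = "M_pig"),
      list(phenotype = "orange", genes = 151:165, marker = "M_orange"),
      list(phenotype = "eyeless", genes = 201:220, marker = "M_eye")),
    f2PhenotypeSpec = c(unpigmented = 3L, orange = 5L, eyeless = 4L),
    nEyeFragment = 1L)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes, seed", object@seed, "\n")
  cat("  transcripts ", object@lengthRange[1], "-", object@lengthRange[2],
      " bp, ", object@snpRange[1], "-", object@snpRange[2],
      " fixed SNPs/gene\n", sep = "")
  cat("  cohort:", object@nParentalReps, "parental reps x",
      length(object@stages), "stage(s) x 2 ecomorphs,",
      object@nF1, "F1,", object@nF2, "F2\n")
  cat("  reads:", object@readLength, "bp, depth", object@meanDepth,
      "per transcript, error", object@errorRate, "\n")
  cat("  planted:", nrow(object@aseGenes), "ASE,", nrow(object@deGenes),
      "DE,", length(object@linkedBlocks), "linked block(s)\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@genes), "genes,",
      nrow(object@snps), "planted SNPs\n")
  cat("  ", nrow(object@ase), "ASE genes, ", nrow(object@de),
      " DE genes, ", length(object@blocks), " linked block(s)\n", sep = "")
  if (length(object@f2))
    cat("  F2 cohort:", length(object@f2$individuals), "individuals\n")
})

#' @describeIn TranscriptPairSet trimmed cave alleles (one per pair).
#' @export
setMethod("caveSeqs", "TranscriptPairSet", function(x) x@cave)

#' @describeIn TranscriptPairSet trimmed surface alleles (one per pair).
#' @export
setMethod("surfaceSeqs", "TranscriptPairSet", function(x) x@surface)

#' @describeIn TranscriptPairSet pair identifiers.
#' @export
setMethod("pairIds", "TranscriptPairSet", function(x) x@pairs$pair_id)

#' @describeIn TranscriptPairSet the pair table (ids, score, identity,
#'   trim offsets and lengths).
#' @export
setMethod("pairInfo", "TranscriptPairSet", function(x) x@pairs)

#' @describeIn TranscriptPairSet the coordinate map of one pair: a
#'   two-column integer matrix of matched (cave, surface) positions on the
#'   trimmed alleles.
#' @export
setMethod("coordMap", "TranscriptPairSet", function(x, pair) {
  m <- x@coordMaps[[pair]]
  if (is.null(m)) stop("no coordinate map for pair '", pair, "'")
  m
})

setMethod("length", "TranscriptPairSet", function(x) nrow(x@pairs))

setMethod("show", "TranscriptPairSet", function(object) {
  cat("TranscriptPairSet with", nrow(object@pairs), "allele pairs\n")
  if (nrow(object@pairs)) {
    cat("  mean identity:",
        round(mean(object@pairs$identity), 2), "%\n")
    cat("  trimmed lengths:", min(object@pairs$caveLength), "-",
        max(object@pairs$caveLength), "bp (cave side)\n")
  }
})

#' Build an AlleleCounts object
#'
#' @param zCave,zSurface numeric matrices (pairs x samples) of fragment
#'   counts assigned to each allele.
#' @param colData a data.frame of sample annotations; must contain a
#'   `generation` column with values among `P_cave`, `P_surface`, `F1`,
#'   `F2`.
#' @param mapCave,mapSurface optional matrices of totals mapped to each
#'   single-allele reference (used for dual-reference DE).
#' @param ... further arguments passed to
#'   [SummarizedExperiment::SummarizedExperiment()].
#' @return an [AlleleCounts-class] object.
#' @examples
#' z <- matrix(rpois(6, 50), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ac <- AlleleCounts(z, z, colData = data.frame(
#'   generation = c("P_cave", "P_surface"), row.names = c("s1", "s2")))
#' @export
AlleleCounts <- function(zCave, zSurface, colData,
                         mapCave = NULL, mapSurface = NULL, ...) {
  assays <- list(zCave = zCave, zSurface = zSurface)
  if (!is.null(mapCave)) assays$mapCave <- mapCave
  if (!is.null(mapSurface)) assays$mapSurface <- mapSurface
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = S4Vectors::DataFrame(colData), ...)
  new("AlleleCounts", se)
}

#' @describeIn AlleleCounts fragment counts assigned to the cave allele.
#' @export
setMethod("zCave", "AlleleCounts", function(x)
  SummarizedExperiment::assay(x, "zCave"))

#' @describeIn AlleleCounts fragment counts assigned to the surface allele.
#' @export
setMethod("zSurface", "AlleleCounts", function(x)
  SummarizedExperiment::assay(x, "zSurface"))

#' @describeIn AlleleCounts total assigned fragments per pair and sample.
#' @export
setMethod("totalCounts", "AlleleCounts", function(x)
  zCave(x) + zSurface(x))

#' @describeIn AlleleCounts surface/cave Z-value ratio (the F2 genotype
#'   statistic; `Inf` when only surface fragments are seen, `NaN` when both
#'   are zero).
#' @export
setMethod("alleleRatio", "AlleleCounts", function(x)
  zSurface(x) / zCave(x))

setMethod("show", "AlleleCounts", function(object) {
  callNextMethod()
  gen <- table(SummarizedExperiment::colData(object)$generation)
  cat("generations:",
      paste(names(gen), gen, sep = "=", collapse = ", "), "\n")
})
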