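#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Simulation configuration for a cave x surface hybrid study
#'
#' A `SimConfig` fixes every knob of the synthetic-data generator: the
#' transcriptome (gene number, transcript lengths, fixed-SNP density,
#' optional duplicated / unpaired transcripts and indels), the sequencing
#' model (read length, per-transcript fragment depth, substitution error
#' rate, negative-binomial dispersion across biological replicates), the
#' cohort (parental replicates per ecomorph per stage, F1 and F2 counts),
#' and the planted signals (allele-biased genes, differentially expressed
#' genes, linked gene blocks with their recessive phenotypes).  The seed
#' fully determines every downstream output.
#'
#' @slot seed integer; master RNG seed.
#' @slot nGenes integer; number of cave/surface gene pairs to simulate.
#' @slot lengthRange integer(2); transcript length range in bp.
#' @slot snpRange integer(2); fixed SNPs planted per gene (range).
#' @slot nParentalReps integer; biological replicates per ecomorph per stage.
#' @slot stages character; embryonic stages sampled for parental replicates.
#' @slot nF1,nF2 integer; number of F1 hybrids and F2 individuals.
#' @slot readLength integer; single-end fragment length in bp.
#' @slot meanDepth numeric; mean fragments per transcript per sample.
#' @slot errorRate numeric; per-base substitution error probability.
#' @slot dispersion numeric; NB dispersion of per-gene depth across
#'   biological replicates (0 gives Poisson depth).
#' @slot aseGenes data.frame with columns `gene` (index) and `caveFraction`,
#'   the cave-allele expression fraction in heterozygotes.
#' @slot deGenes data.frame with columns `gene`, `log2fc` (cave relative to
#'   surface, sign gives direction) and `stage` (`"mid"`, `"late"` or
#'   `"both"`).
#' @slot linkedBlocks list of blocks, each
#'   `list(phenotype=, genes=, marker=)`; genes of a block share each F2
#'   individual's block genotype (perfect linkage).
#' @slot f2PhenotypeSpec named integer or NULL; exact number of CC (hence
#'   recessive-trait) individuals per phenotype.  NULL draws genotypes
#'   unconditionally at Mendelian ratios.
#' @slot nEyeFragment integer; eyed individuals relabelled as having eye
#'   fragments (excluded from the eye pattern scan).
#' @slot duplicatedFraction numeric; fraction of genes emitted with an extra
#'   >90\%-identical copy in one transcriptome (exercises paralog filters).
#' @slot unpairedFraction numeric; fraction of genes emitted in only one
#'   transcriptome (exercises reciprocal-best-hit dropout).
#' @slot unannotatedFraction numeric; fraction of genes without an
#'   annotation id.
#' @slot indelRate numeric; per-gene probability of one short deletion in
#'   the cave transcript (read simulation requires 0).
#'
#' @seealso [SimConfig()], [defaultStudyConfig()], [simulateTranscriptomes()]
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(
    seed = "integer",
    nGenes = "integer",
    lengthRange = "integer",
    snpRange = "integer",
    nParentalReps = "integer",
    stages = "character",
    nF1 = "integer",
    nF2 = "integer",
    readLength = "integer",
    meanDepth = "numeric",
    errorRate = "numeric",
    dispersion = "numeric",
    aseGenes = "data.frame",
    deGenes = "data.frame",
    linkedBlocks = "list",
    f2PhenotypeSpec = "ANY",
    nEyeFragment = "integer",
    duplicatedFraction = "numeric",
    unpairedFraction = "numeric",
    unannotatedFraction = "numeric",
    indelRate = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  chkPos <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1L)
      msg <<- c(msg, sprintf("'%s' must be a single positive integer", nm))
  }
  chkPos(object@seed, "seed"); chkPos(object@nGenes, "nGenes")
  chkPos(object@nParentalReps, "nParentalReps")
  chkPos(object@nF1, "nF1"); chkPos(object@nF2, "nF2")
  chkPos(object@readLength, "readLength")
  if (length(object@lengthRange) != 2L ||
      any(object@lengthRange < object@readLength))
    msg <- c(msg, "lengthRange must be two values >= readLength")
  if (diff(object@lengthRange) < 0) msg <- c(msg, "lengthRange reversed")
  if (length(object@snpRange) != 2L || any(object@snpRange < 0) ||
      diff(object@snpRange) < 0)
    msg <- c(msg, "snpRange must be a non-negative, non-decreasing pair")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  for (nm in c("errorRate", "duplicatedFraction", "unpairedFraction",
               "unannotatedFraction", "indelRate")) {
    v <- slot(object, nm)
    if (v < 0 || v >= 1) msg <- c(msg, sprintf("'%s' must be in [0,1)", nm))
  }
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (!all(object@stages %in% c("mid", "late")))
    msg <- c(msg, "stages must be a subset of c('mid','late')")
  if (nrow(object@aseGenes)) {
    if (!all(c("gene", "caveFraction") %in% names(object@aseGenes)))
      msg <- c(msg, "aseGenes needs columns gene, caveFraction")
    else {
      if (any(object@aseGenes$gene > object@nGenes |
              object@aseGenes$gene < 1))
        msg <- c(msg, "aseGenes$gene out of range")
      if (any(object@aseGenes$caveFraction <= 0 |
              object@aseGenes$caveFraction >= 1))
        msg <- c(msg, "aseGenes$caveFraction must lie in (0,1)")
    }
  }
  if (nrow(object@deGenes)) {
    if (!all(c("gene", "log2fc", "stage") %in% names(object@deGenes)))
      msg <- c(msg, "deGenes needs columns gene, log2fc, stage")
    else if (any(object@deGenes$gene > object@nGenes |
                 object@deGenes$gene < 1))
      msg <- c(msg, "deGenes$gene out of range")
  }
  for (b in object@linkedBlocks) {
    if (!all(c("phenotype", "genes", "marker") %in% names(b)))
      msg <- c(msg, "each linked block needs phenotype, genes, marker")
    else if (any(b$genes > object@nGenes | b$genes < 1))
      msg <- c(msg, sprintf("block '%s' gene indices out of range",
                            b$phenotype))
  }
  if (!is.null(object@f2PhenotypeSpec)) {
    if (is.null(names(object@f2PhenotypeSpec)))
      msg <- c(msg, "f2PhenotypeSpec must be a named count vector")
    if (any(object@f2PhenotypeSpec > object@nF2))
      msg <- c(msg, "f2PhenotypeSpec requests more CC individuals than nF2")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated study
#'
#' Records every planted feature of a synthetic study so downstream stages
#' can be scored against a known answer: per-gene SNP positions and allele
#' bases, true differential-expression and allele-bias status, duplicated
#' and unpaired transcripts, and (after [simulateF2Cohort()]) per-individual
#' block genotypes and the phenotypes they imply under recessive
#' inheritance.
#'
#' @slot genes data.frame: gene_id, length, nSnps, annotation_id, paired,
#'   side (transcriptome(s) the gene was emitted in).
#' @slot snps data.frame: gene_id, posCave, posSurface (1-based positions on
#'   the full transcripts), caveBase, surfaceBase.
#' @slot ase data.frame: gene_id, caveFraction.
#' @slot de data.frame: gene_id, log2fc, stage.
#' @slot blocks list of linked blocks (phenotype, gene_ids, marker).
#' @slot duplicates data.frame: gene_id, copy_id, side.
#' @slot f2 list; filled by [simulateF2Cohort()]: individuals,
#'   blockGenotypes (block x individual), geneGenotypes (gene x individual),
#'   phenotypes table.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(
    genes = "data.frame",
    snps = "data.frame",
    ase = "data.frame",
    de = "data.frame",
    blocks = "list",
    duplicates = "data.frame",
    f2 = "list"
  )
)

#' Matched cave/surface transcript pairs
#'
#' The combined two-allele reference: for every reciprocal-best-hit gene,
#' the cave and surface transcripts trimmed to their aligned region,
#' together with a per-pair coordinate map (1-based positions on the two
#' trimmed alleles, matched alignment columns only, monotone increasing)
#' that carries diagnostic-site positions across indels.
#'
#' @slot pairs data.frame: pair_id, cave_id, surface_id, score, identity,
#'   alignedLength, caveStart, surfaceStart (1-based offsets of the trimmed
#'   region on the full transcripts), caveLength, surfaceLength.
#' @slot cave,surface [Biostrings::DNAStringSet] of trimmed alleles, named
#'   by pair_id.
#' @slot coordMaps named list of two-column integer matrices
#'   (cave, surface), positions on the trimmed alleles.
#' @seealso [makeTranscriptPairs()], [pairDiffSites()]
#' @exportClass TranscriptPairSet
setClass("TranscriptPairSet",
  slots = c(
    pairs = "data.frame",
    cave = "DNAStringSet",
    surface = "DNAStringSet",
    coordMaps = "list"
  )
)

setValidity("TranscriptPairSet", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("pair_id", "cave_id", "surface_id")
  if (!all(need %in% names(p)))
    msg <- c(msg, "pairs table lacks pair_id/cave_id/surface_id")
  else {
    if (anyDuplicated(p$cave_id) || anyDuplicated(p$surface_id))
      msg <- c(msg, "a transcript appears in more than one pair")
    if (length(object@cave) != nrow(p) || length(object@surface) != nrow(p))
      msg <- c(msg, "sequence sets and pairs table disagree in length")
  }
  for (m in object@coordMaps) {
    if (!is.matrix(m) || ncol(m) != 2L) {
      msg <- c(msg, "coordinate maps must be two-column matrices")
      break
    }
    if (nrow(m) > 1L && (any(diff(m[, 1L]) <= 0) || any(diff(m[, 2L]) <= 0))) {
      msg <- c(msg, "coordinate maps must be strictly increasing")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-allele abundance container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per
#' transcript pair and one column per sample.  Assays `zCave` and
#' `zSurface` hold the Z-values (estimated fragment counts assigned to the
#' cave and surface allele); optional assays `mapCave` / `mapSurface` hold
#' per-single-reference mapped totals used for dual-reference differential
#' expression.  Column data carries the sample sheet (generation, stage,
#' F2 phenotypes).
#'
#' @seealso [AlleleCounts()], [zCave()], [zSurface()], [alleleRatio()]
#' @exportClass AlleleCounts
setClass("AlleleCounts", contains = "SummarizedExperiment")

setValidity("AlleleCounts", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("zCave", "zSurface") %in% an))
    msg <- c(msg, "assays 'zCave' and 'zSurface' are required")
  else {
    if (any(SummarizedExperiment::assay(object, "zCave") < 0, na.rm = TRUE) ||
        any(SummarizedExperiment::assay(object, "zSurface") < 0, na.rm = TRUE))
      msg <- c(msg, "Z-values must be non-negative")
  }
  if (!"generation" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'generation' column")
  if (length(msg)) msg else TRUE
})
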