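#' Simulate a pair of cave and surface transcriptomes
#'
#' Generates, for each gene, a surface transcript and a cave transcript that
#' are identical except at planted fixed SNP sites (and, optionally, one
#' short deletion on the cave side).  A configurable fraction of genes is
#' emitted with an extra >90\%-identical copy in one transcriptome (to
#' exercise the paralog / self-similarity filters) and a configurable
#' fraction is emitted in only one transcriptome (to exercise
#' reciprocal-best-hit dropout).  The output is fully determined by
#' `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return a list with elements `cave` and `surface`
#'   ([Biostrings::DNAStringSet], transcript ids `cave_<gene>` /
#'   `surf_<gene>`, duplicate copies suffixed `_dup`) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' sim <- simulateTranscriptomes(SimConfig(seed = 1, nGenes = 4))
#' sim$truth
#' @export
simulateTranscriptomes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  bases <- c("A", "C", "G", "T")
  n <- config@nGenes
  gid <- sprintf("g%04d", seq_len(n))
  lens <- sample(seq(config@lengthRange[1], config@lengthRange[2]), n,
                 replace = TRUE)
  nsnp <- sample(seq(config@snpRange[1], config@snpRange[2]), n,
                 replace = TRUE)

  nUnpaired <- floor(config@unpairedFraction * n)
  unpairedIdx <- if (nUnpaired) sort(sample(n, nUnpaired)) else integer()
  unpairedSide <- sample(c("cave", "surface"), nUnpaired, replace = TRUE)
  dupPool <- setdiff(seq_len(n), unpairedIdx)
  nDup <- min(floor(config@duplicatedFraction * n), length(dupPool))
  dupIdx <- if (nDup) sort(sample(dupPool, nDup)) else integer()
  dupSide <- sample(c("cave", "surface"), nDup, replace = TRUE)

  surfSeq <- caveSeq <- character(n)
  snpList <- vector("list", n)
  indelAt <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    L <- lens[i]
    sc <- sample(bases, L, replace = TRUE)
    cc <- sc
    pos <- if (nsnp[i] > 0) sort(sample.int(L, nsnp[i])) else integer()
    for (p in pos)
      cc[p] <- sample(setdiff(bases, sc[p]), 1L)
    posCave <- pos
    if (config@indelRate > 0 && stats::runif(1) < config@indelRate &&
        L > 50L) {
      # one 3-bp deletion on the cave side, clear of planted SNPs
      ok <- setdiff(seq(10L, L - 12L), unique(c(outer(pos, -4:4, "+"))))
      if (length(ok)) {
        dstart <- sample(ok, 1L)
        cc <- cc[-(dstart:(dstart + 2L))]
        indelAt[i] <- dstart
        posCave <- ifelse(pos > dstart, pos - 3L, pos)
      }
    }
    surfSeq[i] <- paste(sc, collapse = "")
    caveSeq[i] <- paste(cc, collapse = "")
    snpList[[i]] <- if (length(pos))
      data.frame(gene_id = gid[i], posCave = posCave, posSurface = pos,
                 caveBase = cc[posCave], surfaceBase = sc[pos])
    else NULL
  }

  ann <- paste0("ANN_", gid)
  if (config@unannotatedFraction > 0) {
    nna <- floor(config@unannotatedFraction * n)
    if (nna) ann[sample(n, nna)] <- NA_character_
  }

  side <- rep("both", n)
  side[unpairedIdx] <- unpairedSide
  caveKeep <- side %in% c("both", "cave")
  surfKeep <- side %in% c("both", "surface")
  caveSet <- stats::setNames(caveSeq[caveKeep], paste0("cave_", gid[caveKeep]))
  surfSet <- stats::setNames(surfSeq[surfKeep], paste0("surf_", gid[surfKeep]))

  dup <- data.frame(gene_id = character(), copy_id = character(),
                    side = character())
  for (j in seq_along(dupIdx)) {
    i <- dupIdx[j]
    src <- if (dupSide[j] == "cave") caveSeq[i] else surfSeq[i]
    ch <- strsplit(src, "")[[1]]
    nmut <- max(1L, round(0.02 * length(ch)))
    at <- sample(length(ch), nmut)
    for (p in at) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    cid <- sprintf("%s_%s_dup", substr(dupSide[j], 1, 4), gid[i])
    cid <- sub("^surf", "surf", sub("^cave", "cave", cid))
    copy <- stats::setNames(paste(ch, collapse = ""), cid)
    if (dupSide[j] == "cave") caveSet <- c(caveSet, copy)
    else surfSet <- c(surfSet, copy)
    dup <- rbind(dup, data.frame(gene_id = gid[i], copy_id = cid,
                                 side = dupSide[j]))
  }

  genes <- data.frame(
    gene_id = gid, length = lens, nSnps = nsnp, annotation_id = ann,
    paired = side == "both", side = side, indelAt = indelAt,
    stringsAsFactors = FALSE)
  snps <- do.call(rbind, snpList[!vapply(snpList, is.null, logical(1))])
  if (is.null(snps))
    snps <- data.frame(gene_id = character(), posCave = integer(),
                       posSurface = integer(), caveBase = character(),
                       surfaceBase = character())
  rownames(snps) <- NULL

  ase <- config@aseGenes
  de <- config@deGenes
  truth <- new("GroundTruth",
    genes = genes, snps = snps,
    ase = if (nrow(ase))
      data.frame(gene_id = gid[ase$gene], caveFraction = ase$caveFraction)
    else data.frame(gene_id = character(), caveFraction = numeric()),
    de = if (nrow(de))
      data.frame(gene_id = gid[de$gene], log2fc = de$log2fc,
                 stage = de$stage)
    else data.frame(gene_id = character(), log2fc = numeric(),
                    stage = character()),
    blocks = lapply(config@linkedBlocks, function(b)
      list(phenotype = b$phenotype, gene_ids = gid[b$genes],
           marker = b$marker)),
    duplicates = dup, f2 = list())

  list(cave = Biostrings::DNAStringSet(caveSet),
       surface = Biostrings::DNAStringSet(surfSet),
       truth = truth)
}

#' Simulate an F2 cohort: linked-block genotypes and phenotypes
#'
#' Each F2 individual receives a genotype (CC, SC or SS) at every gene.
#' Genes inside a linked block share the individual's block genotype
#' (perfect linkage); all other genes segregate independently at the
#' Mendelian ratios P(CC) = 1/4, P(SC) = 1/2, P(SS) = 1/4.  When
#' `config@f2PhenotypeSpec` fixes the number of CC individuals for a
#' block's phenotype, that many individuals are drawn uniformly at random
#' to be CC (direct assignment; individuals are exchangeable, matching how
#' the permutation null treats them) and the rest are SC or SS at the
#' conditional ratio 2:1.  Phenotypes follow recessive inheritance: an
#' individual shows a block's trait iff it is CC at that block.
#'
#' @param config a [SimConfig-class].
#' @param truth the [GroundTruth-class] from [simulateTranscriptomes()].
#' @return `truth` with the `f2` slot filled: `individuals`,
#'   `blockGenotypes` (block x individual), `geneGenotypes`
#'   (gene x individual) and a `phenotypes` table with columns
#'   `individual_id`, `pigment_class` (brown, light_brown, orange, red or
#'   unpigmented) and `eye` (eyed, eyeless or fragment).
#' @export
simulateF2Cohort <- function(config, truth) {
  stopifnot(is(config, "SimConfig"), is(truth, "GroundTruth"))
  set.seed((config@seed + 1L) %% .Machine$integer.max)
  nI <- config@nF2
  ids <- sprintf("MP%02d", seq_len(nI))
  blocks <- truth@blocks
  spec <- config@f2PhenotypeSpec

  drawS <- function(m) sample(c("SC", "SS"), m, replace = TRUE,
                              prob = c(2, 1) / 3)
  bg <- matrix(character(), nrow = length(blocks), ncol = nI,
               dimnames = list(vapply(blocks, `[[`, "", "phenotype"), ids))
  ccSets <- list()
  for (b in seq_along(blocks)) {
    ph <- blocks[[b]]$phenotype
    if (!is.null(spec) && ph %in% names(spec)) {
      k <- spec[[ph]]
      pool <- seq_len(nI)
      # orange is a pigment class: an unpigmented individual cannot be
      # scored orange, so the orange block's CC set avoids them
      if (ph == "orange" && "unpigmented" %in% names(ccSets))
        pool <- setdiff(pool, ccSets[["unpigmented"]])
      if (k > length(pool))
        stop("infeasible phenotype spec for '", ph, "'")
      cc <- sort(sample(pool, k))
      g <- rep(NA_character_, nI)
      g[cc] <- "CC"
      g[-cc] <- drawS(nI - k)
      ccSets[[ph]] <- cc
    } else {
      g <- sample(c("CC", "SC", "SS"), nI, replace = TRUE,
                  prob = c(1, 2, 1) / 4)
      ccSets[[ph]] <- which(g == "CC")
    }
    bg[b, ] <- g
  }

  gid <- truth@genes$gene_id
  gg <- matrix(sample(c("CC", "SC", "SS"), length(gid) * nI, replace = TRUE,
                      prob = c(1, 2, 1) / 4),
               nrow = length(gid), dimnames = list(gid, ids))
  for (b in seq_along(blocks))
    gg[blocks[[b]]$gene_ids, ] <- rep(bg[b, ], each =
                                        length(blocks[[b]]$gene_ids))

  phn <- rownames(bg)
  pig <- rep(NA_character_, nI)
  if ("unpigmented" %in% phn) pig[bg["unpigmented", ] == "CC"] <- "unpigmented"
  if ("orange" %in% phn) pig[is.na(pig) & bg["orange", ] == "CC"] <- "orange"
  pig[is.na(pig)] <- sample(c("brown", "light_brown", "red"),
                            sum(is.na(pig)), replace = TRUE)
  eye <- rep("eyed", nI)
  if ("eyeless" %in% phn) eye[bg["eyeless", ] == "CC"] <- "eyeless"
  if (config@nEyeFragment > 0) {
    eyed <- which(eye == "eyed")
    frag <- sample(eyed, min(config@nEyeFragment, length(eyed)))
    eye[frag] <- "fragment"
  }

  truth@f2 <- list(
    individuals = ids, blockGenotypes = bg, geneGenotypes = gg,
    phenotypes = data.frame(individual_id = ids, pigment_class = pig,
                            eye = eye, stringsAsFactors = FALSE))
  truth
}

#' Sample sheet for a simulated study
#'
#' One row per sequenced sample: parental replicates per ecomorph per
#' stage, F1 hybrids (late stage) and adult F2 individuals with their
#' phenotypes.
#'
#' @param config a [SimConfig-class].
#' @param truth a [GroundTruth-class] with the F2 cohort simulated.
#' @return a data.frame with columns sample_id, generation, stage,
#'   individual_id, pigment_class, eye.
#' @export
sampleSheet <- function(config, truth) {
  rows <- list()
  for (st in config@stages)
    for (eco in c("cave", "surface"))
      for (r in seq_len(config@nParentalReps))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%d", eco, st, r),
          generation = if (eco == "cave") "P_cave" else "P_surface",
          stage = st, individual_id = NA_character_,
          pigment_class = NA_character_, eye = NA_character_)
  for (r in seq_len(config@nF1))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("F1_%d", r), generation = "F1", stage = "late",
      individual_id = NA_character_, pigment_class = NA_character_,
      eye = NA_character_)
  if (config@nF2 > 0) {
    if (!length(truth@f2))
      stop("simulate the F2 cohort first (simulateF2Cohort)")
    ph <- truth@f2$phenotypes
    for (i in seq_len(nrow(ph)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ph$individual_id[i], generation = "F2",
        stage = "adult", individual_id = ph$individual_id[i],
        pigment_class = ph$pigment_class[i], eye = ph$eye[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$sample_id
  out
}

.otherBases <- local({
  b <- c("A", "C", "G", "T")
  stats::setNames(lapply(b, function(x) setdiff(b, x)), b)
})

.sampleSeed <- function(config, sampleId) {
  h <- sum(utf8ToInt(sampleId) * seq_along(utf8ToInt(sampleId)))
  as.integer((config@seed * 131L + h * 7L + 17L) %% 2147483647L)
}

#' Simulate the read set of one sample
#'
#' Fragments are single-end, fixed-length, drawn uniformly along each
#' paired transcript; per-gene depth is negative-binomial around the
#' configured mean (times the planted fold change for differentially
#' expressed genes in parental samples of the matching stage).  Parental
#' samples draw only their own allele; F1 and F2 heterozygotes draw the
#' cave allele at the gene's allele-bias fraction (0.5 unless planted); F2
#' homozygotes draw a single allele.  Substitution errors are injected at
#' the configured per-base rate.
#'
#' Two output modes are supported.  `"sequence"` materialises literal read
#' sequences (exportable with [writeSampleFastq()]).  `"sites"` stores,
#' per fragment, its start, the observed base at every fixed-SNP site it
#' covers, and its mismatch count at non-SNP positions -- at non-SNP
#' positions the two alleles are identical, so a substitution error adds
#' one mismatch against both alleles regardless of the source allele,
#' making this a lossless summary for allele classification.  Both modes
#' feed [quantifySample()] and agree; `"sites"` scales to full-study
#' depth.
#'
#' @param config a [SimConfig-class] (indel-free: `indelRate = 0`).
#' @param truth matching [GroundTruth-class] (with the F2 cohort if the
#'   sample is an F2 individual).
#' @param sample one row of [sampleSheet()] (or an equivalent list).
#' @param mode `"sites"` or `"sequence"`.
#' @return a `SampleReads` object: a list with `sample_id`, `mode`,
#'   `readLength` and `genes`, a per-gene list of fragments.
#' @export
simulateSampleReads <- function(config, truth, sample,
                                mode = c("sites", "sequence")) {
  mode <- match.arg(mode)
  stopifnot(is(config, "SimConfig"), is(truth, "GroundTruth"))
  if (config@indelRate > 0 || any(!is.na(truth@genes$indelAt)))
    stop("read simulation supports indel-free transcriptomes only")
  gen <- sample$generation
  if (!gen %in% c("P_cave", "P_surface", "F1", "F2"))
    stop("unknown sample generation '", gen, "'")
  set.seed(.sampleSeed(config, sample$sample_id))

  genes <- truth@genes[truth@genes$paired, , drop = FALSE]
  gid <- genes$gene_id
  rl <- config@readLength
  e <- config@errorRate

  # per-gene expected depth, fold change applied to parental stages
  mu <- rep(config@meanDepth, nrow(genes))
  names(mu) <- gid
  if (nrow(truth@de) && gen %in% c("P_cave", "P_surface")) {
    act <- truth@de$stage %in% c("both", sample$stage)
    dg <- truth@de$gene_id[act]
    lfc <- truth@de$log2fc[act]
    hit <- dg %in% gid
    fac <- 2^(ifelse(gen == "P_cave", 1, -1) * lfc[hit] / 2)
    mu[dg[hit]] <- mu[dg[hit]] * fac
  }
  depth <- as.integer(if (config@dispersion > 0)
    stats::rnbinom(length(mu), mu = mu, size = 1 / config@dispersion)
  else stats::rpois(length(mu), mu))

  # cave-allele sampling fraction per gene
  aseFrac <- stats::setNames(rep(0.5, length(gid)), gid)
  if (nrow(truth@ase)) {
    hit <- truth@ase$gene_id %in% gid
    aseFrac[truth@ase$gene_id[hit]] <- truth@ase$caveFraction[hit]
  }
  pcave <- switch(gen,
    P_cave = rep(1, length(gid)),
    P_surface = rep(0, length(gid)),
    F1 = unname(aseFrac),
    F2 = {
      if (!length(truth@f2))
        stop("simulate the F2 cohort before F2 samples")
      g <- truth@f2$geneGenotypes[gid, sample$individual_id]
      ifelse(g == "CC", 1, ifelse(g == "SS", 0, unname(aseFrac)))
    })

  snpsByGene <- split(truth@snps, truth@snps$gene_id)
  out <- vector("list", length(gid))
  names(out) <- gid
  srcList <- vector("list", length(gid))
  for (i in seq_along(gid)) {
    g <- gid[i]
    L <- genes$length[i]
    nf <- depth[i]
    if (nf == 0L) {
      out[[i]] <- list(n = 0L, starts = integer(), eNd = integer(),
                       obs = data.frame(frag = integer(), pos = integer(),
                                        base = character()))
      next
    }
    starts <- sample.int(L - rl + 1L, nf, replace = TRUE)
    fromCave <- stats::runif(nf) < pcave[i]
    sn <- snpsByGene[[g]]
    obsF <- obsP <- integer(0)
    obsB <- character(0)
    nCov <- integer(nf)
    if (!is.null(sn) && nrow(sn)) {
      for (r in seq_len(nrow(sn))) {
        p <- sn$posSurface[r]          # indel-free: shared coordinates
        idx <- which(starts <= p & p < starts + rl)
        if (!length(idx)) next
        nCov[idx] <- nCov[idx] + 1L
        b <- ifelse(fromCave[idx], sn$caveBase[r], sn$surfaceBase[r])
        err <- which(stats::runif(length(idx)) < e)
        if (length(err))
          b[err] <- vapply(b[err], function(x)
            .otherBases[[x]][sample.int(3L, 1L)], "")
        obsF <- c(obsF, idx)
        obsP <- c(obsP, rep.int(p, length(idx)))
        obsB <- c(obsB, b)
      }
    }
    eNd <- stats::rbinom(nf, rl - nCov, e)
    out[[i]] <- list(n = nf, starts = starts, eNd = eNd,
                     obs = data.frame(frag = obsF, pos = obsP, base = obsB,
                                      stringsAsFactors = FALSE))
    if (mode == "sequence") srcList[[i]] <- fromCave
  }
  if (mode == "sequence") {
    # second pass so that the site-level draws above consume the RNG
    # stream identically in both output modes
    for (i in seq_along(gid)) {
      rec <- out[[i]]
      if (!rec$n) { out[[i]]$seqs <- character(); next }
      out[[i]]$seqs <- .materialiseReads(gid[i], truth, rec$starts,
                                         srcList[[i]], rec$eNd, rec$obs,
                                         rl)
      out[[i]]$eNd <- NULL  # sequences carry the errors explicitly
    }
  }
  structure(list(sample_id = sample$sample_id, mode = mode,
                 readLength = rl, generation = gen, genes = out),
            class = "SampleReads")
}

# Build literal read sequences consistent with the drawn site observations
# and non-site error counts.  Used by the "sequence" output mode.
.materialiseReads <- function(gene, truth, starts, fromCave, eNd, obs, rl) {
  gi <- match(gene, truth@genes$gene_id)
  # reconstruct allele strings from the truth SNP table requires the
  # transcript sequences; they are regenerated deterministically by the
  # caller via simulateTranscriptomes, so store chars on first use
  env <- .readSeqCache
  key <- paste0(truth@genes$gene_id[gi], "#", truth@genes$length[gi])
  if (is.null(env$chars[[key]]))
    stop("internal: allele sequences not registered for sequence mode; ",
         "use simulateStudyReads() or registerAlleleSeqs()")
  ch <- env$chars[[key]]
  n <- length(starts)
  bases <- c("A", "C", "G", "T")
  seqs <- character(n)
  for (j in seq_len(n)) {
    src <- if (fromCave[j]) ch$cave else ch$surface
    rd <- src[starts[j]:(starts[j] + rl - 1L)]
    # apply site observations (already error-injected)
    oj <- which(obs$frag == j)
    if (length(oj))
      rd[obs$pos[oj] - starts[j] + 1L] <- obs$base[oj]
    # inject the non-site errors at non-SNP positions
    if (eNd[j] > 0L) {
      sitePos <- obs$pos[oj] - starts[j] + 1L
      cand <- setdiff(seq_len(rl), sitePos)
      at <- sample(cand, min(eNd[j], length(cand)))
      for (p in at) rd[p] <- sample(setdiff(bases, rd[p]), 1L)
    }
    seqs[j] <- paste(rd, collapse = "")
  }
  seqs
}

.readSeqCache <- new.env(parent = emptyenv())
.readSeqCache$chars <- list()

#' Register allele sequences for sequence-mode read simulation
#'
#' Sequence-mode reads need the literal allele strings; call this once with
#' the simulated transcriptomes before requesting
#' `simulateSampleReads(..., mode = "sequence")`.
#'
#' @param sim the list returned by [simulateTranscriptomes()].
#' @return invisibly, the number of genes registered.
#' @export
registerAlleleSeqs <- function(sim) {
  truth <- sim$truth
  genes <- truth@genes[truth@genes$paired, , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    key <- paste0(g, "#", genes$length[i])
    .readSeqCache$chars[[key]] <- list(
      cave = strsplit(as.character(sim$cave[[paste0("cave_", g)]]), "")[[1]],
      surface = strsplit(as.character(sim$surface[[paste0("surf_", g)]]),
                         "")[[1]])
  }
  invisible(nrow(genes))
}

#' @export
print.SampleReads <- function(x, ...) {
  nf <- sum(vapply(x$genes, `[[`, 0L, "n"))
  cat("SampleReads '", x$sample_id, "' (", x$generation, "): ",
      nf, " fragments over ", length(x$genes), " genes, ",
      x$readLength, " bp, mode ", x$mode, "\n", sep = "")
  invisible(x)
}

#' Write a sequence-mode read set as FASTQ
#'
#' Phred+33 qualities are constant ("I", Q40); the simulator models
#' substitution errors directly rather than through a quality profile.
#'
#' @param reads a `SampleReads` object in `"sequence"` mode.
#' @param file output path.
#' @return invisibly, the number of reads written.
#' @export
writeSampleFastq <- function(reads, file) {
  stopifnot(inherits(reads, "SampleReads"))
  if (reads$mode != "sequence")
    stop("FASTQ export needs mode = 'sequence' reads")
  con <- file(file, "w")
  on.exit(close(con))
  total <- 0L
  qual <- strrep("I", reads$readLength)
  for (g in names(reads$genes)) {
    rec <- reads$genes[[g]]
    if (!rec$n) next
    ids <- sprintf("@%s:%s:%d", reads$sample_id, g, seq_len(rec$n))
    writeLines(rbind(ids, rec$seqs, "+", qual), con)
    total <- total + rec$n
  }
  invisible(total)
}
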