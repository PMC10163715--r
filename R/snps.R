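#' Per-position base counts of a sequence-mode read set
#'
#' @param seqs character vector of equal-length reads.
#' @param starts 1-based start positions on the transcript.
#' @param L transcript length.
#' @return a 4 x L integer matrix, rows A, C, G, T.
#' @export
pileupCounts <- function(seqs, starts, L) {
  out <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (!length(seqs)) return(out)
  rl <- nchar(seqs[1])
  ch <- unlist(strsplit(seqs, ""), use.names = FALSE)
  pos <- as.vector(t(outer(starts, 0:(rl - 1L), "+")))
  b <- match(ch, c("A", "C", "G", "T"))
  keep <- !is.na(b) & pos >= 1L & pos <= L
  idx <- (pos[keep] - 1L) * 4L + b[keep]
  tab <- tabulate(idx, 4L * L)
  out[] <- tab
  out
}

# Convert two full pileups into the aligned site table consumed by
# callFixedSNPs, walking the pair's coordinate map.
.pileupSiteTable <- function(cavePileup, surfPileup, caveSeq, surfSeq,
                             map = NULL) {
  cch <- strsplit(caveSeq, "")[[1]]
  sch <- strsplit(surfSeq, "")[[1]]
  if (is.null(map))
    map <- cbind(cave = seq_along(cch), surface = seq_along(sch))
  data.frame(posCave = map[, "cave"], posSurface = map[, "surface"],
             refCave = cch[map[, "cave"]], refSurface = sch[map[, "surface"]],
             cA = cavePileup["A", map[, "cave"]],
             cC = cavePileup["C", map[, "cave"]],
             cG = cavePileup["G", map[, "cave"]],
             cT = cavePileup["T", map[, "cave"]],
             sA = surfPileup["A", map[, "surface"]],
             sC = surfPileup["C", map[, "surface"]],
             sG = surfPileup["G", map[, "surface"]],
             sT = surfPileup["T", map[, "surface"]],
             stringsAsFactors = FALSE)
}

#' Call population-fixed diagnostic SNPs from parental pileups
#'
#' A site is a cave-fixed SNP when 100 percent of the covering
#' cave-population reads carry one base, that base differs from the
#' surface allele's base at the aligned position, and coverage is at
#' least `minSupport` (5 by default); symmetrically for surface-fixed
#' SNPs.  Sites at which both populations are fixed for the same base
#' (shared variants) are removed.  Positions are carried across the two
#' alleles by the pair's coordinate map, so indels between the alleles do
#' not break the correspondence.
#'
#' @param sites an aligned site table: columns posCave, posSurface,
#'   refCave, refSurface (allele bases) and per-population base counts
#'   cA..cT (cave population) and sA..sT (surface population).  Build it
#'   from full pileups with [pileupSiteTable()] or from accumulated
#'   site counts (see [studySiteList()] internals).
#' @param minSupport minimum covering reads on the defining side.
#' @return data.frame of diagnostic SNPs: posCave, posSurface, caveBase,
#'   surfaceBase, supportCave, supportSurface.
#' @export
callFixedSNPs <- function(sites, minSupport = 5L) {
  bs <- c("A", "C", "G", "T")
  cm <- as.matrix(sites[, paste0("c", bs)])
  sm <- as.matrix(sites[, paste0("s", bs)])
  cCov <- rowSums(cm); sCov <- rowSums(sm)
  cUnan <- rowSums(cm > 0) == 1L
  sUnan <- rowSums(sm > 0) == 1L
  cObs <- ifelse(cUnan & cCov > 0, bs[max.col(cm, ties.method = "first")],
                 NA)
  sObs <- ifelse(sUnan & sCov > 0, bs[max.col(sm, ties.method = "first")],
                 NA)
  caveFixed <- !is.na(cObs) & cCov >= minSupport & cObs != sites$refSurface
  surfFixed <- !is.na(sObs) & sCov >= minSupport & sObs != sites$refCave
  shared <- !is.na(cObs) & !is.na(sObs) & cObs == sObs
  keep <- (caveFixed | surfFixed) & !shared
  caveBase <- ifelse(is.na(cObs), sites$refCave, cObs)
  surfBase <- ifelse(is.na(sObs), sites$refSurface, sObs)
  keep <- keep & caveBase != surfBase
  data.frame(posCave = sites$posCave[keep],
             posSurface = sites$posSurface[keep],
             caveBase = caveBase[keep], surfaceBase = surfBase[keep],
             supportCave = cCov[keep], supportSurface = sCov[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname callFixedSNPs
#' @param cavePileup,surfPileup 4 x L base-count matrices
#'   ([pileupCounts()]) of the two parental populations against their own
#'   allele.
#' @param caveSeq,surfSeq the trimmed allele sequences (character).
#' @param map optional coordinate map (matched-position matrix); identity
#'   when NULL.
#' @export
pileupSiteTable <- function(cavePileup, surfPileup, caveSeq, surfSeq,
                            map = NULL)
  .pileupSiteTable(cavePileup, surfPileup, caveSeq, surfSeq, map)

#' Select up to five SNPs spanning a gene
#'
#' When more than `maxN` diagnostic SNPs are available the first and last
#' are always kept, plus the SNPs closest to the quarter, half and
#' three-quarter points of the spanned interval (ties broken leftmost),
#' maximizing positional spread along the transcript.
#'
#' @param positions numeric vector of SNP positions.
#' @param maxN maximum SNPs retained (default 5).
#' @return integer indices into `positions`, in positional order.
#' @examples
#' selectSpanningSNPs(seq(0, 900, by = 100))
#' @export
selectSpanningSNPs <- function(positions, maxN = 5L) {
  n <- length(positions)
  if (n == 0L) stop("at least one SNP required")
  o <- order(positions)
  if (n <= maxN) return(o)
  first <- o[1]; last <- o[n]
  chosen <- c(first, last)
  targets <- positions[first] +
    (positions[last] - positions[first]) * c(0.25, 0.5, 0.75)
  for (t in targets) {
    avail <- setdiff(o, chosen)
    d <- abs(positions[avail] - t)
    pick <- avail[order(d, positions[avail])][1]
    chosen <- c(chosen, pick)
  }
  chosen[order(positions[chosen])]
}

#' Count alleles at diagnostic SNPs in a sequence-mode read set
#'
#' Reads covering each SNP are partitioned by their observed base into
#' cave-allele and surface-allele counts; bases matching neither allele
#' are tallied separately (sequencing error) and excluded from the
#' counts.  The positions used are those of the reference named by
#' `reference`, mirroring a mapping run against that single-allele
#' reference; SNPs whose position falls outside the reference transcript
#' are skipped with a warning.
#'
#' @param seqs,starts fragments and their 1-based start positions on the
#'   chosen reference.
#' @param snps data.frame from [callFixedSNPs()].
#' @param reference `"cave"` or `"surface"`.
#' @param L reference transcript length (for bounds checking).
#' @return data.frame: pos, reference, nCave, nSurface, nOther.
#' @export
countAlleles <- function(seqs, starts, snps, reference = c("cave",
                         "surface"), L = NULL) {
  reference <- match.arg(reference)
  pos <- if (reference == "cave") snps$posCave else snps$posSurface
  if (!length(seqs))
    return(data.frame(pos = pos, reference = reference,
                      nCave = 0L, nSurface = 0L, nOther = 0L))
  rl <- nchar(seqs[1])
  M <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  out <- vector("list", length(pos))
  for (r in seq_along(pos)) {
    p <- pos[r]
    if (!is.null(L) && (p < 1L || p > L)) {
      warning("SNP position ", p, " outside the ", reference,
              " reference; skipped")
      next
    }
    idx <- which(starts <= p & p < starts + rl)
    b <- M[cbind(idx, p - starts[idx] + 1L)]
    out[[r]] <- data.frame(pos = p, reference = reference,
                           nCave = sum(b == snps$caveBase[r]),
                           nSurface = sum(b == snps$surfaceBase[r]),
                           nOther = sum(b != snps$caveBase[r] &
                                          b != snps$surfaceBase[r]))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(pos = integer(), reference = character(),
                      nCave = integer(), nSurface = integer(),
                      nOther = integer())
  rownames(res) <- NULL
  res
}

#' Allele counts at selected SNPs from accumulated site counts
#'
#' The site-level path of [countAlleles()]: looks the per-site ACGT
#' tallies of one sample up at the selected SNP positions.
#'
#' @param siteCounts per-sample site table (gene, pos, A, C, G, T) as
#'   returned by [quantifySample()].
#' @param gene gene id.
#' @param snps data.frame from [callFixedSNPs()] with a `pos` column in
#'   the same coordinates as `siteCounts` (indel-free data).
#' @param reference label recorded in the output.
#' @return as [countAlleles()].
#' @export
siteAlleleCounts <- function(siteCounts, gene, snps,
                             reference = c("cave", "surface")) {
  reference <- match.arg(reference)
  pos <- if (reference == "cave") snps$posCave else snps$posSurface
  sub <- siteCounts[siteCounts$gene == gene, , drop = FALSE]
  m <- match(pos, sub$pos)
  getb <- function(base, j) ifelse(is.na(j), 0L, sub[[base]][j])
  nC <- nS <- nO <- integer(length(pos))
  for (r in seq_along(pos)) {
    j <- m[r]
    tot <- c(A = getb("A", j), C = getb("C", j), G = getb("G", j),
             T = getb("T", j))
    nC[r] <- tot[[snps$caveBase[r]]]
    nS[r] <- tot[[snps$surfaceBase[r]]]
    nO[r] <- sum(tot) - nC[r] - nS[r]
  }
  data.frame(pos = pos, reference = reference, nCave = nC, nSurface = nS,
             nOther = nO, stringsAsFactors = FALSE)
}

# exact two-sided binomial p at predicted fraction 0.5 (vectorized);
# equals stats::binom.test for p = 0.5 by symmetry
.binomTwoSided <- function(x, n) {
  p <- ifelse(n > 0, pmin(1, 2 * stats::pbinom(pmin(x, n - x), n, 0.5)), 1)
  p
}

#' Gene-level allele-specific-expression decision from SNP allele counts
#'
#' Per SNP, sample and reference, a two-sided exact binomial test of the
#' cave-allele read count against a predicted fraction of 0.5 is
#' computed.  A gene is confirmed when at least `minSigSNPs` of its
#' representative SNPs are significant (p < `alpha`) in every hybrid
#' sample under both references.  Genes offering fewer than two selected
#' SNPs are flagged as not confirmable rather than raising an error, and
#' the dominant failure reason (low counts versus cross-reference or
#' cross-sample inconsistency) is recorded.
#'
#' @param counts long data.frame with columns gene, snp (identifier or
#'   position), sample, reference, nCave, nSurface.
#' @param alpha per-test significance threshold (default 0.05).
#' @param minSigSNPs SNPs that must be significant everywhere (default 2).
#' @param lowCount totals at or below this are reported as "low counts"
#'   when a gene fails (default 10).
#' @return list: `decisions` (gene, nSNPs, nSigSNPs, confirmed, reason)
#'   and `pvalues` (the input with a p column -- the per-SNP p-value
#'   grid).
#' @export
binomialDecision <- function(counts, alpha = 0.05, minSigSNPs = 2L,
                             lowCount = 10L) {
  counts$p <- .binomTwoSided(counts$nCave, counts$nCave + counts$nSurface)
  counts$sig <- counts$p < alpha
  key <- interaction(counts$gene, counts$snp, drop = TRUE)
  snpAllSig <- tapply(counts$sig, key, all)
  snpGene <- tapply(as.character(counts$gene), key, `[`, 1)
  genes <- unique(as.character(counts$gene))
  nS <- as.integer(table(factor(snpGene, levels = genes)))
  nSig <- as.integer(tapply(snpAllSig, factor(snpGene, levels = genes),
                            sum, default = 0L))
  confirmed <- nSig >= minSigSNPs & nS >= 2L
  low <- tapply(counts$nCave + counts$nSurface <= lowCount,
                factor(as.character(counts$gene), levels = genes), any)
  reason <- ifelse(confirmed, "",
                   ifelse(nS < 2L, "fewer than 2 SNPs",
                          ifelse(low, "low counts", "inconsistent")))
  list(decisions = data.frame(gene = genes, nSNPs = nS, nSigSNPs = nSig,
                              confirmed = confirmed, reason = reason,
                              row.names = NULL, stringsAsFactors = FALSE),
       pvalues = counts)
}
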