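#' Median-of-ratios size factors
#'
#' For every sample, the size factor is the median over genes (restricted
#' to genes expressed in all samples, i.e. with a finite log geometric
#' mean) of the ratio of the sample's count to the gene's geometric mean
#' across samples.  When no gene is expressed in every sample the
#' function falls back to total-count scaling with a warning.
#'
#' @param counts non-negative count matrix (genes x samples).
#' @return positive numeric vector of per-sample factors.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' medianOfRatios(m)   # 1 and 2, up to a common scale
#' @export
medianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use)) {
    warning("no gene expressed in all samples; using total-count scaling")
    tot <- colSums(counts)
    return(tot / mean(tot))
  }
  geo <- exp(logGeo[use])
  apply(counts[use, , drop = FALSE], 2, function(col) stats::median(col / geo))
}

#' Negative-binomial Wald test on normalized counts
#'
#' Per-gene two-sided Wald test of the log2 ratio of group means on
#' median-of-ratios normalized counts, with a method-of-moments NB
#' dispersion pooled across the two groups,
#' alpha = max(0, (s^2 - m)/m^2) averaged over groups, and
#' Benjamini-Hochberg adjustment across genes.  Genes at zero in both
#' groups get p = 1.
#'
#' @param counts non-negative integer-like matrix (genes x samples).
#' @param group factor/character of length ncol(counts) with two levels.
#' @param numerator,denominator the group labels forming the log2 fold
#'   change numerator and denominator (defaults: first and second level).
#' @param sizeFactors optional precomputed factors
#'   (default [medianOfRatios()]).
#' @param pseudocount added to group means for fold-change stability.
#' @return data.frame: gene, baseMean, log2fc, p, padj.
#' @export
nbWaldTest <- function(counts, group, numerator = NULL, denominator = NULL,
                       sizeFactors = NULL, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (is.null(numerator)) numerator <- lv[1]
  if (is.null(denominator)) denominator <- lv[2]
  if (sum(group == numerator) < 2L || sum(group == denominator) < 2L)
    stop("need >= 2 replicates per group")
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
  norm <- sweep(counts, 2, sizeFactors, "/")
  g1 <- norm[, group == numerator, drop = FALSE]
  g2 <- norm[, group == denominator, drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, stats::var); v2 <- apply(g2, 1, stats::var)
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, 0)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, 0)
  alpha <- pmax(0, (a1 + a2) / 2)
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  se2 <- ((m1 + alpha * m1^2) / n1 / (m1 + pseudocount)^2 +
          (m2 + alpha * m2^2) / n2 / (m2 + pseudocount)^2) / log(2)^2
  w <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(w))
  zero <- m1 == 0 & m2 == 0
  p[zero] <- 1; lfc[zero] <- 0
  data.frame(gene = rownames(counts), baseMean = (m1 + m2) / 2,
             log2fc = lfc, p = p, padj = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dual-reference concordant differential expression
#'
#' A gene is called biased only when it passes the adjusted-p and
#' magnitude thresholds with the same sign against BOTH references: cave
#' biased when both log2 fold changes (cave relative to surface) are
#' >= `lfcThreshold`, surface biased when both are <= -`lfcThreshold`.
#'
#' @param resCave,resSurface [nbWaldTest()]-style result tables (columns
#'   gene, log2fc, padj) from counts against the cave and the surface
#'   reference; must cover the same gene set.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfcThreshold log2 fold-change magnitude threshold (default 2).
#' @return data.frame: gene, log2fcCave, log2fcSurface, padjCave,
#'   padjSurface, concordant, bias (factor cave/surface/none).
#' @export
concordantDE <- function(resCave, resSurface, alpha = 0.05,
                         lfcThreshold = 2) {
  if (!setequal(resCave$gene, resSurface$gene))
    stop("gene sets differ between the two reference results")
  m <- match(resCave$gene, resSurface$gene)
  lc <- resCave$log2fc; ls <- resSurface$log2fc[m]
  pc <- resCave$padj; ps <- resSurface$padj[m]
  sig <- pc < alpha & ps < alpha
  up <- sig & lc >= lfcThreshold & ls >= lfcThreshold
  dn <- sig & lc <= -lfcThreshold & ls <= -lfcThreshold
  bias <- rep("none", length(lc))
  bias[up] <- "cave"; bias[dn] <- "surface"
  data.frame(gene = resCave$gene, log2fcCave = lc, log2fcSurface = ls,
             padjCave = pc, padjSurface = ps,
             concordant = up | dn,
             bias = factor(bias, levels = c("cave", "surface", "none")),
             stringsAsFactors = FALSE)
}

#' Read an external per-gene DE result table
#'
#' Ingests a TSV with columns gene, log2fc, padj (for example exported
#' from another DE tool) so the concordance logic can run on external
#' results.
#'
#' @param file TSV path (header required).
#' @return data.frame usable as an argument to [concordantDE()].
#' @export
readDEResults <- function(file) {
  tb <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(tb)))
    stop("expected columns: ", paste(need, collapse = ", "))
  tb
}

#' Differential expression between parental ecomorphs, both references
#'
#' Runs the NB-Wald test on the per-reference mapped totals (assays
#' `mapCave` and `mapSurface`) of the parental samples at one stage and
#' combines the two results with [concordantDE()].  Falls back to the
#' combined totals for both references (with a warning) when
#' single-reference totals are absent.
#'
#' @param ac an [AlleleCounts-class] containing parental samples.
#' @param stage parental stage to compare (e.g. "late").
#' @param alpha,lfcThreshold thresholds passed to [concordantDE()].
#' @return list: `cave`, `surface` (per-reference [nbWaldTest()] tables),
#'   `result` (the [concordantDE()] table).
#' @export
differentialExpression <- function(ac, stage = "late", alpha = 0.05,
                                   lfcThreshold = 2) {
  cd <- SummarizedExperiment::colData(ac)
  sel <- cd$generation %in% c("P_cave", "P_surface") & cd$stage == stage
  if (sum(sel) < 4L) stop("need >= 2 parental replicates per ecomorph")
  group <- cd$generation[sel]
  an <- SummarizedExperiment::assayNames(ac)
  if (all(c("mapCave", "mapSurface") %in% an)) {
    cc <- SummarizedExperiment::assay(ac, "mapCave")[, sel, drop = FALSE]
    cs <- SummarizedExperiment::assay(ac, "mapSurface")[, sel, drop = FALSE]
  } else {
    warning("no per-reference totals; using combined totals for both")
    cc <- cs <- totalCounts(ac)[, sel, drop = FALSE]
  }
  resC <- nbWaldTest(round(cc), group, numerator = "P_cave",
                     denominator = "P_surface")
  resS <- nbWaldTest(round(cs), group, numerator = "P_cave",
                     denominator = "P_surface")
  list(cave = resC, surface = resS,
       result = concordantDE(resC, resS, alpha, lfcThreshold))
}
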