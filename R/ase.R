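# cross-multiplied ratio test: a >= factor * b, requiring signal
.ratioPass <- function(a, b, factor) a >= factor * b & (a + b) > 0

#' Parental allele-fidelity filter
#'
#' A gene is kept only when every cave parental sample assigns at least
#' `biasFactor` times more fragments to the cave allele than to the
#' surface allele, and every surface parental sample shows the mirror
#' image.  This removes pairs whose alleles cross-attract reads through
#' assembly or trimming artefacts before any hybrid is examined.  All
#' comparisons are cross-multiplied (no division), so zero denominators
#' are exact; a sample with zero counts on both alleles fails the filter.
#'
#' @param ac an [AlleleCounts-class].
#' @param biasFactor ratio threshold (default 3.3, inclusive).
#' @param pooled pool replicates per ecomorph instead of requiring every
#'   replicate to pass (default FALSE: per-replicate, the stricter
#'   reading).
#' @param stage restrict parental samples to one stage (NULL = all).
#' @return data.frame: gene, passedFidelity (logical), caveOk, surfaceOk.
#' @export
parentalFidelityFilter <- function(ac, biasFactor = 3.3, pooled = FALSE,
                                   stage = NULL) {
  stopifnot(biasFactor > 1)
  cd <- SummarizedExperiment::colData(ac)
  sel <- cd$generation %in% c("P_cave", "P_surface")
  if (!is.null(stage)) sel <- sel & cd$stage == stage
  if (!any(cd$generation[sel] == "P_cave") ||
      !any(cd$generation[sel] == "P_surface"))
    stop("need parental samples of both ecomorphs")
  zc <- zCave(ac)[, sel, drop = FALSE]
  zs <- zSurface(ac)[, sel, drop = FALSE]
  isCave <- cd$generation[sel] == "P_cave"
  if (pooled) {
    caveOk <- .ratioPass(rowSums(zc[, isCave, drop = FALSE]),
                         rowSums(zs[, isCave, drop = FALSE]), biasFactor)
    surfOk <- .ratioPass(rowSums(zs[, !isCave, drop = FALSE]),
                         rowSums(zc[, !isCave, drop = FALSE]), biasFactor)
  } else {
    caveOk <- rowSums(!.ratioPass(zc[, isCave, drop = FALSE],
                                  zs[, isCave, drop = FALSE],
                                  biasFactor)) == 0
    surfOk <- rowSums(!.ratioPass(zs[, !isCave, drop = FALSE],
                                  zc[, !isCave, drop = FALSE],
                                  biasFactor)) == 0
  }
  data.frame(gene = rownames(zc), passedFidelity = caveOk & surfOk,
             caveOk = caveOk, surfaceOk = surfOk,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' F1 hybrid allele-bias calls
#'
#' A gene is called biased toward the cave allele when every F1 hybrid
#' sample assigns at least `biasFactor` times more fragments to the cave
#' allele than to the surface allele (cross-multiplied, zero-safe), and
#' toward the surface allele in the mirror case; otherwise no call.
#' Optionally, genes without an annotation id and genes whose annotation
#' id is shared by `maxSharedAnnotation` or more transcripts (summed over
#' both transcriptomes) are removed afterwards.
#'
#' @param ac an [AlleleCounts-class].
#' @param biasFactor ratio threshold (default 3.3, inclusive).
#' @param genes optional gene subset (typically the fidelity-passing set).
#' @param annotations optional [annotationTable()]-style data.frame; when
#'   supplied the annotation filters are applied.
#' @param maxSharedAnnotation remove annotation ids carried by this many
#'   or more transcripts (default 9).
#' @return data.frame: gene, direction (factor cave_allele /
#'   surface_allele), minRatio (smallest per-hybrid cross ratio, Inf when
#'   the disfavoured allele is at zero everywhere), plus one ratio column
#'   per hybrid.  Genes with no call are omitted.
#' @export
hybridBias <- function(ac, biasFactor = 3.3, genes = NULL,
                       annotations = NULL, maxSharedAnnotation = 9L) {
  stopifnot(biasFactor > 1)
  cd <- SummarizedExperiment::colData(ac)
  sel <- cd$generation == "F1"
  if (!any(sel)) stop("no F1 hybrid samples in the object")
  zc <- zCave(ac)[, sel, drop = FALSE]
  zs <- zSurface(ac)[, sel, drop = FALSE]
  if (!is.null(genes)) {
    zc <- zc[rownames(zc) %in% genes, , drop = FALSE]
    zs <- zs[rownames(zs) %in% genes, , drop = FALSE]
  }
  caveAll <- rowSums(!.ratioPass(zc, zs, biasFactor)) == 0
  surfAll <- rowSums(!.ratioPass(zs, zc, biasFactor)) == 0
  dir <- ifelse(caveAll & !surfAll, "cave_allele",
                ifelse(surfAll & !caveAll, "surface_allele", NA))
  keep <- !is.na(dir)
  ratios <- zc / zs
  out <- data.frame(gene = rownames(zc)[keep],
                    direction = factor(dir[keep],
                      levels = c("cave_allele", "surface_allele")),
                    stringsAsFactors = FALSE)
  rr <- ratios[keep, , drop = FALSE]
  # orient ratios in the called direction so minRatio >= biasFactor
  flip <- out$direction == "surface_allele"
  rr[flip, ] <- 1 / rr[flip, , drop = FALSE]
  out$minRatio <- apply(rr, 1, min)
  colnames(rr) <- paste0("ratio_", colnames(zc))
  out <- cbind(out, as.data.frame(rr, optional = TRUE))
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    an <- annotations[match(out$gene, annotations$gene_id), , drop = FALSE]
    shared <- an$copiesCave + an$copiesSurface
    drop <- is.na(an$annotation_id) |
      (!is.na(shared) & shared >= maxSharedAnnotation)
    removed <- out$gene[drop]
    out <- out[!drop, , drop = FALSE]
    attr(out, "removedByAnnotation") <- removed
  }
  out
}

#' Intersect allele-bias calls with concordant differential expression
#'
#' Genes are prioritized when the hybrid allele bias and the
#' between-ecomorph expression bias point the same way (cave allele with
#' cave-biased expression, surface allele with surface-biased
#' expression).  Calls without differential expression are retained in
#' the report but not prioritized; direction disagreements are flagged
#' discordant, never silently dropped.
#'
#' @param aseCalls result of [hybridBias()].
#' @param deResult result table of [concordantDE()].
#' @return `aseCalls` with columns deBias, intersectsDE, discordant
#'   added; the prioritized subset is `subset(out, intersectsDE)`.
#' @export
intersectWithDE <- function(aseCalls, deResult) {
  m <- match(aseCalls$gene, deResult$gene)
  deBias <- as.character(deResult$bias[m])
  deBias[is.na(deBias)] <- "none"
  agree <- (aseCalls$direction == "cave_allele" & deBias == "cave") |
    (aseCalls$direction == "surface_allele" & deBias == "surface")
  discord <- deBias != "none" & !agree
  out <- aseCalls
  out$deBias <- deBias
  out$intersectsDE <- agree
  out$discordant <- discord
  out
}
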