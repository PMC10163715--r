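# Shared decision kernel: assign each fragment to an allele from its votes
# at diagnostic sites and its mismatch counts against the two alleles.
.classifyKernel <- function(votesCave, votesSurface, mmCave, mmSurface,
                            tol = 3L) {
  lab <- rep("ambiguous", length(votesCave))
  lab[votesCave > votesSurface] <- "cave"
  lab[votesSurface > votesCave] <- "surface"
  lab[pmin(mmCave, mmSurface) > tol] <- "incompatible"
  factor(lab, levels = c("cave", "surface", "ambiguous", "incompatible"))
}

#' Classify sequence fragments against an allele pair
#'
#' Each fragment, located on the pair by its start position, is compared
#' to both alleles.  At the diagnostic sites it covers it votes for the
#' allele whose base it matches; the fragment is labelled for the allele
#' with strictly more votes, `ambiguous` if it covers no diagnostic site
#' or ties, and `incompatible` if its mismatch count against both alleles
#' exceeds `tol`.
#'
#' @param seqs character vector of fragment sequences (equal length).
#' @param starts 1-based start positions on the (indel-free) pair
#'   coordinate system.
#' @param caveSeq,surfSeq the two allele sequences (character).
#' @param sites data.frame of diagnostic sites as from [pairDiffSites()]
#'   (columns posCave, caveBase, surfaceBase; cave coordinates are used).
#' @param tol mismatch tolerance (default 3).
#' @return data.frame: label (factor cave/surface/ambiguous/incompatible),
#'   votesCave, votesSurface, mmCave, mmSurface.
#' @examples
#' classifyFragments("ACGT", 1L, "ACGT", "AGGT",
#'   data.frame(posCave = 2L, caveBase = "C", surfaceBase = "G"))
#' @export
classifyFragments <- function(seqs, starts, caveSeq, surfSeq, sites,
                              tol = 3L) {
  rl <- unique(nchar(seqs))
  if (length(rl) > 1L) stop("fragments must have equal length")
  if (!length(seqs))
    return(data.frame(label = factor(character(),
      levels = c("cave", "surface", "ambiguous", "incompatible")),
      votesCave = integer(), votesSurface = integer(),
      mmCave = integer(), mmSurface = integer()))
  n <- length(seqs)
  M <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = n, byrow = TRUE)
  cch <- strsplit(caveSeq, "")[[1]]
  sch <- strsplit(surfSeq, "")[[1]]
  POS <- outer(starts, 0:(rl - 1L), "+")
  ok <- POS <= length(cch)   # fragments must fit; guard ragged ends
  mmCave <- rowSums(M != matrix(cch[pmin(POS, length(cch))], n) & ok)
  okS <- POS <= length(sch)
  mmSurface <- rowSums(M != matrix(sch[pmin(POS, length(sch))], n) & okS)
  votesC <- votesS <- integer(n)
  for (r in seq_len(nrow(sites))) {
    p <- sites$posCave[r]
    idx <- which(starts <= p & p < starts + rl)
    if (!length(idx)) next
    b <- M[cbind(idx, p - starts[idx] + 1L)]
    votesC[idx] <- votesC[idx] + (b == sites$caveBase[r])
    votesS[idx] <- votesS[idx] + (b == sites$surfaceBase[r])
  }
  data.frame(label = .classifyKernel(votesC, votesS, mmCave, mmSurface, tol),
             votesCave = votesC, votesSurface = votesS,
             mmCave = mmCave, mmSurface = mmSurface)
}

#' Apportion ambiguous fragments between the two alleles
#'
#' Fragments covering no diagnostic site are split between the alleles in
#' proportion to the informative fragments, by iterating
#' theta <- (nCave + theta * nAmb) / (nCave + nSurface + nAmb) to its
#' fixed point (closed form theta = nCave / (nCave + nSurface); a 50:50
#' split when no informative fragments exist).  The resulting Z-values are
#' zCave = nCave + theta * nAmb and zSurface the complement, preserving
#' the total.
#'
#' @param nCave,nSurface,nAmbiguous integer vectors (per pair).
#' @param maxIter,tol iteration controls for `method = "iterate"`.
#' @param method `"closed"` (default) or `"iterate"` (verifies the fixed
#'   point numerically).
#' @return data.frame: zCave, zSurface, theta.
#' @examples
#' emAlleleAbundance(80, 20, 100)   # zCave 160, zSurface 40
#' @export
emAlleleAbundance <- function(nCave, nSurface, nAmbiguous,
                              maxIter = 100L, tol = 1e-10,
                              method = c("closed", "iterate")) {
  method <- match.arg(method)
  stopifnot(length(nCave) == length(nSurface),
            length(nCave) == length(nAmbiguous))
  inf <- nCave + nSurface
  if (method == "closed") {
    theta <- ifelse(inf > 0, nCave / inf, 0.5)
  } else {
    theta <- rep(0.5, length(nCave))
    tot <- inf + nAmbiguous
    for (it in seq_len(maxIter)) {
      new <- ifelse(tot > 0, (nCave + theta * nAmbiguous) / tot, 0.5)
      # the update has fixed point nCave/inf; damped form converges there
      if (max(abs(new - theta)) < tol) { theta <- new; break }
      theta <- new
    }
    theta <- ifelse(inf > 0, theta, 0.5)
  }
  data.frame(zCave = nCave + theta * nAmbiguous,
             zSurface = nSurface + (1 - theta) * nAmbiguous,
             theta = theta)
}

# site observations of one gene (frag, pos, base) -> per-fragment votes
# and site-level mismatch counts; shared by the sites-mode quantifier
.votesFromObs <- function(obs, n, sites) {
  votesC <- votesS <- dC <- dS <- integer(n)
  if (nrow(obs) && nrow(sites)) {
    m <- match(obs$pos, sites$pos)
    keep <- !is.na(m)
    if (any(keep)) {
      f <- obs$frag[keep]
      isC <- obs$base[keep] == sites$caveBase[m[keep]]
      isS <- obs$base[keep] == sites$surfaceBase[m[keep]]
      votesC <- votesC + tabulate(f[isC], n)
      votesS <- votesS + tabulate(f[isS], n)
      dC <- dC + tabulate(f[!isC], n)
      dS <- dS + tabulate(f[!isS], n)
    }
  }
  list(votesC = votesC, votesS = votesS, dC = dC, dS = dS)
}

#' Quantify one sample against the allele-pair reference
#'
#' Classifies every fragment of the sample (majority vote at the
#' diagnostic sites of its gene's pair), apportions ambiguous fragments
#' with [emAlleleAbundance()], and tallies per-single-reference mapped
#' totals (fragments within `tol` mismatches of that allele), emulating
#' separate mapping runs against each assembly.  Per-site base counts are
#' accumulated for downstream SNP calling and allele counting.
#'
#' @param reads a `SampleReads` object ([simulateSampleReads()]).
#' @param siteList named list (by gene) of diagnostic-site data.frames
#'   with columns pos (position in the reads' coordinate system),
#'   caveBase, surfaceBase.  For simulated indel-free data use
#'   [studySiteList()].
#' @param tol mismatch tolerance for compatibility (default 3).
#' @return list with `abundance` (data.frame gene, nCave, nSurface,
#'   nAmbiguous, nIncompatible, zCave, zSurface, mapCave, mapSurface) and
#'   `siteCounts` (data.frame gene, pos, A, C, G, T).
#' @export
quantifySample <- function(reads, siteList, tol = 3L) {
  stopifnot(inherits(reads, "SampleReads"))
  genes <- names(reads$genes)
  ng <- length(genes)
  nCave <- nSurf <- nAmb <- nInc <- mapC <- mapS <- integer(ng)
  zC <- zS <- numeric(ng)
  sc <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- genes[i]
    rec <- reads$genes[[g]]
    sites <- siteList[[g]]
    if (is.null(sites))
      sites <- data.frame(pos = integer(), caveBase = character(),
                          surfaceBase = character())
    if (!rec$n) next
    if (reads$mode == "sites") {
      v <- .votesFromObs(rec$obs, rec$n, sites)
      mmC <- rec$eNd + v$dC
      mmS <- rec$eNd + v$dS
      lab <- .classifyKernel(v$votesC, v$votesS, mmC, mmS, tol)
    } else {
      stop("sequence-mode reads: use classifyFragments() per gene, or ",
           "simulate in 'sites' mode for whole-sample quantification")
    }
    tab <- table(lab)
    nCave[i] <- tab[["cave"]]; nSurf[i] <- tab[["surface"]]
    nAmb[i] <- tab[["ambiguous"]]; nInc[i] <- tab[["incompatible"]]
    em <- emAlleleAbundance(nCave[i], nSurf[i], nAmb[i])
    zC[i] <- em$zCave; zS[i] <- em$zSurface
    mapC[i] <- sum(mmC <= tol)
    mapS[i] <- sum(mmS <= tol)
    if (nrow(rec$obs)) {
      bt <- table(factor(rec$obs$pos),
                  factor(rec$obs$base, levels = c("A", "C", "G", "T")))
      sc[[i]] <- data.frame(gene = g,
                            pos = as.integer(rownames(bt)),
                            A = as.integer(bt[, "A"]),
                            C = as.integer(bt[, "C"]),
                            G = as.integer(bt[, "G"]),
                            T = as.integer(bt[, "T"]),
                            stringsAsFactors = FALSE)
    }
  }
  siteCounts <- do.call(rbind, sc[!vapply(sc, is.null, logical(1))])
  if (is.null(siteCounts))
    siteCounts <- data.frame(gene = character(), pos = integer(),
                             A = integer(), C = integer(), G = integer(),
                             T = integer())
  list(abundance = data.frame(gene = genes, nCave = nCave,
                              nSurface = nSurf, nAmbiguous = nAmb,
                              nIncompatible = nInc, zCave = zC,
                              zSurface = zS, mapCave = mapC,
                              mapSurface = mapS, stringsAsFactors = FALSE),
       siteCounts = siteCounts)
}

#' Quantify a sequence-mode sample via fragment classification
#'
#' The sequence-level path of [quantifySample()]: runs
#' [classifyFragments()] per gene against the trimmed alleles and then
#' the same apportionment and tallies.  Intended for small read sets and
#' for verifying the site-level fast path.
#'
#' @param reads `SampleReads` in `"sequence"` mode.
#' @param tp a [TranscriptPairSet-class].
#' @param geneMap named character: gene id -> pair id.
#' @param tol mismatch tolerance.
#' @return as [quantifySample()], without `siteCounts`.
#' @export
quantifySampleSeq <- function(reads, tp, geneMap, tol = 3L) {
  stopifnot(inherits(reads, "SampleReads"), reads$mode == "sequence")
  diffs <- pairDiffSites(tp)
  genes <- names(reads$genes)
  caveCh <- as.character(tp@cave)
  surfCh <- as.character(tp@surface)
  info <- tp@pairs
  out <- lapply(genes, function(g) {
    rec <- reads$genes[[g]]
    pid_ <- geneMap[[g]]
    if (is.null(pid_) || !rec$n)
      return(data.frame(gene = g, nCave = 0L, nSurface = 0L,
                        nAmbiguous = 0L, nIncompatible = 0L, zCave = 0,
                        zSurface = 0, mapCave = 0L, mapSurface = 0L))
    j <- match(pid_, info$pair_id)
    # reads carry full-transcript coordinates; shift to trimmed coords
    off <- info$caveStart[j] - 1L
    st <- rec$starts - off
    sites <- diffs[[pid_]]
    cl <- classifyFragments(rec$seqs, st, caveCh[[j]], surfCh[[j]],
                            sites, tol)
    tab <- table(cl$label)
    em <- emAlleleAbundance(tab[["cave"]], tab[["surface"]],
                            tab[["ambiguous"]])
    data.frame(gene = g, nCave = tab[["cave"]], nSurface = tab[["surface"]],
               nAmbiguous = tab[["ambiguous"]],
               nIncompatible = tab[["incompatible"]],
               zCave = em$zCave, zSurface = em$zSurface,
               mapCave = sum(cl$mmCave <= tol),
               mapSurface = sum(cl$mmSurface <= tol),
               stringsAsFactors = FALSE)
  })
  list(abundance = do.call(rbind, out))
}

#' Assemble per-sample abundances into an AlleleCounts object
#'
#' @param quantList named list (by sample id) of [quantifySample()]
#'   results.
#' @param samples the sample sheet (rows matching `names(quantList)`).
#' @return an [AlleleCounts-class] with assays zCave, zSurface, mapCave,
#'   mapSurface.
#' @export
abundanceMatrix <- function(quantList, samples) {
  sids <- names(quantList)
  if (!all(sids %in% rownames(samples)))
    stop("samples sheet does not cover all quantified samples")
  genes <- quantList[[1]]$abundance$gene
  pull <- function(col) {
    m <- vapply(sids, function(s) {
      ab <- quantList[[s]]$abundance
      if (!identical(ab$gene, genes))
        stop("sample '", s, "' was quantified against a different pair set")
      ab[[col]]
    }, numeric(length(genes)))
    dimnames(m) <- list(genes, sids)
    m
  }
  AlleleCounts(zCave = pull("zCave"), zSurface = pull("zSurface"),
               mapCave = pull("mapCave"), mapSurface = pull("mapSurface"),
               colData = samples[sids, , drop = FALSE])
}

#' Write / read a long-format Z-value table
#'
#' `writeZMatrix` emits sample_id, pair_id, z_cave, z_surface (TSV);
#' `readZMatrix` ingests the same layout (for example Z-values computed by
#' an external quantifier), plus a sample sheet giving each sample's
#' generation, and rebuilds an [AlleleCounts-class].
#'
#' @param ac an [AlleleCounts-class].
#' @param file TSV path.
#' @param samples data.frame with rownames = sample ids and at least a
#'   `generation` column.
#' @return `writeZMatrix`: invisibly, rows written; `readZMatrix`: an
#'   [AlleleCounts-class].
#' @export
writeZMatrix <- function(ac, file) {
  zc <- zCave(ac); zs <- zSurface(ac)
  long <- data.frame(
    sample_id = rep(colnames(zc), each = nrow(zc)),
    pair_id = rep(rownames(zc), ncol(zc)),
    z_cave = as.vector(zc), z_surface = as.vector(zs))
  utils::write.table(long, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(nrow(long))
}

#' @rdname writeZMatrix
#' @export
readZMatrix <- function(file, samples) {
  long <- utils::read.table(file, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "pair_id", "z_cave", "z_surface")
  if (!all(need %in% names(long)))
    stop("expected columns: ", paste(need, collapse = ", "))
  genes <- unique(long$pair_id)
  sids <- unique(long$sample_id)
  shape <- function(col) {
    m <- matrix(0, length(genes), length(sids),
                dimnames = list(genes, sids))
    m[cbind(match(long$pair_id, genes), match(long$sample_id, sids))] <-
      long[[col]]
    m
  }
  AlleleCounts(zCave = shape("z_cave"), zSurface = shape("z_surface"),
               colData = samples[sids, , drop = FALSE])
}
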