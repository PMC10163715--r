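#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment
#'   nucleotideSubstitutionMatrix alignedPattern alignedSubject score pid
#'   writeXStringSet subseq
NULL

.subMat <- function(match = 1, mismatch = -2)
  Biostrings::nucleotideSubstitutionMatrix(match = match,
                                           mismatch = mismatch,
                                           baseOnly = TRUE)

.baseCode <- c(A = 0, C = 1, G = 2, T = 3)

.charVec <- function(s) strsplit(s, "")[[1]]

# integer codes of all overlapping k-mers (base-4 rolling encoding;
# exact in doubles up to k = 26, NA across ambiguous bases)
.kmerCodes <- function(chv, k = 11L) {
  v <- .baseCode[chv]
  n <- length(v)
  if (n < k) return(numeric())
  km <- stats::filter(v, 4^(0:(k - 1)), method = "convolution", sides = 1)
  as.numeric(km[k:n])
}

# all (query, subject) index pairs sharing exact k-mers, with the number
# of distinct shared k-mers per pair; one sorted global pass, no
# per-query hashing
.candidatePairs <- function(qkm, skm) {
  squ <- lapply(skm, function(x) unique(x[!is.na(x)]))
  qqu <- lapply(qkm, function(x) unique(x[!is.na(x)]))
  sv <- unlist(squ, use.names = FALSE)
  si <- rep(seq_along(squ), lengths(squ))
  qv <- unlist(qqu, use.names = FALSE)
  qi <- rep(seq_along(qqu), lengths(qqu))
  if (!length(sv) || !length(qv))
    return(data.frame(q = integer(), s = integer(), nShared = integer()))
  o <- order(sv)
  sv <- sv[o]; si <- si[o]
  lo <- findInterval(qv - 0.5, sv) + 1L
  hi <- findInterval(qv + 0.5, sv)
  len <- pmax(0L, hi - lo + 1L)
  keep <- len > 0L
  if (!any(keep))
    return(data.frame(q = integer(), s = integer(), nShared = integer()))
  qrep <- rep(qi[keep], len[keep])
  sidx <- si[sequence(len[keep], from = lo[keep])]
  ns <- length(skm)
  r <- rle(sort((qrep - 1) * ns + sidx))
  data.frame(q = (r$values - 1) %/% ns + 1L,
             s = (r$values - 1) %% ns + 1L,
             nShared = r$lengths)
}

.alignLocal <- function(q, s, match = 1, mismatch = -2,
                        gapOpening = 5, gapExtension = 2) {
  Biostrings::pairwiseAlignment(q, s, type = "local",
    substitutionMatrix = .subMat(match, mismatch),
    gapOpening = gapOpening, gapExtension = gapExtension)
}

# maximum-sum subarray (Kadane, vectorized): the optimal local alignment
# restricted to one diagonal under +match/-mismatch scoring
.maxSubarray <- function(x) {
  s <- cumsum(x)
  prefix <- c(0, s[-length(s)])
  m <- cummin(prefix)
  val <- s - m
  end <- which.max(val)
  start <- which(prefix[seq_len(end)] == m[end])[1]
  list(score = val[end], start = start, end = end)
}

# dominant shared-kmer diagonal between two code vectors
.seedDiagonals <- function(qkm, skm) {
  if (!length(qkm) || !length(skm)) return(NULL)
  m <- match(qkm, skm)
  hit <- !is.na(m)
  if (!any(hit)) return(NULL)
  d <- which(hit) - m[hit]
  tab <- table(d)
  best <- as.integer(names(tab)[which.max(tab)])
  list(diag = best, share = max(tab) / sum(hit), nSeeds = sum(hit))
}

# gapless local alignment along one diagonal (qpos = spos + diag);
# exact Smith-Waterman result whenever the optimum contains no gap
.diagonalAlign <- function(qc, sc, diag, match = 1, mismatch = -2) {
  nq <- length(qc); ns <- length(sc)
  sFrom <- max(1L, 1L - diag)
  sTo <- min(ns, nq - diag)
  if (sTo < sFrom) return(NULL)
  sIdx <- sFrom:sTo
  qIdx <- sIdx + diag
  eq <- qc[qIdx] == sc[sIdx]
  best <- .maxSubarray(ifelse(eq, match, mismatch))
  len <- best$end - best$start + 1L
  nmatch <- sum(eq[best$start:best$end])
  list(score = best$score,
       qstart = qIdx[best$start], qend = qIdx[best$end],
       sstart = sIdx[best$start], send = sIdx[best$end],
       alignedLength = len, identity = 100 * nmatch / len,
       gapless = TRUE)
}

# hit between one query and one subject given precomputed char and kmer
# vectors: seed-diagonal fast path; full Smith-Waterman only when seed
# support is strong but split across diagonals (real indels)
.pairHitPre <- function(qc, sc, qkm, skm, qxs = NULL, sxs = NULL,
                        diagShare = 0.9, swSeedMin = 10L) {
  sd <- .seedDiagonals(qkm, skm)
  if (is.null(sd)) return(NULL)
  if (sd$share >= diagShare || sd$nSeeds < swSeedMin) {
    da <- .diagonalAlign(qc, sc, sd$diag)
    if (!is.null(da)) return(da)
  }
  if (is.null(qxs)) qxs <- Biostrings::DNAString(paste(qc, collapse = ""))
  if (is.null(sxs)) sxs <- Biostrings::DNAString(paste(sc, collapse = ""))
  pa <- .alignLocal(qxs, sxs)
  p <- Biostrings::pattern(pa)
  sj <- Biostrings::subject(pa)
  list(score = Biostrings::score(pa),
       qstart = BiocGenerics::start(p), qend = BiocGenerics::end(p),
       sstart = BiocGenerics::start(sj), send = BiocGenerics::end(sj),
       alignedLength = nchar(as.character(Biostrings::alignedPattern(pa))),
       identity = Biostrings::pid(pa, type = "PID1"),
       gapless = FALSE)
}

# convenience wrapper over two sequences
.pairHit <- function(q, s, qs, ss, wordSize = 11L, diagShare = 0.9) {
  qc <- .charVec(qs); sc <- .charVec(ss)
  .pairHitPre(qc, sc, .kmerCodes(qc, wordSize), .kmerCodes(sc, wordSize),
              q, s, diagShare)
}

#' All-vs-all nucleotide hits between two transcript sets
#'
#' A seed-and-extend aligner standing in for a BLAST search: candidate
#' subject transcripts are those sharing at least one exact 11-mer with
#' the query (so sequences with no shared 11-mer produce no hit).  When
#' the seed matches of a candidate fall overwhelmingly on one diagonal
#' the extension is a gapless local alignment along that diagonal
#' (a maximum-scoring-segment scan, which equals the Smith-Waterman
#' optimum whenever that optimum contains no gap); otherwise -- e.g.
#' across indels -- a full local Smith-Waterman is run.  Scoring is
#' match +1, mismatch -2, gap opening 5, gap extension 2 throughout.
#' Hits below `minScore` are dropped.  Tabular hits from an external
#' aligner can be ingested instead via [readHitsTable()].
#'
#' @param query,subject named [Biostrings::DNAStringSet] objects (or
#'   named character vectors).
#' @param minScore minimum alignment score to report.
#' @param wordSize exact seed length.
#' @param minSeeds minimum number of distinct shared seeds before an
#'   extension is attempted (a BLAST-like multi-hit heuristic that skips
#'   chance single-seed collisions between unrelated transcripts).
#' @return a data.frame with columns query_id, subject_id, score,
#'   identity (percent, over alignment columns), alignedLength (alignment
#'   columns), qstart, qend, sstart, send (1-based, closed).
#' @examples
#' a <- Biostrings::DNAStringSet(c(x = strrep("ACGTT", 60)))
#' allVsAllHits(a, a)
#' @export
allVsAllHits <- function(query, subject, minScore = 40, wordSize = 11L,
                         minSeeds = 5L) {
  if (is.character(query)) query <- Biostrings::DNAStringSet(query)
  if (is.character(subject)) subject <- Biostrings::DNAStringSet(subject)
  if (!length(query) || !length(subject))
    stop("empty input sequence set")
  if (is.null(names(query)) || is.null(names(subject)))
    stop("sequences must be named")
  qcv <- lapply(as.character(query), .charVec)
  scv <- lapply(as.character(subject), .charVec)
  qkm <- lapply(qcv, .kmerCodes, k = wordSize)
  skm <- lapply(scv, .kmerCodes, k = wordSize)
  cand <- .candidatePairs(qkm, skm)
  cand <- cand[cand$nShared >= minSeeds, , drop = FALSE]
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$q[r]; j <- cand$s[r]
    h <- .pairHitPre(qcv[[i]], scv[[j]], qkm[[i]], skm[[j]])
    if (is.null(h) || h$score < minScore) next
    rows[[r]] <- data.frame(
      query_id = names(query)[i], subject_id = names(subject)[j],
      score = h$score, identity = h$identity,
      alignedLength = h$alignedLength,
      qstart = h$qstart, qend = h$qend,
      sstart = h$sstart, send = h$send, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), identity = numeric(),
                      alignedLength = integer(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer())
  rownames(out) <- NULL
  out
}

#' Read a tabular hit file (BLAST outfmt-6 style)
#'
#' Expects columns qseqid, sseqid, pident, length, qstart, qend, sstart,
#' send, bitscore (no header), 1-based inclusive coordinates.
#'
#' @param file path to the TSV.
#' @return a hit data.frame in the layout of [allVsAllHits()].
#' @export
readHitsTable <- function(file) {
  tb <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 9) stop("expected >= 9 outfmt-6 columns")
  data.frame(query_id = as.character(tb[[1]]),
             subject_id = as.character(tb[[2]]),
             score = tb[[9]], identity = tb[[3]], alignedLength = tb[[4]],
             qstart = tb[[5]], qend = tb[[6]],
             sstart = tb[[7]], send = tb[[8]],
             stringsAsFactors = FALSE)
}

# best hit per query: score, then aligned length, then identity, then
# lexicographic subject id
.bestHits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_id, -hits$score, -hits$alignedLength,
             -hits$identity, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Reciprocal best pairs between two transcriptomes
#'
#' A cave transcript c and a surface transcript s are paired iff s is c's
#' best hit and c is s's best hit, where "best" means highest score with
#' ties broken by longer aligned length, then higher identity, then
#' lexicographic subject id.  Transcripts without hits in either direction
#' drop out.
#'
#' @param hitsAB hits of set A (queries) against set B.
#' @param hitsBA hits of set B against set A.
#' @return a data.frame with one row per pair: a_id, b_id plus the A->B
#'   hit statistics (score, identity, alignedLength, intervals).
#' @export
reciprocalBestPairs <- function(hitsAB, hitsBA) {
  bAB <- .bestHits(hitsAB)
  bBA <- .bestHits(hitsBA)
  back <- stats::setNames(bBA$subject_id, bBA$query_id)
  keep <- !is.na(back[bAB$subject_id]) & back[bAB$subject_id] == bAB$query_id
  out <- bAB[keep, , drop = FALSE]
  names(out)[names(out) == "query_id"] <- "a_id"
  names(out)[names(out) == "subject_id"] <- "b_id"
  rownames(out) <- NULL
  out
}

#' Trim an allele pair to its aligned region
#'
#' Local alignment of the two full-length transcripts; both sequences are
#' cut to their aligned interval and a coordinate map of matched alignment
#' columns (1-based positions on the trimmed sequences, strictly
#' increasing, skipping indel columns) is built from the alignment path.
#'
#' @param caveSeq,surfSeq [Biostrings::DNAString] (or character) full
#'   transcripts.
#' @param minLength minimum trimmed length (bp) on both sides; shorter
#'   pairs are rejected (`NULL` returned, with the reason as an
#'   attribute-free message via `warning`).
#' @return a list: caveTrimmed, surfTrimmed (character), caveStart,
#'   surfStart (1-based offsets of the trimmed region on the full
#'   transcripts), map (matched-position matrix, columns cave/surface),
#'   score, identity, alignedLength; or `NULL` if the trimmed region is
#'   shorter than `minLength`.
#' @export
trimToAlignment <- function(caveSeq, surfSeq, minLength = 400L) {
  if (is.character(caveSeq)) caveSeq <- Biostrings::DNAString(caveSeq)
  if (is.character(surfSeq)) surfSeq <- Biostrings::DNAString(surfSeq)
  cs <- as.character(caveSeq)
  ss <- as.character(surfSeq)
  h <- .pairHit(caveSeq, surfSeq, cs, ss)
  if (is.null(h)) {
    warning("no alignment between the two sequences; pair rejected")
    return(NULL)
  }
  if (isTRUE(h$gapless)) {
    caveTrim <- substr(cs, h$qstart, h$qend)
    surfTrim <- substr(ss, h$sstart, h$send)
    n <- nchar(caveTrim)
    map <- cbind(cave = seq_len(n), surface = seq_len(n))
    caveStart <- h$qstart
    surfStart <- h$sstart
  } else {
    pa <- .alignLocal(caveSeq, surfSeq)
    p <- Biostrings::pattern(pa)
    s <- Biostrings::subject(pa)
    caveTrim <- as.character(Biostrings::subseq(
      caveSeq, BiocGenerics::start(p), BiocGenerics::end(p)))
    surfTrim <- as.character(Biostrings::subseq(
      surfSeq, BiocGenerics::start(s), BiocGenerics::end(s)))
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ci <- cumsum(ap != "-")
    si <- cumsum(as_ != "-")
    keep <- ap != "-" & as_ != "-"
    map <- cbind(cave = ci[keep], surface = si[keep])
    caveStart <- BiocGenerics::start(p)
    surfStart <- BiocGenerics::start(s)
  }
  if (nchar(caveTrim) < minLength || nchar(surfTrim) < minLength) {
    warning("trimmed aligned region shorter than ", minLength,
            " bp; pair rejected")
    return(NULL)
  }
  list(caveTrimmed = caveTrim, surfTrimmed = surfTrim,
       caveStart = caveStart, surfStart = surfStart,
       map = map, score = h$score, identity = h$identity,
       alignedLength = h$alignedLength)
}

#' Build the combined cave/surface allele-pair reference
#'
#' Runs the full pairing procedure: all-vs-all hits in both directions
#' (computed with the built-in seed-and-extend aligner, or ingested),
#' reciprocal-best-hit selection with "longest and highest identity"
#' tie-breaking, trimming of each retained pair to its aligned region, and
#' removal of pairs whose trimmed region is shorter than `minLength`
#' (400 bp by default).  Pair ids take the surface transcript's name.
#'
#' @param cave,surface named [Biostrings::DNAStringSet]s of the two
#'   transcriptomes.
#' @param minLength minimum trimmed length.
#' @param minScore,wordSize,minSeeds aligner parameters, see
#'   [allVsAllHits()].
#' @param hitsAB,hitsBA optional precomputed hit tables
#'   (cave-vs-surface and surface-vs-cave).
#' @return a [TranscriptPairSet-class]; pairs rejected at the length
#'   filter are recorded in `metadata`-style attribute `rejected`.
#' @examples
#' sim <- simulateTranscriptomes(SimConfig(seed = 2, nGenes = 3,
#'   lengthRange = c(500L, 800L)))
#' tp <- makeTranscriptPairs(sim$cave, sim$surface)
#' pairInfo(tp)
#' @export
makeTranscriptPairs <- function(cave, surface, minLength = 400L,
                                minScore = 40, wordSize = 11L,
                                minSeeds = 5L,
                                hitsAB = NULL, hitsBA = NULL) {
  if (is.null(hitsAB))
    hitsAB <- allVsAllHits(cave, surface, minScore, wordSize, minSeeds)
  if (is.null(hitsBA))
    hitsBA <- allVsAllHits(surface, cave, minScore, wordSize, minSeeds)
  rb <- reciprocalBestPairs(hitsAB, hitsBA)
  rows <- list(); caveTr <- character(); surfTr <- character()
  maps <- list(); rejected <- character()
  for (i in seq_len(nrow(rb))) {
    cid <- rb$a_id[i]; sid <- rb$b_id[i]
    tr <- withCallingHandlers(
      trimToAlignment(cave[[cid]], surface[[sid]], minLength),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(tr)) {
      rejected <- c(rejected, sid)
      next
    }
    pid_ <- sid
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = pid_, cave_id = cid, surface_id = sid,
      score = tr$score, identity = tr$identity,
      alignedLength = tr$alignedLength,
      caveStart = tr$caveStart, surfaceStart = tr$surfStart,
      caveLength = nchar(tr$caveTrimmed),
      surfaceLength = nchar(tr$surfTrimmed), stringsAsFactors = FALSE)
    caveTr[pid_] <- tr$caveTrimmed
    surfTr[pid_] <- tr$surfTrimmed
    maps[[pid_]] <- tr$map
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), cave_id = character(),
               surface_id = character(), score = numeric(),
               identity = numeric(), alignedLength = integer(),
               caveStart = integer(), surfaceStart = integer(),
               caveLength = integer(), surfaceLength = integer())
  tp <- new("TranscriptPairSet", pairs = pairs,
            cave = Biostrings::DNAStringSet(caveTr),
            surface = Biostrings::DNAStringSet(surfTr),
            coordMaps = maps)
  attr(tp, "rejected") <- rejected
  tp
}

#' Diagnostic difference sites of each pair
#'
#' Positions (on the trimmed alleles, via the coordinate map) where the
#' cave and surface sequences differ -- the sites fragments are classified
#' by.
#'
#' @param tp a [TranscriptPairSet-class].
#' @return a named list (per pair) of data.frames with columns posCave,
#'   posSurface (1-based, trimmed coordinates), caveBase, surfaceBase.
#' @export
pairDiffSites <- function(tp) {
  caveCh <- strsplit(as.character(tp@cave), "")
  surfCh <- strsplit(as.character(tp@surface), "")
  out <- vector("list", nrow(tp@pairs))
  names(out) <- tp@pairs$pair_id
  for (i in seq_len(nrow(tp@pairs))) {
    pid_ <- tp@pairs$pair_id[i]
    m <- tp@coordMaps[[pid_]]
    cb <- caveCh[[i]][m[, "cave"]]
    sb <- surfCh[[i]][m[, "surface"]]
    d <- which(cb != sb)
    out[[pid_]] <- data.frame(posCave = m[d, "cave"],
                              posSurface = m[d, "surface"],
                              caveBase = cb[d], surfaceBase = sb[d],
                              stringsAsFactors = FALSE)
  }
  out
}

#' Write the combined two-allele FASTA
#'
#' Emits both trimmed alleles of every pair, ids suffixed `|cave` and
#' `|surface`, mirroring the combined-reference construction used for
#' allele-aware quantification.
#'
#' @param tp a [TranscriptPairSet-class].
#' @param file output FASTA path.
#' @return invisibly, the number of records written.
#' @export
writeCombinedFasta <- function(tp, file) {
  ids <- tp@pairs$pair_id
  seqs <- c(stats::setNames(as.character(tp@cave), paste0(ids, "|cave")),
            stats::setNames(as.character(tp@surface),
                            paste0(ids, "|surface")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(length(seqs))
}

#' Remove genes with near-identical non-self hits in the same transcriptome
#'
#' A gene is eliminated when it has a hit to a different transcript in the
#' same transcriptome longer than `minLen` bp and more than `minIdentity`
#' percent identical -- evidence that the transcriptome represents the
#' same gene multiple times.
#'
#' @param seqs named [Biostrings::DNAStringSet]: the transcriptome.
#' @param geneIds ids to screen (default: all).
#' @param minLen aligned-length threshold (bp, exclusive).
#' @param minIdentity identity threshold (percent, exclusive).
#' @param wordSize,minScore aligner parameters.
#' @return list with `kept` (character), and `removed` (data.frame id,
#'   hit_id, alignedLength, identity -- the offending hit).
#' @export
selfSimilarityFilter <- function(seqs, geneIds = names(seqs),
                                 minLen = 150L, minIdentity = 90,
                                 wordSize = 11L, minScore = 40,
                                 minSeeds = 5L) {
  scv <- lapply(as.character(seqs), .charVec)
  skm <- lapply(scv, .kmerCodes, k = wordSize)
  gi <- match(geneIds, names(seqs))
  allCand <- .candidatePairs(skm[gi], skm)
  allCand <- allCand[allCand$nShared >= minSeeds, , drop = FALSE]
  removed <- list()
  for (r in seq_along(geneIds)) {
    g <- geneIds[r]
    cand <- setdiff(allCand$s[allCand$q == r], gi[r])
    for (j in cand) {
      h <- .pairHitPre(scv[[gi[r]]], scv[[j]], skm[[gi[r]]], skm[[j]])
      if (is.null(h) || h$score < minScore) next
      if (h$alignedLength > minLen && h$identity > minIdentity) {
        removed[[g]] <- data.frame(id = g, hit_id = names(seqs)[j],
                                   alignedLength = h$alignedLength,
                                   identity = h$identity,
                                   stringsAsFactors = FALSE)
        break
      }
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(), hit_id = character(),
               alignedLength = integer(), identity = numeric())
  rownames(removed) <- NULL
  list(kept = setdiff(geneIds, removed$id), removed = removed)
}

#' Remove annotation ids present in too many copies
#'
#' Any annotation id carried by more than `maxCopies` transcripts in
#' either transcriptome is removed everywhere (it likely tags repeated
#' fragments of one gene).  Unannotated entries are unaffected here.
#'
#' @param ids gene/transcript ids to filter.
#' @param annotations data.frame with columns gene_id, annotation_id,
#'   copiesCave, copiesSurface (see [annotationTable()]).
#' @param maxCopies maximum copies allowed (strictly more are removed).
#' @return list with `kept` and `removed` (data.frame gene_id,
#'   annotation_id, copiesCave, copiesSurface).
#' @export
copyNumberFilter <- function(ids, annotations, maxCopies = 9L) {
  an <- annotations[match(ids, annotations$gene_id), , drop = FALSE]
  bad <- !is.na(an$annotation_id) &
    (an$copiesCave > maxCopies | an$copiesSurface > maxCopies)
  bad[is.na(bad)] <- FALSE
  list(kept = ids[!bad], removed = an[bad, , drop = FALSE])
}

#' Annotation table of a simulated study
#'
#' Gene-level annotation ids with per-transcriptome copy counts (planted
#' duplicates share their source gene's annotation).
#'
#' @param truth a [GroundTruth-class].
#' @return data.frame: gene_id, annotation_id, copiesCave, copiesSurface.
#' @export
annotationTable <- function(truth) {
  g <- truth@genes
  copiesCave <- as.integer(g$side %in% c("both", "cave"))
  copiesSurface <- as.integer(g$side %in% c("both", "surface"))
  for (i in seq_len(nrow(truth@duplicates))) {
    j <- match(truth@duplicates$gene_id[i], g$gene_id)
    if (truth@duplicates$side[i] == "cave")
      copiesCave[j] <- copiesCave[j] + 1L
    else copiesSurface[j] <- copiesSurface[j] + 1L
  }
  data.frame(gene_id = g$gene_id, annotation_id = g$annotation_id,
             copiesCave = copiesCave, copiesSurface = copiesSurface,
             stringsAsFactors = FALSE)
}
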