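#' Call F2 genotypes from surface/cave Z-value ratios
#'
#' For each gene and F2 individual the surface Z-value is divided by the
#' cave Z-value.  A ratio strictly below `ccMax` calls a homozygous cave
#' genotype (CC); a ratio strictly above `sMin` calls a surface-carrying
#' genotype (SC or SS, written S_).  Ratios exactly at a cutoff, and
#' genes with zero counts on both alleles, are NA.  A gene with zero cave
#' but positive surface counts has ratio +Inf and is called S_.
#'
#' @param x an [AlleleCounts-class] (all its columns are called; subset
#'   to F2 samples first) or a numeric ratio matrix (genes x
#'   individuals).
#' @param ccMax CC cutoff (default 0.5).
#' @param sMin S_ cutoff (default 0.5); must be >= `ccMax`.
#' @return character matrix of "CC", "S_" and NA.
#' @examples
#' callGenotypes(matrix(c(0.2, 1.4), 1, dimnames = list("g", c("a", "b"))))
#' @export
callGenotypes <- function(x, ccMax = 0.5, sMin = 0.5) {
  stopifnot(ccMax <= sMin, ccMax > 0)
  ratio <- if (is(x, "AlleleCounts")) alleleRatio(x) else as.matrix(x)
  call <- matrix(NA_character_, nrow(ratio), ncol(ratio),
                 dimnames = dimnames(ratio))
  call[!is.nan(ratio) & ratio < ccMax] <- "CC"
  call[!is.nan(ratio) & ratio > sMin] <- "S_"
  call
}

#' Expected-genotype patterns of the scored phenotypes
#'
#' Builds, from an F2 phenotype table, the three recessive patterns
#' scanned by the study design: unpigmented individuals CC versus all
#' pigmented individuals S_; orange individuals CC versus all non-orange
#' individuals S_; eyeless individuals CC versus eyed individuals S_,
#' with eye-fragment individuals excluded from the eye pattern (they can
#' be scored neither eyed nor eyeless).
#'
#' @param phenotypes data.frame with columns individual_id,
#'   pigment_class, eye.
#' @return named list of patterns, each
#'   `list(phenotype, cc, s, excluded)` (character id vectors).
#' @export
phenotypePatterns <- function(phenotypes) {
  ids <- phenotypes$individual_id
  out <- list()
  if ("pigment_class" %in% names(phenotypes)) {
    unp <- ids[phenotypes$pigment_class == "unpigmented"]
    if (length(unp))
      out$unpigmented <- list(phenotype = "unpigmented", cc = unp,
                              s = setdiff(ids, unp),
                              excluded = character())
    org <- ids[phenotypes$pigment_class == "orange"]
    if (length(org))
      out$orange <- list(phenotype = "orange", cc = org,
                         s = setdiff(ids, org), excluded = character())
  }
  if ("eye" %in% names(phenotypes)) {
    eyeless <- ids[phenotypes$eye == "eyeless"]
    frag <- ids[phenotypes$eye == "fragment"]
    if (length(eyeless))
      out$eyeless <- list(phenotype = "eyeless", cc = eyeless,
                          s = ids[phenotypes$eye == "eyed"],
                          excluded = frag)
  }
  out
}

#' Scan genes for an exact genotype pattern
#'
#' A gene matches when its call is CC for every affected (cc) individual
#' and S_ for every unaffected (s) individual; any NA among the required
#' individuals prevents a match.  Excluded individuals are ignored.
#'
#' @param calls genotype-call matrix from [callGenotypes()].
#' @param pattern one element of [phenotypePatterns()].
#' @return character vector of matching gene ids.
#' @export
patternScan <- function(calls, pattern) {
  need <- c(pattern$cc, pattern$s)
  if (!all(need %in% colnames(calls)))
    stop("pattern references unknown individuals: ",
         paste(setdiff(need, colnames(calls)), collapse = ", "))
  ccOK <- rowSums(calls[, pattern$cc, drop = FALSE] == "CC",
                  na.rm = TRUE) == length(pattern$cc)
  naCC <- rowSums(is.na(calls[, pattern$cc, drop = FALSE])) > 0
  sOK <- rowSums(calls[, pattern$s, drop = FALSE] == "S_",
                 na.rm = TRUE) == length(pattern$s)
  naS <- rowSums(is.na(calls[, pattern$s, drop = FALSE])) > 0
  rownames(calls)[ccOK & sOK & !naCC & !naS]
}

#' Exhaustive permutation null of a pattern scan
#'
#' Enumerates ALL `choose(n, k)` assignments of CC status to k of the n
#' scored individuals (the remaining n-k individuals are required to be
#' S_) and counts, for each assignment, the genes whose genotype calls
#' match it exactly.  The distribution of these counts is the permutation
#' null of the observed match count; the observed assignment is one of
#' the enumerated columns.
#'
#' @param calls genotype-call matrix from [callGenotypes()].
#' @param k number of CC individuals.
#' @param individuals ids over which to permute (the scored cohort:
#'   cc + s individuals of the pattern, excluded ones left out).
#' @param cap refuse to enumerate more than this many assignments
#'   (default 1e6) -- use a sampled null beyond that.
#' @return list: `counts` (integer vector, length `choose(n, k)`),
#'   `assignments` (k x N matrix of individual indices), `individuals`,
#'   `k`.
#' @examples
#' calls <- matrix("S_", 2, 15,
#'   dimnames = list(c("g1", "g2"), sprintf("i%02d", 1:15)))
#' length(permutationNull(calls, 3, colnames(calls))$counts)  # 455
#' @export
permutationNull <- function(calls, k, individuals, cap = 1e6) {
  n <- length(individuals)
  if (k >= n) stop("k must be smaller than the number of individuals")
  nAssign <- choose(n, k)
  if (nAssign > cap)
    stop("choose(", n, ", ", k, ") = ", nAssign, " exceeds the ",
         "enumeration cap; use a sampled null instead")
  sub <- calls[, individuals, drop = FALSE]
  isCC <- sub == "CC"; isCC[is.na(isCC)] <- FALSE
  isS <- sub == "S_"; isS[is.na(isS)] <- FALSE
  rowS <- rowSums(isS)
  cmb <- utils::combn(n, k)
  counts <- integer(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    cols <- cmb[, j]
    ccPart <- rowSums(isCC[, cols, drop = FALSE]) == k
    sPart <- (rowS - rowSums(isS[, cols, drop = FALSE])) == n - k
    counts[j] <- sum(ccPart & sPart)
  }
  list(counts = counts, assignments = cmb, individuals = individuals,
       k = k)
}

#' Locate the observed assignment inside a permutation null
#'
#' @param null result of [permutationNull()].
#' @param ccIds the observed CC individuals.
#' @return the column index of the observed assignment.
#' @export
observedIndex <- function(null, ccIds) {
  target <- sort(match(ccIds, null$individuals))
  if (anyNA(target) || length(target) != null$k)
    stop("observed CC set does not match the permuted cohort")
  hit <- which(colSums(null$assignments == target) == null$k)
  if (!length(hit)) stop("observed assignment not found")
  hit[1]
}

#' Compare an observed match count to its permutation null
#'
#' The study's test: a one-sample Wilcoxon signed-rank test (normal
#' approximation with continuity correction) of the permutation counts
#' against the observed count.  Because testing one observed number
#' against its own null distribution this way is unconventional, the
#' standard empirical permutation p-value -- the share of assignments
#' with a count at least as large as observed -- is reported alongside.
#'
#' @param counts permutation count vector.
#' @param observed the observed match count.
#' @return list: wilcoxonP, empiricalP, statistic (V).  If every
#'   permutation count equals the observed value the test is degenerate:
#'   p = 1 with a warning.
#' @export
wilcoxonCompare <- function(counts, observed) {
  if (!length(counts)) stop("empty permutation count vector")
  if (all(counts == observed)) {
    warning("all permutation counts equal the observed value; p = 1")
    return(list(wilcoxonP = 1, empiricalP = 1, statistic = NA_real_))
  }
  wt <- stats::wilcox.test(counts, mu = observed, exact = FALSE,
                           correct = TRUE)
  list(wilcoxonP = wt$p.value, empiricalP = mean(counts >= observed),
       statistic = unname(wt$statistic))
}

#' Mendelian probability of a recessive genotype pattern
#'
#' Under F2 segregation each individual is CC with probability 1/4 and
#' SC-or-SS with probability 3/4, so the probability that k named
#' individuals are all CC while m named individuals all carry a surface
#' allele is (1/4)^k * (3/4)^m.
#'
#' @param k number of CC individuals.
#' @param m number of SC-or-SS individuals.
#' @return the pattern probability (vectorized).
#' @examples
#' patternProbability(3, 12)   # 0.000495
#' patternProbability(5, 10)   # 0.000055
#' @export
patternProbability <- function(k, m) {
  if (any(k < 0) || any(m < 0)) stop("k and m must be non-negative")
  (1 / 4)^k * (3 / 4)^m
}

#' Post-filter linked candidates to annotated, single-copy genes
#'
#' Unannotated genes are removed, and any annotation id occurring more
#' than once in the matched list is removed entirely (all its
#' occurrences), keeping only genes present by id a single time.
#'
#' @param genes matched gene ids.
#' @param annotations data.frame gene_id, annotation_id.
#' @return list: `kept`, `removed` (data.frame gene_id, reason).
#' @export
postfilterCandidates <- function(genes, annotations) {
  ann <- annotations$annotation_id[match(genes, annotations$gene_id)]
  unann <- is.na(ann)
  tab <- table(ann[!unann])
  multi <- !unann & ann %in% names(tab)[tab > 1]
  removed <- data.frame(
    gene_id = genes[unann | multi],
    reason = ifelse(unann[unann | multi], "unannotated",
                    "annotation id not unique in list"),
    stringsAsFactors = FALSE)
  list(kept = genes[!(unann | multi)], removed = removed)
}

#' Assign a candidate gene to the map marker it best agrees with
#'
#' Agreement between a candidate's F2 genotype vector and each marker's
#' genotype vector is the number of individuals at which both are
#' non-NA and equal.  The marker(s) with maximal agreement are returned;
#' ties are reported, not broken.
#'
#' @param candidate named character vector (CC / S_ / NA per individual).
#' @param markers character matrix (markers x individuals), same codes.
#' @return list: `best` (marker names, >1 on ties), `agreement` (the
#'   maximal count), `table` (per-marker agreement).
#' @export
assignToMarker <- function(candidate, markers) {
  shared <- intersect(names(candidate), colnames(markers))
  cand <- candidate[shared]
  agree <- apply(markers[, shared, drop = FALSE], 1, function(m) {
    ok <- !is.na(m) & !is.na(cand)
    sum(m[ok] == cand[ok])
  })
  overlap <- apply(markers[, shared, drop = FALSE], 1, function(m)
    sum(!is.na(m) & !is.na(cand)))
  if (all(overlap == 0))
    stop("no overlapping non-NA individuals between candidate and markers")
  best <- names(agree)[agree == max(agree)]
  list(best = best, agreement = max(agree), table = agree)
}

#' Full linkage scan of an F2 cohort
#'
#' For each phenotype pattern: calls genotypes at the requested ratio
#' cutoffs, scans for exact cosegregation, builds the exhaustive
#' permutation null, computes the signed-rank and empirical p-values and
#' the Mendelian pattern probability, applies the annotated/single-copy
#' post-filter, and (when markers are given) places each surviving
#' candidate next to its best-agreeing marker.
#'
#' @param ac an [AlleleCounts-class] containing F2 samples.
#' @param phenotypes F2 phenotype table (see [phenotypePatterns()]).
#' @param cutoffs numeric pair `c(ccMax, sMin)`.
#' @param annotations optional annotation table for the post-filter.
#' @param markers optional marker genotype matrix for placement.
#' @param cap permutation enumeration cap.
#' @return named list per phenotype: matched, nMatched, counts
#'   (permutation null), wilcoxonP, empiricalP, patternProbability,
#'   candidates (post-filtered), markerAssignment.
#' @export
linkageScan <- function(ac, phenotypes, cutoffs = c(0.5, 0.5),
                        annotations = NULL, markers = NULL, cap = 1e6) {
  cd <- SummarizedExperiment::colData(ac)
  f2 <- ac[, cd$generation == "F2"]
  calls <- callGenotypes(f2, cutoffs[1], cutoffs[2])
  pats <- phenotypePatterns(phenotypes)
  out <- list()
  for (nm in names(pats)) {
    pat <- pats[[nm]]
    matched <- patternScan(calls, pat)
    cohort <- c(pat$cc, pat$s)
    null <- permutationNull(calls, length(pat$cc), cohort, cap = cap)
    cmp <- wilcoxonCompare(null$counts, length(matched))
    res <- list(matched = matched, nMatched = length(matched),
                counts = null$counts,
                observedIndex = observedIndex(null, pat$cc),
                wilcoxonP = cmp$wilcoxonP, empiricalP = cmp$empiricalP,
                patternProbability = patternProbability(length(pat$cc),
                                                        length(pat$s)))
    if (!is.null(annotations)) {
      pf <- postfilterCandidates(matched, annotations)
      res$candidates <- pf$kept
      res$removed <- pf$removed
    } else res$candidates <- matched
    if (!is.null(markers) && length(res$candidates)) {
      res$markerAssignment <- lapply(
        stats::setNames(res$candidates, res$candidates),
        function(g) assignToMarker(calls[g, cohort], markers))
    }
    out[[nm]] <- res
  }
  out
}
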