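---
title: "Methods: allele-specific expression and expression-based linkage in cave x surface hybrids"
author: "hybridASE"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression and expression-based linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

A cave ecomorph and a surface ecomorph of one species differ in eyes
and pigmentation, traits that segregate recessively in crosses.  With
no genome assembly, the two *de novo* population transcriptomes stand
in for the two alleles of every gene: once homologous transcripts are
paired, any read covering a site at which the pair differs can be
assigned to the cave or the surface allele.  Three questions follow,
each answered by one arm of the package:

* which genes differ in overall expression between the ecomorphs
  (differential expression, DE);
* which genes express their two alleles unequally **within** an F1
  hybrid (allele-specific expression, ASE) — the signature of a
  *cis*-regulatory difference, since both alleles share one nuclear
  environment;
* where candidate genes sit relative to the recessive eye and pigment
  loci, inferred from which F2 individuals are homozygous cave (CC) at
  each gene (expression-derived genotyping and a cosegregation scan).

# Allele pairing

`makeTranscriptPairs()` forms reciprocal best hits (RBH) between the
two transcriptomes.  "Best" is the highest alignment score, with ties
broken by longer aligned length, then higher identity, then
lexicographic subject id — a fixed, deterministic order.  Retained
pairs are trimmed to their aligned region; pairs whose trimmed region
is shorter than 400 bp are rejected (the threshold is applied to the
trimmed region, the stricter reading).  A per-pair coordinate map
records matched alignment columns so diagnostic-site positions carry
across indels between the alleles.

The aligner is a seed-and-extend design: candidate partners share at
least `minSeeds = 5` distinct exact 11-mers (chance collisions between
unrelated 3 kb transcripts average about two 11-mers, so a small
support threshold separates homology from noise the way BLAST's
multi-hit heuristic does).  When the seed matches of a candidate fall
on one dominant diagonal, extension is a gapless local alignment along
that diagonal via a maximum-scoring-segment scan — exactly the
Smith-Waterman optimum whenever that optimum contains no gap, which is
the generic case for SNP-divergent allele pairs.  When seed support is
strong but split across diagonals (an indel), a full affine-gap local
Smith-Waterman (`Biostrings::pairwiseAlignment`) is run instead.
Scoring is match +1, mismatch -2, gap opening 5, gap extension 2
throughout, for pairing and for the self-similarity filter alike; the
hit interface also ingests tabular (outfmt-6 style) output from an
external aligner.

All coordinates in the package are 1-based and closed, the
R/Bioconductor convention (IRanges, Biostrings); the outfmt-6 reader
keeps that convention on ingestion.

# Allele quantification (Z-values)

For each sample, each fragment is located on its gene pair and
compared to both alleles.  At the diagnostic sites it covers it votes
for the allele whose base it shows; strictly more votes assigns the
fragment, ties or no covered site leave it ambiguous, and a fragment
more than `tol = 3` mismatches from **both** alleles is incompatible
and discarded.  Ambiguous fragments are then apportioned by iterating

```
theta <- (nCave + theta * nAmb) / (nCave + nSurface + nAmb)
```

to its fixed point, which is in closed form
`theta = nCave / (nCave + nSurface)` (a 50:50 split when no
informative fragment exists).  The per-allele totals
`zCave = nCave + theta * nAmb` and its complement preserve the total
fragment count; they are the Z-values all downstream decision rules
consume.  Because the apportionment is proportional, allele *ratios*
are driven entirely by informative fragments — ambiguous coverage
never manufactures bias.

Alongside the combined-reference Z-values, the quantifier tallies how
many fragments lie within `tol` mismatches of each single allele.
These per-reference totals emulate separate mapping runs against each
assembly: a fragment from one allele that crosses many diagnostic
sites can fail to map to the other assembly, which is precisely the
reference bias the dual-reference DE design is meant to absorb.

# Differential expression

Counts are normalized by median-of-ratios size factors (per sample,
the median over all-sample-expressed genes of the count over the
gene's geometric mean).  The per-gene test is a Wald statistic on the
log2 ratio of group means with a method-of-moments negative-binomial
dispersion, `alpha = max(0, (s^2 - m) / m^2)` averaged over the two
groups, and Benjamini-Hochberg adjustment.  A gene is *cave biased*
only when `padj < 0.05` and `log2FC >= 2` against **both** references,
*surface biased* in the mirror case ("log2 fold change of 2" is read
as a magnitude threshold, with the sign giving the direction).

Two properties of this small-replicate Wald test are worth knowing.
Under low-dispersion (near-Poisson) nulls it is mildly conservative —
simulation places the raw p < 0.05 fraction near 0.037 rather than
0.05, because the dispersion estimate is truncated at zero.  Under
strongly overdispersed nulls with only three replicates per group the
raw test is anticonservative, an inherent property of moment
dispersion estimates at n = 3.  The pipeline's *decision rule* is
robust to both: at realistic depths a null gene essentially never
clears the |log2FC| >= 2 magnitude threshold on both references
simultaneously, and the planted-signal experiments in the test suite
measure zero false positives at the default settings.  Biased lists
then pass the paralog filter (a non-self hit in the same transcriptome
longer than 150 bp and more than 90% identical removes the gene) and
the copy-number filter (annotation ids present in more than 9 copies
in either transcriptome are removed everywhere).

# The ASE screen

The screen never divides: every ratio test is the cross-multiplied
comparison `a >= 3.3 * b`, so zero denominators are handled exactly
(a gene with `zSurface = 0` and `zCave > 0` passes the cave-direction
test; a sample at zero on both alleles fails the filter).  The 3.3x
threshold is inclusive.

*Parental fidelity* keeps a gene only when **every** cave parental
replicate has `zCave >= 3.3 * zSurface` and every surface replicate
the mirror — per-replicate, not pooled (a pooled mode exists as an
option).  This removes pairs whose alleles cross-attract reads through
assembly artefacts before any hybrid is examined.  *Hybrid bias* then
requires the 3.3x ratio for one allele in **all** F1 hybrids;
unannotated genes and annotation ids shared by nine or more
transcripts are removed (this filter's boundary is >= 9, distinct from
the DE copy filter's > 9).  Finally, calls are intersected with
concordant DE: agreement in direction prioritizes the gene,
disagreement is flagged discordant and reported, never silently
dropped.

At a cave-allele fraction of 0.5 the probability that all three
hybrids exceed 3.3x is vanishing at realistic depths; the suite
verifies zero calls across a thousand balanced genes.

# Diagnostic SNPs and the binomial confirmation

Fixed SNPs are called directly from parental pileups: a site is
cave-fixed when 100% of covering cave-population reads carry one base,
that base differs from the surface allele at the aligned position, and
coverage is at least five; symmetrically for surface; sites where both
populations are fixed for the same base are shared variants and
removed.  Positions are carried between alleles by the pair's
coordinate map.

Up to five SNPs represent each gene, chosen to span it: always the
first and last, plus the SNPs closest to the quarter, half and
three-quarter points (ties broken leftmost).  Allele counts at those
SNPs are taken in every F1 hybrid against the cave reference and the
surface reference separately; on indel-free data the two countings
agree exactly, and reads showing a third base are excluded as
sequencing error and tallied separately.

The per-SNP test is a two-sided exact binomial test of the cave-allele
count against a predicted fraction of 0.5 (deviation in either
direction counts; a one-sided variant is available).  A gene is
confirmed when at least two SNPs are significant at p < 0.05 in all
three hybrids under both references.  Genes offering fewer than two
SNPs are flagged as not confirmable rather than erroring — at the
default study conditions this is the dominant non-confirmation mode,
mirroring how low counts, not inconsistency, drive most failures.

# The F2 linkage scan

For each F2 individual and gene the genotype statistic is the ratio
`zSurface / zCave` — surface over cave, so homozygous cave (CC)
individuals sit near zero.  A ratio strictly below 0.5 calls CC; a
ratio strictly above 0.5 calls S_ (SC or SS, indistinguishable from
expression alone); a ratio exactly at a cutoff, or a gene at zero on
both alleles, is NA, and NA fails any pattern requirement.  The
stricter cutoff pairs (0.4/0.6 and 0.3/0.7) can only widen the NA band
and therefore only shrink matched sets — the cutoff-ladder
monotonicity the suite asserts.  The rule assumes no ASE: a strongly
cave-biased heterozygote drifts toward the CC side, which is why the
scan is run genome-wide and validated by permutation rather than
trusted per gene.

A gene *matches* a phenotype when its call is CC for every affected
individual and S_ for every unaffected one (recessive inheritance);
eye-fragment individuals are excluded from the eye pattern, shrinking
that cohort from 15 to 14.  The null distribution is exhaustive: all
`choose(n, k)` reassignments of the CC label are enumerated (455 for
3 of 15, 3003 for 5 of 15, 1001 for 4 of 14) and the matched-gene
count recomputed for each; the observed assignment is one of the
enumerated columns, a consistency the tests check against a
brute-force rebuild.  An enumeration cap (10^6) guards against
infeasible cohorts.

Two p-values are reported.  The study's test — a one-sample Wilcoxon
signed-rank test of the permutation counts against the observed count,
normal approximation with continuity correction — is implemented as
described, but comparing one observed number against its own null this
way is statistically unconventional, so the standard empirical
permutation p-value (the share of assignments matching at least as
many genes) is always reported alongside and is the number to quote.
The Mendelian pattern probability uses P(CC) = 1/4 and
P(SC or SS) = 3/4 per individual, giving `(1/4)^k * (3/4)^m` for a
pattern of k affected and m unaffected individuals.

Post-filters keep only annotated candidates whose annotation id occurs
a single time in the matched list (both copies of a duplicated id are
removed), and each survivor is placed next to the map marker with
which its genotype vector agrees at the most individuals — ties are
reported, not broken.

# The synthetic-data generator

`SimConfig` fixes the whole study; the seed determines every output
byte.  `defaultStudyConfig()` is the design the acceptance experiments
run: 500 genes of 500-3000 bp with 3-12 fixed SNPs each; three
parental replicates per ecomorph at each of two embryonic stages;
three F1 hybrids; fifteen F2 individuals with 3 unpigmented, 5 orange
and 4 eyeless (plus one eyed individual carrying eye fragments, which
the eye scan excludes); 10 allele-biased genes at cave fraction 0.8,
also cave-biased in parental expression so they flow into the
allele-count confirmation the way the screen's output does; 20 DE
genes at |log2FC| = 3; and linked blocks of 25/15/20 genes in perfect
linkage with their phenotypes.

Sequencing is modelled as single-end 100 bp fragments, uniform along
the transcript, with substitution errors at 0.001 per base (post-QC
trimmed reads) and no indel errors.  Per-gene depth averages 5000
fragments per transcript per sample — about 2.5 million fragments per
sample over the 500-gene panel, i.e. bulk-RNA-seq-scale coverage for
well-expressed transcripts; chosen a priori so the weakest plausible
ASE gene (3 SNPs on a 3 kb transcript, ~10% of fragments informative)
still yields several hundred informative fragments per hybrid, the
depth at which an 0.8 fraction reliably clears an inclusive 3.3x
threshold in all three hybrids.  Biological replicate variation is
negative-binomial with dispersion 0.05 (CV ~22%).  F2 genotype
conditioning assigns the required number of CC individuals uniformly
at random — individuals are exchangeable, exactly as the permutation
null treats them — with non-CC individuals SC:SS at 2:1; orange CC
individuals are drawn among the pigmented, since an unpigmented
individual cannot be scored orange.

Reads exist in two interchangeable representations.  `"sequence"`
mode materialises literal reads (exportable as FASTQ).  `"sites"` mode
stores, per fragment, the observed base at each diagnostic site it
covers plus its mismatch count at non-diagnostic positions.  The two
are informationally equivalent for allele classification: at
non-diagnostic positions the alleles agree, so a substitution error
adds one mismatch against both alleles regardless of the source
allele, and classification depends only on site bases and the two
mismatch totals.  Both modes draw the site-level variates from the
RNG in the same order, so with one seed they produce *identical*
classifications — an equality the suite asserts — while the sites
mode scales the full 75-million-fragment study to about a minute.

What the generator does **not** emulate: isoforms and UTR structure,
expression distributions fitted to real data, paired-end fragments,
mapping ambiguity beyond winner-takes-all pair assignment, real
divergence structure (SNPs are uniform, independent sites), or
allele-specific transcript length effects.  Passing tests therefore
demonstrate that the decision rules are implemented correctly and
behave as designed under the stated model — not that the thresholds
are optimal for any particular real dataset.

# Numerical conventions and degenerate inputs

* Ratio tests are cross-multiplied; `0/0` cases fail filters
  explicitly and are logged, never silently passed.
* The EM apportionment returns theta = 0.5 when no informative
  fragment exists; totals are always conserved.
* Exact binomial p-values use the symmetric closed form
  `min(1, 2 * pbinom(min(x, n - x), n, 1/2))`, identical to
  `binom.test` at fraction 0.5; `n = 0` gives p = 1.
* Genotype ratios exactly at a cutoff are NA (the calls are defined by
  strict inequalities); `Inf` (surface reads only) is a valid S_ call.
* All tie-breaks (best hit, spanning-SNP selection, marker placement)
  are deterministic and documented at the function level; marker ties
  are reported rather than broken.
* A degenerate permutation comparison (all counts equal the observed
  value) returns p = 1 with a warning.

# Problem sizes used by the test suite

The end-to-end experiments run the 500-gene default study (about
90 seconds); unit tests use 1-50 gene configurations, 10^4-gene
simulated count matrices for test calibration, and 10^3-10^5-draw
simulations for Mendelian ratios and null behavior.  These sizes were
chosen so the full suite completes in a few minutes while keeping
every Monte-Carlo assertion's sampling error an order of magnitude
below the tolerance it checks.
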