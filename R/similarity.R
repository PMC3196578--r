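#' @include AllGenerics.R
NULL

#' Create a threshold profile
#'
#' @param maxEvalue maximum E-value.
#' @param minIdentity,minSimilarity,minQueryCov,minSubjectCov minimum
#'   percentages (0-100).
#' @param maxMismatches maximum mismatch count (\code{Inf} disables).
#' @param mode \code{"nucleotide"} or \code{"translated"}.
#' @return a \code{\link{ThresholdProfile}}.
#' @export
thresholdProfile <- function(maxEvalue = 10, minIdentity = 0,
                             minSimilarity = 0, minQueryCov = 0,
                             minSubjectCov = 0, maxMismatches = Inf,
                             mode = c("nucleotide", "translated")) {
  mode <- match.arg(mode)
  new("ThresholdProfile", maxEvalue = maxEvalue, minIdentity = minIdentity,
      minSimilarity = minSimilarity, minQueryCov = minQueryCov,
      minSubjectCov = minSubjectCov, maxMismatches = maxMismatches,
      mode = mode)
}

#' Preset threshold profiles of the survey pipeline
#'
#' The filtering bounds each pipeline stage uses:
#' \describe{
#'   \item{repeat_nt}{known-TE screen, nucleotide, E <= 1e-6.}
#'   \item{repeat_prot}{novel-TE screen, translated, E <= 1e-6.}
#'   \item{viral}{viral-protein screen, translated: E <= 0.001,
#'     identity >= 30, similarity >= 50, read coverage >= 50,
#'     protein coverage >= 1.}
#'   \item{gene_protein}{protein gene evidence, translated: E <= 1e-6,
#'     identity >= 30, similarity >= 50, read coverage >= 50, database entry
#'     coverage >= 1.}
#'   \item{gene_est}{EST gene evidence, nucleotide: as \code{gene_protein}
#'     but E <= 1e-30.}
#'   \item{synteny}{best-hit mapping onto reference proteomes, translated:
#'     E <= 1e-6, identity >= 30, similarity >= 50, read coverage >= 50.}
#'   \item{zipper}{nucleotide anchoring of reads/markers/homologs,
#'     E <= 1e-10.}
#'   \item{mirna}{mature miRNA search, nucleotide, E <= 10 (word size 7 and
#'     the 10-hit cap are applied at search time).}
#' }
#'
#' @param name profile name.
#' @return a \code{\link{ThresholdProfile}}.
#' @export
presetProfile <- function(name = c("repeat_nt", "repeat_prot", "viral",
                                   "gene_protein", "gene_est", "synteny",
                                   "zipper", "mirna")) {
  name <- match.arg(name)
  switch(name,
    repeat_nt = thresholdProfile(maxEvalue = 1e-6, mode = "nucleotide"),
    repeat_prot = thresholdProfile(maxEvalue = 1e-6, mode = "translated"),
    viral = thresholdProfile(maxEvalue = 1e-3, minIdentity = 30,
                             minSimilarity = 50, minQueryCov = 50,
                             minSubjectCov = 1, mode = "translated"),
    gene_protein = thresholdProfile(maxEvalue = 1e-6, minIdentity = 30,
                                    minSimilarity = 50, minQueryCov = 50,
                                    minSubjectCov = 1, mode = "translated"),
    gene_est = thresholdProfile(maxEvalue = 1e-30, minIdentity = 30,
                                minSimilarity = 50, minQueryCov = 50,
                                minSubjectCov = 1, mode = "nucleotide"),
    synteny = thresholdProfile(maxEvalue = 1e-6, minIdentity = 30,
                               minSimilarity = 50, minQueryCov = 50,
                               mode = "translated"),
    zipper = thresholdProfile(maxEvalue = 1e-10, mode = "nucleotide"),
    mirna = thresholdProfile(maxEvalue = 10, mode = "nucleotide"))
}

.as_char_seqs <- function(x, what = "sequences") {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else stop(what, " must be an XStringSet or a named character vector")
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop(what, " must be named")
  if (anyDuplicated(names(out))) stop(what, " names must be unique")
  out
}

#' Seeded local similarity search
#'
#' k-mer-seeded local alignment of every query against every subject.
#' Nucleotide mode searches both strands with +1/-2 scoring and affine gaps
#' (open 5, extend 2); translated mode searches all six reading frames of
#' the nucleotide query against protein subjects with BLOSUM62 scoring
#' (gap open 11, extend 1), reporting percent positive-scoring columns as
#' similarity.  Seeds are clustered by diagonal and each cluster is extended
#' with a full affine-gap Smith-Waterman over the seeded subject window, so
#' reported hits carry locally optimal scores.  E-values use the
#' Karlin-Altschul form E = m n 2^(-bits) with documentary (not fitted)
#' constants; the coarse thresholds the pipeline filters on (1e-6, 1e-10,
#' 1e-30) do not require calibrated statistics.
#'
#' @param queries,subjects named \code{XStringSet} or character vectors.
#'   Subjects must be protein for translated mode.
#' @param mode \code{"nucleotide"} or \code{"translated"}.
#' @param wordSize seed word size; defaults to 11 (nucleotide) or 3
#'   (translated).  Use 7 for the mature-miRNA search.
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param gapOpen,gapExtend gap penalties (positive costs); a gap of length
#'   L costs \code{gapOpen + L * gapExtend}.
#' @param maxEvalue report only hits with E-value at or below this bound.
#' @param minSeeds minimum seeds per diagonal cluster before extension
#'   (2 suppresses spurious single-seed extensions; set 1 for short or
#'   low-identity queries such as mature miRNAs).
#' @param maxExtensions per query frame, extend at most this many clusters
#'   (best-seeded first).
#' @param maxHitsPerQuery cap on reported hits per query (by E-value then
#'   bitscore); 0 disables.
#' @param bothStrands search the reverse complement of nucleotide queries.
#' @param earlyExit stop searching a query as soon as one reportable hit is
#'   found (screening mode: use only when hit existence, not the best hit,
#'   is needed).
#' @return a \code{\link{HitTable}}.
#' @examples
#' s <- c(g1 = paste(rep("ACGTTGCA", 40), collapse = ""))
#' searchHits(c(r1 = substr(s[[1]], 30, 150)), s)
#' @export
searchHits <- function(queries, subjects,
                       mode = c("nucleotide", "translated"),
                       wordSize = NULL, match = 1L, mismatch = -2L,
                       gapOpen = 5L, gapExtend = 2L, maxEvalue = 10,
                       minSeeds = 2L, maxExtensions = 16L,
                       maxHitsPerQuery = 0L, bothStrands = TRUE,
                       earlyExit = FALSE) {
  mode <- match.arg(mode)
  q <- .as_char_seqs(queries, "queries")
  s <- .as_char_seqs(subjects, "subjects")
  if (length(q) == 0 || length(s) == 0)
    stop("queries and subjects must be non-empty")
  if (mode == "translated" && any(grepl("^[ACGTUN]+$", s)) &&
      all(grepl("^[ACGTUN]+$", s)))
    stop("translated mode expects protein subjects")
  if (is.null(wordSize)) wordSize <- if (mode == "translated") 3L else 11L
  df <- cpp_search(names(q), unname(q), names(s), unname(s), mode,
                   as.integer(wordSize), as.integer(match),
                   as.integer(mismatch), as.integer(gapOpen),
                   as.integer(gapExtend), maxEvalue, as.integer(minSeeds),
                   as.integer(maxExtensions), as.integer(maxHitsPerQuery),
                   bothStrands, earlyExit)
  new("HitTable", hits = df)
}

#' Karlin-Altschul style E-value
#'
#' E = m n 2^(-bits): linear in the query-length x database-length search
#' space, halving per extra bit of score.
#'
#' @param bits bitscore.
#' @param queryLen,dbLen search space dimensions (positive).
#' @return expectation value.
#' @examples
#' evalueOf(0, 1, 1)     # 1 by definition
#' @export
evalueOf <- function(bits, queryLen, dbLen) {
  stopifnot(queryLen > 0, dbLen > 0)
  queryLen * dbLen * 2^(-bits)
}

#' Filter hits by a threshold profile
#'
#' Keeps exactly the hits satisfying every bound of the profile, preserving
#' input order.  Idempotent.
#'
#' @param x a \code{\link{HitTable}}.
#' @param profile a \code{\link{ThresholdProfile}}.
#' @return filtered \code{\link{HitTable}}.
#' @export
filterHits <- function(x, profile) {
  stopifnot(is(x, "HitTable"), is(profile, "ThresholdProfile"))
  h <- hits(x)
  keep <- h$evalue <= profile@maxEvalue &
    h$identity_pct >= profile@minIdentity &
    h$similarity_pct >= profile@minSimilarity &
    h$query_cov_pct >= profile@minQueryCov &
    h$subject_cov_pct >= profile@minSubjectCov &
    h$mismatches <= profile@maxMismatches
  new("HitTable", hits = h[keep, , drop = FALSE])
}

#' Best hit per query
#'
#' Per query, the hit with the lowest E-value; ties broken by higher
#' bitscore, then lexicographically smaller subject id.
#'
#' @param x a \code{\link{HitTable}}.
#' @return \code{\link{HitTable}} with at most one row per query.
#' @export
bestHitPerQuery <- function(x) {
  stopifnot(is(x, "HitTable"))
  h <- hits(x)
  if (nrow(h) == 0) return(x)
  o <- order(h$query_id, h$evalue, -h$bitscore, h$subject_id)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  new("HitTable", hits = h)
}

#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is reported iff b is a's best hit in the A-to-B search and
#' a is b's best hit in the B-to-A search.
#'
#' @param hitsAB hits of set A queried against set B
#'   (a \code{\link{HitTable}}).
#' @param hitsBA hits of set B queried against set A.
#' @return \code{data.frame} with columns \code{a}, \code{b}.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA) {
  ba <- hits(bestHitPerQuery(hitsAB))
  bb <- hits(bestHitPerQuery(hitsBA))
  bestAB <- setNames(ba$subject_id, ba$query_id)
  bestBA <- setNames(bb$subject_id, bb$query_id)
  a <- names(bestAB)
  b <- unname(bestAB)
  mutual <- !is.na(bestBA[b]) & bestBA[b] == a
  data.frame(a = a[mutual], b = b[mutual], stringsAsFactors = FALSE,
             row.names = NULL)
}
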