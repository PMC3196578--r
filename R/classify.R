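#' @include similarity.R
NULL

#' Build a contig membership ledger
#'
#' @param members \code{data.frame} with columns \code{contig_id},
#'   \code{read_id}.
#' @param consensusLen named vector of contig consensus lengths (bp).
#' @param readLengths named vector of read lengths (bp), used for the mean
#'   member read length r of the (n*r)/c coverage statistic.
#' @return a \code{\link{ContigSet}}.
#' @export
contigSet <- function(members, consensusLen, readLengths) {
  stopifnot(all(c("contig_id", "read_id") %in% names(members)))
  ids <- unique(members$contig_id)
  if (!all(ids %in% names(consensusLen)))
    stop("consensusLen missing for some contigs")
  if (!all(members$read_id %in% names(readLengths)))
    stop("readLengths missing for some member reads")
  n <- as.integer(table(members$contig_id)[ids])
  avg <- vapply(split(readLengths[members$read_id], members$contig_id)[ids],
                mean, numeric(1))
  contigs <- data.frame(contig_id = ids,
                        consensus_len = as.numeric(consensusLen[ids]),
                        n_reads = n, avg_read_len = as.numeric(avg),
                        stringsAsFactors = FALSE, row.names = NULL)
  new("ContigSet", contigs = contigs, members = members)
}

#' Contig coverage statistic (n*r)/c
#'
#' Coverage of a contig consensus: number of member reads n times mean read
#' length r, divided by the consensus length c.  Collapsed repeat contigs
#' show anomalously high values.
#'
#' @param n number of member reads (>= 1).
#' @param r mean member read length (bp).
#' @param c consensus length (bp, > 0).
#' @return coverage (x-fold).
#' @examples
#' contigCoverage(10, 345, 690)   # 5
#' @export
contigCoverage <- function(n, r, c) {
  if (any(c <= 0)) stop("consensus length must be positive")
  stopifnot(all(n >= 1), all(r > 0))
  n * r / c
}

#' Reads participating in high-coverage contigs
#'
#' Union of member reads of contigs whose (n*r)/c coverage reaches the
#' cutoff.  The boundary is inclusive (coverage exactly 5 qualifies):
#' the estimate is coarse and the conventional phrasing "above a cutoff of
#' 5" is read as >= 5.  Singleton reads have no contig coverage and can
#' never qualify.
#'
#' @param x a \code{\link{ContigSet}}.
#' @param cutoff coverage cutoff (default 5, chosen for ~2x survey
#'   coverage).
#' @return character vector of read ids.
#' @export
highCoverageReadSet <- function(x, cutoff = 5) {
  stopifnot(is(x, "ContigSet"))
  ci <- contigInfo(x)
  if (nrow(ci) == 0) return(character())
  cov <- contigCoverage(ci$n_reads, ci$avg_read_len, ci$consensus_len)
  hot <- ci$contig_id[cov >= cutoff]
  mb <- memberReads(x)
  unique(mb$read_id[mb$contig_id %in% hot])
}

#' Classify survey reads through the repeat/gene cascade
#'
#' Sequential classification cascade: a read is tested by each stage only if
#' it escaped all previous stages.
#' \enumerate{
#'   \item \strong{KNOWN_TE}: nucleotide match to the curated repeat library
#'     (E <= 1e-6); the best-hit family name is recorded.
#'   \item \strong{NOVEL_TE}: translated match to the repeat protein library
#'     (E <= 1e-6).
#'   \item \strong{VIRAL}: translated match to viral proteins (E <= 0.001,
#'     identity >= 30, similarity >= 50, read coverage >= 50, protein
#'     coverage >= 1).
#'   \item \strong{GENE}: protein or EST evidence via
#'     \code{\link{identifyGeneReads}} (TE-associated protein domains
#'     excluded).
#'   \item \strong{REPEAT}: membership in a contig with (n*r)/c coverage at
#'     or above \code{coverageCutoff} (uncharacterised repeats).
#'   \item \strong{OTHER}: everything left.
#' }
#' The stage order follows the convention that the uncharacterised-repeat
#' class contains reads escaping the TE \emph{and} gene classes; it can be
#' changed via \code{stageOrder}.  Viral reads are reported separately by
#' default (fold them into the combined repeat row downstream if desired).
#'
#' @param reads named \code{DNAStringSet} or character vector of reads.
#' @param repeatNtDb nucleotide repeat library (named sequences, ids =
#'   family names).
#' @param repeatProtDb repeat protein library (translated screen), or NULL
#'   to skip.
#' @param viralProtDb viral protein set, or NULL to skip.
#' @param geneProtDb,geneEstDb protein and EST gene-evidence databases, or
#'   NULL to skip.
#' @param contigs a \code{\link{ContigSet}} for the high-coverage repeat
#'   stage, or NULL to skip.  Reads absent from the membership table are
#'   treated as singletons (with a warning if the table is non-empty but
#'   incomplete relative to assembled reads is expected).
#' @param excludedDomainTags Pfam-style TE domain codes excluded from gene
#'   evidence (see \code{\link{pfamTeDomains}}).
#' @param coverageCutoff contig-coverage cutoff for the REPEAT stage.
#' @param stageOrder permutation of
#'   \code{c("KNOWN_TE","NOVEL_TE","VIRAL","GENE","REPEAT")}.
#' @param minSeeds seed-count trigger passed to \code{\link{searchHits}}.
#' @return list with \code{labels} (named character, one label per read),
#'   \code{families} (named character: best-hit TE family of KNOWN_TE
#'   reads), and \code{summary} (a \code{\link{ClassificationSummary}}).
#' @export
classifyReads <- function(reads, repeatNtDb, repeatProtDb = NULL,
                          viralProtDb = NULL, geneProtDb = NULL,
                          geneEstDb = NULL, contigs = NULL,
                          excludedDomainTags = pfamTeDomains(),
                          coverageCutoff = 5,
                          stageOrder = c("KNOWN_TE", "NOVEL_TE", "VIRAL",
                                         "GENE", "REPEAT"),
                          minSeeds = 2L) {
  rds <- .as_char_seqs(reads, "reads")
  stopifnot(all(stageOrder %in% c("KNOWN_TE", "NOVEL_TE", "VIRAL", "GENE",
                                  "REPEAT")), !anyDuplicated(stageOrder))
  labels <- setNames(rep(NA_character_, length(rds)), names(rds))
  families <- character()
  for (stage in stageOrder) {
    todo <- names(labels)[is.na(labels)]
    if (length(todo) == 0) break
    got <- character()
    if (stage == "KNOWN_TE") {
      ht <- searchHits(rds[todo], repeatNtDb, mode = "nucleotide",
                       maxEvalue = 1e-6, minSeeds = minSeeds,
                       maxExtensions = 8L, maxHitsPerQuery = 8L,
                       earlyExit = TRUE)
      ht <- filterHits(ht, presetProfile("repeat_nt"))
      best <- hits(bestHitPerQuery(ht))
      got <- best$query_id
      families <- c(families, setNames(best$subject_id, best$query_id))
    } else if (stage == "NOVEL_TE" && !is.null(repeatProtDb)) {
      ht <- searchHits(rds[todo], repeatProtDb, mode = "translated",
                       maxEvalue = 1e-6, minSeeds = max(minSeeds, 3L),
                       maxExtensions = 8L, maxHitsPerQuery = 4L,
                       earlyExit = TRUE)
      ht <- filterHits(ht, presetProfile("repeat_prot"))
      got <- unique(hits(ht)$query_id)
    } else if (stage == "VIRAL" && !is.null(viralProtDb)) {
      ht <- searchHits(rds[todo], viralProtDb, mode = "translated",
                       maxEvalue = 1e-3, minSeeds = max(minSeeds, 3L),
                       maxExtensions = 8L, maxHitsPerQuery = 4L)
      ht <- filterHits(ht, presetProfile("viral"))
      got <- unique(hits(ht)$query_id)
    } else if (stage == "GENE" && (!is.null(geneProtDb) ||
                                   !is.null(geneEstDb))) {
      ev <- identifyGeneReads(rds[todo], geneProtDb, geneEstDb,
                              excludedDomainTags = excludedDomainTags,
                              minSeeds = minSeeds)
      got <- ev$read_id[ev$is_gene]
    } else if (stage == "REPEAT" && !is.null(contigs)) {
      got <- intersect(todo, highCoverageReadSet(contigs, coverageCutoff))
    }
    labels[got] <- stage
    logStage(paste0("classify/", stage), length(todo), length(got))
  }
  labels[is.na(labels)] <- "OTHER"
  list(labels = labels, families = families,
       summary = summarizeClasses(labels))
}

#' Summarise classification labels into a per-class ledger
#'
#' @param labels named character vector of class labels (one per read).
#' @param arm arm label for display.
#' @return a \code{\link{ClassificationSummary}}.
#' @export
summarizeClasses <- function(labels, arm = "") {
  if (any(is.na(labels))) stop("labels missing for some reads")
  bad <- setdiff(unique(labels), .CLASS_LEVELS)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  counts <- setNames(numeric(length(.CLASS_LEVELS)), .CLASS_LEVELS)
  tab <- table(labels)
  counts[names(tab)] <- as.numeric(tab)
  classSummaryFromCounts(counts, arm = arm)
}

#' Build a classification ledger from per-class read counts
#'
#' Used both by \code{\link{summarizeClasses}} and to lay out externally
#' tabulated per-class counts (e.g. published survey ledgers) in the
#' standard format: percentages to two decimals and a combined
#' "known TE + novel TE + repeats" row.
#'
#' @param counts named numeric vector; names among
#'   \code{KNOWN_TE, NOVEL_TE, REPEAT, GENE, VIRAL, OTHER}.  Missing
#'   classes count 0.
#' @param total total reads (defaults to \code{sum(counts)}; if supplied it
#'   must equal the sum -- conservation).
#' @param arm arm label.
#' @param foldViral fold VIRAL counts into the combined repeat row.
#' @return a \code{\link{ClassificationSummary}}.
#' @examples
#' s <- classSummaryFromCounts(c(KNOWN_TE = 1749853, NOVEL_TE = 59832,
#'                               REPEAT = 23419, GENE = 24721,
#'                               OTHER = 550066))
#' classTable(s)
#' @export
classSummaryFromCounts <- function(counts, total = sum(counts), arm = "",
                                   foldViral = FALSE) {
  full <- setNames(numeric(length(.CLASS_LEVELS)), .CLASS_LEVELS)
  bad <- setdiff(names(counts), .CLASS_LEVELS)
  if (length(bad)) stop("unknown classes: ", paste(bad, collapse = ", "))
  full[names(counts)] <- counts
  if (!isTRUE(all.equal(sum(full), total)))
    stop("counts must sum to the total read count")
  pct <- function(x) round(100 * x / total, 2)
  combined <- full[["KNOWN_TE"]] + full[["NOVEL_TE"]] + full[["REPEAT"]] +
    if (foldViral) full[["VIRAL"]] else 0
  rows <- list(
    c("Known TE", full[["KNOWN_TE"]]),
    c("Novel TE", full[["NOVEL_TE"]]),
    c("Repeats (unknown)", full[["REPEAT"]]),
    c("Known TE + Novel TE + Repeats", combined),
    c("Genes", full[["GENE"]]))
  if (!foldViral && full[["VIRAL"]] > 0)
    rows <- c(rows, list(c("Viral", full[["VIRAL"]])))
  rows <- c(rows, list(c("Other", full[["OTHER"]]),
                       c("Total reads", total)))
  tabl <- data.frame(class = vapply(rows, `[`, character(1), 1),
                     reads = as.numeric(vapply(rows, `[`, character(1), 2)),
                     stringsAsFactors = FALSE)
  tabl$pct <- pct(tabl$reads)
  new("ClassificationSummary", arm = arm, counts = full, total = total,
      table = tabl)
}

#' Census of known-TE families
#'
#' @param families named character vector (read id -> best-hit family) as
#'   returned by \code{\link{classifyReads}}.
#' @return \code{data.frame} (\code{family}, \code{reads}) sorted by
#'   descending read count, with attribute \code{n_families} giving the
#'   number of distinct families observed.
#' @export
teFamilyCensus <- function(families) {
  if (length(families) == 0) {
    out <- data.frame(family = character(), reads = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "n_families") <- 0L
    return(out)
  }
  tab <- sort(table(families), decreasing = TRUE)
  out <- data.frame(family = names(tab), reads = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_families") <- nrow(out)
  out
}
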