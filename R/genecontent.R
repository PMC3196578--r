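#' @include classify.R
NULL

#' TE-associated protein domain codes excluded from gene evidence
#'
#' Pfam-style codes of transposon, retrotransposon and integrase domains;
#' reads whose only protein evidence carries one of these codes are not
#' counted as genes even though they match a protein database.
#'
#' @return character vector of 21 domain codes.
#' @export
pfamTeDomains <- function() {
  c("PF00078", "PF03732", "PF05380", "PF07727", "PF07999", "PF08284",
    "PF12382", "PF00098", "PF02992", "PF03004", "PF03017", "PF04827",
    "PF10536", "PF10551", "PF12620", "PF01021", "PF04195", "PF01480",
    "PF04094", "PF05754", "PF00665")
}

# domain codes carried in a protein id after '|' separators
.domain_tags <- function(ids) {
  lapply(strsplit(ids, "|", fixed = TRUE), function(parts)
    grep("^PF\\d+$", parts, value = TRUE))
}

#' Identify gene-evidence reads
#'
#' A read carries gene evidence when it matches the protein database
#' (translated: E <= 1e-6, identity >= 30, similarity >= 50, read coverage
#' >= 50, database entry coverage >= 1) or the EST database (nucleotide,
#' same bounds but E <= 1e-30).  Reads whose protein matches all carry
#' TE-associated domain tags are excluded from the gene set.  Domain tags
#' are read from pipe-separated tokens of the protein id
#' (e.g. \code{"prt9|PF00078"}) or supplied explicitly.
#'
#' @param reads named sequences.
#' @param proteinDb,estDb protein / EST databases (either may be NULL).
#' @param excludedDomainTags codes to exclude
#'   (default \code{\link{pfamTeDomains}}).
#' @param proteinDomains optional named list: protein id -> character vector
#'   of domain codes (overrides id parsing).
#' @param minSeeds seed trigger for \code{\link{searchHits}}.
#' @return \code{data.frame} with columns \code{read_id},
#'   \code{protein_hit}, \code{est_hit}, \code{excluded_by_domain},
#'   \code{is_gene}.
#' @export
identifyGeneReads <- function(reads, proteinDb = NULL, estDb = NULL,
                              excludedDomainTags = pfamTeDomains(),
                              proteinDomains = NULL, minSeeds = 2L) {
  rds <- .as_char_seqs(reads, "reads")
  prot_best <- est_best <- setNames(rep(NA_character_, length(rds)),
                                    names(rds))
  excluded <- setNames(rep(NA_character_, length(rds)), names(rds))
  if (!is.null(proteinDb) && length(proteinDb)) {
    ht <- filterHits(searchHits(rds, proteinDb, mode = "translated",
                                maxEvalue = 1e-6,
                                minSeeds = max(minSeeds, 3L),
                                maxExtensions = 8L, maxHitsPerQuery = 10L),
                     presetProfile("gene_protein"))
    h <- hits(ht)
    if (nrow(h)) {
      tags <- if (is.null(proteinDomains)) {
        tg <- .domain_tags(unique(h$subject_id))
        names(tg) <- unique(h$subject_id)
        tg
      } else proteinDomains
      h$excluded <- vapply(h$subject_id, function(s) {
        tgs <- tags[[s]]
        length(tgs) > 0 && all(tgs %in% excludedDomainTags)
      }, logical(1))
      sp <- split(h, h$query_id)
      for (q in names(sp)) {
        hh <- sp[[q]]
        if (all(hh$excluded)) {
          code <- .domain_tags(hh$subject_id[1])[[1]][1]
          excluded[q] <- if (is.na(code) || !length(code)) "TE" else code
        } else {
          hh <- hh[!hh$excluded, , drop = FALSE]
          prot_best[q] <- hh$subject_id[which.min(hh$evalue)]
        }
      }
    }
  }
  if (!is.null(estDb) && length(estDb)) {
    ht <- filterHits(searchHits(rds, estDb, mode = "nucleotide",
                                maxEvalue = 1e-30, minSeeds = minSeeds,
                                maxHitsPerQuery = 10L),
                     presetProfile("gene_est"))
    best <- hits(bestHitPerQuery(ht))
    est_best[best$query_id] <- best$subject_id
  }
  is_gene <- is.na(excluded) & (!is.na(prot_best) | !is.na(est_best))
  out <- data.frame(read_id = names(rds), protein_hit = unname(prot_best),
                    est_hit = unname(est_best),
                    excluded_by_domain = unname(excluded),
                    is_gene = unname(is_gene),
                    stringsAsFactors = FALSE)
  logStage("gene_evidence", length(rds), sum(out$is_gene))
  out
}

#' Theoretical sequencing coverage
#'
#' Total sequenced bases over the predicted chromosome (arm) length,
#' reported to two decimals.
#'
#' @param totalBases total read bases (bp).
#' @param predictedLen predicted arm/chromosome length (bp).
#' @return coverage (x-fold), rounded to two decimals.
#' @examples
#' theoreticalCoverage(720256529, 295e6)   # 2.44
#' @export
theoreticalCoverage <- function(totalBases, predictedLen) {
  stopifnot(totalBases >= 0, predictedLen > 0)
  round(totalBases / predictedLen, 2)
}

#' Coding fraction of an arm
#'
#' Percent of sequenced bases belonging to gene-evidence reads.  Computing
#' matched over total read bases is the algebraic simplification of
#' "matched bases / coverage / arm length" and avoids compounding the
#' rounding of a printed coverage value.
#'
#' @param matchedGeneBases total bases of gene-evidence reads (bp).
#' @param totalBases total read bases (bp).
#' @return coding fraction in percent (unrounded).
#' @examples
#' round(codingFraction(7779334, 720256529), 2)   # 1.08
#' @export
codingFraction <- function(matchedGeneBases, totalBases) {
  stopifnot(matchedGeneBases >= 0, totalBases > 0,
            matchedGeneBases <= totalBases)
  100 * matchedGeneBases / totalBases
}

#' Project a gene count from the coding fraction
#'
#' floor(codingFraction/100 * armLength / avgCdsLen): the expected number of
#' average-sized coding sequences filling the estimated coding space.
#'
#' @param codingFractionPct coding fraction in percent (0-100).
#' @param predictedArmLen predicted arm length (bp).
#' @param avgCdsLen mean coding sequence length (bp; default 2,000).
#' @return integer gene count.
#' @export
estimateGeneCount <- function(codingFractionPct, predictedArmLen,
                              avgCdsLen = 2000) {
  stopifnot(codingFractionPct >= 0, codingFractionPct <= 100,
            predictedArmLen > 0, avgCdsLen > 0)
  as.integer(floor(codingFractionPct / 100 * predictedArmLen / avgCdsLen))
}

#' Assembly metrics of a survey pseudo-assembly
#'
#' Standard survey assembly statistics: large-contig (> 500 bp) count,
#' bases, mean size, N50 (cumulative-half definition) and largest contig;
#' plus a coverage-based genome size estimate: the mode of the contig
#' (n*r)/c coverage histogram at 0.1x binning restricted to (0, 5) is taken
#' as the realised sequence coverage, and genome size = total read bases /
#' coverage.  The returned histogram pools all contigs above 10x into one
#' class, the usual display convention for repeat-heavy assemblies.
#'
#' @param contigLengths numeric vector of all contig lengths (bp).
#' @param contigs optional \code{\link{ContigSet}} for the coverage
#'   histogram (NULL disables the coverage/genome-size estimates).
#' @param totalReadBases total sequenced bases (bp).
#' @param largeCutoff large-contig length cutoff (bp, exclusive).
#' @return named list: \code{n_contigs}, \code{n_large_contigs},
#'   \code{bases_large}, \code{avg_large_contig}, \code{n50_large},
#'   \code{largest}, \code{estimated_coverage}, \code{estimated_genome_size},
#'   \code{coverage_histogram}.
#' @export
assemblyMetrics <- function(contigLengths, contigs = NULL,
                            totalReadBases = NA_real_, largeCutoff = 500) {
  if (length(contigLengths) == 0) stop("empty assembly")
  large <- contigLengths[contigLengths > largeCutoff]
  n50 <- function(x) {
    if (!length(x)) return(NA_real_)
    x <- sort(x, decreasing = TRUE)
    x[which(cumsum(x) >= sum(x) / 2)[1]]
  }
  est_cov <- NA_real_
  hist_df <- NULL
  if (!is.null(contigs)) {
    ci <- contigInfo(contigs)
    cov <- contigCoverage(ci$n_reads, ci$avg_read_len, ci$consensus_len)
    inwin <- cov[cov > 0 & cov < 5]
    if (length(inwin)) {
      bin <- floor(inwin * 10 + 1e-6)
      tab <- table(bin)
      mode_bin <- as.numeric(names(tab)[which.max(tab)])
      est_cov <- (mode_bin + 0.5) * 0.1
    }
    idx <- pmin(floor(cov * 10 + 1e-6), 101)
    tab <- table(idx)
    lab <- as.numeric(names(tab))
    hist_df <- data.frame(coverage_bin = ifelse(lab > 100, ">10",
                                                format(lab / 10)),
                          n_contigs = as.integer(tab),
                          stringsAsFactors = FALSE, row.names = NULL)
  }
  list(n_contigs = length(contigLengths),
       n_large_contigs = length(large),
       bases_large = sum(large),
       avg_large_contig = if (length(large)) round(sum(large) / length(large))
                          else NA_real_,
       n50_large = n50(large),
       largest = max(contigLengths),
       estimated_coverage = est_cov,
       estimated_genome_size = if (is.na(est_cov)) NA_real_
                               else totalReadBases / est_cov,
       coverage_histogram = hist_df)
}
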