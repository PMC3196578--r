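#' @include similarity.R
NULL

#' Map gene reads onto related reference proteomes
#'
#' Translated best-hit search of coding reads against each reference
#' proteome (E <= 1e-6, identity >= 30, similarity >= 50, read coverage
#' >= 50, best hit only), plus the Venn partition of reads by the set of
#' species in which they found a homolog.
#'
#' @param geneReads named nucleotide sequences (TE/repeat-filtered reads).
#' @param proteomes named list of protein databases, one per species.
#' @param minSeeds seed trigger for \code{\link{searchHits}}.
#' @return list: \code{bestHits} (named list of best-hit
#'   \code{\link{HitTable}}s per species) and \code{venn} (named counts over
#'   the non-empty species subsets, e.g. \code{"A&B&C"}).
#' @export
mapGeneReads <- function(geneReads, proteomes, minSeeds = 2L) {
  stopifnot(is.list(proteomes), !is.null(names(proteomes)))
  rds <- .as_char_seqs(geneReads, "geneReads")
  prof <- presetProfile("synteny")
  best <- lapply(proteomes, function(db) {
    ht <- filterHits(searchHits(rds, db, mode = "translated",
                                maxEvalue = prof@maxEvalue,
                                minSeeds = max(minSeeds, 3L),
                                maxExtensions = 8L, maxHitsPerQuery = 5L),
                     prof)
    bestHitPerQuery(ht)
  })
  present <- lapply(best, function(b) unique(hits(b)$query_id))
  species <- names(proteomes)
  pattern <- vapply(names(rds), function(r) {
    inset <- species[vapply(present, function(p) r %in% p, logical(1))]
    paste(inset, collapse = "&")
  }, character(1))
  pattern <- pattern[nzchar(pattern)]
  venn <- table(pattern)
  venn <- setNames(as.integer(venn), names(venn))
  list(bestHits = best, venn = venn)
}

#' Sliding-window gene density track
#'
#' Number of distinct matched genes per window (default 1 Mb) at a fixed
#' step (default 20 kb); trailing windows are truncated at the chromosome
#' end.
#'
#' @param positions named numeric vector: gene id -> chromosomal position
#'   (bp midpoint).  Duplicate gene ids are counted once.
#' @param chromLen chromosome length (bp).
#' @param chrom chromosome label for the track.
#' @param window,step window width and shift (bp).
#' @return \code{data.frame}: \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{density} (genes per window).
#' @export
windowDensity <- function(positions, chromLen, chrom = "chr",
                          window = 1e6, step = 2e4) {
  stopifnot(chromLen > 0, window > 0, step > 0)
  if (length(positions)) {
    if (is.null(names(positions))) stop("positions must be named by gene id")
    positions <- positions[!duplicated(names(positions))]
    if (any(positions < 0 | positions > chromLen))
      stop("positions outside the chromosome")
  }
  starts <- seq(0, max(0, chromLen - 1), by = step)
  ends <- pmin(starts + window, chromLen)
  dens <- vapply(seq_along(starts), function(i)
    sum(positions >= starts[i] & positions < starts[i] + window),
    numeric(1))
  data.frame(chrom = chrom, start = starts, end = ends, density = dens,
             stringsAsFactors = FALSE)
}

#' Call syntenic regions from a density track
#'
#' Maximal runs of consecutive windows at or above the density cutoff,
#' merged into intervals.
#'
#' @param track density track from \code{\link{windowDensity}}.
#' @param minDensity genes-per-window cutoff (default 50, i.e. 50 genes/Mb
#'   for 1 Mb windows).
#' @return \code{data.frame}: \code{chrom}, \code{start}, \code{end} of
#'   merged qualifying intervals.
#' @export
callSyntenicRegions <- function(track, minDensity = 50) {
  out <- do.call(rbind, lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    hot <- tr$density >= minDensity
    if (!any(hot)) return(NULL)
    r <- rle(hot)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    keep <- which(r$values)
    data.frame(chrom = tr$chrom[1],
               start = tr$start[idx_start[keep]],
               end = tr$end[idx_end[keep]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.gene_set_ok <- function(g, what) {
  if (!is.list(g) || !all(c("info", "seq") %in% names(g)))
    stop(what, " must be a list(info = data.frame, seq = sequences)")
  if (!all(c("gene_id", "chrom", "pos") %in% names(g$info)))
    stop(what, "$info needs gene_id, chrom, pos")
  if (!all(g$info$gene_id %in% names(g$seq)))
    stop(what, ": every gene needs a sequence")
  invisible(TRUE)
}

#' Build a genome zipper virtual gene order
#'
#' Orders the reference-species ("A") genes lying in the configured syntenic
#' intervals by chromosomal position, keeping only genes with a nucleotide
#' homolog (E below \code{maxEvalue}) in at least one of the two related
#' species, and annotates each entry with the OxSx(hyz) reliability code:
#' \itemize{
#'   \item O = 1 iff the best species-B homolog lies on a configured
#'     syntenic B chromosome (S likewise for species C);
#'   \item h/y/z = 1 iff the A-B / A-C / B-C gene pair is a reciprocal best
#'     hit.
#' }
#'
#' @param genesA,genesB,genesC each a list with \code{info}
#'   (\code{data.frame}: \code{gene_id}, \code{chrom}, \code{pos}) and
#'   \code{seq} (named nucleotide sequences).
#' @param syntenicChromsB,syntenicChromsC chromosome names accepted as
#'   syntenic in species B and C (configured, never inferred).
#' @param intervalsA optional \code{data.frame} (\code{chrom}, \code{start},
#'   \code{end}) restricting species-A genes to syntenic intervals.
#' @param maxEvalue homology threshold (default 1e-10).
#' @param minSeeds seed trigger for \code{\link{searchHits}}.
#' @return a \code{\link{GenomeZipper}}.
#' @export
buildZipper <- function(genesA, genesB, genesC, syntenicChromsB,
                        syntenicChromsC, intervalsA = NULL,
                        maxEvalue = 1e-10, minSeeds = 2L) {
  .gene_set_ok(genesA, "genesA"); .gene_set_ok(genesB, "genesB")
  .gene_set_ok(genesC, "genesC")
  infoA <- genesA$info
  if (!is.null(intervalsA) && nrow(intervalsA)) {
    keep <- vapply(seq_len(nrow(infoA)), function(i)
      any(intervalsA$chrom == infoA$chrom[i] &
            intervalsA$start <= infoA$pos[i] &
            infoA$pos[i] < intervalsA$end), logical(1))
    infoA <- infoA[keep, , drop = FALSE]
  }
  if (nrow(infoA) == 0)
    return(new("GenomeZipper", entries = data.frame(
      rank = integer(), gene_id = character(), chrom = character(),
      pos = numeric(), code = character(), O = integer(), S = integer(),
      h = integer(), y = integer(), z = integer())))
  seqA <- .as_char_seqs(genesA$seq)[infoA$gene_id]
  seqB <- .as_char_seqs(genesB$seq); seqC <- .as_char_seqs(genesC$seq)
  srch <- function(q, s) searchHits(q, s, mode = "nucleotide",
                                    maxEvalue = maxEvalue,
                                    minSeeds = minSeeds,
                                    maxHitsPerQuery = 5L)
  hAB <- srch(seqA, seqB); hBA <- srch(seqB, seqA)
  hAC <- srch(seqA, seqC); hCA <- srch(seqC, seqA)
  hBC <- srch(seqB, seqC); hCB <- srch(seqC, seqB)
  bAB <- hits(bestHitPerQuery(hAB)); bAC <- hits(bestHitPerQuery(hAC))
  bestB <- setNames(bAB$subject_id, bAB$query_id)
  bestC <- setNames(bAC$subject_id, bAC$query_id)
  rbhAB <- reciprocalBestHits(hAB, hBA)
  rbhAC <- reciprocalBestHits(hAC, hCA)
  rbhBC <- reciprocalBestHits(hBC, hCB)
  pairKey <- function(df) paste(df$a, df$b)
  chromB <- setNames(genesB$info$chrom, genesB$info$gene_id)
  chromC <- setNames(genesC$info$chrom, genesC$info$gene_id)
  haveB <- infoA$gene_id %in% names(bestB)
  haveC <- infoA$gene_id %in% names(bestC)
  infoA <- infoA[haveB | haveC, , drop = FALSE]
  if (nrow(infoA) == 0)
    return(new("GenomeZipper", entries = data.frame(
      rank = integer(), gene_id = character(), chrom = character(),
      pos = numeric(), code = character(), O = integer(), S = integer(),
      h = integer(), y = integer(), z = integer())))
  g <- infoA$gene_id
  homB <- unname(bestB[g]); homC <- unname(bestC[g])
  O <- as.integer(!is.na(homB) & chromB[homB] %in% syntenicChromsB)
  S <- as.integer(!is.na(homC) & chromC[homC] %in% syntenicChromsC)
  h <- as.integer(!is.na(homB) & paste(g, homB) %in% pairKey(rbhAB))
  y <- as.integer(!is.na(homC) & paste(g, homC) %in% pairKey(rbhAC))
  z <- as.integer(!is.na(homB) & !is.na(homC) &
                    paste(homB, homC) %in% pairKey(rbhBC))
  entries <- data.frame(gene_id = g, chrom = infoA$chrom, pos = infoA$pos,
                        O = O, S = S, h = h, y = y, z = z,
                        homolog_B = homB, homolog_C = homC,
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$pos), , drop = FALSE]
  entries$rank <- seq_len(nrow(entries))
  entries$code <- sprintf("O%dS%d(%d%d%d)", entries$O, entries$S,
                          entries$h, entries$y, entries$z)
  entries <- entries[, c("rank", "gene_id", "chrom", "pos", "code",
                         "O", "S", "h", "y", "z", "homolog_B", "homolog_C")]
  rownames(entries) <- NULL
  logStage("zipper/build", length(genesA$info$gene_id), nrow(entries))
  new("GenomeZipper", entries = entries)
}

# best anchor per query onto a sequence set restricted to zipper genes,
# resolving exact ties to the lower zipper rank
.anchor_best <- function(queries, zipper, geneSeqs, maxEvalue, minSeeds) {
  e <- zipperEntries(zipper)
  seqs <- .as_char_seqs(geneSeqs)
  seqs <- seqs[names(seqs) %in% e$gene_id]
  if (!length(seqs) || !length(queries)) {
    return(data.frame(query_id = character(), rank = integer(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  }
  ht <- searchHits(queries, seqs, mode = "nucleotide", maxEvalue = maxEvalue,
                   minSeeds = minSeeds, maxHitsPerQuery = 5L)
  h <- hits(ht)
  if (nrow(h) == 0) {
    return(data.frame(query_id = character(), rank = integer(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  }
  rank_of <- setNames(e$rank, e$gene_id)
  h$rank <- rank_of[h$subject_id]
  o <- order(h$query_id, h$evalue, -h$bitscore, h$rank)
  h <- h[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  # ambiguous: the runner-up ties on E-value and bitscore but is a
  # different zipper gene
  amb <- logical(nrow(h))
  idx <- which(first)
  nxt <- c(idx[-1] - 1, nrow(h))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (nxt[k] > i) {
      j <- i + 1
      amb[i] <- h$evalue[j] == h$evalue[i] & h$bitscore[j] == h$bitscore[i] &
        h$rank[j] != h$rank[i]
    }
  }
  out <- h[first, c("query_id", "rank"), drop = FALSE]
  out$ambiguous <- amb[first]
  rownames(out) <- NULL
  out
}

#' Anchor survey reads onto a genome zipper
#'
#' Nucleotide best-hit anchoring of reads onto the zipper's reference gene
#' sequences (E below \code{maxEvalue}).  Each read is anchored to at most
#' one entry; reads tying exactly between two entries go to the lower rank
#' and are flagged ambiguous.
#'
#' @param reads named nucleotide sequences.
#' @param zipper a \code{\link{GenomeZipper}}.
#' @param geneSeqs named sequences of the species-A genes.
#' @param maxEvalue anchoring threshold (default 1e-10).
#' @param minSeeds seed trigger.
#' @return the zipper with \code{readAnchors} filled; anchoring statistics
#'   (entries with >= 1 anchor, fraction of anchored entries on syntenic
#'   chromosomes / with RBH support) in \code{attr(, "stats")}.
#' @export
anchorReads <- function(reads, zipper, geneSeqs, maxEvalue = 1e-10,
                        minSeeds = 2L) {
  an <- .anchor_best(reads, zipper, geneSeqs, maxEvalue, minSeeds)
  names(an)[1] <- "read_id"
  zipper@readAnchors <- an
  e <- zipperEntries(zipper)
  anchored <- unique(an$rank)
  ea <- e[e$rank %in% anchored, , drop = FALSE]
  stats <- list(
    n_entries = nrow(e),
    n_anchored_entries = length(anchored),
    n_anchored_reads = nrow(an),
    frac_syntenic = if (nrow(ea)) mean(ea$O == 1 | ea$S == 1) else NA_real_,
    frac_ortholog = if (nrow(ea)) mean(ea$h == 1 | ea$y == 1) else NA_real_)
  attr(zipper, "stats") <- stats
  logStage("zipper/anchor_reads", length(reads), nrow(an))
  zipper
}

#' Anchor EST markers onto a genome zipper
#'
#' Markers are anchored to zipper entries by nucleotide best hit and carry
#' their deletion-bin assignment from the bin map.
#'
#' @param markers named marker sequences.
#' @param zipper a \code{\link{GenomeZipper}}.
#' @param geneSeqs named species-A gene sequences.
#' @param binmap a \code{\link{BinMap}} with marker assignments.
#' @param maxEvalue anchoring threshold (default 1e-10).
#' @param minSeeds seed trigger.
#' @return the zipper with \code{markerAnchors} filled.
#' @export
anchorMarkersToZipper <- function(markers, zipper, geneSeqs, binmap,
                                  maxEvalue = 1e-10, minSeeds = 2L) {
  an <- .anchor_best(markers, zipper, geneSeqs, maxEvalue, minSeeds)
  names(an)[1] <- "marker_id"
  mk <- binMarkers(binmap)
  bin_of <- setNames(mk$bin, mk$marker_id)
  missing <- setdiff(an$marker_id, names(bin_of))
  if (length(missing))
    stop("markers without bin assignment: ", paste(missing, collapse = ", "))
  an$bin <- unname(bin_of[an$marker_id])
  zipper@markerAnchors <- an[, c("marker_id", "rank", "bin")]
  zipper
}

#' Anchor reads to bin-mapped EST markers
#'
#' Nucleotide best-hit assignment of survey reads to EST markers (E below
#' \code{maxEvalue}); each read inherits the marker's deletion bin.  The
#' per-arm report gives, for reads of each source arm, the fraction
#' anchoring to markers of their own arm versus the opposite arm (both the
#' read-level and the marker-level tally are reported, since either
#' convention is used in practice).
#'
#' @param reads named read sequences.
#' @param readArms named character vector: read id -> source arm.
#' @param markers named marker sequences.
#' @param binmap a \code{\link{BinMap}} whose markers are assigned to bins.
#' @param maxEvalue anchoring threshold (default 1e-10).
#' @param minSeeds seed trigger.
#' @return list: \code{anchors} (\code{data.frame}: read, marker, bin,
#'   read_arm, bin_arm), \code{armReport} (per-arm own/cross fractions,
#'   reads and markers), \code{binCounts} (reads per bin).
#' @export
anchorMarkers <- function(reads, readArms, markers, binmap,
                          maxEvalue = 1e-10, minSeeds = 2L) {
  rds <- .as_char_seqs(reads, "reads")
  mks <- .as_char_seqs(markers, "markers")
  mk <- binMarkers(binmap)
  if (!all(names(mks) %in% mk$marker_id))
    stop("marker without bin: ",
         paste(setdiff(names(mks), mk$marker_id), collapse = ", "))
  ht <- searchHits(rds, mks, mode = "nucleotide", maxEvalue = maxEvalue,
                   minSeeds = minSeeds, maxHitsPerQuery = 5L)
  best <- hits(bestHitPerQuery(ht))
  if (nrow(best) == 0) {
    anchors <- data.frame(read_id = character(), marker_id = character(),
                          bin = character(), read_arm = character(),
                          bin_arm = character(), stringsAsFactors = FALSE)
  } else {
    bin_of <- setNames(mk$bin, mk$marker_id)
    b <- bins(binmap)
    arm_of_bin <- setNames(b$arm, b$bin)
    anchors <- data.frame(read_id = best$query_id,
                          marker_id = best$subject_id,
                          bin = unname(bin_of[best$subject_id]),
                          read_arm = unname(readArms[best$query_id]),
                          stringsAsFactors = FALSE)
    anchors$bin_arm <- unname(arm_of_bin[anchors$bin])
  }
  armReport <- do.call(rbind, lapply(split(anchors, anchors$read_arm),
    function(a) {
      own <- a$bin_arm == a$read_arm
      mk_own <- tapply(own, a$marker_id, any)
      data.frame(read_arm = a$read_arm[1], n_reads = nrow(a),
                 own_arm_reads = sum(own), cross_arm_reads = sum(!own),
                 own_frac_reads = mean(own),
                 own_frac_markers = mean(mk_own),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(armReport))
    armReport <- data.frame(read_arm = character(), n_reads = integer(),
                            own_arm_reads = integer(),
                            cross_arm_reads = integer(),
                            own_frac_reads = numeric(),
                            own_frac_markers = numeric(),
                            stringsAsFactors = FALSE)
  rownames(armReport) <- NULL
  binCounts <- if (nrow(anchors)) {
    tb <- table(anchors$bin)
    data.frame(bin = names(tb), n_reads = as.integer(tb),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(bin = character(), n_reads = integer(),
                    stringsAsFactors = FALSE)
  logStage("zipper/anchor_markers", length(rds), nrow(anchors))
  list(anchors = anchors, armReport = armReport, binCounts = binCounts)
}

#' Check collinearity of the zipper against the deletion-bin map
#'
#' For each selected (non-overlapping) bin, collects the zipper ranks of its
#' anchored markers.  A marker is "out of place" when its rank falls outside
#' the maximal contiguous run of its bin's markers in the rank-ordered
#' marker sequence.  An inversion candidate is flagged for every maximal run
#' of >= 2 consecutive bins whose median ranks strictly decrease along the
#' physical (fractional) bin order.
#'
#' @param zipper a \code{\link{GenomeZipper}} with marker anchors (see
#'   \code{\link{anchorMarkersToZipper}}).
#' @param binmap the \code{\link{BinMap}}.
#' @param selectedBins bins to analyse; default: all non-overlapping bins
#'   with at least \code{minMarkers} anchored markers.  Bins with fewer than
#'   \code{minMarkers} markers are skipped with a warning.
#' @param minMarkers minimum anchored markers per bin (default 2).
#' @return list: \code{perBin} (\code{data.frame}: bin, n markers, median
#'   rank, out-of-place count), \code{outOfPlace} (total),
#'   \code{inversions} (\code{data.frame}: first/last bin and fractional
#'   interval of each candidate).
#' @export
collinearityCheck <- function(zipper, binmap, selectedBins = NULL,
                              minMarkers = 2L) {
  an <- markerAnchors(zipper)
  b <- bins(binmap)
  if (is.null(selectedBins)) {
    cand <- b$bin[!b$overlaps]
  } else {
    cand <- selectedBins
    if (any(b$overlaps[match(cand, b$bin)]))
      warning("selected bins include overlapping bins; they are excluded ",
              "from collinearity statistics")
    cand <- cand[!b$overlaps[match(cand, b$bin)]]
  }
  an <- an[an$bin %in% cand, , drop = FALSE]
  counts <- table(an$bin)
  small <- names(counts)[counts < minMarkers]
  small <- c(small, setdiff(cand, names(counts)))
  if (length(small)) {
    warning("bins with < ", minMarkers, " anchored markers skipped: ",
            paste(small, collapse = ", "))
    cand <- setdiff(cand, small)
  }
  an <- an[an$bin %in% cand, , drop = FALSE]
  if (nrow(an) == 0) {
    return(list(perBin = data.frame(bin = character(), n_markers = integer(),
                                    median_rank = numeric(),
                                    out_of_place = integer(),
                                    stringsAsFactors = FALSE),
                outOfPlace = 0L,
                inversions = data.frame(from_bin = character(),
                                        to_bin = character(),
                                        frac_start = numeric(),
                                        frac_end = numeric(),
                                        stringsAsFactors = FALSE)))
  }
  an <- an[order(an$rank), , drop = FALSE]
  oop_of <- vapply(cand, function(bb) {
    lab <- an$bin == bb
    r <- rle(lab)
    runs <- r$lengths[r$values]
    sum(lab) - max(runs)
  }, numeric(1))
  # physical order of the selected bins along the arm
  bsel <- b[match(cand, b$bin), , drop = FALSE]
  bsel <- bsel[order(bsel$arm, bsel$frac_start), , drop = FALSE]
  med <- vapply(bsel$bin, function(bb) stats::median(an$rank[an$bin == bb]),
                numeric(1))
  inv <- NULL
  if (nrow(bsel) >= 2) {
    dec <- diff(med) < 0
    r <- rle(dec)
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- start_i[k]; i1 <- stop_i[k] + 1   # bins i0 .. i1 reversed
      inv <- rbind(inv, data.frame(
        from_bin = bsel$bin[i0], to_bin = bsel$bin[i1],
        frac_start = bsel$frac_start[i0], frac_end = bsel$frac_end[i1],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(inv))
    inv <- data.frame(from_bin = character(), to_bin = character(),
                      frac_start = numeric(), frac_end = numeric(),
                      stringsAsFactors = FALSE)
  perBin <- data.frame(bin = bsel$bin,
                       n_markers = as.integer(counts[bsel$bin]),
                       median_rank = med[bsel$bin],
                       out_of_place = as.integer(oop_of[bsel$bin]),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(perBin = perBin, outOfPlace = sum(perBin$out_of_place),
       inversions = inv)
}

#' Export a genome zipper as a TSV table
#'
#' One row per entry: rank, gene, chromosome, position, code, number of
#' anchored reads and anchored markers with bins.
#'
#' @param zipper a \code{\link{GenomeZipper}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeZipperTable <- function(zipper, path) {
  e <- zipperEntries(zipper)
  ra <- readAnchors(zipper); ma <- markerAnchors(zipper)
  nread <- table(factor(ra$rank, levels = e$rank))
  mk <- vapply(e$rank, function(r)
    paste(ma$marker_id[ma$rank == r], collapse = ","), character(1))
  bn <- vapply(e$rank, function(r)
    paste(unique(ma$bin[ma$rank == r]), collapse = ","), character(1))
  out <- cbind(e[, c("rank", "gene_id", "chrom", "pos", "code")],
               n_anchored_reads = as.integer(nread),
               markers = mk, bins = bn)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
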