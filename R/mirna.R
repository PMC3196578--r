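#' @include similarity.R
NULL

#' Parse miRNA family names from mature ids
#'
#' miRBase-style ids (\code{"tae-miR1122a"}) reduce to their family
#' (\code{"miR1122"}); ids without a recognisable family token are returned
#' unchanged.
#'
#' @param ids character vector of mature miRNA ids.
#' @return character vector of family names.
#' @export
mirnaFamily <- function(ids) {
  fam <- sub("^[A-Za-z]{3,4}-", "", ids)
  hit <- regexpr("[Mm]i[Rr][0-9]+", fam)
  out <- ifelse(hit > 0, regmatches(fam, hit), ids)
  sub("^mir", "miR", out, ignore.case = TRUE)
}

#' Search mature miRNAs against survey sequences
#'
#' Nucleotide search of each mature sequence (19-24 nt, U mapped to T)
#' against the contigs and singletons, word size 7, E <= 10, at most
#' \code{maxHits} retained hits per mature.  Plus-strand alignments are
#' "direct" hits, minus-strand alignments "revcomp" hits.  Mismatches are
#' counted against the full mature sequence (substitutions plus unaligned
#' mature bases); direct hits with more than \code{maxDirectMismatches}
#' mismatches, or containing gaps, are discarded, while all revcomp hits
#' are retained (the passenger strand is allowed to diverge).  The hit cap
#' applies per query and subject sequence, after mismatch filtering: with a
#' fragmented survey assembly the same locus recurs on a contig and on the
#' singleton reads covering it, and a per-query-overall cap would silently
#' crowd out the (weaker-scoring) passenger hits of real loci.
#'
#' @param sequences named subject sequences (contigs + singletons).
#' @param matureDb named mature miRNA sequences.
#' @param maxHits per-mature retained hit cap (default 10).
#' @param maxDirectMismatches mismatch allowance for direct hits (default 3).
#' @param wordSize seed word size (default 7).
#' @param maxEvalue E-value bound (default 10).
#' @return \code{data.frame}: \code{mature_id}, \code{family},
#'   \code{subject_id}, \code{orientation} (direct/revcomp),
#'   \code{s_start}, \code{s_end} (0-based half-open), \code{mismatches},
#'   \code{evalue}, \code{bitscore}.
#' @export
findMatureHits <- function(sequences, matureDb, maxHits = 10L,
                           maxDirectMismatches = 3L, wordSize = 7L,
                           maxEvalue = 10) {
  mt <- .as_char_seqs(matureDb, "matureDb")
  if (length(mt) == 0) stop("empty mature database")
  mt <- chartr("Uu", "Tt", mt)
  wl <- nchar(mt)
  if (any(wl < 16 | wl > 30))
    warning("mature sequences outside the usual 19-24 nt range")
  # blastn-default +2/-3 scoring: at 21 nt query length this is the only
  # scheme under which an E <= 10 cutoff tolerates the 2-3 mismatches the
  # passenger strand is expected to carry
  # mature queries are ~21 nt: extensions cost almost nothing, while a
  # passenger hit may carry a single seed word, so every cluster is extended
  ht <- searchHits(mt, sequences, mode = "nucleotide", wordSize = wordSize,
                   match = 2L, mismatch = -3L,
                   maxEvalue = maxEvalue, minSeeds = 1L,
                   maxExtensions = 1000000L, maxHitsPerQuery = 0L)
  h <- hits(ht)
  if (nrow(h) == 0) {
    return(data.frame(mature_id = character(), family = character(),
                      subject_id = character(), orientation = character(),
                      s_start = integer(), s_end = integer(),
                      mismatches = integer(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  h$orientation <- ifelse(h$strand == "+", "direct", "revcomp")
  h$eff_mismatch <- h$mismatches + (h$q_len - (h$q_end - h$q_start))
  drop <- h$orientation == "direct" &
    (h$eff_mismatch > maxDirectMismatches | h$gap_opens > 0)
  h <- h[!drop, , drop = FALSE]
  # per query-subject cap, best E-value first
  h <- h[order(h$query_id, h$subject_id, h$evalue, -h$bitscore), ,
         drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(h)),
                              paste(h$query_id, h$subject_id, sep = "\r")),
                        function(i) utils::head(i, maxHits)), use.names = FALSE)
  h <- h[sort(keep), , drop = FALSE]
  out <- data.frame(mature_id = h$query_id, family = mirnaFamily(h$query_id),
                    subject_id = h$subject_id, orientation = h$orientation,
                    s_start = h$s_start, s_end = h$s_end,
                    q_start = h$q_start, q_end = h$q_end, q_len = h$q_len,
                    strand = h$strand,
                    mismatches = as.integer(h$eff_mismatch),
                    evalue = h$evalue, bitscore = h$bitscore,
                    stringsAsFactors = FALSE, row.names = NULL)
  logStage("mirna/mature_hits", length(mt), nrow(out))
  out
}

#' Pair direct and revcomp mature hits into candidate loci
#'
#' A candidate hairpin locus requires both a mature sequence and a paired
#' passenger (star) on the same subject: loci are formed from
#' (direct, revcomp) hit pairs of the same miRNA family on the same
#' subject whose intervals do not overlap, spanning at most
#' \code{maxSpan} nt.
#'
#' @param matureHits \code{data.frame} from \code{\link{findMatureHits}}.
#' @param maxSpan maximum locus span in nt (default 500, accommodating the
#'   long tail of plant precursor lengths).
#' @return \code{data.frame}, one row per locus: subject, family, the
#'   direct and revcomp hit intervals, and the 5'/3' ordered interval pair.
#' @export
pairHits <- function(matureHits, maxSpan = 500L) {
  empty <- data.frame(subject_id = character(), family = character(),
                      mature_id = character(), d_start = integer(),
                      d_end = integer(), r_start = integer(),
                      r_end = integer(), five_start = integer(),
                      three_end = integer(), span = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(matureHits) == 0) return(empty)
  mh <- matureHits
  # extend trimmed local alignments to the full mature span on the subject
  # (floor at 0; downstream extraction clips at the sequence end)
  if (all(c("q_start", "q_end", "q_len", "strand") %in% names(mh))) {
    plus <- mh$strand == "+"
    ext_l <- ifelse(plus, mh$q_start, mh$q_len - mh$q_end)
    ext_r <- ifelse(plus, mh$q_len - mh$q_end, mh$q_start)
    mh$s_start <- pmax(0L, mh$s_start - ext_l)
    mh$s_end <- mh$s_end + ext_r
  }
  matureHits <- mh
  loci <- list()
  for (key in unique(paste(matureHits$subject_id, matureHits$family,
                           sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    hh <- matureHits[matureHits$subject_id == parts[1] &
                     matureHits$family == parts[2], , drop = FALSE]
    dd <- hh[hh$orientation == "direct", , drop = FALSE]
    rr <- hh[hh$orientation == "revcomp", , drop = FALSE]
    if (nrow(dd) == 0 || nrow(rr) == 0) next
    for (i in seq_len(nrow(dd))) for (j in seq_len(nrow(rr))) {
      ds <- dd$s_start[i]; de <- dd$s_end[i]
      rs <- rr$s_start[j]; re <- rr$s_end[j]
      if (max(ds, rs) < min(de, re)) next        # overlapping pair
      span <- max(de, re) - min(ds, rs)
      if (span > maxSpan) next
      loci[[length(loci) + 1]] <- data.frame(
        subject_id = parts[1], family = parts[2],
        mature_id = dd$mature_id[i],
        d_start = ds, d_end = de, r_start = rs, r_end = re,
        five_start = min(ds, rs), three_end = max(de, re),
        span = span, stringsAsFactors = FALSE)
    }
  }
  if (!length(loci)) return(empty)
  out <- do.call(rbind, loci)
  out <- out[!duplicated(out[, c("subject_id", "five_start", "three_end")]),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a precursor sequence around a candidate locus
#'
#' Cuts 13 nt (by default) before the 5' hit and 13 nt after the 3' hit,
#' the average pri-extension length of plant hairpins; clipping at sequence
#' ends is flagged.
#'
#' @param subjectSeq subject sequence (character or \code{DNAString}).
#' @param fiveStart,threeEnd 0-based half-open locus interval (5' hit start,
#'   3' hit end).
#' @param flank flank length (default 13).
#' @return list: \code{seq}, \code{start}, \code{end} (0-based half-open on
#'   the subject), \code{clipped}.
#' @export
extractPrecursor <- function(subjectSeq, fiveStart, threeEnd, flank = 13L) {
  s <- as.character(subjectSeq)
  n <- nchar(s)
  if (threeEnd <= fiveStart) stop("degenerate locus interval")
  p0 <- max(0L, as.integer(fiveStart) - as.integer(flank))
  p1 <- min(n, as.integer(threeEnd) + as.integer(flank))
  list(seq = substr(s, p0 + 1L, p1), start = p0, end = p1,
       clipped = (p0 == 0L && fiveStart - flank < 0) ||
                 (p1 == n && threeEnd + flank > n))
}

#' Fold a precursor into its MFE hairpin structure
#'
#' Minimum-free-energy secondary structure (no pseudoknots, hairpin loops
#' >= 3 nt) under the package's simple additive energy model: pair energies
#' GC -3, AU -2, GU -1 kcal/mol, +1 kcal/mol per unpaired nt in interior
#' loops/bulges, multiloops free.  Deterministic; N and other ambiguity
#' codes are unpairable.  An adapter for externally folded structures is
#' available: supply a precomputed dot-bracket/MFE pair to the downstream
#' functions instead.
#'
#' @param seq nucleotide sequence (character or \code{DNAString}/RNA;
#'   T and U are equivalent).
#' @param allowGU allow G:U wobble pairs (default TRUE).
#' @param maxInterior interior-loop cap per side (default 30 nt).
#' @return list: \code{structure} (dot-bracket), \code{mfe} (kcal/mol,
#'   <= 0).
#' @examples
#' foldHairpin("GCGCGCGCGCAAAAGCGCGCGCGC")
#' @export
foldHairpin <- function(seq, allowGU = TRUE, maxInterior = 30L) {
  s <- toupper(as.character(seq))
  cpp_fold(s, allowGU, as.integer(maxInterior))
}

#' Adjusted MFE and minimal folding free energy index
#'
#' AMFE is the folding energy normalised to 100 nt
#' (\code{-mfe * 100 / length}); MFEI divides AMFE by the GC percentage
#' (in percent units, e.g. 40 not 0.40).  Both are length-intensive:
#' duplicating a sequence (doubling MFE and length) leaves them unchanged.
#'
#' @param mfe minimum folding free energy (kcal/mol, <= 0).
#' @param length precursor length (nt).
#' @param gcPct GC content in percent (0 < gcPct <= 100).
#' @return list: \code{amfe}, \code{mfei}.
#' @examples
#' mfei(-34, 100, 40)   # amfe 34, mfei 0.85
#' @export
mfei <- function(mfe, length, gcPct) {
  stopifnot(mfe <= 0, length > 0)
  if (any(gcPct <= 0)) stop("gcPct must be positive (percent units)")
  amfe <- -mfe * 100 / length
  list(amfe = amfe, mfei = amfe / gcPct)
}

# integer range that is empty (not reversed) when from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

# wobble-aware mismatch count between a mature and the reverse complement
# of its star region: mature G vs rc-star A is a G:U wobble, mature T vs
# rc-star C likewise; neither counts as a mismatch.  Length differences are
# resolved by sliding the shorter sequence and count as mismatches.
.seq_duplex_mismatches <- function(mature, starRc) {
  a <- strsplit(toupper(mature), "")[[1]]
  b <- strsplit(toupper(starRc), "")[[1]]
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  d <- length(b) - length(a)
  # x = mature, y = rc(star): G vs A <=> mature G : star U (wobble);
  # T vs C <=> mature U : star G (wobble); nothing else is tolerated
  mmat <- function(x, y) sum(!(x == y | (x == "G" & y == "A") |
                                 (x == "T" & y == "C")))
  best <- min(vapply(0:d, function(off)
    mmat(a, b[seq_along(a) + off]), numeric(1)))
  best + d
}

# pairing partner table from a dot-bracket string (0-based; NA = unpaired)
.pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  partner
}

# mature/star duplex geometry.  A mature position counts as paired only
# when its partner falls inside the star window (with a few nt of slack for
# trimmed star alignments); pairing with flank or loop sequence is not
# pairing with the passenger strand and counts as a mismatch.  Asymmetric
# bulges are assessed between consecutive star-paired mature positions.
.duplex_stats <- function(structure, matureStart, matureEnd,
                          starStart = NA, starEnd = NA, slack = 2L) {
  partner <- .pair_table(structure)
  n <- length(partner)
  idx <- (matureStart + 1):matureEnd       # 1-based positions of the mature
  idx <- idx[idx >= 1 & idx <= n]
  win <- if (is.na(starStart) || is.na(starEnd)) c(1, n) else
    c(max(1, starStart + 1 - slack), min(n, starEnd + slack))
  pt <- partner[idx]
  instar <- !is.na(pt) & pt >= win[1] & pt <= win[2]
  paired <- idx[instar]
  unpaired <- length(idx) - length(paired)
  asym <- integer(0)
  if (length(paired) >= 2) {
    for (k in seq_len(length(paired) - 1)) {
      i <- paired[k]; i2 <- paired[k + 1]
      j <- partner[i]; j2 <- partner[i2]
      # compare UNPAIRED counts between consecutive duplex pairs: bases
      # sequestered in side branches are stem decorations, not bulges
      a <- sum(is.na(partner[seq2(i + 1, i2 - 1)]))
      b <- sum(is.na(partner[seq2(min(j, j2) + 1, max(j, j2) - 1)]))
      if (a != b) asym <- c(asym, abs(a - b))
    }
  }
  list(unpaired = unpaired, n_asym = length(asym),
       max_asym = if (length(asym)) max(asym) else 0L,
       frac_paired = length(paired) / length(idx))
}

#' Validate a folded miRNA candidate
#'
#' A candidate passes iff
#' \itemize{
#'   \item MFEI strictly greater than \code{mfeiCutoff} (default 0.85);
#'   \item at most \code{maxStarMismatches} (default 4) mismatches between
#'     the mature sequence and the passenger sequence, counted on the
#'     sequences (mature vs reverse-complemented star; G:U wobble does not
#'     count, indels do);
#'   \item no asymmetric bulge larger than \code{maxBulge} (default 3 nt)
#'     and at most \code{maxBulgeCount} (default 2) asymmetric bulges in
#'     the mature-star duplex ("few and small" bulges);
#'   \item no protein-coding evidence: translated hit against
#'     \code{proteinDb} at E < 0.001, identity > 30, similarity > 50,
#'     read coverage > 50, protein coverage > 1 disqualifies.
#' }
#' The mature arm is 5' when the mature (direct) hit precedes the star in
#' the precursor, else 3'.
#'
#' @param precursorSeq precursor sequence.
#' @param structure,mfeValue folded structure (dot-bracket) and its MFE.
#' @param matureStart,matureEnd mature interval, 0-based half-open within
#'   the precursor.
#' @param starStart,starEnd star interval (0-based half-open within the
#'   precursor); pairing outside this window (plus a few nt of slack) is
#'   pairing with flank or loop, not with the passenger strand, and counts
#'   as a mismatch.
#' @param proteinDb protein database for the coding screen (NULL skips).
#' @param mfeiCutoff,maxStarMismatches,maxBulge,maxBulgeCount see above.
#' @return list: \code{pass}, \code{reasons} (character), \code{amfe},
#'   \code{mfei}, \code{gc_pct}, \code{mature_star_mismatches},
#'   \code{n_asym_bulges}, \code{max_asym_bulge}, \code{mature_arm},
#'   \code{protein_coding}.
#' @export
validateCandidate <- function(precursorSeq, structure, mfeValue,
                              matureStart, matureEnd, starStart,
                              starEnd = NA, proteinDb = NULL,
                              mfeiCutoff = 0.85, maxStarMismatches = 4L,
                              maxBulge = 3L, maxBulgeCount = 2L) {
  s <- toupper(as.character(precursorSeq))
  if (nchar(structure) != nchar(s))
    stop("structure and sequence lengths differ (unfolded candidate?)")
  gc <- 100 * lengths(regmatches(s, gregexpr("[GC]", s))) / nchar(s)
  ix <- mfei(mfeValue, nchar(s), max(gc, 1e-9))
  dp <- .duplex_stats(structure, matureStart, matureEnd, starStart, starEnd)
  mseq <- substr(s, max(0, matureStart) + 1, min(nchar(s), matureEnd))
  mm <- dp$unpaired
  if (!is.na(starStart) && !is.na(starEnd)) {
    sseq <- substr(s, max(0, starStart) + 1, min(nchar(s), starEnd))
    if (nchar(sseq) >= 8)
      mm <- .seq_duplex_mismatches(mseq, .revcomp(sseq))
  }
  coding <- FALSE
  if (!is.null(proteinDb) && length(proteinDb)) {
    ht <- filterHits(searchHits(c(prec = s), proteinDb, mode = "translated",
                                maxEvalue = 1e-3, minSeeds = 1L,
                                maxHitsPerQuery = 2L),
                     presetProfile("viral"))
    coding <- length(ht) > 0
  }
  reasons <- character()
  if (!(ix$mfei > mfeiCutoff)) reasons <- c(reasons, "mfei")
  if (mm > maxStarMismatches) reasons <- c(reasons, "star_mismatches")
  if (dp$max_asym > maxBulge || dp$n_asym > maxBulgeCount)
    reasons <- c(reasons, "bulges")
  if (coding) reasons <- c(reasons, "protein_coding")
  list(pass = length(reasons) == 0, reasons = reasons,
       amfe = ix$amfe, mfei = ix$mfei, gc_pct = gc,
       mature_star_mismatches = mm,
       n_asym_bulges = dp$n_asym, max_asym_bulge = dp$max_asym,
       mature_arm = if (matureStart <= starStart) "5'" else "3'",
       protein_coding = coding)
}

#' Run the conserved-miRNA discovery pipeline
#'
#' Orchestrates the four stages: mature-hit search
#' (\code{\link{findMatureHits}}), direct/revcomp pairing
#' (\code{\link{pairHits}}), 13-nt-flank precursor extraction
#' (\code{\link{extractPrecursor}}), folding
#' (\code{\link{foldHairpin}}) and validation
#' (\code{\link{validateCandidate}}).
#'
#' @param sequences named subject sequences (contigs + singletons).
#' @param matureDb named mature miRNA sequences.
#' @param proteinDb protein database for the coding screen (NULL skips).
#' @param mfeiCutoff MFEI cutoff (default 0.85; recalibrate when plugging
#'   in an external folder with a different energy scale).
#' @param flank precursor flank (default 13 nt).
#' @param maxSpan maximum locus span (default 500 nt).
#' @param allowGU allow G:U wobble pairs when folding.
#' @param ... passed to \code{\link{findMatureHits}}.
#' @return a \code{\link{MirnaCandidates}} object.
#' @export
discoverMirnas <- function(sequences, matureDb, proteinDb = NULL,
                           mfeiCutoff = 0.85, flank = 13L, maxSpan = 500L,
                           allowGU = TRUE, ...) {
  seqs <- .as_char_seqs(sequences, "sequences")
  mh <- findMatureHits(seqs, matureDb, ...)
  loci <- pairHits(mh, maxSpan = maxSpan)
  rows <- list(); pseq <- character()
  for (i in seq_len(nrow(loci))) {
    L <- loci[i, ]
    px <- extractPrecursor(seqs[[L$subject_id]], L$five_start, L$three_end,
                           flank = flank)
    fold <- foldHairpin(px$seq, allowGU = allowGU)
    v <- validateCandidate(px$seq, fold$structure, fold$mfe,
                           matureStart = L$d_start - px$start,
                           matureEnd = L$d_end - px$start,
                           starStart = L$r_start - px$start,
                           starEnd = L$r_end - px$start,
                           proteinDb = proteinDb, mfeiCutoff = mfeiCutoff)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("mir_cand_%04d", i), source_id = L$subject_id,
      p_start = px$start, p_end = px$end, clipped = px$clipped,
      length = nchar(px$seq),
      family = L$family, mature_id = L$mature_id,
      mature_start = L$d_start - px$start, mature_end = L$d_end - px$start,
      star_start = L$r_start - px$start, star_end = L$r_end - px$start,
      structure = fold$structure, mfe = fold$mfe,
      amfe = v$amfe, mfei = v$mfei, gc_pct = v$gc_pct,
      mature_star_mismatches = v$mature_star_mismatches,
      n_asym_bulges = v$n_asym_bulges, max_asym_bulge = v$max_asym_bulge,
      mature_arm = v$mature_arm, protein_coding = v$protein_coding,
      pass = v$pass, fail_reasons = paste(v$reasons, collapse = ","),
      known_precursor_similar = NA, contains_repeat = NA,
      stringsAsFactors = FALSE)
    pseq <- c(pseq, px$seq)
  }
  cd <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), source_id = character(),
               p_start = integer(), p_end = integer(), clipped = logical(),
               length = integer(), family = character(),
               mature_id = character(), mature_start = integer(),
               mature_end = integer(), star_start = integer(),
               star_end = integer(), structure = character(),
               mfe = numeric(), amfe = numeric(), mfei = numeric(),
               gc_pct = numeric(), mature_star_mismatches = integer(),
               n_asym_bulges = integer(), max_asym_bulge = integer(),
               mature_arm = character(), protein_coding = logical(),
               pass = logical(), fail_reasons = character(),
               known_precursor_similar = logical(),
               contains_repeat = logical(), stringsAsFactors = FALSE)
  names(pseq) <- cd$id
  logStage("mirna/candidates", nrow(loci), sum(cd$pass))
  new("MirnaCandidates", candidates = cd,
      precursors = Biostrings::DNAStringSet(pseq))
}

#' Annotate passing candidates against known precursors and repeats
#'
#' Flags candidates whose best nucleotide hit against a known-precursor
#' database exceeds 70\% identity (known-precursor similar) and candidates
#' overlapped by any repeat-library hit (contains repeat), and aggregates a
#' per-family report (number of precursors, length range, mature arm(s)).
#'
#' @param x a \code{\link{MirnaCandidates}} object.
#' @param knownPrecursorDb named nucleotide sequences of known precursors
#'   (NULL skips the similarity flag).
#' @param repeatNtDb nucleotide repeat library (NULL skips the repeat flag).
#' @param identityCutoff known-similarity identity bound (default 70,
#'   exclusive).
#' @param minQueryCov minimum fraction of the candidate precursor the
#'   known-precursor alignment must cover, in percent (default 60; a local
#'   alignment over the 21-nt conserved mature alone must not trigger the
#'   whole-precursor similarity flag).
#' @return the annotated \code{\link{MirnaCandidates}}; the family report
#'   is in \code{attr(, "familyReport")}.
#' @export
annotateCandidates <- function(x, knownPrecursorDb = NULL,
                               repeatNtDb = NULL, identityCutoff = 70,
                               minQueryCov = 60) {
  stopifnot(is(x, "MirnaCandidates"))
  cd <- candidates(x)
  if (nrow(cd)) {
    pre <- setNames(as.character(precursors(x)), cd$id)
    cd$known_precursor_similar <- FALSE
    cd$contains_repeat <- FALSE
    if (!is.null(knownPrecursorDb) && length(knownPrecursorDb)) {
      ht <- searchHits(pre, knownPrecursorDb, mode = "nucleotide",
                       maxEvalue = 1e-3, minSeeds = 1L,
                       maxHitsPerQuery = 3L)
      h <- hits(ht)
      h <- h[h$query_cov_pct >= minQueryCov, , drop = FALSE]
      best <- hits(bestHitPerQuery(new("HitTable", hits = h)))
      sim <- best$query_id[best$identity_pct > identityCutoff]
      cd$known_precursor_similar <- cd$id %in% sim
    }
    if (!is.null(repeatNtDb) && length(repeatNtDb)) {
      ht <- searchHits(pre, repeatNtDb, mode = "nucleotide",
                       maxEvalue = 1e-6, minSeeds = 1L,
                       maxHitsPerQuery = 1L)
      cd$contains_repeat <- cd$id %in% hits(ht)$query_id
    }
  }
  pass <- cd[cd$pass, , drop = FALSE]
  rep_rows <- lapply(split(pass, pass$family), function(p) {
    arms <- sort(unique(p$mature_arm), decreasing = TRUE)
    data.frame(family = p$family[1], n_precursors = nrow(p),
               length_range = if (min(p$length) == max(p$length))
                 as.character(min(p$length)) else
                 paste0(min(p$length), "-", max(p$length)),
               mature_position = paste(arms, collapse = " - "),
               stringsAsFactors = FALSE)
  })
  fam <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(family = character(), n_precursors = integer(),
               length_range = character(), mature_position = character(),
               stringsAsFactors = FALSE)
  rownames(fam) <- NULL
  out <- new("MirnaCandidates", candidates = cd, precursors = precursors(x))
  attr(out, "familyReport") <- fam
  out
}
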