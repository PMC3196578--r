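#' @include similarity.R
NULL

# merge 0-based half-open intervals; returns matrix (start, end)
.merge_iv <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out <- NULL
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me) me <- max(me, end[k])
    else { out <- rbind(out, c(ms, me)); ms <- start[k]; me <- end[k] }
  }
  rbind(out, c(ms, me))
}

#' Map unigenes onto assembly contigs
#'
#' High-stringency nucleotide matching of unigenes against contigs:
#' matched windows must reach \code{minIdentity} percent identity (default
#' 97) over at least \code{minLen} bp (default 50).  The high stringency is
#' what keeps homeologous copies from scaffolding together.  The summary
#' tallies unigenes matching one arm, the other, or both (when a
#' contig-to-arm map is supplied), plus per-unigene coverage and contig
#' counts.
#'
#' @param unigenes named unigene sequences.
#' @param contigs named contig sequences.
#' @param minIdentity identity floor in percent (inclusive).
#' @param minLen matched-window length floor in bp (inclusive).
#' @param contigArms optional named vector contig id -> arm label.
#' @param minSeeds seed trigger.
#' @return list: \code{matches} (\code{data.frame}: unigene, contig,
#'   intervals on both, identity, length), \code{summary} (match-fraction
#'   table), \code{perUnigene} (\code{data.frame}: unigene, n_contigs,
#'   coverage_pct).
#' @export
mapUnigenes <- function(unigenes, contigs, minIdentity = 97, minLen = 50,
                        contigArms = NULL, minSeeds = 2L) {
  ug <- .as_char_seqs(unigenes, "unigenes")
  ct <- .as_char_seqs(contigs, "contigs")
  ht <- searchHits(ug, ct, mode = "nucleotide", maxEvalue = 1e-6,
                   minSeeds = minSeeds, maxHitsPerQuery = 0L,
                   maxExtensions = 64L)
  h <- hits(ht)
  h <- h[h$identity_pct >= minIdentity & h$align_len >= minLen, ,
         drop = FALSE]
  matches <- data.frame(unigene_id = h$query_id, contig_id = h$subject_id,
                        u_start = h$q_start, u_end = h$q_end,
                        c_start = h$s_start, c_end = h$s_end,
                        identity_pct = h$identity_pct,
                        align_len = h$align_len,
                        stringsAsFactors = FALSE, row.names = NULL)
  perUnigene <- do.call(rbind, lapply(split(matches, matches$unigene_id),
    function(m) {
      iv <- .merge_iv(m$u_start, m$u_end)
      data.frame(unigene_id = m$unigene_id[1],
                 n_contigs = length(unique(m$contig_id)),
                 coverage_pct = 100 * sum(iv[, 2] - iv[, 1]) /
                   nchar(ug[[m$unigene_id[1]]]),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(perUnigene))
    perUnigene <- data.frame(unigene_id = character(), n_contigs = integer(),
                             coverage_pct = numeric(),
                             stringsAsFactors = FALSE)
  rownames(perUnigene) <- NULL
  n_tot <- length(ug)
  matched <- unique(matches$unigene_id)
  summary <- data.frame(metric = "total_unigenes", n = n_tot,
                        pct = 100, stringsAsFactors = FALSE)
  add <- function(s, metric, n) rbind(s, data.frame(
    metric = metric, n = n, pct = round(100 * n / n_tot, 1),
    stringsAsFactors = FALSE))
  summary <- add(summary, "unigenes_matching", length(matched))
  summary <- add(summary, "one_hit",
                 sum(perUnigene$n_contigs == 1))
  summary <- add(summary, "multi_hit", sum(perUnigene$n_contigs > 1))
  if (!is.null(contigArms)) {
    armsets <- lapply(split(matches$contig_id, matches$unigene_id),
                      function(cc) unique(unname(contigArms[cc])))
    arms <- sort(unique(unlist(armsets)))
    if (length(arms) >= 2) {
      only1 <- sum(vapply(armsets, function(a) identical(a, arms[1]),
                          logical(1)))
      only2 <- sum(vapply(armsets, function(a) identical(a, arms[2]),
                          logical(1)))
      both <- sum(vapply(armsets, function(a) length(a) > 1, logical(1)))
      summary <- add(summary, paste0("only_", arms[1]), only1)
      summary <- add(summary, paste0("only_", arms[2]), only2)
      summary <- add(summary, "both_arms", both)
    }
  }
  logStage("unigene/map", n_tot, length(matched))
  list(matches = matches, summary = summary, perUnigene = perUnigene)
}

#' Flag repetitive and homeolog-redundant unigenes
#'
#' A unigene is flagged repetitive when some region of it is present on
#' more than \code{repeatThreshold} distinct contigs (default 10) at the
#' mapping stringency.  Unigenes matching the identical contig set with
#' different identities are taken as homeolog copies: only the
#' highest-identity unigene is retained, the others are flagged dropped.
#'
#' @param matches match table from \code{\link{mapUnigenes}}.
#' @param repeatThreshold distinct-contig depth above which a region is
#'   repetitive.
#' @return \code{data.frame}: \code{unigene_id}, \code{repetitive},
#'   \code{homeolog_dropped}.
#' @export
flagProblemUnigenes <- function(matches, repeatThreshold = 10L) {
  ids <- unique(matches$unigene_id)
  if (!length(ids))
    return(data.frame(unigene_id = character(), repetitive = logical(),
                      homeolog_dropped = logical(), stringsAsFactors = FALSE))
  repetitive <- vapply(ids, function(u) {
    m <- matches[matches$unigene_id == u, , drop = FALSE]
    # one merged interval set per distinct contig, then sweep for max depth
    ev <- NULL
    for (cc in unique(m$contig_id)) {
      iv <- .merge_iv(m$u_start[m$contig_id == cc], m$u_end[m$contig_id == cc])
      ev <- rbind(ev, cbind(iv[, 1], 1L), cbind(iv[, 2], -1L))
    }
    ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
    max(cumsum(ev[, 2])) > repeatThreshold
  }, logical(1))
  cs <- vapply(ids, function(u) paste(sort(unique(
    matches$contig_id[matches$unigene_id == u])), collapse = ","),
    character(1))
  mid <- vapply(ids, function(u)
    mean(matches$identity_pct[matches$unigene_id == u]), numeric(1))
  dropped <- setNames(rep(FALSE, length(ids)), ids)
  for (set in unique(cs[duplicated(cs)])) {
    grp <- ids[cs == set]
    keep <- grp[which.max(mid[grp])]
    dropped[setdiff(grp, keep)] <- TRUE
  }
  data.frame(unigene_id = ids, repetitive = unname(repetitive),
             homeolog_dropped = unname(dropped),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scaffold contigs along unigenes
#'
#' Unigenes uniquely and univocally matching more than one contig order
#' those contigs by their matched unigene coordinates and join them with a
#' row of exactly 100 Ns (the gap span cannot be inferred, so it is fixed).
#' "Uniquely and univocally" means: the unigene is neither repetitive nor a
#' dropped homeolog copy, every member contig matches only that unigene,
#' and the matched unigene intervals of different contigs do not overlap.
#' A contig claimed by two unigenes is excluded from both and logged.
#'
#' @param matches match table from \code{\link{mapUnigenes}}.
#' @param contigs named contig sequences.
#' @param flags output of \code{\link{flagProblemUnigenes}} (computed here
#'   when NULL).
#' @param gapLen spacer length (fixed 100 by convention).
#' @return list: \code{scaffolds} (\code{data.frame}: scaffold, guiding
#'   unigene, ordered contigs, n_contigs, bases excluding Ns, n_exons),
#'   \code{sequences} (\code{DNAStringSet}), \code{placements} (AGP-style
#'   \code{data.frame}), \code{stats} (scaffold count, mean contigs and
#'   bases per scaffold, mean exons per scaffold), \code{conflicts}
#'   (contigs excluded for being claimed twice).
#' @export
scaffoldContigs <- function(matches, contigs, flags = NULL, gapLen = 100L) {
  ct <- .as_char_seqs(contigs, "contigs")
  if (is.null(flags)) flags <- flagProblemUnigenes(matches)
  bad <- flags$unigene_id[flags$repetitive | flags$homeolog_dropped]
  m <- matches[!matches$unigene_id %in% bad, , drop = FALSE]
  # contigs claimed by more than one unigene leave the analysis entirely
  claims <- unique(m[, c("unigene_id", "contig_id")])
  dup <- unique(claims$contig_id[duplicated(claims$contig_id)])
  if (length(dup))
    logStage("scaffold/conflicting_contigs", length(unique(m$contig_id)),
             length(dup))
  m <- m[!m$contig_id %in% dup, , drop = FALSE]
  scf <- list(); seqs <- character(); placements <- list()
  for (u in unique(m$unigene_id)) {
    mu <- m[m$unigene_id == u, , drop = FALSE]
    cc <- unique(mu$contig_id)
    if (length(cc) < 2) next
    # per contig: span of matched unigene coordinates
    span <- do.call(rbind, lapply(cc, function(x) {
      mm <- mu[mu$contig_id == x, , drop = FALSE]
      data.frame(contig_id = x, u_start = min(mm$u_start),
                 u_end = max(mm$u_end), n_exons = nrow(mm),
                 stringsAsFactors = FALSE)
    }))
    span <- span[order(span$u_start, span$u_end), , drop = FALSE]
    # matched intervals of different contigs must not overlap
    if (any(span$u_start[-1] < span$u_end[-nrow(span)])) next
    sid <- sprintf("scaffold_%s", u)
    joined <- paste(ct[span$contig_id],
                    collapse = strrep("N", gapLen))
    scf[[length(scf) + 1]] <- data.frame(
      scaffold_id = sid, unigene_id = u,
      contig_ids = paste(span$contig_id, collapse = ","),
      n_contigs = nrow(span),
      bases = sum(nchar(ct[span$contig_id])),
      n_exons = sum(span$n_exons),
      stringsAsFactors = FALSE)
    seqs[sid] <- joined
    off <- 0L
    for (k in seq_len(nrow(span))) {
      w <- nchar(ct[[span$contig_id[k]]])
      placements[[length(placements) + 1]] <- data.frame(
        scaffold_id = sid, start = off, end = off + w,
        component = span$contig_id[k], type = "W",
        stringsAsFactors = FALSE)
      off <- off + w
      if (k < nrow(span)) {
        placements[[length(placements) + 1]] <- data.frame(
          scaffold_id = sid, start = off, end = off + gapLen,
          component = "gap", type = "N", stringsAsFactors = FALSE)
        off <- off + gapLen
      }
    }
  }
  scaffolds <- if (length(scf)) do.call(rbind, scf) else
    data.frame(scaffold_id = character(), unigene_id = character(),
               contig_ids = character(), n_contigs = integer(),
               bases = numeric(), n_exons = integer(),
               stringsAsFactors = FALSE)
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(scaffold_id = character(), start = integer(),
               end = integer(), component = character(), type = character(),
               stringsAsFactors = FALSE)
  stats <- list(
    n_scaffolds = nrow(scaffolds),
    n_contigs_in_scaffolds = sum(scaffolds$n_contigs),
    contigs_per_scaffold = if (nrow(scaffolds))
      round(mean(scaffolds$n_contigs), 1) else NA_real_,
    bases_per_scaffold = if (nrow(scaffolds))
      round(mean(scaffolds$bases), 1) else NA_real_,
    exons_per_scaffold = if (nrow(scaffolds))
      round(mean(scaffolds$n_exons), 1) else NA_real_)
  logStage("scaffold/build", length(unique(matches$unigene_id)),
           nrow(scaffolds))
  list(scaffolds = scaffolds, sequences = Biostrings::DNAStringSet(seqs),
       placements = placements, stats = stats, conflicts = dup)
}

#' Write scaffolds as FASTA plus an AGP-style placement table
#'
#' @param x result of \code{\link{scaffoldContigs}}.
#' @param fastaPath scaffold FASTA output (Ns literal).
#' @param agpPath placement TSV output (NULL skips).
#' @return \code{fastaPath}, invisibly.
#' @export
writeScaffolds <- function(x, fastaPath, agpPath = NULL) {
  writeFasta(x$sequences, fastaPath)
  if (!is.null(agpPath))
    write.table(x$placements, agpPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fastaPath)
}
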