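#' @include classify.R
NULL

# ---------------------------------------------------------------------------
# low-level sequence helpers

.BASES <- c("A", "C", "G", "T")

.rand_dna <- function(n, gc = 0.45) {
  if (n <= 0) return("")
  paste(sample(.BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# substitution-only mutation at a given per-base rate
.mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(.BASES, b), 1), character(1))
  paste(ch, collapse = "")
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.rand_protein <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                   collapse = "")

# reverse-translate a protein with uniformly chosen synonymous codons
.rev_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  bycodon <- split(names(gc), unname(gc))
  ch <- strsplit(aa, "")[[1]]
  paste(vapply(ch, function(a) {
    cands <- bycodon[[a]]
    cands[sample.int(length(cands), 1)]
  }, character(1)), collapse = "")
}

# ---------------------------------------------------------------------------
# configuration

#' Create a simulation configuration
#'
#' Defaults encode the survey world the pipeline targets: 5 Mb arms read at
#' 2.3x coverage with 454-style reads (truncated-normal lengths, mean 345,
#' sd 60, min 50), 75\% planted repeat content (a 30-family library with
#' nested insertions and 0-15\% copy divergence, including 3 protein-only
#' "novel" families and ~2\% of the arm in an unknown tandem family absent
#' from every library), ~1\% coding fraction from genes whose coding length
#' distribution is normalised to mean 2,000 bp, 20 planted hairpins
#' embedding known mature miRNAs with a 0-2-mismatch star, 5.3\% cross-arm
#' contamination, ortholog retention 0.85 per related species with 55\%
#' syntenic-chromosome placement, and one inversion planted on the long arm
#' at arm fractions 0.78-1.00.
#'
#' @param seed integer seed; fixed seed makes every run bit-reproducible.
#' @param ... overrides for any default parameter (see
#'   \code{simParams(simulationConfig())} for the full list).
#' @return a \code{\link{SimulationConfig}}.
#' @export
simulationConfig <- function(seed = 1L, ...) {
  p <- list(
    seed = as.integer(seed),
    arm_length = 5e6,
    te_fraction = 0.75,
    n_te_families = 30L,
    n_novel_te_families = 3L,
    unknown_repeat_fraction = 0.02,
    copies_per_block = c(2L, 4L),
    n_genes = 25L,
    cds_len_mean = 2000,
    cds_len_sdlog = 0.35,
    min_exon_len = 250L,
    intron_len_range = c(80L, 400L),
    n_hairpins = 20L,
    n_mirna_families = 16L,
    star_mismatch_max = 2L,
    coverage = 2.3,
    read_len_mean = 345,
    read_len_sd = 60,
    read_len_min = 50,
    subst_rate = 0.003,
    homopolymer_indel_rate = 0.004,
    contamination_rate = 0.053,
    min_overlap = 40L,
    collapse_prob = 0.9,
    retention_B = 0.85,
    retention_C = 0.85,
    p_syntenic = 0.55,
    divergence_refA = 0.05,
    divergence_BC = 0.06,
    inversion_arm = "L",
    inversion_interval = c(0.78, 1.00),
    expressed_fraction = 0.8,
    homeolog_divergence = 0.025,
    est_divergence = 0.03,
    marker_len = 300L,
    bins = list(
      S = data.frame(bin = c("C-S1-0.40", "S1-0.40-0.75", "S3-0.75-0.98"),
                     arm = "S",
                     frac_start = c(0, 0.40, 0.75),
                     frac_end = c(0.40, 0.75, 0.98),
                     stringsAsFactors = FALSE),
      L = data.frame(bin = c("C-L-0.35", "L12-0.35-0.57", "L10-0.57-0.78",
                             "L17-0.78-0.87", "L23-0.87-1.00"),
                     arm = "L",
                     frac_start = c(0, 0.35, 0.57, 0.78, 0.87),
                     frac_end = c(0.35, 0.57, 0.78, 0.87, 1.00),
                     stringsAsFactors = FALSE)))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  new("SimulationConfig", params = p)
}

# ---------------------------------------------------------------------------
# shared libraries (repeat families, proteins, matures)

#' Generate the shared sequence libraries of a simulated survey
#'
#' Builds the TE family library (nucleotide consensus + ORF-derived protein
#' per family; a configured number of families are "novel": present only in
#' the protein library), an unknown tandem repeat absent from both, decoy
#' viral proteins, and the mature miRNA set (families with 1-4 mature
#' variants, mimicking multi-precursor conserved families).
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @return named list of libraries: \code{repeat_nt}, \code{repeat_prot},
#'   \code{viral_prot}, \code{matures}, \code{mature_info},
#'   \code{families} (bookkeeping data.frame), \code{unknown_consensus}.
#' @export
simulateLibrary <- function(config) {
  p <- simParams(config)
  set.seed(p$seed + 101L)
  nf <- p$n_te_families
  sup <- sample(c("RLC", "RLG", "DTC", "DHH"), nf, replace = TRUE,
                prob = c(0.4, 0.35, 0.15, 0.1))
  fam_ids <- sprintf("%s_fam%02d", sup, seq_len(nf))
  novel <- seq_len(nf) > (nf - p$n_novel_te_families)
  lens <- pmin(pmax(round(stats::rlnorm(nf, log(8000), 0.45)), 2500), 16000)
  prot_len <- sample(250:350, nf, replace = TRUE)
  prots <- vapply(prot_len, .rand_protein, character(1))
  cons <- character(nf)
  for (i in seq_len(nf)) {
    orf <- .rev_translate(prots[i])
    left <- max(200L, round((lens[i] - nchar(orf)) * 0.4))
    right <- max(200L, lens[i] - nchar(orf) - left)
    cons[i] <- paste0(.rand_dna(left), orf, .rand_dna(right))
  }
  names(cons) <- fam_ids
  names(prots) <- paste0(fam_ids, "_prot")
  weights <- (1 / seq_len(nf)^0.9)
  weights <- sample(weights)  # abundance decoupled from family index
  unknown <- .rand_dna(1200)
  viral <- setNames(vapply(sample(220:320, 10, replace = TRUE),
                           .rand_protein, character(1)),
                    sprintf("virprot%02d", 1:10))
  # mature miRNA families
  nfam <- p$n_mirna_families
  fam_nums <- 9000L + seq_len(nfam)
  matures <- character(); minfo <- NULL
  for (k in seq_len(nfam)) {
    base <- .rand_dna(21, gc = 0.45)
    nvar <- sample(1:3, 1)
    for (v in seq_len(nvar)) {
      id <- sprintf("syn-miR%d%s", fam_nums[k], letters[v])
      matures[id] <- if (v == 1) base else .mutate_seq(base, 0.06)
      minfo <- rbind(minfo, data.frame(
        mature_id = id, family = sprintf("miR%d", fam_nums[k]),
        stringsAsFactors = FALSE))
    }
  }
  list(
    repeat_nt = cons[!novel],
    repeat_prot = prots,
    viral_prot = viral,
    matures = matures,
    mature_info = minfo,
    families = data.frame(family = fam_ids, length = lens, novel = novel,
                          weight = weights / sum(weights),
                          stringsAsFactors = FALSE),
    consensus_all = cons,
    unknown_consensus = unknown)
}

# ---------------------------------------------------------------------------
# arm construction

# one nested TE block; returns list(seq, truth = data.frame of relative rows)
.te_block <- function(lib, p) {
  k <- sample(seq(p$copies_per_block[1], p$copies_per_block[2]), 1)
  fams <- sample(lib$families$family, k, replace = TRUE,
                 prob = lib$families$weight)
  seq <- ""
  truth <- NULL
  for (f in fams) {
    div <- runif(1, 0, 0.15)
    copy <- .mutate_seq(lib$consensus_all[[f]], div)
    is_novel <- lib$families$novel[lib$families$family == f]
    if (nchar(seq) > 600 && runif(1) < 0.5) {
      # nested insertion into the growing block
      at <- sample(300:(nchar(seq) - 300), 1)
      seq <- paste0(substr(seq, 1, at), copy,
                    substr(seq, at + 1, nchar(seq)))
      if (!is.null(truth)) {
        shift <- nchar(copy)
        grow <- truth$start < at & truth$end > at
        truth$end[truth$end > at] <- truth$end[truth$end > at] + shift
        truth$start[!grow & truth$start >= at] <-
          truth$start[!grow & truth$start >= at] + shift
        truth <- rbind(truth, data.frame(
          start = at, end = at + shift, type = "te", family = f,
          class = if (is_novel) "novel" else "known",
          divergence = div, stringsAsFactors = FALSE))
      }
    } else {
      at <- nchar(seq)
      seq <- paste0(seq, copy)
      truth <- rbind(truth, data.frame(
        start = at, end = at + nchar(copy), type = "te", family = f,
        class = if (is_novel) "novel" else "known",
        divergence = div, stringsAsFactors = FALSE))
    }
  }
  list(seq = seq, truth = truth)
}

# a planted gene: protein-first coding sequence split into exons
.make_gene <- function(gid, cds_len, p) {
  cds_len <- max(3L * ceiling(cds_len / 3), 3L * ceiling(p$min_exon_len / 3))
  prot <- .rand_protein(cds_len / 3)
  cds <- .rev_translate(prot)
  n_ex <- max(1L, min(4L, floor(nchar(cds) / (p$min_exon_len + 50))))
  if (n_ex > 1) {
    repeat {
      cuts <- sort(sample(seq(p$min_exon_len, nchar(cds) - p$min_exon_len),
                          n_ex - 1))
      lens <- diff(c(0, cuts, nchar(cds)))
      if (all(lens >= p$min_exon_len)) break
    }
  } else lens <- nchar(cds)
  offs <- cumsum(c(0, utils::head(lens, -1)))
  exon_seqs <- substring(cds, offs + 1, offs + lens)
  introns <- if (n_ex > 1)
    vapply(seq_len(n_ex - 1), function(i)
      .rand_dna(sample(seq(p$intron_len_range[1], p$intron_len_range[2]), 1)),
      character(1)) else character(0)
  seq <- exon_seqs[1]
  exon_rel <- data.frame(start = 0, end = lens[1])
  for (i in seq_len(n_ex - 1)) {
    seq <- paste0(seq, introns[i])
    st <- nchar(seq)
    seq <- paste0(seq, exon_seqs[i + 1])
    exon_rel <- rbind(exon_rel, data.frame(start = st, end = nchar(seq)))
  }
  list(id = gid, seq = seq, cds = cds, prot = prot, exon_rel = exon_rel)
}

# a planted hairpin embedding a known mature with a detectable star
.make_hairpin <- function(hid, mature_id, mature, p) {
  loop <- .rand_dna(sample(8:30, 1))
  k <- sample(0:p$star_mismatch_max, 1)
  rc <- .revcomp(mature)
  repeat {
    ch <- strsplit(rc, "")[[1]]
    if (k > 0) {
      pos <- sample.int(length(ch), k)
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(.BASES, b), 1), character(1))
    }
    star <- paste(ch, collapse = "")
    # the star must keep a word-size-7 seedable stretch to be findable
    diffs <- which(ch != strsplit(rc, "")[[1]])
    runs <- diff(c(0, diffs, nchar(star) + 1)) - 1
    if (max(runs) >= 7) break
  }
  mature_first <- runif(1) > 0.65   # most matures sit on the 3' arm
  if (mature_first) {
    seq <- paste0(mature, loop, star)
    m0 <- 0; s0 <- nchar(mature) + nchar(loop)
  } else {
    seq <- paste0(star, loop, mature)
    s0 <- 0; m0 <- nchar(star) + nchar(loop)
  }
  list(id = hid, seq = seq, mature_id = mature_id,
       mature_rel = c(m0, m0 + nchar(mature)),
       star_rel = c(s0, s0 + nchar(star)),
       arm5 = mature_first)
}

#' Simulate one chromosome arm with planted truth
#'
#' Lays out the arm as alternating nested-TE blocks and background spacers
#' hosting the planted features (genes with exon/intron structure, hairpin
#' loci, unknown-repeat copies), sized so the realised repeat fraction
#' matches the configured target.  Genes are padded by >= 220 bp of
#' background so TE-boundary reads do not bleed into the coding estimate.
#' All coordinates are recorded as 0-based half-open planted truth.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param arm arm label (\code{"S"} or \code{"L"}).
#' @param lib shared libraries from \code{\link{simulateLibrary}} (built
#'   fresh when NULL).
#' @return a \code{\link{SimulatedArm}}.
#' @export
simulateArm <- function(config, arm = "S", lib = NULL) {
  p <- simParams(config)
  if (is.null(lib)) lib <- simulateLibrary(config)
  set.seed(p$seed + 1000L + match(arm, c("S", "L"), nomatch = 3L))
  L <- p$arm_length
  te_budget <- (p$te_fraction - p$unknown_repeat_fraction) * L
  unk_budget <- p$unknown_repeat_fraction * L
  # pre-draw TE blocks up to the budget
  blocks <- list(); te_bases <- 0
  while (te_bases < te_budget) {
    b <- .te_block(lib, p)
    blocks[[length(blocks) + 1]] <- b
    te_bases <- te_bases + nchar(b$seq)
  }
  # trim the final block so the realised repeat budget is met exactly
  # (truncated terminal copies are a normal feature of TE landscapes)
  over <- te_bases - te_budget
  if (over > 0 && length(blocks)) {
    b <- blocks[[length(blocks)]]
    keep <- nchar(b$seq) - over
    if (keep < 1000) {
      te_bases <- te_bases - nchar(b$seq)
      blocks[[length(blocks)]] <- NULL
    } else {
      b$seq <- substr(b$seq, 1, keep)
      b$truth <- b$truth[b$truth$start < keep, , drop = FALSE]
      b$truth$end <- pmin(b$truth$end, keep)
      blocks[[length(blocks)]] <- b
      te_bases <- te_bases - over
    }
  }
  nb <- length(blocks)
  # features: genes at even fractions, hairpins and unknown copies spread out
  cds_draw <- stats::rlnorm(p$n_genes, log(p$cds_len_mean), p$cds_len_sdlog)
  cds_draw <- round(cds_draw * p$cds_len_mean / mean(cds_draw)) # stated mean
  genes <- lapply(seq_len(p$n_genes), function(i)
    .make_gene(sprintf("%s_g%02d", arm, i), cds_draw[i], p))
  hairpins <- lapply(seq_len(p$n_hairpins), function(i) {
    mid <- lib$mature_info$mature_id[(i - 1) %% nrow(lib$mature_info) + 1]
    .make_hairpin(sprintf("%s_h%02d", arm, i), mid, lib$matures[[mid]], p)
  })
  n_unk <- max(1L, round(unk_budget / nchar(lib$unknown_consensus)))
  unknowns <- lapply(seq_len(n_unk), function(i)
    list(id = sprintf("%s_u%02d", arm, i), type = "unknown_repeat",
         seq = .mutate_seq(lib$unknown_consensus, runif(1, 0, 0.08))))
  feats <- c(
    lapply(seq_along(genes), function(i)
      list(kind = "gene", frac = (i - 0.5) / p$n_genes, obj = genes[[i]])),
    lapply(seq_along(hairpins), function(i)
      list(kind = "hairpin", frac = (i - 0.37) / p$n_hairpins,
           obj = hairpins[[i]])),
    lapply(seq_along(unknowns), function(i)
      list(kind = "unknown", frac = runif(1), obj = unknowns[[i]])))
  feats <- feats[order(vapply(feats, `[[`, numeric(1), "frac"))]
  feat_bases <- sum(vapply(feats, function(f) nchar(f$obj$seq), numeric(1)))
  bg_total <- max(L - te_bases - feat_bases, 0.05 * L)
  wt <- runif(nb + 1, 0.6, 1.4)
  bg_slot <- bg_total * wt / sum(wt)
  slot_of <- pmin(nb + 1, pmax(1, ceiling(vapply(feats, `[[`, numeric(1),
                                                 "frac") * (nb + 1))))
  pad <- 220L
  segs <- character(0)
  truth <- NULL
  pos <- 0
  emit <- function(s) { segs[[length(segs) + 1]] <<- s; pos <<- pos + nchar(s) }
  add_truth <- function(df) truth <<- rbind(truth, df)
  for (slot in seq_len(nb + 1)) {
    idx <- which(slot_of == slot)
    nfeat <- length(idx)
    bg_piece <- max(pad, round(bg_slot[slot] / (nfeat + 1)))
    emit(.rand_dna(bg_piece))
    for (fi in idx) {
      f <- feats[[fi]]
      at <- pos
      emit(f$obj$seq)
      if (f$kind == "gene") {
        add_truth(data.frame(start = at, end = pos, type = "gene",
                             family = NA, class = NA, divergence = NA,
                             feature_id = f$obj$id, stringsAsFactors = FALSE))
        er <- f$obj$exon_rel
        add_truth(data.frame(start = at + er$start, end = at + er$end,
                             type = "exon", family = NA, class = NA,
                             divergence = NA, feature_id = f$obj$id,
                             stringsAsFactors = FALSE))
      } else if (f$kind == "hairpin") {
        add_truth(data.frame(start = at, end = pos, type = "hairpin",
                             family = NA, class = NA, divergence = NA,
                             feature_id = f$obj$id, stringsAsFactors = FALSE))
        add_truth(data.frame(start = at + f$obj$mature_rel[1],
                             end = at + f$obj$mature_rel[2], type = "mature",
                             family = NA, class = NA, divergence = NA,
                             feature_id = f$obj$mature_id,
                             stringsAsFactors = FALSE))
        add_truth(data.frame(start = at + f$obj$star_rel[1],
                             end = at + f$obj$star_rel[2], type = "star",
                             family = NA, class = NA, divergence = NA,
                             feature_id = f$obj$id, stringsAsFactors = FALSE))
      } else {
        add_truth(data.frame(start = at, end = pos, type = "unknown_repeat",
                             family = "unknown", class = "unknown",
                             divergence = NA, feature_id = f$obj$id,
                             stringsAsFactors = FALSE))
      }
      emit(.rand_dna(bg_piece))
    }
    if (slot <= nb) {
      b <- blocks[[slot]]
      bt <- b$truth
      bt$start <- bt$start + pos; bt$end <- bt$end + pos
      bt$feature_id <- sprintf("%s_te%04d_%02d", arm, slot, seq_len(nrow(bt)))
      add_truth(bt)
      emit(b$seq)
    }
  }
  seq <- paste(segs, collapse = "")
  gr <- GenomicRanges::GRanges(
    seqnames = arm,
    ranges = IRanges::IRanges(start = truth$start + 1, end = truth$end),
    type = truth$type, family = truth$family, class = truth$class,
    divergence = truth$divergence, feature_id = truth$feature_id)
  gene_prots <- setNames(vapply(genes, `[[`, character(1), "prot"),
                         sprintf("gprot_%s", vapply(genes, `[[`,
                                                    character(1), "id")))
  gene_cds <- setNames(vapply(genes, `[[`, character(1), "cds"),
                       vapply(genes, `[[`, character(1), "id"))
  lib_arm <- c(lib, list(gene_prot = gene_prots, gene_cds = gene_cds,
                         genes = genes, hairpins = hairpins))
  new("SimulatedArm", arm = arm, seq = Biostrings::DNAString(seq),
      truth = gr, library = lib_arm)
}

# ---------------------------------------------------------------------------
# read shredding

#' Shred 454-style reads from a simulated arm
#'
#' Reads are sampled uniformly with truncated-normal lengths, random strand,
#' substitution and homopolymer-style indel errors, until the configured
#' coverage is reached.  A configured fraction of reads is drawn from the
#' sibling arm (flow-sorting contamination); their true origin is recorded.
#'
#' @param armObj a \code{\link{SimulatedArm}}.
#' @param config a \code{\link{SimulationConfig}}.
#' @param contaminant optional sibling \code{\link{SimulatedArm}} supplying
#'   cross-arm contamination reads.
#' @return list: \code{reads} (named character), \code{origin}
#'   (\code{data.frame}: read_id, arm, start, end, strand, length).
#' @export
shredReads <- function(armObj, config, contaminant = NULL) {
  p <- simParams(config)
  arm <- armObj@arm
  set.seed(p$seed + 2000L + match(arm, c("S", "L"), nomatch = 3L))
  src <- list(as.character(armSeq(armObj)))
  names(src) <- arm
  if (!is.null(contaminant)) src[[contaminant@arm]] <-
    as.character(armSeq(contaminant))
  L <- nchar(src[[arm]])
  target <- p$coverage * L
  n_guess <- ceiling(target / p$read_len_mean * 1.1)
  lens <- round(rnorm(n_guess, p$read_len_mean, p$read_len_sd))
  bad <- lens < p$read_len_min
  while (any(bad)) {
    lens[bad] <- round(rnorm(sum(bad), p$read_len_mean, p$read_len_sd))
    bad <- lens < p$read_len_min
  }
  n <- which(cumsum(lens) >= target)[1]
  if (is.na(n)) n <- n_guess
  lens <- lens[seq_len(n)]
  n_cont <- if (is.null(contaminant)) 0L else round(p$contamination_rate * n)
  src_arm <- rep(arm, n)
  if (n_cont > 0) src_arm[seq(n - n_cont + 1, n)] <- contaminant@arm
  src_len <- vapply(src, nchar, numeric(1))[src_arm]
  lens <- pmin(lens, src_len)
  starts <- floor(runif(n) * (src_len - lens)) # 0-based
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("%s_r%06d", arm, seq_len(n))
  seqs <- character(n)
  for (a in unique(src_arm)) {
    i <- which(src_arm == a)
    seqs[i] <- substring(src[[a]], starts[i] + 1, starts[i] + lens[i])
  }
  minus <- strands == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  # substitution errors
  n_sub <- rbinom(n, lens, p$subst_rate)
  for (i in which(n_sub > 0)) {
    s <- seqs[i]
    for (q in sample.int(nchar(s), n_sub[i])) {
      b <- substr(s, q, q)
      substr(s, q, q) <- sample(setdiff(.BASES, b), 1)
    }
    seqs[i] <- s
  }
  # homopolymer-style single-base indels
  n_ind <- rbinom(n, lens, p$homopolymer_indel_rate)
  for (i in which(n_ind > 0)) {
    s <- seqs[i]
    for (k in seq_len(n_ind[i])) {
      q <- sample.int(nchar(s) - 1, 1)
      if (runif(1) < 0.5) {     # duplicate the base (insertion)
        s <- paste0(substr(s, 1, q), substr(s, q, q),
                    substr(s, q + 1, nchar(s)))
      } else {                  # deletion
        s <- paste0(substr(s, 1, q - 1), substr(s, q + 1, nchar(s)))
      }
    }
    seqs[i] <- s
  }
  names(seqs) <- ids
  origin <- data.frame(read_id = ids, arm = src_arm, start = starts,
                       end = starts + lens, strand = strands,
                       length = nchar(seqs), stringsAsFactors = FALSE)
  logStage(paste0("shred/", arm), L, n)
  list(reads = seqs, origin = origin)
}

# ---------------------------------------------------------------------------
# truth-guided pseudo-assembly

#' Pseudo-assemble shredded reads using the planted truth
#'
#' Truth-guided stand-in for a de novo assembler: reads overlapping by at
#' least \code{min_overlap} bp on their source arm are merged into
#' positional contigs (consensus = the error-free arm subsequence, the
#' idealisation a consensus caller approaches), while reads drawn from
#' distinct copies of the same TE family are, with probability
#' \code{collapse_prob}, collapsed onto a single family contig whose
#' consensus is the family sequence -- reproducing the collapsed
#' high-coverage contigs that the (n*r)/c statistic must detect.  Remaining
#' reads are singletons.
#'
#' @param shred output of \code{\link{shredReads}}.
#' @param armObj the \code{\link{SimulatedArm}} the reads were shredded
#'   from.
#' @param config a \code{\link{SimulationConfig}}.
#' @param contaminant optional sibling arm (for contamination reads).
#' @return list: \code{contigs} (a \code{\link{ContigSet}}),
#'   \code{contigSeqs} (named character), \code{singletons} (read ids),
#'   \code{contigOrigin} (\code{data.frame}: contig, arm, start, end; NA
#'   rows for collapsed family contigs).
#' @export
pseudoAssemble <- function(shred, armObj, config, contaminant = NULL) {
  p <- simParams(config)
  set.seed(p$seed + 3000L + match(armObj@arm, c("S", "L"), nomatch = 3L))
  org <- shred$origin
  reads <- shred$reads
  truths <- list(); seqs <- list(as.character(armSeq(armObj)))
  truths[[armObj@arm]] <- plantedTruth(armObj)
  names(seqs) <- armObj@arm
  if (!is.null(contaminant)) {
    truths[[contaminant@arm]] <- plantedTruth(contaminant)
    seqs[[contaminant@arm]] <- as.character(armSeq(contaminant))
  }
  # family assignment per read: majority overlap with a repeat copy
  fam <- rep(NA_character_, nrow(org))
  for (a in names(truths)) {
    tr <- truths[[a]]
    rep_tr <- tr[S4Vectors::mcols(tr)$type %in% c("te", "unknown_repeat")]
    sel <- which(org$arm == a)
    if (!length(sel) || !length(rep_tr)) next
    ir <- IRanges::IRanges(org$start[sel] + 1, org$end[sel])
    ov <- IRanges::findOverlaps(ir, IRanges::ranges(rep_tr))
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(
      ir[S4Vectors::queryHits(ov)],
      IRanges::ranges(rep_tr)[S4Vectors::subjectHits(ov)]))
    df <- data.frame(q = S4Vectors::queryHits(ov),
                     f = S4Vectors::mcols(rep_tr)$family[
                       S4Vectors::subjectHits(ov)], w = w)
    agg <- stats::aggregate(w ~ q + f, df, sum)
    agg <- agg[order(agg$q, -agg$w), ]
    agg <- agg[!duplicated(agg$q), ]
    frac <- agg$w / (org$end[sel][agg$q] - org$start[sel][agg$q])
    ok <- frac >= 0.5
    fam[sel[agg$q[ok]]] <- agg$f[ok]
  }
  collapse <- !is.na(fam) & runif(nrow(org)) < p$collapse_prob
  fam_members <- split(org$read_id[collapse], fam[collapse])
  fam_members <- fam_members[lengths(fam_members) >= 2]
  # positional merge of remaining reads, overlap >= min_overlap
  rest <- org[!org$read_id %in% unlist(fam_members), , drop = FALSE]
  members <- list(); contig_rows <- list(); origin_rows <- list()
  singletons <- character()
  half <- floor(p$min_overlap / 2)
  for (a in unique(rest$arm)) {
    ra <- rest[rest$arm == a, , drop = FALSE]
    ir <- IRanges::IRanges(ra$start + 1, ra$end)
    narrowed <- IRanges::IRanges(ra$start + 1 + half,
                                 pmax(ra$start + 1 + half, ra$end - half))
    red <- IRanges::reduce(narrowed)
    ov <- IRanges::findOverlaps(narrowed, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (g in unique(grp)) {
      sel <- which(grp == g)
      if (length(sel) < 2) {
        singletons <- c(singletons, ra$read_id[sel])
        next
      }
      span0 <- min(ra$start[sel]); span1 <- max(ra$end[sel])
      cid <- sprintf("ctg_%s_%05d", a, length(contig_rows) + 1)
      members[[cid]] <- ra$read_id[sel]
      contig_rows[[cid]] <- data.frame(
        contig_id = cid, consensus_len = span1 - span0,
        stringsAsFactors = FALSE)
      origin_rows[[cid]] <- data.frame(contig_id = cid, arm = a,
                                       start = span0, end = span1,
                                       stringsAsFactors = FALSE)
    }
  }
  contigSeqs <- character()
  for (cid in names(contig_rows)) {
    o <- origin_rows[[cid]]
    contigSeqs[cid] <- substring(seqs[[o$arm]], o$start + 1, o$end)
  }
  # collapsed family contigs
  fam_seq_of <- c(setNames(as.list(armObj@library$consensus_all),
                           names(armObj@library$consensus_all)),
                  list(unknown = armObj@library$unknown_consensus))
  for (f in names(fam_members)) {
    cid <- sprintf("ctg_fam_%s", f)
    cs <- fam_seq_of[[f]]
    members[[cid]] <- fam_members[[f]]
    contig_rows[[cid]] <- data.frame(contig_id = cid,
                                     consensus_len = nchar(cs),
                                     stringsAsFactors = FALSE)
    origin_rows[[cid]] <- data.frame(contig_id = cid, arm = NA_character_,
                                     start = NA_real_, end = NA_real_,
                                     stringsAsFactors = FALSE)
    contigSeqs[cid] <- cs
  }
  mdf <- data.frame(
    contig_id = rep(names(members), lengths(members)),
    read_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
  clen <- vapply(contig_rows, `[[`, numeric(1), "consensus_len")
  names(clen) <- names(contig_rows)
  rl <- setNames(org$length, org$read_id)
  cs <- contigSet(mdf, clen, rl)
  logStage(paste0("assemble/", armObj@arm), nrow(org), nrow(contigInfo(cs)))
  co <- if (length(origin_rows)) do.call(rbind, origin_rows) else
    data.frame(contig_id = character(), arm = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  rownames(co) <- NULL
  list(contigs = cs, contigSeqs = contigSeqs, singletons = singletons,
       contigOrigin = co)
}

# ---------------------------------------------------------------------------
# reference trio

#' Simulate a related-species reference trio for one arm
#'
#' Species A (the ordered reference) carries one ortholog per planted wheat
#' gene at the configured divergence, ordered like the wheat arm except for
#' the planted inversion interval (when this arm is configured to carry
#' one).  Species B and C retain each A gene with the configured retention
#' rates at higher divergence, and are placed on a syntenic chromosome with
#' probability \code{p_syntenic}, otherwise on a decoy chromosome.
#'
#' @param armObj a \code{\link{SimulatedArm}}.
#' @param config a \code{\link{SimulationConfig}}.
#' @return list: \code{genesA}, \code{genesB}, \code{genesC} (each
#'   \code{list(info, seq)}), \code{syntenicChromsB},
#'   \code{syntenicChromsC}, \code{proteomes} (named list A/B/C),
#'   \code{ortholog_truth} (\code{data.frame} incl. wheat rank and A rank),
#'   \code{inversion} (fractional interval or NULL).
#' @export
simulateReferenceTrio <- function(armObj, config) {
  p <- simParams(config)
  arm <- armObj@arm
  set.seed(p$seed + 4000L + match(arm, c("S", "L"), nomatch = 3L))
  tr <- plantedTruth(armObj)
  genes <- tr[S4Vectors::mcols(tr)$type == "gene"]
  genes <- genes[order(GenomicRanges::start(genes))]
  gids <- S4Vectors::mcols(genes)$feature_id
  cds <- armObj@library$gene_cds[gids]
  L <- length(armSeq(armObj))
  frac <- (GenomicRanges::start(genes) + GenomicRanges::end(genes)) / 2 / L
  n <- length(gids)
  # species A order: wheat order with the planted inversion (if on this arm)
  a_order <- seq_len(n)
  inv <- NULL
  if (identical(arm, p$inversion_arm) && !is.null(p$inversion_interval)) {
    inside <- which(frac >= p$inversion_interval[1] &
                      frac < p$inversion_interval[2])
    if (length(inside) >= 2) {
      a_order[inside] <- rev(a_order[inside])
      inv <- p$inversion_interval
    }
  }
  a_rank <- a_order                  # wheat index -> A-chromosome rank
  chromA <- paste0("A4", arm)
  idsA <- sprintf("A_%s", gids)
  seqA <- setNames(vapply(cds, .mutate_seq, character(1),
                          rate = p$divergence_refA), idsA)
  posA <- a_rank * 30000 + round(runif(n, 0, 4000))
  infoA <- data.frame(gene_id = idsA, chrom = chromA, pos = posA,
                      stringsAsFactors = FALSE)
  synB <- paste0("O", if (arm == "S") "12" else "9")
  synC <- paste0("Sb", if (arm == "S") "8" else "1")
  decoyB <- paste0("O", 1:5); decoyC <- paste0("Sb", 3:7)
  mk_species <- function(prefix, retention, syn, decoy) {
    keep <- runif(n) < retention
    ids <- sprintf("%s_%s", prefix, gids[keep])
    seqs <- setNames(vapply(seqA[keep], .mutate_seq, character(1),
                            rate = p$divergence_BC), ids)
    on_syn <- runif(sum(keep)) < p$p_syntenic
    chrom <- ifelse(on_syn, syn, sample(decoy, sum(keep), replace = TRUE))
    info <- data.frame(gene_id = ids, chrom = chrom,
                       pos = round(runif(sum(keep), 1e5, 3e7)),
                       stringsAsFactors = FALSE)
    list(info = info, seq = seqs, keep = keep)
  }
  B <- mk_species("B", p$retention_B, synB, decoyB)
  C <- mk_species("C", p$retention_C, synC, decoyC)
  translate1 <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x), if.fuzzy.codon = "solve"))
  suffix_p <- function(x) if (length(x)) paste0(names(x), "_p") else
    character(0)
  proteomes <- list(
    A = setNames(translate1(seqA), suffix_p(seqA)),
    B = setNames(translate1(B$seq), suffix_p(B$seq)),
    C = setNames(translate1(C$seq), suffix_p(C$seq)))
  truth <- data.frame(
    wheat_gene = gids, wheat_rank = seq_len(n), frac = frac,
    geneA = idsA, a_rank = a_rank,
    geneB = ifelse(B$keep, sprintf("B_%s", gids), NA),
    geneC = ifelse(C$keep, sprintf("C_%s", gids), NA),
    stringsAsFactors = FALSE)
  list(genesA = list(info = infoA, seq = seqA),
       genesB = list(info = B$info, seq = B$seq),
       genesC = list(info = C$info, seq = C$seq),
       syntenicChromsB = synB, syntenicChromsC = synC,
       proteomes = proteomes, ortholog_truth = truth, inversion = inv)
}

# ---------------------------------------------------------------------------
# unigenes and markers

#' Simulate unigenes and bin-mapped EST markers for one arm
#'
#' Unigenes are the spliced transcripts of a configured subset of planted
#' genes, plus homeolog variants at ~2-3\% divergence (distinguishable at a
#' 97\% identity floor) for a third of them.  Markers are exon fragments of
#' every planted gene, assigned to deletion bins by the gene's fractional
#' arm position.
#'
#' @param armObj a \code{\link{SimulatedArm}}.
#' @param config a \code{\link{SimulationConfig}}.
#' @return list: \code{unigenes} (named character), \code{unigene_truth}
#'   (\code{data.frame}: unigene -> gene, homeolog flag), \code{markers}
#'   (named character), \code{binmap} (a \code{\link{BinMap}}),
#'   \code{marker_truth}.
#' @export
simulateUnigenesAndMarkers <- function(armObj, config) {
  p <- simParams(config)
  arm <- armObj@arm
  set.seed(p$seed + 5000L + match(arm, c("S", "L"), nomatch = 3L))
  tr <- plantedTruth(armObj)
  genes <- tr[S4Vectors::mcols(tr)$type == "gene"]
  genes <- genes[order(GenomicRanges::start(genes))]
  gids <- S4Vectors::mcols(genes)$feature_id
  cds <- armObj@library$gene_cds[gids]
  L <- length(armSeq(armObj))
  frac <- (GenomicRanges::start(genes) + GenomicRanges::end(genes)) / 2 / L
  n_expr <- max(2L, round(p$expressed_fraction * length(gids)))
  expr <- sort(sample(seq_along(gids), n_expr))
  ug <- setNames(unname(cds[expr]), sprintf("ug_%s", gids[expr]))
  ug_truth <- data.frame(unigene_id = names(ug), gene_id = gids[expr],
                         homeolog = FALSE, stringsAsFactors = FALSE)
  hom_idx <- expr[seq_len(max(0L, floor(n_expr / 3)))]
  if (length(hom_idx)) {
    hom <- setNames(vapply(cds[hom_idx], .mutate_seq, character(1),
                           rate = p$homeolog_divergence),
                    sprintf("ug_hom_%s", gids[hom_idx]))
    ug <- c(ug, hom)
    ug_truth <- rbind(ug_truth, data.frame(
      unigene_id = names(hom), gene_id = gids[hom_idx], homeolog = TRUE,
      stringsAsFactors = FALSE))
  }
  # markers: one exon fragment per gene, binned by fractional position
  bins_arm <- p$bins[[arm]]
  bm0 <- binMap(bins_arm)
  marker_rows <- NULL; markers <- character()
  for (i in seq_along(gids)) {
    b <- bins_arm$bin[bins_arm$frac_start <= frac[i] &
                        frac[i] < bins_arm$frac_end]
    if (!length(b)) next
    s <- cds[[i]]
    mlen <- min(p$marker_len, nchar(s))
    at <- sample.int(nchar(s) - mlen + 1, 1)
    mid <- sprintf("est_%s", gids[i])
    markers[mid] <- substr(s, at, at + mlen - 1)
    marker_rows <- rbind(marker_rows, data.frame(
      marker_id = mid, bin = b[1], gene_id = gids[i], frac = frac[i],
      stringsAsFactors = FALSE))
  }
  bm <- binMap(bins_arm, marker_rows[, c("marker_id", "bin")])
  list(unigenes = ug, unigene_truth = ug_truth, markers = markers,
       binmap = bm, marker_truth = marker_rows)
}

# ---------------------------------------------------------------------------
# full survey bundle

#' Simulate a complete two-arm chromosome survey
#'
#' Orchestrates the whole generator: shared libraries, both arms, shredded
#' reads with cross-arm contamination, truth-guided pseudo-assemblies,
#' per-arm reference trios, and unigenes/markers/bin maps.  With a fixed
#' seed the bundle is bit-reproducible.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @return named list: \code{config}, \code{lib}, and per-arm entries
#'   \code{arms}, \code{reads}, \code{assemblies}, \code{trios},
#'   \code{annotation} (unigenes/markers), keyed \code{"S"} and \code{"L"}.
#' @export
simulateSurvey <- function(config = simulationConfig()) {
  lib <- simulateLibrary(config)
  arms <- list(S = simulateArm(config, "S", lib),
               L = simulateArm(config, "L", lib))
  reads <- list(S = shredReads(arms$S, config, contaminant = arms$L),
                L = shredReads(arms$L, config, contaminant = arms$S))
  assemblies <- list(
    S = pseudoAssemble(reads$S, arms$S, config, contaminant = arms$L),
    L = pseudoAssemble(reads$L, arms$L, config, contaminant = arms$S))
  trios <- list(S = simulateReferenceTrio(arms$S, config),
                L = simulateReferenceTrio(arms$L, config))
  annotation <- list(S = simulateUnigenesAndMarkers(arms$S, config),
                     L = simulateUnigenesAndMarkers(arms$L, config))
  list(config = config, lib = lib, arms = arms, reads = reads,
       assemblies = assemblies, trios = trios, annotation = annotation)
}
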