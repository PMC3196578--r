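#' @include chromSurvey-package.R
NULL

# ---------------------------------------------------------------------------
# ThresholdProfile

#' Similarity-search threshold profile
#'
#' Bundle of hit-filtering bounds used throughout the pipeline: maximum
#' E-value, minimum percent identity and similarity (percent positive-scoring
#' columns, translated mode), minimum query ("read") and subject ("database
#' entry") coverage, and an optional cap on mismatches.  Subject coverage is
#' computed against the full length of the matched database entry, per
#' subject, which is the only reading consistent with a >= 1\% bound.
#'
#' @slot maxEvalue maximum E-value (inclusive).
#' @slot minIdentity minimum percent identity (inclusive).
#' @slot minSimilarity minimum percent similarity (inclusive; equals identity
#'   for nucleotide hits).
#' @slot minQueryCov minimum percent of the query covered by the alignment.
#' @slot minSubjectCov minimum percent of the subject covered.
#' @slot maxMismatches maximum number of aligned mismatching columns
#'   (\code{Inf} to disable).
#' @slot mode \code{"nucleotide"} or \code{"translated"}.
#' @exportClass ThresholdProfile
setClass("ThresholdProfile",
  representation(maxEvalue = "numeric", minIdentity = "numeric",
                 minSimilarity = "numeric", minQueryCov = "numeric",
                 minSubjectCov = "numeric", maxMismatches = "numeric",
                 mode = "character"),
  prototype(maxEvalue = 10, minIdentity = 0, minSimilarity = 0,
            minQueryCov = 0, minSubjectCov = 0, maxMismatches = Inf,
            mode = "nucleotide"))

setValidity("ThresholdProfile", function(object) {
  msg <- character()
  if (object@maxEvalue < 0) msg <- c(msg, "maxEvalue must be >= 0")
  for (s in c("minIdentity", "minSimilarity", "minQueryCov", "minSubjectCov")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 100)
      msg <- c(msg, paste(s, "must be a single value in [0, 100]"))
  }
  if (!object@mode %in% c("nucleotide", "translated"))
    msg <- c(msg, "mode must be 'nucleotide' or 'translated'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# HitTable

.HIT_COLS <- c("query_id", "subject_id", "identity_pct", "similarity_pct",
               "align_len", "mismatches", "gap_opens", "q_start", "q_end",
               "s_start", "s_end", "strand", "frame", "evalue", "bitscore",
               "score", "query_cov_pct", "subject_cov_pct", "q_len", "s_len")

#' Table of local-similarity hits
#'
#' Container for local alignment hits in the style of a 12-column tabular
#' search report, extended with similarity, coverage and frame columns.
#' In-memory coordinates are 0-based half-open on the plus strand of both
#' sequences, with a \code{strand} column; serialisation
#' (\code{\link{writeHitsTable}}) emits 1-based closed coordinates with
#' reversed subject coordinates for minus-strand hits.
#'
#' @slot hits \code{data.frame} with one row per hit.
#' @exportClass HitTable
setClass("HitTable", representation(hits = "data.frame"))

setValidity("HitTable", function(object) {
  h <- object@hits
  missing <- setdiff(.HIT_COLS, names(h))
  if (length(missing))
    return(paste("missing hit columns:", paste(missing, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$evalue < 0)) return("evalue must be >= 0")
    if (any(h$q_start < 0 | h$q_end > h$q_len | h$q_start >= h$q_end))
      return("query intervals out of bounds")
    if (any(h$s_start < 0 | h$s_end > h$s_len | h$s_start >= h$s_end))
      return("subject intervals out of bounds")
    if (any(h$identity_pct > h$similarity_pct + 1e-9))
      return("identity_pct must not exceed similarity_pct")
    if (!all(h$strand %in% c("+", "-"))) return("strand must be + or -")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# ContigSet

#' Contig membership ledger of a read assembly
#'
#' Records, for every contig, which reads participate in it, together with
#' the consensus length, read count and mean member read length needed for
#' the (n*r)/c contig-coverage statistic.
#'
#' @slot contigs \code{data.frame} with columns \code{contig_id},
#'   \code{consensus_len}, \code{n_reads}, \code{avg_read_len}.
#' @slot members \code{data.frame} with columns \code{contig_id},
#'   \code{read_id}.
#' @exportClass ContigSet
setClass("ContigSet",
  representation(contigs = "data.frame", members = "data.frame"))

setValidity("ContigSet", function(object) {
  ci <- object@contigs; mb <- object@members
  if (!all(c("contig_id", "consensus_len", "n_reads", "avg_read_len") %in%
           names(ci)))
    return("contigs needs contig_id, consensus_len, n_reads, avg_read_len")
  if (!all(c("contig_id", "read_id") %in% names(mb)))
    return("members needs contig_id, read_id")
  if (nrow(ci)) {
    if (any(ci$consensus_len <= 0)) return("consensus_len must be > 0")
    if (any(ci$n_reads < 1)) return("each contig needs >= 1 member read")
    tab <- table(mb$contig_id)
    if (!all(ci$n_reads == as.integer(tab[ci$contig_id])))
      return("n_reads inconsistent with membership table")
  }
  if (anyDuplicated(mb$read_id))
    return("a read may participate in only one contig")
  TRUE
})

# ---------------------------------------------------------------------------
# ClassificationSummary

.CLASS_LEVELS <- c("KNOWN_TE", "NOVEL_TE", "REPEAT", "GENE", "VIRAL", "OTHER")

#' Per-class read classification ledger
#'
#' Read counts and percentages per classification label for one chromosome
#' arm, with a combined repeats row (known TE + novel TE + uncharacterised
#' repeats) as reported in survey-sequencing repeat ledgers.
#'
#' @slot arm arm label.
#' @slot counts named integer vector over the six class labels.
#' @slot total total number of reads.
#' @slot table formatted \code{data.frame} (class, reads, pct).
#' @exportClass ClassificationSummary
setClass("ClassificationSummary",
  representation(arm = "character", counts = "numeric", total = "numeric",
                 table = "data.frame"))

setValidity("ClassificationSummary", function(object) {
  if (!identical(sort(names(object@counts)), sort(.CLASS_LEVELS)))
    return("counts must be named by the six class labels")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!isTRUE(all.equal(sum(object@counts), object@total)))
    return("counts must sum to the total (partition conservation)")
  TRUE
})

# ---------------------------------------------------------------------------
# BinMap

#' Deletion-bin physical map
#'
#' Ordered deletion bins of a chromosome arm expressed as fractional arm
#' intervals, with optional marker-to-bin assignments.  Overlapping bins are
#' kept and flagged; they are excluded from collinearity statistics but
#' their marker counts can be summed for display.
#'
#' @slot bins \code{data.frame}: \code{bin}, \code{arm}, \code{frac_start},
#'   \code{frac_end}, \code{overlaps} (logical).
#' @slot markers \code{data.frame}: \code{marker_id}, \code{bin}.
#' @exportClass BinMap
setClass("BinMap",
  representation(bins = "data.frame", markers = "data.frame"),
  prototype(markers = data.frame(marker_id = character(),
                                 bin = character())))

setValidity("BinMap", function(object) {
  b <- object@bins
  if (!all(c("bin", "arm", "frac_start", "frac_end") %in% names(b)))
    return("bins needs bin, arm, frac_start, frac_end")
  if (nrow(b)) {
    if (any(b$frac_start < 0 | b$frac_end > 1))
      return("bin fractions must lie in [0, 1]")
    if (any(b$frac_start >= b$frac_end))
      return("bin frac_start must be < frac_end")
    if (anyDuplicated(b$bin)) return("bin names must be unique")
  }
  m <- object@markers
  if (nrow(m) && !all(m$bin %in% b$bin))
    return("markers assigned to unknown bins")
  if (anyDuplicated(object@markers$marker_id))
    return("each marker is assigned to exactly one bin")
  TRUE
})

# ---------------------------------------------------------------------------
# GenomeZipper

#' Genome zipper virtual gene order
#'
#' Ordered reference ("species A") genes restricted to configured syntenic
#' intervals, each carrying an OxSx(hyz) reliability code: O/S record whether
#' the best homolog in each related species lies on a configured syntenic
#' chromosome, and h/y/z record reciprocal-best-hit orthology for the A-B,
#' A-C and B-C pairs.  Survey reads and EST markers can be anchored onto
#' entries by nucleotide similarity.
#'
#' @slot entries \code{data.frame}: \code{rank}, \code{gene_id},
#'   \code{chrom}, \code{pos}, \code{code}, bit columns \code{O}, \code{S},
#'   \code{h}, \code{y}, \code{z}.
#' @slot readAnchors \code{data.frame}: \code{read_id}, \code{rank},
#'   \code{ambiguous}.
#' @slot markerAnchors \code{data.frame}: \code{marker_id}, \code{rank},
#'   \code{bin}.
#' @exportClass GenomeZipper
setClass("GenomeZipper",
  representation(entries = "data.frame", readAnchors = "data.frame",
                 markerAnchors = "data.frame"),
  prototype(readAnchors = data.frame(read_id = character(), rank = integer(),
                                     ambiguous = logical()),
            markerAnchors = data.frame(marker_id = character(),
                                       rank = integer(), bin = character())))

setValidity("GenomeZipper", function(object) {
  e <- object@entries
  need <- c("rank", "gene_id", "chrom", "pos", "code", "O", "S", "h", "y", "z")
  if (!all(need %in% names(e)))
    return(paste("entries needs columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(grepl("^O[01]S[01]\\([01]{3}\\)$", e$code)))
      return("codes must match O[01]S[01]([01]{3})")
    if (any(diff(e$rank) <= 0)) return("ranks must be strictly increasing")
    if (is.unsorted(e$pos)) return("entries must be ordered by position")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# MirnaCandidates

#' Candidate miRNA precursor set
#'
#' Candidate hairpin precursors recovered by mature-miRNA homology: the
#' extracted precursor sequences plus, per candidate, the mature/star hit
#' geometry, predicted secondary structure, MFE, AMFE (MFE per 100 nt),
#' MFEI (AMFE / GC\%), validation verdict and annotation flags.
#'
#' @slot candidates \code{data.frame}, one row per candidate locus.
#' @slot precursors \code{DNAStringSet} of extracted precursor sequences,
#'   parallel to \code{candidates}.
#' @exportClass MirnaCandidates
setClass("MirnaCandidates",
  representation(candidates = "data.frame", precursors = "DNAStringSet"))

setValidity("MirnaCandidates", function(object) {
  cd <- object@candidates
  if (nrow(cd) != length(object@precursors))
    return("candidates and precursors must be parallel")
  if (nrow(cd) && "mfe" %in% names(cd) && any(cd$mfe > 0, na.rm = TRUE))
    return("mfe must be <= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# SimulationConfig and simulation products (list-backed)

#' Synthetic survey simulation configuration
#'
#' Validated parameter bundle for the synthetic-data generator.  Defaults
#' encode the survey conditions the pipeline targets: ~2.3x read coverage,
#' mean read length 345 bp, 75\% planted repeat content, ~1\% coding
#' fraction with mean coding length 2,000 bp, and 5.3\% cross-arm
#' contamination.  See \code{\link{simulationConfig}}.
#'
#' @slot params named list of generator parameters.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(params = "list"))

setValidity("SimulationConfig", function(object) {
  p <- object@params
  msg <- character()
  frac01 <- c("te_fraction", "contamination_rate", "subst_rate",
              "homopolymer_indel_rate", "collapse_prob", "p_syntenic",
              "retention_B", "retention_C", "expressed_fraction")
  for (f in frac01) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1)
      msg <- c(msg, paste(f, "must lie in [0, 1]"))
  }
  if (!is.numeric(p$coverage) || p$coverage <= 0)
    msg <- c(msg, "coverage must be > 0")
  if (!is.numeric(p$arm_length) || any(p$arm_length < 1e4))
    msg <- c(msg, "arm_length must be >= 10 kb")
  if (!is.numeric(p$seed) || length(p$seed) != 1)
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Simulated chromosome arm with planted truth
#'
#' One synthetic chromosome arm: its sequence plus the planted-truth
#' annotation (TE copies with family labels, genes with exon structure,
#' hairpin loci with mature/star coordinates, unknown-repeat copies) as a
#' \code{GRanges}, and the generated sequence libraries shared across arms.
#'
#' @slot arm arm label, e.g. \code{"S"} or \code{"L"}.
#' @slot seq \code{DNAString} arm sequence.
#' @slot truth \code{GRanges} of planted features (metadata columns
#'   \code{type}, \code{family}, \code{feature_id}, ...).
#' @slot library named list of generated libraries (repeat consensus
#'   sequences, proteins, matures, ...).
#' @exportClass SimulatedArm
setClass("SimulatedArm",
  representation(arm = "character", seq = "DNAString", truth = "GRanges",
                 library = "list"))

setValidity("SimulatedArm", function(object) {
  if (length(object@truth)) {
    if (any(end(object@truth) > length(object@seq)))
      return("truth intervals must lie within the arm sequence")
    if (!"type" %in% names(S4Vectors::mcols(object@truth)))
      return("truth needs a 'type' metadata column")
  }
  TRUE
})
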