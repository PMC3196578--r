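#' @include AllClasses.R
NULL

#' Extract the hit data.frame from a HitTable
#'
#' @param x a \code{\link{HitTable}}.
#' @return \code{data.frame} of hits (0-based half-open coordinates).
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname hits
#' @export
setMethod("hits", "HitTable", function(x) x@hits)

#' Number of hits in a HitTable
#' @param x a \code{\link{HitTable}}.
#' @export
setMethod("length", "HitTable", function(x) nrow(x@hits))

setMethod("show", "HitTable", function(object) {
  h <- object@hits
  cat("HitTable with", nrow(h), "hits over", length(unique(h$query_id)),
      "queries\n")
  if (nrow(h)) {
    cat("  E-value range:", format(range(h$evalue), digits = 3), "\n")
    print(utils::head(h[, c("query_id", "subject_id", "identity_pct", "evalue",
                     "bitscore", "strand")], 5))
    if (nrow(h) > 5) cat("  ...\n")
  }
})

setMethod("show", "ThresholdProfile", function(object) {
  cat("ThresholdProfile (", object@mode, " mode)\n", sep = "")
  cat("  E <= ", object@maxEvalue, ", identity >= ", object@minIdentity,
      "%, similarity >= ", object@minSimilarity, "%\n", sep = "")
  cat("  query cov >= ", object@minQueryCov, "%, subject cov >= ",
      object@minSubjectCov, "%", sep = "")
  if (is.finite(object@maxMismatches))
    cat(", mismatches <= ", object@maxMismatches, sep = "")
  cat("\n")
})

#' Contig-level statistics of a ContigSet
#'
#' @param x a \code{\link{ContigSet}}.
#' @return \code{data.frame} with one row per contig.
#' @export
setGeneric("contigInfo", function(x) standardGeneric("contigInfo"))

#' @rdname contigInfo
#' @export
setMethod("contigInfo", "ContigSet", function(x) x@contigs)

#' Read membership table of a ContigSet
#'
#' @param x a \code{\link{ContigSet}}.
#' @return \code{data.frame} with columns \code{contig_id}, \code{read_id}.
#' @export
setGeneric("memberReads", function(x) standardGeneric("memberReads"))

#' @rdname memberReads
#' @export
setMethod("memberReads", "ContigSet", function(x) x@members)

setMethod("show", "ContigSet", function(object) {
  cat("ContigSet:", nrow(object@contigs), "contigs,",
      nrow(object@members), "member reads\n")
})

#' Formatted ledger table of a ClassificationSummary
#'
#' @param x a \code{\link{ClassificationSummary}}.
#' @return \code{data.frame} with class, reads and pct columns, including
#'   the combined repeats row.
#' @export
setGeneric("classTable", function(x) standardGeneric("classTable"))

#' @rdname classTable
#' @export
setMethod("classTable", "ClassificationSummary", function(x) x@table)

setMethod("show", "ClassificationSummary", function(object) {
  cat("ClassificationSummary for arm", object@arm, "(", object@total,
      "reads )\n")
  print(object@table, row.names = FALSE)
})

#' Bin table of a BinMap
#'
#' @param x a \code{\link{BinMap}}.
#' @return \code{data.frame} of ordered bins.
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname bins
#' @export
setMethod("bins", "BinMap", function(x) x@bins)

#' Marker-to-bin assignments of a BinMap
#'
#' @param x a \code{\link{BinMap}}.
#' @return \code{data.frame} with columns \code{marker_id}, \code{bin}.
#' @export
setGeneric("binMarkers", function(x) standardGeneric("binMarkers"))

#' @rdname binMarkers
#' @export
setMethod("binMarkers", "BinMap", function(x) x@markers)

setMethod("show", "BinMap", function(object) {
  cat("BinMap:", nrow(object@bins), "bins,", nrow(object@markers),
      "assigned markers\n")
  if (nrow(object@bins)) print(object@bins, row.names = FALSE)
})

#' Entry table of a GenomeZipper
#'
#' @param x a \code{\link{GenomeZipper}}.
#' @return \code{data.frame} of ordered zipper entries with OxSx(hyz) codes.
#' @export
setGeneric("zipperEntries", function(x) standardGeneric("zipperEntries"))

#' @rdname zipperEntries
#' @export
setMethod("zipperEntries", "GenomeZipper", function(x) x@entries)

#' Read anchors of a GenomeZipper
#'
#' @param x a \code{\link{GenomeZipper}}.
#' @return \code{data.frame} with columns \code{read_id}, \code{rank},
#'   \code{ambiguous}.
#' @export
setGeneric("readAnchors", function(x) standardGeneric("readAnchors"))

#' @rdname readAnchors
#' @export
setMethod("readAnchors", "GenomeZipper", function(x) x@readAnchors)

#' Marker anchors of a GenomeZipper
#'
#' @param x a \code{\link{GenomeZipper}}.
#' @return \code{data.frame} with columns \code{marker_id}, \code{rank},
#'   \code{bin}.
#' @export
setGeneric("markerAnchors", function(x) standardGeneric("markerAnchors"))

#' @rdname markerAnchors
#' @export
setMethod("markerAnchors", "GenomeZipper", function(x) x@markerAnchors)

setMethod("show", "GenomeZipper", function(object) {
  e <- object@entries
  cat("GenomeZipper with", nrow(e), "entries")
  if (nrow(e)) {
    syn <- mean(e$O == 1 | e$S == 1) * 100
    orth <- mean(e$h == 1 | e$y == 1) * 100
    cat(sprintf(" (%.0f%% on syntenic chromosomes, %.0f%% RBH-supported)",
                syn, orth))
  }
  cat("\n  anchored reads:", nrow(object@readAnchors),
      " anchored markers:", nrow(object@markerAnchors), "\n")
})

#' Candidate table of a MirnaCandidates object
#'
#' @param x a \code{\link{MirnaCandidates}}.
#' @return \code{data.frame}, one row per candidate precursor locus.
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname candidates
#' @export
setMethod("candidates", "MirnaCandidates", function(x) x@candidates)

#' Precursor sequences of a MirnaCandidates object
#'
#' @param x a \code{\link{MirnaCandidates}}.
#' @return \code{DNAStringSet} parallel to \code{candidates(x)}.
#' @export
setGeneric("precursors", function(x) standardGeneric("precursors"))

#' @rdname precursors
#' @export
setMethod("precursors", "MirnaCandidates", function(x) x@precursors)

setMethod("show", "MirnaCandidates", function(object) {
  cd <- object@candidates
  cat("MirnaCandidates:", nrow(cd), "candidate loci")
  if (nrow(cd) && "pass" %in% names(cd))
    cat(" (", sum(cd$pass), "passing validation )")
  cat("\n")
})

#' Generator parameters of a SimulationConfig
#'
#' @param x a \code{\link{SimulationConfig}}.
#' @return named list of parameters.
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname simParams
#' @export
setMethod("simParams", "SimulationConfig", function(x) x@params)

setMethod("show", "SimulationConfig", function(object) {
  p <- object@params
  cat("SimulationConfig: arm", format(p$arm_length, big.mark = ","),
      "bp, coverage", p$coverage, "x, TE fraction", p$te_fraction, "\n")
  cat("  ", p$n_te_families, "TE families,", p$n_genes, "genes,",
      p$n_hairpins, "hairpins, seed", p$seed, "\n")
})

#' Planted truth annotation of a SimulatedArm
#'
#' @param x a \code{\link{SimulatedArm}}.
#' @return \code{GRanges} of planted features.
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "SimulatedArm", function(x) x@truth)

#' Sequence of a SimulatedArm
#'
#' @param x a \code{\link{SimulatedArm}}.
#' @return \code{DNAString}.
#' @export
setGeneric("armSeq", function(x) standardGeneric("armSeq"))

#' @rdname armSeq
#' @export
setMethod("armSeq", "SimulatedArm", function(x) x@seq)

setMethod("show", "SimulatedArm", function(object) {
  tr <- object@truth
  cat("SimulatedArm", object@arm, ":", length(object@seq), "bp\n")
  if (length(tr)) {
    tt <- table(S4Vectors::mcols(tr)$type)
    cat("  planted features:",
        paste(names(tt), as.integer(tt), collapse = ", "), "\n")
  }
})
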