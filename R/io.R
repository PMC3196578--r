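#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# FASTA

#' Read a FASTA file
#'
#' Thin wrapper around the Biostrings FASTA reader that enforces the
#' pipeline's record contract: non-empty unique ids, non-empty sequences,
#' uppercased residues.  In DNA mode, U is mapped to T so that RNA-alphabet
#' inputs (e.g. mature miRNA databases) can be used directly in nucleotide
#' searches.
#'
#' @param path FASTA file.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @return \code{DNAStringSet} or \code{AAStringSet}, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) .fastaParseError(path, conditionMessage(e)))
  if (length(x) == 0) {
    return(if (type == "DNA") Biostrings::DNAStringSet()
           else Biostrings::AAStringSet())
  }
  if (any(!nzchar(names(x))) || any(Biostrings::width(x) == 0))
    .fastaParseError(path, "empty header or empty sequence")
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  # keep only the id token; descriptions beyond the first word are dropped
  names(x) <- sub("\\s.*$", "", names(x))
  ch <- toupper(as.character(x))
  if (type == "DNA") {
    ch <- chartr("U", "T", ch)
    out <- Biostrings::DNAStringSet(ch)
  } else {
    out <- Biostrings::AAStringSet(ch)
  }
  names(out) <- names(x)
  out
}

# locate the offending line for a malformed FASTA record
.fastaParseError <- function(path, why) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  bad <- NA_integer_
  if (length(lines)) {
    hdr <- grepl("^>", lines)
    # empty-sequence record: header followed by header/EOF
    nxt <- c(hdr[-1], TRUE)
    empty <- which(hdr & nxt)
    if (length(empty)) bad <- empty[1]
    else if (!hdr[1] && any(nzchar(lines))) bad <- which(nzchar(lines))[1]
  }
  stop("malformed FASTA in ", path,
       if (!is.na(bad)) paste0(" at line ", bad), ": ", why, call. = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x named \code{XStringSet} or named character vector.
#' @param path output file.
#' @param width line-wrapping width (default 80 columns).
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 80L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# hit tables (12-column tabular format)

#' Write hits as a 12-column tabular report
#'
#' Serialises a \code{\link{HitTable}} in the conventional 12-column
#' tab-separated layout (query, subject, \%identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore).
#' Coordinates become 1-based inclusive; minus-strand hits are written with
#' \code{sstart > send}.
#'
#' @param x a \code{\link{HitTable}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeHitsTable <- function(x, path) {
  stopifnot(is(x, "HitTable"))
  h <- hits(x)
  ss <- ifelse(h$strand == "-", h$s_end, h$s_start + 1L)
  se <- ifelse(h$strand == "-", h$s_start + 1L, h$s_end)
  out <- data.frame(
    query_id = h$query_id, subject_id = h$subject_id,
    identity = sprintf("%.2f", h$identity_pct),
    align_len = h$align_len, mismatches = h$mismatches,
    gap_opens = h$gap_opens,
    qstart = h$q_start + 1L, qend = h$q_end,
    sstart = ss, send = se,
    evalue = format(h$evalue, digits = 3, scientific = TRUE),
    bitscore = sprintf("%.1f", h$bitscore),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write hit table to ", path)
  invisible(path)
}

#' Read a 12-column tabular hit report
#'
#' Inverse of \code{\link{writeHitsTable}}; also the adapter for ingesting
#' hit tables produced by external search tools.  Columns beyond the twelve
#' standard ones are not expected; similarity, coverage and frame fields are
#' reconstructed where derivable (similarity defaults to identity, coverage
#' requires \code{queryLengths}/\code{subjectLengths}).
#'
#' @param path tabular hit file.
#' @param queryLengths,subjectLengths optional named vectors of sequence
#'   lengths used to compute coverage percentages; defaults fall back to the
#'   aligned span (coverage 100\%).
#' @param mode \code{"nucleotide"} or \code{"translated"}.
#' @return a \code{\link{HitTable}}.
#' @export
readHitsTable <- function(path, queryLengths = NULL, subjectLengths = NULL,
                          mode = "nucleotide") {
  cols <- c("query_id", "subject_id", "identity", "align_len", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  raw <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                    colClasses = c("character", "character", rep("numeric", 10)),
                    stringsAsFactors = FALSE)
  minus <- raw$sstart > raw$send
  s_start <- ifelse(minus, raw$send, raw$sstart) - 1L
  s_end <- ifelse(minus, raw$sstart, raw$send)
  qlen <- if (is.null(queryLengths)) raw$qend else
    unname(queryLengths[raw$query_id])
  slen <- if (is.null(subjectLengths)) s_end else
    unname(subjectLengths[raw$subject_id])
  h <- data.frame(
    query_id = raw$query_id, subject_id = raw$subject_id,
    identity_pct = raw$identity, similarity_pct = raw$identity,
    align_len = as.integer(raw$align_len),
    mismatches = as.integer(raw$mismatches),
    gap_opens = as.integer(raw$gap_opens),
    q_start = as.integer(raw$qstart) - 1L, q_end = as.integer(raw$qend),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    strand = ifelse(minus, "-", "+"), frame = 0L,
    evalue = raw$evalue, bitscore = raw$bitscore,
    score = NA_integer_,
    query_cov_pct = 100 * (raw$qend - raw$qstart + 1) / qlen,
    subject_cov_pct = 100 * (s_end - s_start) / slen,
    q_len = as.integer(qlen), s_len = as.integer(slen),
    stringsAsFactors = FALSE)
  if (mode == "translated") h$similarity_pct <- pmax(h$similarity_pct, 0)
  new("HitTable", hits = h)
}

# ---------------------------------------------------------------------------
# bin maps

#' Construct a deletion-bin map
#'
#' @param bins \code{data.frame} with columns \code{bin}, \code{arm},
#'   \code{frac_start}, \code{frac_end} (fractional arm positions in [0,1]).
#' @param markers optional \code{data.frame} with columns \code{marker_id},
#'   \code{bin}.
#' @return a \code{\link{BinMap}} with bins ordered along the arm and
#'   overlap flags computed.
#' @export
binMap <- function(bins, markers = NULL) {
  if (nrow(bins)) {
    if (any(bins$frac_start < 0 | bins$frac_end > 1))
      stop("bin fractions must lie in [0, 1]")
    if (any(bins$frac_start >= bins$frac_end))
      stop("bin frac_start must be < frac_end")
    bins <- bins[order(bins$arm, bins$frac_start, bins$frac_end), ,
                 drop = FALSE]
    ov <- vapply(seq_len(nrow(bins)), function(i) {
      same <- bins$arm == bins$arm[i]
      any(same & seq_len(nrow(bins)) != i &
            bins$frac_start < bins$frac_end[i] &
            bins$frac_end > bins$frac_start[i])
    }, logical(1))
    bins$overlaps <- ov
    rownames(bins) <- NULL
  } else {
    bins$overlaps <- logical(0)
  }
  if (is.null(markers))
    markers <- data.frame(marker_id = character(), bin = character(),
                          stringsAsFactors = FALSE)
  new("BinMap", bins = bins, markers = markers)
}

#' Read a deletion-bin map from TSV
#'
#' Expects a header line and columns \code{bin}, \code{arm},
#' \code{frac_start}, \code{frac_end}.
#'
#' @param path TSV file.
#' @return a \code{\link{BinMap}}.
#' @export
readBinMap <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    return(binMap(data.frame(bin = character(), arm = character(),
                             frac_start = numeric(), frac_end = numeric(),
                             stringsAsFactors = FALSE)))
  need <- c("bin", "arm", "frac_start", "frac_end")
  if (!all(need %in% names(raw)))
    stop("bin map needs columns: ", paste(need, collapse = ", "))
  binMap(raw[, need])
}

# ---------------------------------------------------------------------------
# GFF3 truth round-trip and BED density tracks

#' Write planted-truth (or any) annotation as GFF3
#'
#' \code{GRanges} metadata columns become GFF3 attributes; coordinates are
#' serialised 1-based closed per the GFF3 convention.
#'
#' @param gr a \code{GRanges}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGff <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) {
    S4Vectors::mcols(gr)$type <- as.character(mc$type)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation GFF3 back into GRanges
#'
#' @param path GFF3 file.
#' @return \code{GRanges}.
#' @export
readAnnotationGff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  S4Vectors::mcols(gr)$type <- as.character(S4Vectors::mcols(gr)$type)
  gr
}

#' Write a window-density track as BED
#'
#' Densities become the BED score column; one feature per window.
#'
#' @param track density track \code{data.frame} from
#'   \code{\link{windowDensity}} (columns \code{chrom}, \code{start},
#'   \code{end}, \code{density}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDensityBed <- function(track, path) {
  df <- data.frame(chrom = track$chrom,
                   start = format(track$start, scientific = FALSE, trim = TRUE),
                   end = format(track$end, scientific = FALSE, trim = TRUE),
                   name = sprintf("win%06d", seq_len(nrow(track))),
                   score = track$density)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# run configuration and stage logging

#' Write a run configuration as JSON
#'
#' @param config named list (e.g. \code{simParams} of a
#'   \code{\link{SimulationConfig}}, threshold settings, ...).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' @param path JSON file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# one structured line per pipeline stage; collected so ledgers can be audited
.logEnv <- new.env(parent = emptyenv())
.logEnv$log <- NULL

#' Log a pipeline stage with input/output record counts
#'
#' Every cascade stage calls this; the accumulated log lets per-class read
#' ledgers be audited for conservation (inputs of each stage equal the
#' outputs plus the records passed downstream).
#'
#' @param stage stage name.
#' @param n_in,n_out input and output record counts.
#' @return the log entry, invisibly.
#' @export
logStage <- function(stage, n_in, n_out) {
  entry <- data.frame(time = format(Sys.time(), "%H:%M:%S"), stage = stage,
                      n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
  .logEnv$log <- rbind(.logEnv$log, entry)
  if (isTRUE(getOption("chromSurvey.verbose", FALSE)))
    message(sprintf("[%s] %s: %d in, %d out", entry$time, stage, n_in, n_out))
  invisible(entry)
}

#' Retrieve (and optionally clear) the stage log
#'
#' @param clear reset the log after reading.
#' @return \code{data.frame} of logged stages.
#' @export
stageLog <- function(clear = FALSE) {
  out <- .logEnv$log
  if (clear) .logEnv$log <- NULL
  if (is.null(out))
    out <- data.frame(time = character(), stage = character(),
                      n_in = integer(), n_out = integer(),
                      stringsAsFactors = FALSE)
  out
}
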