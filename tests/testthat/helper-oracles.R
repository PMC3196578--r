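# Shared fixtures and independent oracles used across the suite.

.bases <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(.bases, n, TRUE), collapse = "")

mutate_frac <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  i <- which(runif(length(ch)) < rate)
  ch[i] <- vapply(ch[i], function(b) sample(setdiff(.bases, b), 1),
                  character(1))
  paste(ch, collapse = "")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# exact Smith-Waterman local score via Biostrings (independent oracle for
# the seeded search engine); same scoring: +1/-2, gap open 5 extend 2
sw_oracle_score <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  best <- -Inf
  for (qq in c(q, revcomp_chr(q))) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qq), Biostrings::DNAString(s), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    best <- max(best, Biostrings::score(pa))
  }
  best
}

# ---------------------------------------------------------------------------
# exhaustive folding oracle: enumerate every pseudoknot-free structure
# (hairpin loops >= 3 nt, pairs AU/GC/GU) and score it with the structural
# energy definition applied to the explicit pair set.

.pair_energy_oracle <- function(a, b, gu = TRUE) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(-2)
  if (gu && ((a == "G" && b == "T") || (a == "T" && b == "G"))) return(-1)
  NA_real_
}

# energy of an explicit structure (list of c(i, j) pairs, 1-based):
# sum of pair energies; for each pair with exactly one directly nested
# pair, +1 per unpaired nt between them; hairpins/multiloops/exterior free
structure_energy_oracle <- function(ch, pairs, gu = TRUE) {
  if (!length(pairs)) return(0)
  e <- 0
  for (p in pairs) {
    pe <- .pair_energy_oracle(ch[p[1]], ch[p[2]], gu)
    if (is.na(pe)) return(NA_real_)
    e <- e + pe
    # directly nested pairs: those inside (p1, p2) not inside a sibling
    inside <- Filter(function(q) q[1] > p[1] && q[2] < p[2], pairs)
    direct <- Filter(function(q) {
      !any(vapply(inside, function(r)
        r[1] < q[1] && q[2] < r[2], logical(1)))
    }, inside)
    if (length(direct) == 1) {
      q <- direct[[1]]
      e <- e + (q[1] - p[1] - 1) + (p[2] - q[2] - 1)
    }
  }
  e
}

# enumerate all structures over ch[i..j]; returns minimal oracle energy
fold_oracle_mfe <- function(seq, gu = TRUE) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  best <- 0
  # collect all structures of a region as lists of pair lists (memoised)
  memo <- new.env(parent = emptyenv())
  enum_collect <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum_collect(i + 1, j)
    if (j - i >= 4) {
      for (k in (i + 4):j) {
        if (is.na(.pair_energy_oracle(ch[i], ch[k], gu))) next
        inner <- enum_collect(i + 1, k - 1)
        outer <- enum_collect(k + 1, j)
        for (pi in inner) for (po in outer)
          out <- c(out, list(c(list(c(i, k)), pi, po)))
      }
    }
    memo[[key]] <- out
    out
  }
  structs <- enum_collect(1, n)
  for (p in structs) {
    if (!length(p)) next
    e <- structure_energy_oracle(ch, p, gu)
    if (!is.na(e) && e < best) best <- e
  }
  best
}

# small helper: build a HitTable directly from a data.frame of partial
# columns (fills the remaining required columns consistently)
make_hits <- function(df) {
  n <- nrow(df)
  defaults <- data.frame(
    query_id = paste0("q", seq_len(max(n, 1))),
    subject_id = paste0("s", seq_len(max(n, 1))),
    identity_pct = 100, similarity_pct = 100, align_len = 100L,
    mismatches = 0L, gap_opens = 0L, q_start = 0L, q_end = 100L,
    s_start = 0L, s_end = 100L, strand = "+", frame = 0L,
    evalue = 1e-10, bitscore = 100, score = 100L,
    query_cov_pct = 100, subject_cov_pct = 100, q_len = 100L, s_len = 200L,
    stringsAsFactors = FALSE)
  if (n == 0) {
    defaults <- defaults[0, , drop = FALSE]
  } else {
    for (nm in names(df)) defaults[[nm]] <- df[[nm]]
  }
  defaults$similarity_pct <- pmax(defaults$similarity_pct,
                                  defaults$identity_pct)
  defaults$q_len <- pmax(defaults$q_len, defaults$q_end)
  defaults$s_len <- pmax(defaults$s_len, defaults$s_end)
  new("HitTable", hits = defaults)
}
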