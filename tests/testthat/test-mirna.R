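test_that("mature hit search keeps revcomp hits and drops divergent direct hits", {
  set.seed(21)
  mature <- rand_seq(21)
  # substitutions at fixed positions for exact mismatch counts
  sub_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) setdiff(.bases, b)[1], character(1))
    paste(ch, collapse = "")
  }
  subj <- c(
    exact = paste0(rand_seq(80), mature, rand_seq(80)),
    rc_only = paste0(rand_seq(80), revcomp_chr(sub_at(mature, c(3, 8, 13))),
                     rand_seq(80)),
    mm4 = paste0(rand_seq(80), sub_at(mature, c(3, 7, 12, 17)),
                 rand_seq(80)))
  mh <- findMatureHits(subj, c("osa-miR9991" = mature))
  exact <- mh[mh$subject_id == "exact", ]
  expect_true(any(exact$orientation == "direct" & exact$mismatches == 0))
  # reverse complement retained regardless of mismatches
  expect_true(any(mh$subject_id == "rc_only" & mh$orientation == "revcomp"))
  # direct hit with 4 mismatches discarded
  expect_false(any(mh$subject_id == "mm4" & mh$orientation == "direct"))
  expect_error(findMatureHits(subj, character()), "empty|named")
})

test_that("miRNA family names parse from miRBase-style ids", {
  expect_identical(mirnaFamily(c("tae-miR1122a", "osa-miR156", "weird")),
                   c("miR1122", "miR156", "weird"))
})

test_that("hit pairing matches a brute-force pair enumeration oracle", {
  # direct-only: no locus
  d_only <- data.frame(mature_id = "m1", family = "f", subject_id = "s",
                       orientation = "direct", s_start = 10L, s_end = 31L,
                       mismatches = 0L, evalue = 1e-4, bitscore = 40,
                       stringsAsFactors = FALSE)
  expect_equal(nrow(pairHits(d_only)), 0)
  # one direct + one revcomp of the same family: one locus
  pair <- rbind(d_only, data.frame(mature_id = "m1", family = "f",
                                   subject_id = "s", orientation = "revcomp",
                                   s_start = 80L, s_end = 101L,
                                   mismatches = 2L, evalue = 1e-2,
                                   bitscore = 30))
  got <- pairHits(pair)
  expect_equal(nrow(got), 1)
  expect_equal(got$five_start, 10L)
  expect_equal(got$three_end, 101L)
  # random toy hit sets equal the brute-force enumeration
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    mh <- data.frame(
      mature_id = "m", family = sample(c("fA", "fB"), n, TRUE),
      subject_id = sample(c("s1", "s2"), n, TRUE),
      orientation = sample(c("direct", "revcomp"), n, TRUE),
      s_start = sample(seq(0, 900, 20), n), stringsAsFactors = FALSE)
    mh$s_end <- mh$s_start + 21L
    mh$mismatches <- 0L; mh$evalue <- 1e-3; mh$bitscore <- 40
    got <- pairHits(mh, maxSpan = 500L)
    # brute-force oracle: every valid (direct, revcomp) combination,
    # reduced to its distinct (subject, span) locus
    oracle <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      a <- mh[i, ]; b <- mh[j, ]
      if (a$orientation != "direct" || b$orientation != "revcomp") next
      if (a$subject_id != b$subject_id || a$family != b$family) next
      if (max(a$s_start, b$s_start) < min(a$s_end, b$s_end)) next
      if (max(a$s_end, b$s_end) - min(a$s_start, b$s_start) > 500) next
      oracle <- rbind(oracle, data.frame(
        s = a$subject_id, f0 = min(a$s_start, b$s_start),
        t1 = max(a$s_end, b$s_end), stringsAsFactors = FALSE))
    }
    n_oracle <- if (is.null(oracle)) 0L else nrow(unique(oracle))
    expect_equal(nrow(got), n_oracle)
    if (n_oracle > 0) {
      expect_setequal(paste(got$subject_id, got$five_start, got$three_end),
                      unique(paste(oracle$s, oracle$f0, oracle$t1)))
    }
  }
})

test_that("precursor extraction cuts 13 nt flanks and flags clipping", {
  set.seed(23)
  s <- rand_seq(300)
  px <- extractPrecursor(s, 113, 181)
  expect_equal(px$start, 100)
  expect_equal(px$end, 194)
  expect_equal(nchar(px$seq), 94)
  expect_identical(px$seq, substr(s, 101, 194))
  expect_false(px$clipped)
  clip <- extractPrecursor(s, 5, 60)
  expect_equal(clip$start, 0)
  expect_true(clip$clipped)
  expect_error(extractPrecursor(s, 50, 50), "degenerate")
})

test_that("folding: perfect hairpin pairs the full stem; poly-A has no structure", {
  f <- foldHairpin(paste0(strrep("GC", 10), "AAAA",
                          revcomp_chr(strrep("GC", 10))))
  expect_equal(f$mfe, -60)                        # 20 GC pairs
  expect_equal(substr(f$structure, 1, 20), strrep("(", 20))
  fa <- foldHairpin(strrep("A", 60))
  expect_equal(fa$mfe, 0)
  expect_equal(fa$structure, strrep(".", 60))
})

test_that("DP folding equals the exhaustive enumeration oracle", {
  set.seed(24)
  lens <- c(12, 14, 16, 17, 18, 19, 20)
  for (n in lens) {
    s <- rand_seq(n)
    expect_equal(foldHairpin(s)$mfe, fold_oracle_mfe(s),
                 label = paste("n =", n, s))
  }
  # and with wobble pairs disabled
  for (n in c(14, 18)) {
    s <- rand_seq(n)
    expect_equal(foldHairpin(s, allowGU = FALSE)$mfe,
                 fold_oracle_mfe(s, gu = FALSE), label = paste("GU off", s))
  }
})

test_that("folding energy is reverse-complement symmetric without wobble pairs", {
  set.seed(25)
  for (i in 1:6) {
    s <- rand_seq(40)
    expect_equal(foldHairpin(s, allowGU = FALSE)$mfe,
                 foldHairpin(revcomp_chr(s), allowGU = FALSE)$mfe)
  }
})

test_that("AMFE and MFEI arithmetic and duplication invariance", {
  x <- mfei(-34, 100, 40)
  expect_equal(x$amfe, 34)
  expect_equal(x$mfei, 0.85)
  y <- mfei(-50, 200, 50)
  expect_equal(y$amfe, 25)
  expect_equal(y$mfei, 0.5)
  # duplication: doubling mfe and length changes nothing
  z2 <- mfei(-68, 200, 40)
  expect_equal(z2$amfe, x$amfe)
  expect_equal(z2$mfei, x$mfei)
  expect_error(mfei(-10, 100, 0), "positive")
})

test_that("candidate validation enforces the MFEI and duplex rules", {
  # construct a clean hairpin candidate: mature + loop + star
  set.seed(26)
  mature <- rand_seq(21)
  hp <- paste0(rand_seq(13), mature, rand_seq(9), revcomp_chr(mature),
               rand_seq(13))
  f <- foldHairpin(hp)
  v <- validateCandidate(hp, f$structure, f$mfe, 13, 34, 43, 64)
  expect_true(v$pass)
  expect_lte(v$mature_star_mismatches, 4)
  expect_identical(v$mature_arm, "5'")
  # MFEI boundary is exclusive: 0.84 fails, 0.851 passes the cutoff test
  v2 <- validateCandidate(hp, f$structure, -0.84 * 40 * nchar(hp) / 100 /
                            (100 / nchar(hp)) / 100, 13, 34, 43, 64)
  # simpler: drive mfei below cutoff via a tiny |mfe|
  v2 <- validateCandidate(hp, f$structure, -1, 13, 34, 43, 64)
  expect_false(v2$pass)
  expect_true("mfei" %in% v2$reasons)
  # five unpaired mature positions fail the mismatch rule: break the star
  broken <- paste0(rand_seq(13), mature, rand_seq(9),
                   revcomp_chr(paste0(substr(mature, 1, 10),
                                      rand_seq(11))), rand_seq(13))
  fb <- foldHairpin(broken)
  vb <- validateCandidate(broken, fb$structure, fb$mfe, 13, 34, 43, 64)
  expect_true(vb$mature_star_mismatches > 4 || !vb$pass)
})

test_that("validator separates planted hairpins from shuffled decoys", {
  set.seed(27)
  n_true <- 15; n_decoy <- 15
  res <- c()
  for (i in seq_len(n_true)) {
    mature <- rand_seq(21)
    hp <- paste0(rand_seq(13), mature, rand_seq(sample(8:25, 1)),
                 revcomp_chr(mutate_frac(mature, 0.07)), rand_seq(13))
    f <- foldHairpin(hp)
    star_start <- nchar(hp) - 13 - 21
    v <- validateCandidate(hp, f$structure, f$mfe, 13, 34, star_start,
                           star_start + 21)
    res <- c(res, v$pass)
  }
  sens <- mean(res)
  decoy <- c()
  for (i in seq_len(n_decoy)) {
    mature <- rand_seq(21)
    # mature present but the rest is shuffled background: no star
    hp <- paste0(rand_seq(13), mature, rand_seq(42), rand_seq(13))
    f <- foldHairpin(hp)
    star_start <- nchar(hp) - 13 - 21
    v <- validateCandidate(hp, f$structure, f$mfe, 13, 34, star_start,
                           star_start + 21)
    decoy <- c(decoy, v$pass)
  }
  expect_gte(sens, 0.9)
  expect_lte(mean(decoy), 0.1)
})

test_that("annotation flags known-precursor similarity and repeats", {
  set.seed(28)
  sv <- small_survey()
  mature <- rand_seq(21)
  hp <- paste0(rand_seq(13), mature, rand_seq(12), revcomp_chr(mature),
               rand_seq(13))
  f <- foldHairpin(hp)
  cd <- data.frame(
    id = c("c1", "c2"), source_id = "x", p_start = 0L,
    p_end = nchar(hp), clipped = FALSE, length = nchar(hp), family = "miR1",
    mature_id = "m1", mature_start = 13L, mature_end = 34L,
    star_start = 46L, star_end = 67L, structure = f$structure, mfe = f$mfe,
    amfe = 30, mfei = 1.2, gc_pct = 45, mature_star_mismatches = 0L,
    n_asym_bulges = 0L, max_asym_bulge = 0L, mature_arm = "5'",
    protein_coding = FALSE, pass = TRUE, fail_reasons = "",
    known_precursor_similar = NA, contains_repeat = NA,
    stringsAsFactors = FALSE)
  pre2 <- rand_seq(nchar(hp))
  mc <- new("MirnaCandidates", candidates = cd,
            precursors = Biostrings::DNAStringSet(c(c1 = hp, c2 = pre2)))
  known <- c(kp1 = mutate_frac(hp, 0.1))    # ~90% identical to c1
  ann <- annotateCandidates(mc, knownPrecursorDb = known,
                            repeatNtDb = sv$lib$repeat_nt)
  acd <- candidates(ann)
  expect_true(acd$known_precursor_similar[acd$id == "c1"])
  expect_false(acd$known_precursor_similar[acd$id == "c2"])
  fam <- attr(ann, "familyReport")
  expect_identical(names(fam), c("family", "n_precursors", "length_range",
                                 "mature_position"))
  expect_equal(fam$n_precursors[fam$family == "miR1"], 2)
})
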