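test_that("identical and reverse-complement queries are found symmetrically", {
  set.seed(2)
  s <- setNames(rand_seq(300), "g1")
  h <- hits(searchHits(c(r1 = s[[1]]), s, maxEvalue = 1e-6))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$query_cov_pct, 100)
  expect_equal(h$strand, "+")
  hrc <- hits(searchHits(c(r1 = revcomp_chr(s[[1]])), s, maxEvalue = 1e-6))
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$score, h$score)   # strand symmetry: identical score
})

test_that("search is symmetric under reverse-complementing query and subject", {
  set.seed(3)
  for (i in 1:5) {
    s <- rand_seq(250)
    q <- mutate_frac(substr(s, 40, 200), 0.1)
    h1 <- hits(searchHits(c(q = q), c(s = s), maxEvalue = 1e-3))
    h2 <- hits(searchHits(c(q = revcomp_chr(q)), c(s = revcomp_chr(s)),
                          maxEvalue = 1e-3))
    expect_equal(max(h1$score), max(h2$score))
  }
})

test_that("seeded search equals the exhaustive Smith-Waterman oracle", {
  set.seed(4)
  # planted homology structure across a toy sequence set
  subj <- setNames(vapply(sample(250:400, 8, TRUE), rand_seq, character(1)),
                   paste0("s", 1:8))
  qs <- character()
  for (i in 1:8) {
    frag <- substr(subj[[i]], 30, 30 + sample(120:250, 1))
    qs[paste0("q", i)] <- mutate_frac(frag, runif(1, 0.02, 0.12))
  }
  qs["qx"] <- rand_seq(300)   # no homolog
  ht <- hits(searchHits(qs, subj, maxEvalue = 1e-6))
  # oracle: full SW on all pairs, both strands, same cutoff rule
  cutoff_bits <- function(q, s, score) {
    ev <- evalueOf(cpp_bits_of_test(score), nchar(q),
                   sum(nchar(subj)))
    ev <= 1e-6
  }
  cpp_bits_of_test <- function(score) (1.28 * score - log(0.46)) / log(2)
  for (qn in names(qs)) for (sn in names(subj)) {
    osc <- sw_oracle_score(qs[[qn]], subj[[sn]])
    above <- cutoff_bits(qs[[qn]], subj[[sn]], osc)
    eng <- ht[ht$query_id == qn & ht$subject_id == sn, , drop = FALSE]
    if (above) {
      expect_gt(nrow(eng), 0)
      expect_equal(max(eng$score), osc,
                   label = paste("pair", qn, sn))
    } else {
      expect_equal(nrow(eng), 0, label = paste("pair", qn, sn))
    }
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  expect_equal(evalueOf(0, 1, 1), 1)                    # definition
  expect_equal(evalueOf(10, 5, 100) * 2, evalueOf(10, 5, 200))  # linearity
  # toy scored alignment: hand computation of m n 2^-bits
  expect_equal(evalueOf(30, 345, 1e6), 345 * 1e6 * 2^-30)
  # monotone decreasing in score for identical ungapped sequences
  set.seed(5)
  lens <- c(50, 100, 200, 400)
  sc <- vapply(lens, function(L) {
    s <- rand_seq(L)
    h <- hits(searchHits(c(q = s), c(s = s)))
    c(h$bitscore[1], h$evalue[1])
  }, numeric(2))
  expect_true(all(diff(sc[1, ]) > 0))   # bitscore increasing in length
  expect_true(all(diff(sc[2, ]) < 0))   # evalue decreasing
})

test_that("filterHits applies every bound exactly and is idempotent", {
  prof <- thresholdProfile(maxEvalue = 1e-6, minIdentity = 30,
                           minSimilarity = 50, minQueryCov = 50,
                           minSubjectCov = 1)
  # boundary: identity 29.9 under a 30 floor is removed; 30.0 kept
  ht <- make_hits(data.frame(identity_pct = c(29.9, 30),
                             similarity_pct = c(60, 60)))
  expect_equal(hits(filterHits(ht, prof))$identity_pct, 30)
  # empty in, empty out
  empty <- make_hits(data.frame(identity_pct = numeric()))
  expect_length(filterHits(empty, prof), 0)
  # random hit set equals an independent per-bound set comprehension
  set.seed(6)
  n <- 200
  ht <- make_hits(data.frame(
    query_id = paste0("q", 1:n),
    identity_pct = runif(n, 0, 60), similarity_pct = runif(n, 40, 100),
    evalue = 10^runif(n, -12, 0), query_cov_pct = runif(n, 0, 100),
    subject_cov_pct = runif(n, 0, 5), mismatches = sample(0:20, n, TRUE)))
  h <- hits(ht)
  keep <- h$evalue <= 1e-6
  keep <- keep & h$identity_pct >= 30
  keep <- keep & pmax(h$similarity_pct, h$identity_pct) >= 50
  keep <- keep & h$query_cov_pct >= 50
  keep <- keep & h$subject_cov_pct >= 1
  got <- filterHits(ht, prof)
  expect_identical(hits(got)$query_id, h$query_id[keep])
  expect_identical(hits(filterHits(got, prof)), hits(got))  # idempotent
})

test_that("bestHitPerQuery ranks by E-value, bitscore, then subject id", {
  ht <- make_hits(data.frame(
    query_id = c("q", "q"), subject_id = c("a", "b"),
    evalue = c(1e-8, 1e-20), bitscore = c(40, 80)))
  expect_equal(hits(bestHitPerQuery(ht))$subject_id, "b")
  # exact tie on E and bits: lexicographically smaller subject
  tie <- make_hits(data.frame(query_id = c("q", "q"),
                              subject_id = c("zeta", "alpha"),
                              evalue = c(1e-9, 1e-9),
                              bitscore = c(50, 50)))
  expect_equal(hits(bestHitPerQuery(tie))$subject_id, "alpha")
  # random sets equal a sort-based oracle
  set.seed(7)
  n <- 300
  ht <- make_hits(data.frame(
    query_id = sample(paste0("q", 1:40), n, TRUE),
    subject_id = sample(paste0("s", 1:25), n, TRUE),
    evalue = 10^sample(seq(-30, -5), n, TRUE),
    bitscore = sample(seq(20, 200, 10), n, TRUE)))
  h <- hits(ht)
  oracle <- vapply(unique(h$query_id), function(q) {
    hh <- h[h$query_id == q, ]
    hh <- hh[order(hh$evalue, -hh$bitscore, hh$subject_id), ]
    hh$subject_id[1]
  }, character(1))
  got <- hits(bestHitPerQuery(ht))
  expect_identical(setNames(got$subject_id, got$query_id),
                   oracle[got$query_id])
})

test_that("reciprocal best hits require mutual best-hit status", {
  # symmetric toy: a <-> b mutual best
  ab <- make_hits(data.frame(query_id = "a", subject_id = "b"))
  ba <- make_hits(data.frame(query_id = "b", subject_id = "a"))
  expect_identical(reciprocalBestHits(ab, ba),
                   data.frame(a = "a", b = "b", stringsAsFactors = FALSE))
  # a -> b best but b -> c best: no pair
  ba2 <- make_hits(data.frame(query_id = "b", subject_id = "c"))
  expect_equal(nrow(reciprocalBestHits(ab, ba2)), 0)
  # random score matrix equals the exhaustive argmax oracle
  set.seed(8)
  nA <- 12; nB <- 10
  sc <- matrix(runif(nA * nB), nA, nB,
               dimnames = list(paste0("a", 1:nA), paste0("b", 1:nB)))
  tohits <- function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    make_hits(data.frame(query_id = rownames(m)[idx[, 1]],
                         subject_id = colnames(m)[idx[, 2]],
                         evalue = 10^(-20 * m[idx]),
                         bitscore = 100 * m[idx]))
  }
  got <- reciprocalBestHits(tohits(sc), tohits(t(sc)))
  oracle <- NULL
  for (i in seq_len(nA)) {
    j <- which.max(sc[i, ])
    if (which.max(sc[, j]) == i)
      oracle <- rbind(oracle, data.frame(a = rownames(sc)[i],
                                         b = colnames(sc)[j],
                                         stringsAsFactors = FALSE))
  }
  expect_identical(got[order(got$a), ], oracle[order(oracle$a), ],
                   ignore_attr = TRUE)
})

test_that("translated mode reports similarity above identity and finds frames", {
  set.seed(9)
  aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120, TRUE),
              collapse = "")
  gc <- Biostrings::GENETIC_CODE
  bycodon <- split(names(gc), unname(gc))
  cds <- paste(vapply(strsplit(aa, "")[[1]], function(a)
    sample(bycodon[[a]], 1), character(1)), collapse = "")
  # query: the CDS with a frame-shifting prefix, on the minus strand
  q <- revcomp_chr(paste0("AC", cds))
  h <- hits(searchHits(c(q = q), c(p = aa), mode = "translated",
                       maxEvalue = 1e-6))
  expect_gt(nrow(h), 0)
  expect_equal(max(h$identity_pct), 100)
  expect_true(all(h$similarity_pct >= h$identity_pct))
  expect_lt(h$frame[which.max(h$score)], 0)
})
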