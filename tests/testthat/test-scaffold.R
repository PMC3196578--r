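# a controlled unigene/contig world: one unigene spread over three contigs
toy_scaffold_world <- function(seed = 29) {
  set.seed(seed)
  ug <- rand_seq(900)
  contigs <- c(
    cA = paste0(rand_seq(40), substr(ug, 1, 200), rand_seq(60)),
    cB = paste0(rand_seq(30), substr(ug, 401, 600), rand_seq(30)),
    cC = paste0(substr(ug, 801, 900), rand_seq(50)),
    lone = rand_seq(300))
  list(unigenes = c(u1 = ug), contigs = contigs)
}

test_that("unigene mapping enforces identity and window-length floors", {
  set.seed(30)
  ug <- rand_seq(500)
  contigs <- c(
    good = paste0(rand_seq(50), mutate_frac(substr(ug, 100, 160), 0.016)),
    short45 = paste0(rand_seq(50), substr(ug, 300, 344), rand_seq(50)),
    diverged = paste0(rand_seq(50), mutate_frac(substr(ug, 200, 280), 0.12)))
  mu <- mapUnigenes(c(u1 = ug), contigs, minSeeds = 1L)
  m <- mu$matches
  expect_true("good" %in% m$contig_id)      # 60 bp window at ~98% identity
  expect_false("short45" %in% m$contig_id)  # 45 bp perfect: length floor
  expect_false("diverged" %in% m$contig_id) # below the 97% identity floor
  expect_true(all(m$align_len >= 50))
  expect_true(all(m$identity_pct >= 97))
})

test_that("repetitive and homeolog unigenes are flagged", {
  # the same region present on 11 distinct contigs -> repetitive
  m <- data.frame(
    unigene_id = "rep", contig_id = paste0("c", 1:11),
    u_start = 10L, u_end = 80L, c_start = 0L, c_end = 70L,
    identity_pct = 99, align_len = 70L, stringsAsFactors = FALSE)
  fl <- flagProblemUnigenes(m)
  expect_true(fl$repetitive[fl$unigene_id == "rep"])
  # ten contigs: not repetitive
  fl10 <- flagProblemUnigenes(m[1:10, ])
  expect_false(fl10$repetitive)
  # two unigenes on the identical contig set at different identity:
  # only the higher-identity copy is retained
  hm <- rbind(
    data.frame(unigene_id = "uA", contig_id = c("c1", "c2"),
               u_start = c(0L, 300L), u_end = c(200L, 500L),
               c_start = 0L, c_end = 200L, identity_pct = 99.5,
               align_len = 200L, stringsAsFactors = FALSE),
    data.frame(unigene_id = "uB", contig_id = c("c1", "c2"),
               u_start = c(0L, 300L), u_end = c(200L, 500L),
               c_start = 0L, c_end = 200L, identity_pct = 97.2,
               align_len = 200L, stringsAsFactors = FALSE))
  flh <- flagProblemUnigenes(hm)
  expect_false(flh$homeolog_dropped[flh$unigene_id == "uA"])
  expect_true(flh$homeolog_dropped[flh$unigene_id == "uB"])
  # disjoint contig sets: no homeolog flags
  hm2 <- hm; hm2$contig_id[hm2$unigene_id == "uB"] <- c("c3", "c4")
  expect_false(any(flagProblemUnigenes(hm2)$homeolog_dropped))
})

test_that("scaffolding orders contigs along the unigene with 100-N joins", {
  w <- toy_scaffold_world()
  mu <- mapUnigenes(w$unigenes, w$contigs, minSeeds = 1L)
  sc <- scaffoldContigs(mu$matches, w$contigs)
  expect_equal(sc$stats$n_scaffolds, 1)
  s <- sc$scaffolds
  expect_identical(s$contig_ids, "cA,cB,cC")
  expect_equal(s$n_contigs, 3)
  # conservation: joined bases minus Ns equal the member contig lengths
  seq <- as.character(sc$sequences[[1]])
  expect_equal(nchar(gsub("N", "", seq)), s$bases)
  expect_equal(s$bases, sum(nchar(w$contigs[c("cA", "cB", "cC")])))
  # spacers are exactly 100 Ns
  expect_equal(nchar(seq), s$bases + 200)
  expect_true(grepl(strrep("N", 100), seq))
  expect_false(grepl(strrep("N", 101), seq))
  # contig-order invariance
  sc2 <- scaffoldContigs(mu$matches, rev(w$contigs))
  expect_identical(sc2$scaffolds$contig_ids, s$contig_ids)
  # placement table tiles the scaffold
  pl <- sc$placements
  expect_equal(pl$start[1], 0)
  expect_equal(max(pl$end), nchar(seq))
})

test_that("single-contig matches and contested contigs never scaffold", {
  w <- toy_scaffold_world()
  mu <- mapUnigenes(w$unigenes, w$contigs, minSeeds = 1L)
  one <- mu$matches[mu$matches$contig_id == "cA", , drop = FALSE]
  expect_equal(scaffoldContigs(one, w$contigs)$stats$n_scaffolds, 0)
  # a second unigene claiming cB removes cB from both scaffolds
  m2 <- mu$matches
  m2 <- rbind(m2, data.frame(unigene_id = "u2", contig_id = c("cB", "lone"),
                             u_start = c(0L, 300L), u_end = c(200L, 500L),
                             c_start = c(0L, 0L), c_end = c(200L, 200L),
                             identity_pct = 99, align_len = 200L,
                             stringsAsFactors = FALSE))
  sc <- scaffoldContigs(m2, w$contigs)
  expect_true("cB" %in% sc$conflicts)
  expect_false(any(grepl("cB", sc$scaffolds$contig_ids)))
  # no contig appears in two scaffolds (partition property)
  all_c <- unlist(strsplit(sc$scaffolds$contig_ids, ","))
  expect_false(anyDuplicated(all_c) > 0)
})

test_that("synthetic split genes reassemble through their unigenes", {
  sv <- small_survey()
  arm <- "S"
  asm <- sv$assemblies[[arm]]; ann <- sv$annotation[[arm]]
  mu <- mapUnigenes(ann$unigenes, asm$contigSeqs)
  fl <- flagProblemUnigenes(mu$matches)
  sc <- scaffoldContigs(mu$matches, asm$contigSeqs, flags = fl)
  # scaffolds exist and respect the conservation property
  expect_gt(sc$stats$n_scaffolds, 0)
  for (k in seq_len(nrow(sc$scaffolds))) {
    s <- sc$scaffolds[k, ]
    ids <- strsplit(s$contig_ids, ",")[[1]]
    expect_equal(s$bases, sum(nchar(asm$contigSeqs[ids])))
  }
  # ordered correctly: member contigs of own-arm scaffolds follow genomic
  # order of the planted gene (assembly coordinates are known)
  co <- asm$contigOrigin
  ordered_ok <- vapply(seq_len(nrow(sc$scaffolds)), function(k) {
    ids <- strsplit(sc$scaffolds$contig_ids[k], ",")[[1]]
    pos <- co$start[match(ids, co$contig_id)]
    if (any(is.na(pos))) return(NA)
    !is.unsorted(pos)
  }, logical(1))
  expect_true(all(ordered_ok, na.rm = TRUE))
})
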