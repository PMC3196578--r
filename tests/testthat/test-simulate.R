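test_that("configuration validates ranges and rejects unknown parameters", {
  cfg <- simulationConfig(seed = 7)
  p <- simParams(cfg)
  expect_equal(p$te_fraction, 0.75)
  expect_equal(p$coverage, 2.3)
  expect_equal(p$read_len_mean, 345)
  expect_equal(p$contamination_rate, 0.053)
  expect_error(simulationConfig(te_fraction = 1.4), "\\[0, 1\\]")
  expect_error(simulationConfig(coverage = 0), "coverage")
  expect_error(simulationConfig(nonsense = 1), "unknown")
})

test_that("a fixed seed reproduces the arm and its truth bit for bit", {
  cfg <- simulationConfig(seed = 5, arm_length = 1e5, n_genes = 3L,
                          n_hairpins = 2L)
  lib1 <- simulateLibrary(cfg); lib2 <- simulateLibrary(cfg)
  expect_identical(lib1$repeat_nt, lib2$repeat_nt)
  expect_identical(lib1$matures, lib2$matures)
  a1 <- simulateArm(cfg, "S", lib1); a2 <- simulateArm(cfg, "S", lib2)
  expect_identical(as.character(armSeq(a1)), as.character(armSeq(a2)))
  expect_identical(as.data.frame(plantedTruth(a1)),
                   as.data.frame(plantedTruth(a2)))
  r1 <- shredReads(a1, cfg); r2 <- shredReads(a2, cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$origin, r2$origin)
})

test_that("the realised repeat fraction honours the configured target", {
  sv <- small_survey()
  for (arm in c("S", "L")) {
    frac <- planted_repeat_fraction(sv$arms[[arm]])
    expect_gt(frac, 0.73)
    expect_lt(frac, 0.77)
  }
})

test_that("planted truth is self-consistent with the arm sequence", {
  sv <- small_survey()
  armO <- sv$arms$S
  aseq <- as.character(armSeq(armO))
  tr <- plantedTruth(armO)
  # exons concatenate to the recorded coding sequence
  ex <- tr[S4Vectors::mcols(tr)$type == "exon"]
  for (g in unique(S4Vectors::mcols(ex)$feature_id)) {
    ee <- ex[S4Vectors::mcols(ex)$feature_id == g]
    ee <- ee[order(GenomicRanges::start(ee))]
    got <- paste(substring(aseq, GenomicRanges::start(ee),
                           GenomicRanges::end(ee)), collapse = "")
    expect_identical(got, armO@library$gene_cds[[g]])
  }
  # mature intervals carry the planted mature sequence exactly
  mt <- tr[S4Vectors::mcols(tr)$type == "mature"]
  for (k in seq_along(mt)) {
    mid <- S4Vectors::mcols(mt)$feature_id[k]
    expect_identical(substring(aseq, GenomicRanges::start(mt)[k],
                               GenomicRanges::end(mt)[k]),
                     chartr("U", "T", sv$lib$matures[[mid]]))
  }
  # every gene interval contains its exons
  gn <- tr[S4Vectors::mcols(tr)$type == "gene"]
  expect_true(all(GenomicRanges::countOverlaps(ex, gn, type = "within") >= 1))
})

test_that("shredding meets coverage, length and contamination targets", {
  sv <- small_survey()
  cfg <- sv$config
  p <- simParams(cfg)
  for (arm in c("S", "L")) {
    sh <- sv$reads[[arm]]
    total <- sum(sh$origin$end - sh$origin$start)
    L <- length(armSeq(sv$arms[[arm]]))
    expect_gt(total, p$coverage * L * 0.95)
    expect_lt(total, p$coverage * L * 1.05)
    expect_gt(mean(sh$origin$length), p$read_len_mean - 25)
    expect_lt(mean(sh$origin$length), p$read_len_mean + 25)
    expect_true(all(sh$origin$length >= p$read_len_min - 3))
    cont <- mean(sh$origin$arm != arm)
    expect_gt(cont, p$contamination_rate - 0.01)
    expect_lt(cont, p$contamination_rate + 0.01)
  }
})

test_that("error-free shredding yields exact substrings of the arm", {
  cfg <- simulationConfig(seed = 6, arm_length = 1e5, n_genes = 3L,
                          n_hairpins = 2L, subst_rate = 0,
                          homopolymer_indel_rate = 0)
  lib <- simulateLibrary(cfg)
  armO <- simulateArm(cfg, "S", lib)
  sh <- shredReads(armO, cfg)
  aseq <- as.character(armSeq(armO))
  for (i in sample(nrow(sh$origin), 25)) {
    o <- sh$origin[i, ]
    sub <- substring(aseq, o$start + 1, o$end)
    if (o$strand == "-") sub <- revcomp_chr(sub)
    expect_identical(sh$reads[[o$read_id]], sub)
  }
})

test_that("pseudo-assembly merges overlapping reads and collapses repeat families", {
  sv <- small_survey()
  asm <- sv$assemblies$S
  cs <- asm$contigs
  validObject(cs)
  ci <- contigInfo(cs)
  # collapsed family contigs reach far beyond the 5x repeat cutoff
  fam <- grepl("^ctg_fam_", ci$contig_id)
  expect_gt(sum(fam), 0)
  cov <- contigCoverage(ci$n_reads, ci$avg_read_len, ci$consensus_len)
  expect_gt(max(cov[fam]), 5)
  # positional contigs contain their member reads' origins
  co <- asm$contigOrigin
  mb <- memberReads(cs)
  org <- sv$reads$S$origin
  pos <- co[!is.na(co$arm), ][1:10, ]
  for (k in seq_len(nrow(pos))) {
    rids <- mb$read_id[mb$contig_id == pos$contig_id[k]]
    oo <- org[match(rids, org$read_id), ]
    expect_true(all(oo$start >= pos$start[k] & oo$end <= pos$end[k]))
  }
  # singletons and contig members partition the read set
  expect_false(any(asm$singletons %in% mb$read_id))
})

test_that("two overlapping reads merge; a lone read stays a singleton", {
  cfg <- simulationConfig(seed = 8, arm_length = 5e4, te_fraction = 0.3,
                          unknown_repeat_fraction = 0.01, n_genes = 2L,
                          n_hairpins = 1L, coverage = 0.02,
                          collapse_prob = 0)
  lib <- simulateLibrary(cfg)
  armO <- simulateArm(cfg, "S", lib)
  sh <- shredReads(armO, cfg)
  # craft an origin table with one overlapping pair and one lone read
  sh$origin <- sh$origin[1:3, ]
  sh$origin$start <- c(1000, 1200, 9000)
  sh$origin$end <- c(1400, 1600, 9400)
  sh$reads <- sh$reads[sh$origin$read_id]
  asm <- pseudoAssemble(sh, armO, cfg)
  ci <- contigInfo(asm$contigs)
  expect_equal(nrow(ci), 1)
  expect_equal(ci$n_reads, 2L)
  expect_equal(ci$consensus_len, 600)       # union span of the pair
  expect_length(asm$singletons, 1)
})

test_that("reference trios encode retention, synteny and the planted inversion", {
  sv <- small_survey()
  p <- simParams(sv$config)
  # inversion only on the configured arm
  expect_null(sv$trios$S$inversion)
  expect_equal(sv$trios$L$inversion, p$inversion_interval)
  ot <- sv$trios$L$ortholog_truth
  inside <- ot$frac >= p$inversion_interval[1] &
    ot$frac < p$inversion_interval[2]
  # inverted block: A ranks reversed relative to wheat order
  expect_true(all(diff(ot$a_rank[inside]) < 0))
  expect_true(all(diff(ot$a_rank[!inside]) > 0))
  # retention limits: every retained B/C gene derives from an A gene
  expect_true(all(na.omit(ot$geneB) %in% sv$trios$L$genesB$info$gene_id))
  # degenerate retention edge: no species-B genes at retention 0
  cfg0 <- simulationConfig(seed = 9, arm_length = 1e5, n_genes = 4L,
                           n_hairpins = 2L, retention_B = 0)
  lib0 <- simulateLibrary(cfg0)
  a0 <- simulateArm(cfg0, "S", lib0)
  t0 <- simulateReferenceTrio(a0, cfg0)
  expect_equal(nrow(t0$genesB$info), 0)
})

test_that("markers land in the bin holding their fractional position", {
  sv <- small_survey()
  ann <- sv$annotation$S
  b <- bins(ann$binmap)
  mt <- ann$marker_truth
  for (k in seq_len(nrow(mt))) {
    bb <- b[b$bin == mt$bin[k], ]
    expect_true(bb$frac_start <= mt$frac[k] && mt$frac[k] < bb$frac_end)
  }
  # example: fraction 0.5 with bins [0,.4), [.4,.75), [.75,1) -> second bin
  cfg <- sv$config
  expect_identical(
    b$bin[b$frac_start <= 0.5 & 0.5 < b$frac_end], "S1-0.40-0.75")
})

test_that("homeolog unigene variants stay distinguishable at the 97% floor", {
  sv <- small_survey()
  ann <- sv$annotation$S
  ut <- ann$unigene_truth
  hom <- ut[ut$homeolog, ]
  expect_gt(nrow(hom), 0)
  for (k in seq_len(nrow(hom))) {
    a <- ann$unigenes[[hom$unigene_id[k]]]
    bseq <- sv$arms$S@library$gene_cds[[hom$gene_id[k]]]
    d <- mapply(function(x, y) x != y, strsplit(a, "")[[1]],
                strsplit(bseq, "")[[1]])
    ident <- 100 * (1 - mean(d))
    expect_lt(ident, 99.5)   # below the true copy
    expect_gt(ident, 95)     # but well alignable
  }
})
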