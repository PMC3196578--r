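test_that("window densities count distinct genes with truncated windows", {
  pos <- c(g1 = 10e3, g2 = 500e3, g3 = 1.2e6)
  tr <- windowDensity(pos, chromLen = 2e6)
  expect_equal(tr$density[tr$start == 0], 2)            # hand count
  expect_equal(nrow(windowDensity(numeric(), 1e6)),
               length(seq(0, 1e6 - 1, 2e4)))
  expect_true(all(windowDensity(numeric(), 1e6)$density == 0))
  # random positions equal a brute-force interval-count oracle
  set.seed(18)
  pos <- setNames(runif(80, 0, 3e6), paste0("g", 1:80))
  tr <- windowDensity(pos, 3e6, window = 5e5, step = 1e5)
  for (k in sample(nrow(tr), 10))
    expect_equal(tr$density[k],
                 sum(pos >= tr$start[k] & pos < tr$start[k] + 5e5))
  # conservation: non-overlapping windows partition the genes
  tr2 <- windowDensity(pos, 3e6, window = 5e5, step = 5e5)
  expect_equal(sum(tr2$density), length(pos))
  # duplicate gene ids count once (only the first window covers pos 100)
  dup <- c(g1 = 100, g1 = 200)
  expect_equal(sum(windowDensity(dup, 1e6)$density), 1)
})

test_that("syntenic region calling merges contiguous dense windows", {
  tr <- data.frame(chrom = "c", start = c(0, 2e4, 4e4, 6e4),
                   end = c(1e6, 1.02e6, 1.04e6, 1.06e6),
                   density = c(40, 60, 60, 40))
  got <- callSyntenicRegions(tr)
  expect_equal(nrow(got), 1)                    # one merged interval
  expect_equal(got$start, 2e4)
  expect_equal(got$end, 1.04e6)
  one <- callSyntenicRegions(data.frame(chrom = "c", start = 0, end = 1e6,
                                        density = 60))
  expect_equal(nrow(one), 1)
  none <- callSyntenicRegions(data.frame(chrom = "c", start = 0, end = 1e6,
                                         density = 49))
  expect_equal(nrow(none), 0)
})

# a controlled trio where every homology is exact and known
toy_trio <- function() {
  set.seed(19)
  nts <- vapply(rep(900, 4), rand_seq, character(1))
  genesA <- list(info = data.frame(gene_id = paste0("A", 1:4), chrom = "A4",
                                   pos = c(100, 200, 300, 400) * 1e3),
                 seq = setNames(nts, paste0("A", 1:4)))
  # B: homologs of A1..A3; A2's sits on a decoy chromosome
  genesB <- list(info = data.frame(gene_id = paste0("B", 1:3),
                                   chrom = c("O12", "O5", "O12"),
                                   pos = c(5, 9, 2) * 1e5),
                 seq = setNames(vapply(nts[1:3], mutate_frac, character(1),
                                       rate = 0.08), paste0("B", 1:3)))
  # C: homologs of A1 and A4 on the syntenic chromosome
  genesC <- list(info = data.frame(gene_id = paste0("C", c(1, 4)),
                                   chrom = "Sb8", pos = c(3, 7) * 1e5),
                 seq = setNames(vapply(nts[c(1, 4)], mutate_frac,
                                       character(1), rate = 0.08),
                                paste0("C", c(1, 4))))
  list(A = genesA, B = genesB, C = genesC)
}

test_that("zipper codes record syntenic placement and RBH orthology", {
  tt <- toy_trio()
  z <- buildZipper(tt$A, tt$B, tt$C, syntenicChromsB = "O12",
                   syntenicChromsC = "Sb8", minSeeds = 1L)
  e <- zipperEntries(z)
  expect_identical(e$gene_id, paste0("A", 1:4))   # ordered by position
  expect_identical(e$rank, 1:4)
  code <- setNames(e$code, e$gene_id)
  expect_identical(unname(code["A1"]), "O1S1(111)")  # all mutual, syntenic
  expect_identical(unname(code["A2"]), "O0S0(100)")  # decoy chrom, no C
  expect_identical(unname(code["A3"]), "O1S0(100)")
  expect_identical(unname(code["A4"]), "O0S1(010)")  # C only
  # genes with no homolog in B nor C are excluded
  tt$A$info <- rbind(tt$A$info, data.frame(gene_id = "A5", chrom = "A4",
                                           pos = 5e5))
  tt$A$seq <- c(tt$A$seq, A5 = rand_seq(900))
  z2 <- buildZipper(tt$A, tt$B, tt$C, "O12", "Sb8", minSeeds = 1L)
  expect_false("A5" %in% zipperEntries(z2)$gene_id)
  # syntenic intervals restrict the reference genes
  z3 <- buildZipper(tt$A, tt$B, tt$C, "O12", "Sb8",
                    intervalsA = data.frame(chrom = "A4", start = 0,
                                            end = 2.5e5), minSeeds = 1L)
  expect_identical(zipperEntries(z3)$gene_id, c("A1", "A2"))
})

test_that("zipper order is invariant under gene relabeling", {
  tt <- toy_trio()
  z1 <- buildZipper(tt$A, tt$B, tt$C, "O12", "Sb8", minSeeds = 1L)
  # relabel species-A genes (position-preserving)
  perm <- c(A1 = "gX", A2 = "gB", A3 = "gM", A4 = "gA")
  tt$A$info$gene_id <- unname(perm[tt$A$info$gene_id])
  names(tt$A$seq) <- unname(perm[names(tt$A$seq)])
  z2 <- buildZipper(tt$A, tt$B, tt$C, "O12", "Sb8", minSeeds = 1L)
  e1 <- zipperEntries(z1); e2 <- zipperEntries(z2)
  expect_identical(unname(perm[e1$gene_id]), e2$gene_id)
  expect_identical(e1$code, e2$code)
})

test_that("reads anchor to their own zipper gene; ties go to the lower rank", {
  tt <- toy_trio()
  z <- buildZipper(tt$A, tt$B, tt$C, "O12", "Sb8", minSeeds = 1L)
  reads <- c(rd1 = substr(tt$A$seq[["A3"]], 50, 400),
             far = rand_seq(350))
  z <- anchorReads(reads, z, tt$A$seq, minSeeds = 1L)
  an <- readAnchors(z)
  expect_identical(an$rank[an$read_id == "rd1"], 3L)
  expect_false("far" %in% an$read_id)             # below threshold anywhere
  st <- attr(z, "stats")
  expect_equal(st$n_anchored_reads, 1)
  # exact tie between two identical zipper genes -> lower rank, flagged
  dupA <- list(info = data.frame(gene_id = c("A1", "A2"), chrom = "A4",
                                 pos = c(1e5, 2e5)),
               seq = c(A1 = tt$A$seq[["A1"]], A2 = tt$A$seq[["A1"]]))
  zB <- buildZipper(dupA, tt$B, tt$C, "O12", "Sb8", minSeeds = 1L)
  zB <- anchorReads(c(r = substr(tt$A$seq[["A1"]], 10, 380)), zB, dupA$seq,
                    minSeeds = 1L)
  anB <- readAnchors(zB)
  expect_identical(anB$rank, 1L)
  expect_true(anB$ambiguous)
})

test_that("collinearity: contiguous bins are clean, displaced markers counted", {
  bm <- binMap(data.frame(bin = c("b1", "b2", "b3"), arm = "S",
                          frac_start = c(0, 0.3, 0.6),
                          frac_end = c(0.3, 0.6, 1)),
               data.frame(marker_id = paste0("m", 1:9),
                          bin = rep(c("b1", "b2", "b3"), each = 3)))
  z <- new("GenomeZipper", entries = data.frame(
    rank = 1:9, gene_id = paste0("g", 1:9), chrom = "A4",
    pos = (1:9) * 1e4, code = "O1S1(111)", O = 1L, S = 1L, h = 1L, y = 1L,
    z = 1L, stringsAsFactors = FALSE))
  z@markerAnchors <- data.frame(marker_id = paste0("m", 1:9), rank = 1:9,
                                bin = rep(c("b1", "b2", "b3"), each = 3),
                                stringsAsFactors = FALSE)
  cc <- collinearityCheck(z, bm)
  expect_equal(cc$outOfPlace, 0)                    # perfect collinearity
  expect_equal(nrow(cc$inversions), 0)
  # one b1 marker displaced beyond every other bin
  z2 <- z
  z2@markerAnchors$rank[z2@markerAnchors$marker_id == "m3"] <- 10L
  cc2 <- collinearityCheck(z2, bm)
  expect_equal(cc2$outOfPlace, 1)
  # a reversed tail of bins is flagged as an inversion candidate
  z3 <- z
  z3@markerAnchors$rank <- c(1:3, 7:9, 4:6)         # b3 before b2
  cc3 <- collinearityCheck(z3, bm)
  expect_equal(nrow(cc3$inversions), 1)
  expect_identical(cc3$inversions$from_bin, "b2")
  expect_identical(cc3$inversions$to_bin, "b3")
  # bins with < 2 markers are skipped with a warning
  bm2 <- binMap(bins(bm), data.frame(marker_id = c("m1", "m2", "m4"),
                                     bin = c("b1", "b1", "b2")))
  z4 <- z
  z4@markerAnchors <- data.frame(marker_id = c("m1", "m2", "m4"),
                                 rank = c(1L, 2L, 5L),
                                 bin = c("b1", "b1", "b2"),
                                 stringsAsFactors = FALSE)
  expect_warning(collinearityCheck(z4, bm2), "skipped")
})

test_that("cross-arm marker anchors are tallied per arm", {
  set.seed(20)
  mk <- c(estS = rand_seq(300), estL = rand_seq(300))
  bm <- binMap(data.frame(bin = c("binS", "binL"), arm = c("S", "L"),
                          frac_start = 0, frac_end = 1),
               data.frame(marker_id = c("estS", "estL"),
                          bin = c("binS", "binL")))
  reads <- c(sread = substr(mk[["estS"]], 10, 290),      # own arm
             lread = substr(mk[["estL"]], 10, 290),      # own arm
             xread = substr(mk[["estS"]], 5, 295))       # L read, S marker
  arms <- c(sread = "S", lread = "L", xread = "L")
  am <- anchorMarkers(reads, arms, mk, bm, minSeeds = 1L)
  rep <- am$armReport
  expect_equal(rep$own_frac_reads[rep$read_arm == "S"], 1)
  expect_equal(rep$cross_arm_reads[rep$read_arm == "L"], 1)
  expect_equal(rep$own_frac_reads[rep$read_arm == "L"], 0.5)
})

test_that("the Venn partition matches realized ortholog retention at gene level", {
  sv <- full_survey()
  cls <- full_classification()
  trio <- sv$trios$S
  labels <- cls$S$labels
  gene_reads <- names(labels)[labels == "GENE"]
  mg <- mapGeneReads(sv$reads$S$reads[gene_reads], trio$proteomes)
  # read -> source gene via planted exon truth
  tr <- plantedTruth(sv$arms$S)
  ex <- tr[S4Vectors::mcols(tr)$type == "exon"]
  org <- sv$reads$S$origin
  gene_of <- function(rid) {
    j <- match(rid, org$read_id)
    if (org$arm[j] != "S") return(NA_character_)
    ov <- which(GenomicRanges::start(ex) - 1 < org$end[j] &
                  GenomicRanges::end(ex) > org$start[j])
    if (!length(ov)) return(NA_character_)
    S4Vectors::mcols(ex)$feature_id[ov[1]]
  }
  # gene-level measured pattern: species where any read of the gene hit
  hits_of <- lapply(mg$bestHits, function(b) unique(hits(b)$query_id))
  venn_reads <- unique(unlist(hits_of))
  gmap <- vapply(venn_reads, gene_of, character(1))
  genes <- unique(na.omit(gmap))
  measured <- vapply(genes, function(g) {
    rds <- venn_reads[!is.na(gmap) & gmap == g]
    paste(names(hits_of)[vapply(hits_of, function(h)
      any(rds %in% h), logical(1))], collapse = "&")
  }, character(1))
  ot <- trio$ortholog_truth
  planted <- vapply(genes, function(g) {
    o <- ot[ot$wheat_gene == g, ]
    paste(c("A", if (!is.na(o$geneB)) "B", if (!is.na(o$geneC)) "C"),
          collapse = "&")
  }, character(1))
  cells <- union(unique(measured), unique(planted))
  for (cell in cells) {
    pm <- mean(measured == cell); pp <- mean(planted == cell)
    expect_lt(abs(pm - pp) * 100, 3, label = paste("Venn cell", cell))
  }
})
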