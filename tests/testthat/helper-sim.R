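# Cached simulation bundles shared across test files: a small two-arm
# survey for module tests and the full-scale survey used by the
# end-to-end acceptance checks.  Built once per test run.

.sim_cache <- new.env(parent = emptyenv())

small_survey <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- simulationConfig(seed = 11, arm_length = 4e5, n_genes = 8L,
                            n_hairpins = 6L)
    .sim_cache$small <- simulateSurvey(cfg)
  }
  .sim_cache$small
}

full_survey <- function() {
  if (is.null(.sim_cache$full)) {
    .sim_cache$full <- simulateSurvey(simulationConfig(seed = 42))
  }
  .sim_cache$full
}

full_classification <- function() {
  if (is.null(.sim_cache$full_cls)) {
    sv <- full_survey()
    .sim_cache$full_cls <- lapply(c(S = "S", L = "L"), function(arm) {
      classifyReads(sv$reads[[arm]]$reads,
                    repeatNtDb = sv$lib$repeat_nt,
                    repeatProtDb = sv$lib$repeat_prot,
                    viralProtDb = sv$lib$viral_prot,
                    geneProtDb = sv$arms[[arm]]@library$gene_prot,
                    geneEstDb = sv$arms[[arm]]@library$gene_cds,
                    contigs = sv$assemblies[[arm]]$contigs)
    })
  }
  .sim_cache$full_cls
}

# planted repeat fraction of an arm, by bases
planted_repeat_fraction <- function(armObj) {
  tr <- plantedTruth(armObj)
  rep_tr <- tr[S4Vectors::mcols(tr)$type %in% c("te", "unknown_repeat")]
  sum(IRanges::width(IRanges::reduce(IRanges::ranges(rep_tr)))) /
    length(armSeq(armObj))
}

# map a candidate/contig/singleton id back to arm coordinates
source_interval <- function(id, assembly, origin, arm) {
  co <- assembly$contigOrigin
  i <- match(id, co$contig_id)
  if (!is.na(i) && !is.na(co$arm[i]) && co$arm[i] == arm)
    return(c(co$start[i], co$end[i]))
  j <- match(id, origin$read_id)
  if (!is.na(j) && origin$arm[j] == arm)
    return(c(origin$start[j], origin$end[j]))
  NULL
}
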