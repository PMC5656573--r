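#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  The defaults
#' emulate the study design the pipeline targets: three cell states
#' (undifferentiated, osteogenically differentiated, differentiated under
#' TNF-alpha) with three biological replicates each, negative-binomial
#' counts with common dispersion 0.1, planted differential expression at
#' |log2 fold change| 2, and twenty planted ceRNA triplets whose members
#' share two miRNAs and at least nine seed sites.
#'
#' @param n_chromosomes Number of simulated chromosomes.
#' @param chrom_length Chromosome length in nt.  Must leave placement
#'   headroom; the generators error if genes cannot be placed.
#' @param n_coding_genes,n_known_lncrnas Reference gene counts.
#' @param n_novel_antisense,n_novel_intergenic,n_novel_intronic Planted
#'   novel lncRNAs per positional class.
#' @param n_decoy_coding,n_decoy_mono,n_decoy_short Planted decoys:
#'   multi-exon transcripts carrying a strong ORF, long mono-exonic
#'   transcripts, and multi-exon transcripts of spliced length <= 200 nt.
#' @param n_groups,n_samples_per_group Expression design.
#' @param n_de_genes Planted differentially expressed genes per contrast.
#' @param de_log2fc Absolute planted log2 fold change.
#' @param nb_dispersion Common negative-binomial dispersion alpha in
#'   `Var = mu + alpha * mu^2`.
#' @param n_cerna_triplets Planted lncRNA-mRNA-miRNA-pair triplets.
#' @param n_mirnas Simulated miRNAs (must be >= 2 * `n_cerna_triplets` so
#'   triplets get disjoint miRNA pairs).
#' @param seed Integer seed; fully determines every generator's output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 5e6,
                       n_coding_genes = 40L,
                       n_known_lncrnas = 15L,
                       n_novel_antisense = 4L,
                       n_novel_intergenic = 4L,
                       n_novel_intronic = 4L,
                       n_decoy_coding = 4L,
                       n_decoy_mono = 3L,
                       n_decoy_short = 3L,
                       n_groups = 3L,
                       n_samples_per_group = 3L,
                       n_de_genes = 12L,
                       de_log2fc = 2,
                       nb_dispersion = 0.1,
                       n_cerna_triplets = 6L,
                       n_mirnas = 12L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    n_coding_genes = as.integer(n_coding_genes),
    n_known_lncrnas = as.integer(n_known_lncrnas),
    n_novel_antisense = as.integer(n_novel_antisense),
    n_novel_intergenic = as.integer(n_novel_intergenic),
    n_novel_intronic = as.integer(n_novel_intronic),
    n_decoy_coding = as.integer(n_decoy_coding),
    n_decoy_mono = as.integer(n_decoy_mono),
    n_decoy_short = as.integer(n_decoy_short),
    n_groups = as.integer(n_groups),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_de_genes = as.integer(n_de_genes),
    de_log2fc = as.numeric(de_log2fc),
    nb_dispersion = as.numeric(nb_dispersion),
    n_cerna_triplets = as.integer(n_cerna_triplets),
    n_mirnas = as.integer(n_mirnas),
    seed = as.integer(seed)
  )
  counts <- unlist(cfg[grepl("^n_", names(cfg))])
  if (any(counts < 0)) abort("all counts in sim_config must be >= 0")
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (cfg$n_mirnas < 2L * cfg$n_cerna_triplets) {
    abort("n_mirnas must be at least 2 * n_cerna_triplets")
  }
  structure(cfg, class = "sim_config")
}

group_labels <- function(config) {
  if (config$n_groups == 3L) {
    c("uPDLSC", "dPDLSC", "TNFa_dPDLSC")
  } else {
    paste0("group", seq_len(config$n_groups))
  }
}
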