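#' Write a complete synthetic input bundle with planted truth
#'
#' Runs every generator in order — reference + genome, assembled
#' transcripts, counts, miRNAs, planted seed sites (written back into the
#' genome so FASTA/GTF extraction stays consistent) — and writes the
#' standard-format files a real analysis would start from, plus a JSON
#' truth sidecar.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, a list with the file paths (`$paths`) and the
#'   in-memory `truth`.
#' @export
simulate_bundle <- function(dir, config = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config)
  asm <- simulate_assembly(ref, config)
  genome <- asm$genome

  novel_ids <- asm$truth$transcript_id[asm$truth$role == "novel"]
  novel_spans <- asm$assembled$genes |> filter(.data$gene_id %in% novel_ids)
  count_genes <- bind_rows(
    ref$annotation$genes,
    novel_spans |> mutate(biotype = "lncRNA")
  )
  anti_ids <- asm$truth$transcript_id[
    asm$truth$role == "novel" & asm$truth$true_class == "x"
  ]
  sim_cnt <- simulate_counts(count_genes, config, cerna_lnc_exclude = anti_ids)

  mirnas <- simulate_mirnas(config$n_mirnas, config$seed)
  pairs <- sim_cnt$truth$cerna_pairs
  triplets <- pairs |>
    mutate(mirna_ids = map(.data$triplet, function(t) {
      mirnas$id[c(2L * t - 1L, 2L * t)]
    })) |>
    transmute(
      lncrna_id = .data$lncrna_gene, mrna_id = .data$mrna_gene,
      mirna_ids = .data$mirna_ids
    )

  # lncRNA transcript sequences keyed by gene id; antisense novels are
  # excluded from the MRE scrub because their exons intersect coding CDS
  lnc_gene_tx <- bind_rows(
    ref$annotation$exons |>
      filter(.data$gene_id %in% ref$annotation$genes$gene_id[
        ref$annotation$genes$biotype == "lncRNA"
      ]),
    asm$assembled$exons |> filter(.data$gene_id %in% novel_ids)
  )
  scrub_tx <- lnc_gene_tx |> filter(!.data$gene_id %in% anti_ids)
  lnc_seqs <- scrub_tx |>
    group_by(gene = .data$gene_id) |>
    group_modify(~ tibble(sequence = spliced_sequence(genome, .x))) |>
    ungroup() |>
    transmute(id = .data$gene, sequence = .data$sequence)

  cs <- ref$coding_structure
  coding_spliced_now <- map_chr(seq_len(nrow(cs)), function(i) {
    ex <- ref$annotation$exons |> filter(.data$transcript_id == cs$transcript_id[[i]])
    spliced_sequence(genome, ex)
  })
  utr_seqs <- tibble(
    id = cs$gene_id,
    sequence = substring(
      coding_spliced_now,
      nchar(coding_spliced_now) - cs$utr3 + 1L,
      nchar(coding_spliced_now)
    )
  )

  planted <- plant_mre_sites(lnc_seqs, utr_seqs, mirnas, triplets, config)

  # write edited sequences back into the genome
  chrom_chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  for (i in seq_len(nrow(planted$lnc_seqs))) {
    gid <- planted$lnc_seqs$id[[i]]
    ex <- scrub_tx |> filter(.data$gene_id == gid)
    chrom_chars[[ex$chrom[[1]]]] <- write_spliced(
      chrom_chars[[ex$chrom[[1]]]], ex, planted$lnc_seqs$sequence[[i]]
    )
  }
  for (i in seq_len(nrow(planted$utr_seqs))) {
    gid <- planted$utr_seqs$id[[i]]
    j <- match(gid, cs$gene_id)
    full <- coding_spliced_now[[j]]
    new_full <- paste0(
      substring(full, 1L, nchar(full) - cs$utr3[[j]]),
      planted$utr_seqs$sequence[[i]]
    )
    ex <- ref$annotation$exons |> filter(.data$transcript_id == cs$transcript_id[[j]])
    chrom_chars[[ex$chrom[[1]]]] <- write_spliced(
      chrom_chars[[ex$chrom[[1]]]], ex, new_full
    )
  }
  genome <- vapply(chrom_chars, paste, character(1), collapse = "")

  known_ann <- genome_annotation(
    genes = ref$annotation$genes |> filter(.data$biotype == "lncRNA"),
    exons = ref$annotation$exons |>
      filter(.data$gene_id %in% ref$annotation$genes$gene_id[
        ref$annotation$genes$biotype == "lncRNA"
      ])
  )

  paths <- list(
    genome_fa = file.path(dir, "genome.fa"),
    reference_gtf = file.path(dir, "reference.gtf"),
    assembled_gtf = file.path(dir, "assembled.gtf"),
    known_lncrna_gtf = file.path(dir, "known_lncrnas.gtf"),
    counts_tsv = file.path(dir, "counts.tsv"),
    samples_tsv = file.path(dir, "samples.tsv"),
    mirnas_fa = file.path(dir, "mirnas.fa"),
    utrs_fa = file.path(dir, "utrs.fa"),
    gene_sets_gmt = file.path(dir, "gene_sets.gmt"),
    truth_json = file.path(dir, "truth.json")
  )
  write_fasta(tibble(id = names(genome), sequence = unname(genome)), paths$genome_fa)
  write_gtf(ref$annotation, paths$reference_gtf)
  write_gtf(asm$assembled, paths$assembled_gtf)
  write_gtf(known_ann, paths$known_lncrna_gtf)
  write_counts(sim_cnt$counts, paths$counts_tsv)
  readr::write_tsv(sim_cnt$sample_sheet, paths$samples_tsv)
  write_fasta(mirnas, paths$mirnas_fa)
  write_fasta(planted$utr_seqs, paths$utrs_fa)

  # gene-set collection: one set of the planted ceRNA targets plus random
  # coding-gene sets, for the over-representation stage
  coding_ids <- ref$annotation$genes$gene_id[
    ref$annotation$genes$biotype == "protein_coding"
  ]
  gmt_sets <- with_seed(child_seed(config$seed, "gmt"), {
    sets <- lapply(1:5, function(i) sample(coding_ids, min(8L, length(coding_ids))))
    names(sets) <- paste0("RANDOM_SET_", 1:5)
    if (nrow(pairs) > 0) sets$CERNA_TARGETS <- unique(pairs$mrna_gene)
    sets
  })
  writeLines(
    map_chr(names(gmt_sets), function(nm) {
      paste(c(nm, "synthetic", gmt_sets[[nm]]), collapse = "\t")
    }),
    paths$gene_sets_gmt
  )

  truth <- list(
    assembled = asm$truth,
    de = sim_cnt$truth$de,
    contrasts = sim_cnt$truth$contrasts,
    size_factors = as.list(sim_cnt$truth$size_factors),
    cerna_pairs = pairs,
    mre_sites = planted$sites,
    triplet_mirnas = triplets |>
      mutate(mirna_ids = map_chr(.data$mirna_ids, paste, collapse = ","))
  )
  jsonlite::write_json(truth, paths$truth_json, dataframe = "rows", auto_unbox = TRUE)
  invisible(list(paths = paths, truth = truth, config = config))
}
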