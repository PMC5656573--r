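small_cfg <- function(seed = 1, ...) {
  sim_config(
    chrom_length = 1.5e6, n_coding_genes = 12, n_known_lncrnas = 5,
    n_novel_antisense = 2, n_novel_intergenic = 2, n_novel_intronic = 2,
    n_decoy_coding = 2, n_decoy_mono = 1, n_decoy_short = 1,
    n_de_genes = 6, n_cerna_triplets = 2, n_mirnas = 4, seed = seed, ...
  )
}

test_that("simulate_reference is deterministic and honours a zero-gene config", {
  cfg <- small_cfg(seed = 2)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation$exons, b$annotation$exons)

  cfg0 <- sim_config(
    n_coding_genes = 0, n_known_lncrnas = 0, chrom_length = 1e5,
    n_cerna_triplets = 0, n_mirnas = 0
  )
  r0 <- simulate_reference(cfg0)
  expect_equal(nrow(r0$annotation$genes), 0L)
  expect_equal(nchar(r0$genome[[1]]), 1e5)
})

test_that("every simulated coding transcript carries an ORF of at least 300 nt", {
  cfg <- small_cfg(seed = 5)
  ref <- simulate_reference(cfg)
  coding <- ref$annotation$genes$gene_id[ref$annotation$genes$biotype == "protein_coding"]
  seqs <- extract_transcript_sequences(ref$annotation, ref$genome)
  for (g in coding) {
    s <- seqs$sequence[seqs$gene_id == g]
    want <- oracle_orf(s)
    expect_gte(want$length, 300)
  }
  # known lncRNAs are ORF-poor: no ORF reaches 300 nt
  lnc <- ref$annotation$genes$gene_id[ref$annotation$genes$biotype == "lncRNA"]
  for (g in lnc) {
    s <- seqs$sequence[seqs$gene_id == g]
    o <- oracle_orf(s)
    expect_lt(ifelse(is.null(o), 0, o$length), 300)
  }
})

test_that("assembled plants satisfy their positional class by direct interval checks", {
  cfg <- small_cfg(seed = 9)
  ref <- simulate_reference(cfg)
  asm <- simulate_assembly(ref, cfg)
  coding_ex <- dplyr::semi_join(
    ref$annotation$exons,
    dplyr::filter(ref$annotation$genes, biotype == "protein_coding"),
    by = "gene_id"
  )
  truth <- asm$truth
  for (tid in truth$transcript_id[truth$true_class %in% "x"]) {
    ex <- dplyr::filter(asm$assembled$exons, transcript_id == tid)
    hit <- dplyr::filter(
      coding_ex, chrom %in% ex$chrom, strand != ex$strand[1]
    )
    overlaps <- any(mapply(
      function(s, e) any(s < hit$end & e > hit$start), ex$start, ex$end
    ))
    expect_true(overlaps, info = tid)
  }
  for (tid in truth$transcript_id[truth$decoy_type %in% "short"]) {
    ex <- dplyr::filter(asm$assembled$exons, transcript_id == tid)
    expect_lte(sum(ex$end - ex$start), 200)
  }
  for (tid in truth$transcript_id[truth$true_class %in% "u"]) {
    ex <- dplyr::filter(asm$assembled$exons, transcript_id == tid)
    g <- dplyr::filter(ref$annotation$genes, chrom == ex$chrom[1])
    gaps <- pmax(g$start - max(ex$end), min(ex$start) - g$end)
    expect_true(all(gaps >= 10000), info = tid)
  }
  # truth roles partition the non-reference assembled ids
  expect_setequal(truth$transcript_id, unique(asm$assembled$exons$transcript_id))
})

test_that("count simulation matches its declared null and planted-effect models", {
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:400), biotype = "protein_coding")
  cfg0 <- sim_config(n_de_genes = 0, de_log2fc = 0, n_cerna_triplets = 0,
                     n_mirnas = 0, seed = 19)
  sc0 <- simulate_counts(genes, cfg0)
  m <- sweep(sc0$counts, 2, sc0$truth$size_factors, "/")
  grp <- sc0$sample_sheet$group
  lr <- log2(rowMeans(m[, grp == "dPDLSC"]) + 0.5) -
    log2(rowMeans(m[, grp == "uPDLSC"]) + 0.5)
  expect_lt(abs(mean(lr)), 0.15)

  # determinism
  sc0b <- simulate_counts(genes, cfg0)
  expect_identical(sc0$counts, sc0b$counts)

  # planted lfc = 2: ratio of group sample means within [2, 8] with high
  # probability at n = 3, dispersion 0.1
  cfg2 <- sim_config(n_de_genes = 200, n_cerna_triplets = 0, n_mirnas = 0, seed = 23)
  sc2 <- simulate_counts(genes, cfg2)
  de1 <- dplyr::filter(sc2$truth$de, contrast == "dPDLSC_vs_uPDLSC") |>
    dplyr::filter(sc2$truth$mu[gene_id] >= 50) # well-expressed planted genes
  sfb <- sc2$truth$size_factors
  norm <- sweep(sc2$counts, 2, sfb, "/")
  ratio <- rowMeans(norm[de1$gene_id, sc2$sample_sheet$group == "dPDLSC"]) /
    rowMeans(norm[de1$gene_id, sc2$sample_sheet$group == "uPDLSC"])
  ratio_aligned <- ifelse(de1$true_log2fc > 0, ratio, 1 / ratio)
  expect_gte(mean(ratio_aligned >= 2 & ratio_aligned <= 8), 0.9)
})

test_that("simulate_counts validates its design preconditions", {
  genes <- tibble::tibble(gene_id = "g1", biotype = "protein_coding")
  expect_error(
    simulate_counts(genes, sim_config(n_groups = 1, n_cerna_triplets = 0, n_mirnas = 0)),
    "2 groups"
  )
  expect_error(
    simulate_counts(genes, sim_config(n_samples_per_group = 1, n_cerna_triplets = 0, n_mirnas = 0)),
    "replicates"
  )
})

test_that("plant_mre_sites writes recoverable sites and scrubs negatives", {
  set.seed(33)
  mirnas <- simulate_mirnas(6, seed = 3)
  lnc <- tibble::tibble(id = c("L1", "L2", "L3"),
    sequence = replicate(3, paste(sample(c("A","C","G","T"), 700, TRUE), collapse = "")))
  utr <- tibble::tibble(id = c("M1", "M2", "M3"),
    sequence = replicate(3, paste(sample(c("A","C","G","T"), 700, TRUE), collapse = "")))
  triplets <- tibble::tibble(
    lncrna_id = c("L1", "L2"), mrna_id = c("M1", "M2"),
    mirna_ids = list(mirnas$id[1:2], mirnas$id[3:4])
  )
  pl <- plant_mre_sites(lnc, utr, mirnas, triplets, sim_config(seed = 3))
  # every recorded site is found by the scanner at its position
  for (i in seq_len(nrow(pl$sites))) {
    rec <- pl$sites[i, ]
    seq_tab <- if (rec$molecule_type == "lncRNA") pl$lnc_seqs else pl$utr_seqs
    s <- seq_tab$sequence[seq_tab$id == rec$molecule_id]
    found <- find_seed_sites(s, mirnas$sequence[mirnas$id == rec$mirna_id], rec$mirna_id)
    expect_true(any(found$start == rec$start), info = paste(rec$molecule_id, rec$start))
  }
  # planted intervals do not overlap
  by_mol <- split(pl$sites, pl$sites$molecule_id)
  for (tab in by_mol) {
    tab <- tab[order(tab$start), ]
    if (nrow(tab) > 1) expect_true(all(diff(tab$start) >= 7))
  }
  # each planted pair carries >= 9 unique sites; negatives share <= 1 miRNA
  sites_l <- find_all_seed_sites(pl$lnc_seqs, mirnas)
  sites_u <- find_all_seed_sites(pl$utr_seqs, mirnas)
  for (t in seq_len(nrow(triplets))) {
    sl <- dplyr::filter(sites_l, target_id == triplets$lncrna_id[t])
    sm <- dplyr::filter(sites_u, target_id == triplets$mrna_id[t])
    shared <- intersect(unique(sl$mirna_id), unique(sm$mirna_id))
    expect_gte(length(shared), 2)
    expect_gte(count_unique_sites(sl, sm, shared), 9)
  }
  neg <- list(c("L1", "M2"), c("L2", "M1"), c("L3", "M3"), c("L3", "M1"))
  for (p in neg) {
    sl <- dplyr::filter(sites_l, target_id == p[1])
    sm <- dplyr::filter(sites_u, target_id == p[2])
    expect_lte(length(intersect(unique(sl$mirna_id), unique(sm$mirna_id))), 1)
  }
})
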