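ref_fixture <- function() {
  # one coding gene on chr1 (+) with exons [10,20) and [900,2000)-ish intron
  # structure, one lncRNA gene, one empty chromosome chr9
  exons <- dplyr::bind_rows(
    one_tx("pc.t", "chr1", "+", c(10, 2000), c(900, 2500), gid = "PC"),
    one_tx("lnc.t", "chr1", "-", c(50000, 51000), c(50200, 51300), gid = "LNC")
  )
  ann_from_exons(exons, c(PC = "protein_coding", LNC = "lncRNA"))
}

test_that("classification follows the sense > antisense > intronic > intergenic precedence", {
  ref <- ref_fixture()
  tx <- ann_from_exons(dplyr::bind_rows(
    one_tx("sense", "chr1", "+", 15, 25),        # overlaps coding exon, same strand
    one_tx("anti", "chr1", "-", 15, 25),         # opposite strand exon overlap
    one_tx("intronic", "chr1", "+", c(1000, 1200), c(1100, 1300)),
    one_tx("intergenic", "chr9", "+", c(10, 500), c(100, 600))
  ))
  codes <- classify_transcripts(tx, ref)
  got <- setNames(codes$class_code, codes$transcript_id)
  expect_equal(got[["sense"]], "sense_overlap")
  expect_equal(got[["anti"]], "x")
  expect_equal(got[["intronic"]], "i")
  expect_equal(got[["intergenic"]], "u")
})

test_that("antisense overlap with a known lncRNA also classifies as x", {
  ref <- ref_fixture()
  tx <- ann_from_exons(one_tx("t", "chr1", "+", 50100, 50180))
  expect_equal(classify_transcripts(tx, ref)$class_code, "x")
})

test_that("sense overlap with a known lncRNA does not discard (classifies by position)", {
  ref <- ref_fixture()
  tx <- ann_from_exons(one_tx("t", "chr1", "-", 50100, 50180))
  # same strand as the lncRNA: not sense_overlap (coding only), not antisense
  expect_equal(classify_transcripts(tx, ref)$class_code, "u")
})

test_that("classification agrees with the base-level brute-force oracle", {
  ref <- random_reference(30, seed = 101)
  tx <- random_transcripts(120, seed = 202)
  codes <- classify_transcripts(tx, ref)
  for (tid in codes$transcript_id) {
    ex <- dplyr::filter(tx$exons, transcript_id == tid)
    expect_equal(
      codes$class_code[codes$transcript_id == tid],
      oracle_classify_one(ex, ref),
      info = tid
    )
  }
})

test_that("retention filter applies class, exon-count and strict length rules in order", {
  ref <- ref_fixture()
  tx <- ann_from_exons(dplyr::bind_rows(
    one_tx("ok", "chr9", "+", c(0, 300), c(101, 400)),          # 201 nt, 2 ex
    one_tx("boundary200", "chr9", "+", c(1000, 1300), c(1100, 1400)), # exactly 200
    one_tx("mono", "chr9", "+", 5000, 10000),                   # 1 exon, long
    one_tx("sense_long", "chr1", "+", c(15, 300), c(120, 500))  # sense overlap
  ))
  codes <- classify_transcripts(tx, ref)
  filt <- filter_candidates(tx, codes)
  got <- setNames(filt$reason, filt$transcript_id)
  expect_true(filt$retained[filt$transcript_id == "ok"])
  expect_equal(got[["boundary200"]], "too_short")
  expect_equal(got[["mono"]], "too_few_exons")
  expect_equal(got[["sense_long"]], "sense_overlap")
  # rejection reason is the first failed test: a 1-exon sense overlap reports
  # the class, not the exon count
  tx2 <- ann_from_exons(one_tx("sense_mono", "chr1", "+", 15, 100))
  codes2 <- classify_transcripts(tx2, ref)
  expect_equal(filter_candidates(tx2, codes2)$reason, "sense_overlap")
})

test_that("relaxing filter parameters never removes a retained transcript", {
  ref <- random_reference(20, seed = 7)
  tx <- random_transcripts(80, seed = 8)
  codes <- classify_transcripts(tx, ref)
  base <- filter_candidates(tx, codes, min_exons = 2, min_length = 200)
  relaxed <- filter_candidates(tx, codes, min_exons = 1, min_length = 100)
  expect_true(all(
    base$transcript_id[base$retained] %in% relaxed$transcript_id[relaxed$retained]
  ))
})

test_that("catalog merge collapses identical intron chains, keeping the known identity", {
  known <- ann_from_exons(
    one_tx("KN1", "chr1", "+", c(100, 500, 900), c(200, 600, 1100)),
    c(KN1 = "lncRNA")
  )
  cand <- ann_from_exons(dplyr::bind_rows(
    # same intron chain as KN1, different terminal ends
    one_tx("c_dup", "chr1", "+", c(90, 500, 900), c(200, 600, 1200)),
    # one splice site shifted: distinct
    one_tx("c_new", "chr1", "+", c(100, 510, 900), c(200, 600, 1100))
  ))
  cat <- merge_with_known(cand, list(gencode = known))
  expect_equal(nrow(cat$records), 2L)
  expect_setequal(cat$records$transcript_id, c("KN1", "c_new"))
  expect_equal(
    cat$records$source[cat$records$transcript_id == "KN1"], "gencode"
  )
  expect_equal(
    cat$records$source[cat$records$transcript_id == "c_new"], "novel"
  )
})

test_that("nearest_gene uses closest-endpoint gaps with deterministic ties", {
  genes <- tibble::tibble(
    gene_id = c("far", "overlap", "left", "right"),
    chrom = "chr1", strand = "+",
    start = c(300, 150, 0, 300), end = c(400, 250, 50, 350),
    biotype = "protein_coding"
  )
  ref <- genome_annotation(genes, one_tx("x.t", "chr1", "+", c(0, 150, 300, 300), c(50, 250, 350, 400), gid = "far")[0, ])
  # overlap wins with distance 0
  span <- tibble::tibble(transcript_id = "q", chrom = "chr1", start = 100, end = 200)
  res <- nearest_gene(span, ref)
  expect_equal(res$nearest_gene, "overlap")
  expect_equal(res$nearest_gene_distance, 0)
  # equidistant genes: smaller start wins
  genes2 <- tibble::tibble(
    gene_id = c("b", "a"), chrom = "chr1", strand = "+",
    start = c(250, 0), end = c(300, 50), biotype = "protein_coding"
  )
  ref2 <- genome_annotation(genes2, one_tx("z", "chr1", "+", 1, 2)[0, ])
  span2 <- tibble::tibble(transcript_id = "q", chrom = "chr1", start = 100, end = 200)
  res2 <- nearest_gene(span2, ref2)
  expect_equal(res2$nearest_gene, "a")
  expect_equal(res2$nearest_gene_distance, 50)
  # no coding gene on the chromosome: error
  span3 <- tibble::tibble(transcript_id = "q", chrom = "chrZ", start = 0, end = 10)
  expect_error(nearest_gene(span3, ref2), "chrZ")
})

test_that("nearest_gene agrees with an exhaustive pairwise scan", {
  set.seed(55)
  genes <- tibble::tibble(
    gene_id = paste0("G", 1:50), chrom = sample(c("chr1", "chr2"), 50, TRUE),
    strand = "+", start = sample.int(5e5, 50)
  ) |> dplyr::mutate(end = start + sample(1000:20000, 50), biotype = "protein_coding")
  ref <- genome_annotation(genes, one_tx("d", "chr1", "+", 1, 2)[0, ])
  spans <- tibble::tibble(
    transcript_id = paste0("t", 1:200),
    chrom = sample(c("chr1", "chr2"), 200, TRUE),
    start = sample.int(5e5, 200)
  ) |> dplyr::mutate(end = start + sample(200:2000, 200))
  res <- nearest_gene(spans, ref)
  for (i in seq_len(nrow(spans))) {
    g <- genes[genes$chrom == spans$chrom[i], ]
    gaps <- pmax(0, pmax(g$start - spans$end[i], spans$start[i] - g$end))
    ord <- order(gaps, g$start, g$gene_id)
    expect_equal(res$nearest_gene[i], g$gene_id[ord[1]])
    expect_equal(res$nearest_gene_distance[i], gaps[ord[1]])
  }
})

test_that("nomenclature follows the LINC-/-AS grammar with start-ordered suffixes", {
  genes <- tibble::tibble(
    gene_id = c("PDE10A", "SGOL1"), chrom = "chr1", strand = "+",
    start = c(10000, 400000), end = c(20000, 420000), biotype = "protein_coding"
  )
  ref <- genome_annotation(genes, dplyr::bind_rows(
    one_tx("PDE10A.t", "chr1", "+", 10000, 20000, gid = "PDE10A"),
    one_tx("SGOL1.t", "chr1", "+", 400000, 420000, gid = "SGOL1")
  ))
  cand <- ann_from_exons(dplyr::bind_rows(
    one_tx("u1", "chr1", "+", c(30000, 31000), c(30400, 31500)),
    one_tx("u2", "chr1", "+", c(25000, 26000), c(25400, 26500)),
    one_tx("a1", "chr1", "-", c(405000, 407000), c(405200, 407300))
  ))
  cat <- merge_with_known(cand, list(), reference = ref)
  cat <- assign_nomenclature(cat, ref)
  nm <- setNames(cat$records$name, cat$records$transcript_id)
  # intergenic named LINC-<gene>-<k>, ordered by start: u2 before u1
  expect_equal(nm[["u2"]], "LINC-PDE10A-1")
  expect_equal(nm[["u1"]], "LINC-PDE10A-2")
  expect_equal(nm[["a1"]], "SGOL1-AS-1")
})
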