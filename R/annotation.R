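#' Genome annotation container
#'
#' A `genome_annotation` bundles two tibbles: `genes` (one row per gene:
#' `gene_id`, `chrom`, `strand`, `start`, `end`, `biotype`) and `exons`
#' (one row per exon: `transcript_id`, `gene_id`, `chrom`, `strand`,
#' `start`, `end`).  All coordinates are 0-based half-open `[start, end)`;
#' conversion from the 1-based inclusive GTF convention happens at the
#' I/O boundary and nowhere else.
#'
#' @param genes Tibble of genes. `biotype` must be one of
#'   `"protein_coding"`, `"lncRNA"`, `"other"`.
#' @param exons Tibble of exons.  Exons of one transcript must be sorted,
#'   non-overlapping and non-adjacent (introns of at least 1 nt).
#'
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genes, exons) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  need_g <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  need_e <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!all(need_g %in% names(genes))) {
    abort(paste0("`genes` must have columns: ", paste(need_g, collapse = ", ")))
  }
  if (!all(need_e %in% names(exons))) {
    abort(paste0("`exons` must have columns: ", paste(need_e, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in `genes`")
  if (!all(genes$strand %in% c("+", "-")) || !all(exons$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (any(exons$end <= exons$start)) abort("exon with end <= start")
  orphan <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphan) > 0) {
    abort(paste0("exons reference unknown gene_id: ", orphan[[1]]))
  }
  exons <- arrange(exons, .data$chrom, .data$transcript_id, .data$start)
  bad <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      ok = all(diff(.data$start) > 0) && all(head(.data$end, -1) < tail(.data$start, -1)),
      .groups = "drop"
    ) |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0(
      "exons of transcript ", bad$transcript_id[[1]],
      " overlap or touch (introns must be >= 1 nt)"
    ))
  }
  structure(list(genes = genes, exons = exons), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(
    "<genome_annotation> ", nrow(x$genes), " genes, ",
    length(unique(x$exons$transcript_id)), " transcripts, ",
    nrow(x$exons), " exons\n",
    sep = ""
  )
  invisible(x)
}

#' Per-transcript summary of an annotation
#'
#' @param annotation A `genome_annotation`.
#' @return Tibble with one row per transcript: id, gene, location, exon
#'   count and spliced (exon-sum) length.
#' @export
transcript_summary <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  annotation$exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(
      n_exons = n(), length = sum(.data$end - .data$start),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start)
}

#' @export
tidy.genome_annotation <- function(x, ...) x$exons

#' @export
glance.genome_annotation <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_transcripts = length(unique(x$exons$transcript_id)),
    n_exons = nrow(x$exons),
    n_chromosomes = length(unique(x$genes$chrom))
  )
}

#' Combine annotations
#'
#' @param ... `genome_annotation` objects with disjoint gene/transcript ids.
#' @return A `genome_annotation`.
#' @export
bind_annotations <- function(...) {
  anns <- list(...)
  genome_annotation(
    genes = bind_rows(lapply(anns, function(a) a$genes)),
    exons = bind_rows(lapply(anns, function(a) a$exons))
  )
}

# GRanges views of the container (internal; 1-based conversion localized here)
exons_granges <- function(annotation) {
  e <- annotation$exons
  GenomicRanges::GRanges(
    seqnames = e$chrom,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = e$strand,
    transcript_id = e$transcript_id,
    gene_id = e$gene_id
  )
}

genes_granges <- function(annotation) {
  g <- annotation$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand,
    gene_id = g$gene_id,
    biotype = g$biotype
  )
}

# gene table derived from exon rows (span covers all transcripts)
genes_from_exons <- function(exons, biotype) {
  exons |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    mutate(biotype = biotype) |>
    select("gene_id", "chrom", "strand", "start", "end", "biotype")
}
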