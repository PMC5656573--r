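#' Read a GTF annotation
#'
#' GTF coordinates (1-based, inclusive) are converted to the internal
#' 0-based half-open convention at this boundary.  Gene spans and biotypes
#' are taken from the exon rows (attribute `gene_biotype`, defaulting to
#' `"other"` when absent); transcripts that appear only on `transcript`
#' rows, with no exon rows, are dropped with a warning.  Unstranded (`.`)
#' exon rows are rejected: every downstream classification is
#' strand-aware.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes.
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  is_exon <- !is.na(md$type) & as.character(md$type) == "exon"
  if (!any(is_exon)) abort(paste0("no exon features in GTF: ", path))
  if (!is.null(md$transcript_id)) {
    tx_rows <- !is.na(md$type) & as.character(md$type) == "transcript"
    missing_tx <- setdiff(
      unique(md$transcript_id[tx_rows]),
      unique(md$transcript_id[is_exon])
    )
    missing_tx <- missing_tx[!is.na(missing_tx)]
    if (length(missing_tx) > 0) {
      warn(paste0(
        "dropping ", length(missing_tx),
        " transcript(s) without exon rows: ",
        paste(head(missing_tx, 5), collapse = ", ")
      ))
    }
  }
  ex <- gr[is_exon]
  emd <- S4Vectors::mcols(ex)
  strands <- as.character(GenomicRanges::strand(ex))
  if (any(strands == "*")) {
    abort("unstranded ('.') exon rows are not supported")
  }
  biotype <- if (!is.null(emd$gene_biotype)) {
    ifelse(is.na(emd$gene_biotype), "other", as.character(emd$gene_biotype))
  } else {
    rep("other", length(ex))
  }
  biotype[!biotype %in% c("protein_coding", "lncRNA")] <- "other"
  exons <- tibble(
    transcript_id = as.character(emd$transcript_id),
    gene_id = as.character(emd$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = strands,
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    biotype = biotype
  )
  genes <- exons |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      biotype = .data$biotype[[1]], .groups = "drop"
    ) |>
    select("gene_id", "chrom", "strand", "start", "end", "biotype")
  genome_annotation(genes, select(exons, -"biotype"))
}

# cheap structural scan so malformed rows fail with a line number,
# before rtracklayer sees the file
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) abort(paste0("GTF line ", i, ": fewer than 9 fields"))
    if (f[[3]] != "exon") next
    s <- suppressWarnings(as.integer(f[[4]]))
    e <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(s) || is.na(e)) abort(paste0("GTF line ", i, ": non-numeric coordinates"))
    if (e < s) abort(paste0("GTF line ", i, ": end (", e, ") < start (", s, ")"))
    if (!f[[7]] %in% c("+", "-")) {
      abort(paste0("GTF line ", i, ": unsupported strand '", f[[7]], "'"))
    }
  }
  invisible(TRUE)
}

#' Write an annotation as GTF
#'
#' Emits one `exon` row per exon, carrying `gene_id`, `transcript_id` and
#' `gene_biotype` attributes; internal 0-based half-open coordinates are
#' converted back to the 1-based inclusive GTF convention.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  e <- annotation$exons |>
    left_join(
      select(annotation$genes, "gene_id", "biotype"),
      by = "gene_id"
    ) |>
    arrange(.data$chrom, .data$start, .data$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = e$chrom,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = e$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lincnet",
    type = "exon",
    gene_id = e$gene_id,
    transcript_id = e$transcript_id,
    gene_biotype = e$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
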