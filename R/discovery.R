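#' Classify assembled transcripts against a reference annotation
#'
#' Assigns each transcript exactly one positional class, with precedence:
#' `sense_overlap` (any exonic base shared with a same-strand exon of a
#' reference protein-coding transcript) > `x` (antisense: exonic overlap
#' with an opposite-strand reference exon) > `i` (intronic: the transcript
#' span lies entirely inside a single intron of some reference transcript,
#' either strand) > `u` (intergenic).
#'
#' @param transcripts A [genome_annotation()] of assembled transcripts.
#' @param reference The reference [genome_annotation()] (biotypes used to
#'   restrict the sense test to protein-coding transcripts).
#' @return Tibble with `transcript_id`, `class_code` (one of
#'   `"sense_overlap"`, `"x"`, `"u"`, `"i"`).
#' @export
classify_transcripts <- function(transcripts, reference) {
  stopifnot(inherits(transcripts, "genome_annotation"))
  stopifnot(inherits(reference, "genome_annotation"))
  if (nrow(transcripts$exons) == 0) {
    abort("no exons in `transcripts`")
  }
  t_ex <- exons_granges(transcripts)
  tids <- unique(transcripts$exons$transcript_id)

  coding_tx <- reference$genes$gene_id[reference$genes$biotype == "protein_coding"]
  ref_ex_all <- exons_granges(reference)
  ref_ex_coding <- ref_ex_all[ref_ex_all$gene_id %in% coding_tx]

  # sense: strand-aware exon overlap with coding exons
  sense_hit <- GenomicRanges::findOverlaps(t_ex, ref_ex_coding, ignore.strand = FALSE)
  sense_ids <- unique(t_ex$transcript_id[S4Vectors::queryHits(sense_hit)])

  # antisense: opposite-strand exon overlap with any reference exon
  t_flip <- t_ex
  GenomicRanges::strand(t_flip) <- ifelse(
    as.character(GenomicRanges::strand(t_ex)) == "+", "-", "+"
  )
  anti_hit <- GenomicRanges::findOverlaps(t_flip, ref_ex_all, ignore.strand = FALSE)
  anti_ids <- unique(t_ex$transcript_id[S4Vectors::queryHits(anti_hit)])

  # intronic: span within a single intron of some reference transcript
  introns <- reference$exons |>
    group_by(.data$transcript_id, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      istart = list(head(.data$end, -1)), iend = list(tail(.data$start, -1)),
      .groups = "drop"
    ) |>
    unnest(c("istart", "iend"))
  intron_gr <- if (nrow(introns) > 0) {
    GenomicRanges::GRanges(
      introns$chrom, IRanges::IRanges(introns$istart + 1L, introns$iend)
    )
  } else {
    GenomicRanges::GRanges()
  }
  spans <- transcripts$exons |>
    group_by(.data$transcript_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  span_gr <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end)
  )
  within_hit <- GenomicRanges::findOverlaps(span_gr, intron_gr, type = "within")
  intronic_ids <- unique(spans$transcript_id[S4Vectors::queryHits(within_hit)])

  tibble(transcript_id = tids) |>
    mutate(class_code = case_when(
      .data$transcript_id %in% sense_ids ~ "sense_overlap",
      .data$transcript_id %in% anti_ids ~ "x",
      .data$transcript_id %in% intronic_ids ~ "i",
      TRUE ~ "u"
    ))
}

#' Retention filter for candidate lncRNAs
#'
#' A transcript is retained iff it is not a sense overlap, has at least
#' `min_exons` exons and a spliced (exon-sum) length strictly greater
#' than `min_length`.  The rejection reason is the first failed test in
#' the order class, exons, length.
#'
#' @param transcripts A [genome_annotation()] of classified transcripts.
#' @param class_codes Tibble from [classify_transcripts()].
#' @param min_exons Minimum exon count (default 2).
#' @param min_length Spliced-length threshold in nt (default 200, strict `>`).
#' @return Tibble: `transcript_id`, `class_code`, `n_exons`, `length`,
#'   `retained`, `reason` (`NA` when retained).
#' @export
filter_candidates <- function(transcripts, class_codes,
                              min_exons = 2L, min_length = 200L) {
  stopifnot(min_exons >= 1, min_length >= 0)
  transcript_summary(transcripts) |>
    inner_join(class_codes, by = "transcript_id") |>
    mutate(
      reason = case_when(
        .data$class_code == "sense_overlap" ~ "sense_overlap",
        .data$n_exons < min_exons ~ "too_few_exons",
        .data$length <= min_length ~ "too_short",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$reason)
    ) |>
    select(
      "transcript_id", "class_code", "n_exons", "length", "retained", "reason"
    )
}

intron_chain_key <- function(exons) {
  exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      key = if (n() == 1) {
        paste0(
          .data$chrom[[1]], ":", .data$strand[[1]], ":mono:",
          .data$start[[1]], "-", .data$end[[1]]
        )
      } else {
        paste0(
          .data$chrom[[1]], ":", .data$strand[[1]], ":",
          paste(head(.data$end, -1), tail(.data$start, -1),
            sep = "-", collapse = ","
          )
        )
      },
      .groups = "drop"
    )
}

#' Merge candidate lncRNAs with known catalogs
#'
#' Two transcripts are duplicates iff they have an identical
#' (chromosome, strand, intron chain); duplicates collapse keeping the
#' known-catalog identity.  Candidates surviving as non-duplicates are
#' labelled `source = "novel"`.
#'
#' @param candidates A [genome_annotation()] of retained candidates.
#' @param known_catalogs Named list of [genome_annotation()] objects
#'   (e.g. `list(gencode = ..., lncipedia = ...)`).
#' @param reference Reference annotation, used to (re)classify every
#'   catalog member so nomenclature can be assigned uniformly.
#' @return An `lncrna_catalog`: list with `records` tibble
#'   (`transcript_id`, `class_code`, `source`, `n_exons`, `length`) and
#'   `annotation` holding the merged exon structures.
#' @export
merge_with_known <- function(candidates, known_catalogs = list(), reference = NULL) {
  stopifnot(inherits(candidates, "genome_annotation"))
  if (length(known_catalogs) > 0 && is.null(names(known_catalogs))) {
    names(known_catalogs) <- paste0("catalog", seq_along(known_catalogs))
  }
  cand_keys <- intron_chain_key(candidates$exons) |> mutate(source = "novel")
  known_keys <- imap(known_catalogs, function(ann, nm) {
    intron_chain_key(ann$exons) |> mutate(source = nm)
  }) |> list_rbind()
  all_keys <- bind_rows(known_keys, cand_keys) # known first: wins dedupe
  merged <- all_keys |> distinct(.data$key, .keep_all = TRUE)

  all_exons <- bind_rows(
    c(lapply(known_catalogs, function(a) a$exons), list(candidates$exons))
  ) |> filter(.data$transcript_id %in% merged$transcript_id)
  annotation <- genome_annotation(
    genes = genes_from_exons(all_exons, biotype = "lncRNA"),
    exons = all_exons
  )
  records <- transcript_summary(annotation) |>
    inner_join(select(merged, "transcript_id", "source"), by = "transcript_id")
  if (!is.null(reference)) {
    codes <- classify_transcripts(annotation, reference)
    records <- left_join(records, codes, by = "transcript_id")
  } else {
    records$class_code <- NA_character_
  }
  structure(
    list(
      records = select(
        records, "transcript_id", "gene_id", "chrom", "strand", "start",
        "end", "n_exons", "length", "source", "class_code"
      ),
      annotation = annotation
    ),
    class = "lncrna_catalog"
  )
}

#' @export
print.lncrna_catalog <- function(x, ...) {
  cat(
    "<lncrna_catalog> ", nrow(x$records), " lncRNAs (",
    sum(x$records$source == "novel"), " novel)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.lncrna_catalog <- function(x, ...) x$records

#' @export
glance.lncrna_catalog <- function(x, ...) {
  tibble(
    n_lncrnas = nrow(x$records),
    n_novel = sum(x$records$source == "novel"),
    n_known = sum(x$records$source != "novel")
  )
}

#' Nearest protein-coding gene for genomic spans
#'
#' Distance is the gap between the closest endpoints of the span and the
#' gene body (0 when they overlap).  Ties are broken by smaller gene
#' start, then lexicographically by gene id.  Errors if the span's
#' chromosome carries no protein-coding gene.
#'
#' @param spans Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and an id column `transcript_id`.
#' @param reference Reference [genome_annotation()].
#' @return `spans` with `nearest_gene` and `nearest_gene_distance` added.
#' @export
nearest_gene <- function(spans, reference) {
  coding <- filter(reference$genes, .data$biotype == "protein_coding")
  if (nrow(coding) == 0) abort("no protein-coding gene in the reference")
  res <- pmap(
    list(spans$chrom, spans$start, spans$end),
    function(chrom, s, e) {
      g <- filter(coding, .data$chrom == !!chrom)
      if (nrow(g) == 0) {
        abort(paste0("no protein-coding gene on chromosome ", chrom))
      }
      gap <- pmax(0, pmax(g$start - e, s - g$end))
      g2 <- g[order(gap, g$start, g$gene_id), ]
      tibble(nearest_gene = g2$gene_id[[1]], nearest_gene_distance = sort(gap)[[1]])
    }
  ) |> list_rbind()
  bind_cols(spans, res)
}

#' Assign nomenclature to an lncRNA catalog
#'
#' Intergenic lncRNAs are named `LINC-<nearest coding gene>-<k>`;
#' antisense and intronic lncRNAs `<nearest coding gene>-AS-<k>`, where
#' `k` is the 1-based index among same-named lncRNAs ordered by start
#' coordinate.
#'
#' @param catalog An `lncrna_catalog` from [merge_with_known()].
#' @param reference Reference [genome_annotation()].
#' @return The catalog with `name`, `nearest_gene`,
#'   `nearest_gene_distance` added to its records.
#' @export
assign_nomenclature <- function(catalog, reference) {
  stopifnot(inherits(catalog, "lncrna_catalog"))
  recs <- nearest_gene(catalog$records, reference)
  recs <- recs |>
    mutate(
      base_name = if_else(
        !is.na(.data$class_code) & .data$class_code == "u",
        paste0("LINC-", .data$nearest_gene),
        paste0(.data$nearest_gene, "-AS")
      )
    ) |>
    group_by(.data$base_name) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(name = paste0(.data$base_name, "-", row_number())) |>
    ungroup() |>
    arrange(.data$chrom, .data$start) |>
    select(-"base_name")
  catalog$records <- recs
  catalog
}
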