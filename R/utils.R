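#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(
    x,
    function(s) {
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = ""
      )
    },
    character(1),
    USE.NAMES = FALSE
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Extract the spliced (exon-concatenated) sequence of one transcript from a
# named vector of chromosome sequences; minus-strand transcripts are
# reverse-complemented as a whole.
spliced_sequence <- function(genome, exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  chrom_seq <- genome[[exons$chrom[[1]]]]
  parts <- substring(chrom_seq, exons$start + 1L, exons$end)
  s <- paste(parts, collapse = "")
  if (exons$strand[[1]] == "-") s <- revcomp(s) # nolint
  s
}

#' Spliced sequences for every transcript of an annotation
#'
#' @param annotation A [genome_annotation()].
#' @param genome Named character vector (or tibble from [read_fasta()]) of
#'   chromosome sequences.
#' @return Tibble with columns `transcript_id`, `gene_id`, `sequence`.
#' @export
extract_transcript_sequences <- function(annotation, genome) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  annotation$exons |>
    group_by(.data$transcript_id, .data$gene_id) |>
    group_modify(~ tibble(sequence = spliced_sequence(genome, .x))) |>
    ungroup()
}

# Periodic motif containing stop codons in all three reading frames
# (TAG at offsets 0, 4, 8).  Injected into simulated noncoding loci so no
# long ORF can survive.
STOP_MOTIF <- "TAGCTAGCTAGC"

# Interleave random sequence with the all-frame stop motif so that no ORF
# longer than ~gap + 2*motif can occur in any frame.
orf_poor_dna <- function(n, gap = 36L) {
  unit <- nchar(STOP_MOTIF) + gap
  n_units <- ceiling(n / unit) + 1L
  s <- paste(
    vapply(
      seq_len(n_units),
      function(i) paste0(random_dna(gap), STOP_MOTIF),
      character(1)
    ),
    collapse = ""
  )
  substr(s, 1L, n)
}

# deterministic child seed from a master seed and a stream label
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (seed * 7919L + h) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
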