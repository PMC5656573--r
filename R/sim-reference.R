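STOP_CODONS <- c("TAA", "TAG", "TGA")

# split length L into k parts, each >= min_len
partition_len <- function(L, k, min_len) {
  if (k == 1) return(L)
  free <- L - k * min_len
  if (free < 0) abort("length too short to partition")
  cuts <- sort(sample.int(free + 1L, k - 1L, replace = TRUE) - 1L)
  diff(c(0L, cuts, free)) + min_len
}

# codon string of n codons with no stop codon
nonstop_codons <- function(n) {
  codons <- apply(
    expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("A", "C", "G", "T")),
    1, paste, collapse = ""
  )
  codons <- setdiff(codons, STOP_CODONS)
  paste(sample(codons, n, replace = TRUE), collapse = "")
}

# spliced sequence of a protein-coding transcript: ORF-poor UTRs flanking a
# long in-frame ORF
coding_spliced <- function(utr5, orf_len, utr3) {
  stopifnot(orf_len %% 3 == 0, orf_len >= 300)
  orf <- paste0("ATG", nonstop_codons(orf_len / 3 - 2), sample(STOP_CODONS, 1))
  paste0(orf_poor_dna(utr5), orf, orf_poor_dna(utr3))
}

# write a spliced sequence into chromosome character vectors at the exon
# positions of one transcript (exons: tibble with start/end/strand, genomic
# order); returns the modified char vector
write_spliced <- function(chrom_chars, exons, spliced) {
  exons <- exons[order(exons$start), , drop = FALSE]
  genomic <- if (exons$strand[[1]] == "-") revcomp(spliced) else spliced
  widths <- exons$end - exons$start
  offs <- cumsum(c(0, widths))
  for (i in seq_len(nrow(exons))) {
    part <- substr(genomic, offs[i] + 1L, offs[i + 1L])
    chrom_chars[(exons$start[i] + 1L):exons$end[i]] <-
      strsplit(part, "", fixed = TRUE)[[1]]
  }
  chrom_chars
}

# draw an exon/intron architecture; returns list(exon_lens, intron_lens)
draw_architecture <- function(spliced_len, n_exons, min_exon = 60L,
                              intron_range = c(1500L, 3000L)) {
  list(
    exon_lens = partition_len(spliced_len, n_exons, min_exon),
    intron_lens = if (n_exons > 1) {
      sample(intron_range[1]:intron_range[2], n_exons - 1L, replace = TRUE)
    } else {
      integer()
    }
  )
}

exon_tbl_from_arch <- function(transcript_id, gene_id, chrom, strand,
                               gene_start, arch) {
  k <- length(arch$exon_lens)
  starts <- integer(k)
  pos <- gene_start
  ends <- integer(k)
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + arch$exon_lens[i]
    pos <- ends[i] + if (i < k) arch$intron_lens[i] else 0L
  }
  tibble(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, start = starts, end = ends
  )
}

#' Simulate a genome and reference annotation
#'
#' Generates an i.i.d.-uniform background genome and places non-overlapping
#' genes on it: protein-coding genes whose multi-exon transcripts carry a
#' long in-frame ORF (>= 300 nt) written into the genome, and known
#' lncRNAs that are multi-exon and ORF-poor (a stop-codon motif covering
#' all three frames is injected at most every ~50 nt).  Inter-gene gaps
#' mix short (cis-range) and long (trans-range) distances so co-expression
#' distance classes are all represented.  Fully deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector of chromosome
#'   sequences), `annotation` (a [genome_annotation()]; biotypes
#'   `protein_coding` / `lncRNA`), and `coding_structure` (tibble of
#'   per-coding-transcript UTR/ORF lengths, used downstream to locate
#'   3'UTRs).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "reference"), {
    n_genes <- config$n_coding_genes + config$n_known_lncrnas
    gene_ids <- c(
      sprintf("PCG%d", seq_len(config$n_coding_genes)),
      sprintf("KLNC%d", seq_len(config$n_known_lncrnas))
    )
    biotypes <- c(
      rep("protein_coding", config$n_coding_genes),
      rep("lncRNA", config$n_known_lncrnas)
    )
    ord <- sample.int(max(n_genes, 1L))
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    chrom_chars <- lapply(chroms, function(c) {
      sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE)
    })
    names(chrom_chars) <- chroms

    exons_all <- list()
    genes_all <- list()
    cs_all <- list()
    if (n_genes > 0) {
      chrom_of <- rep(chroms, length.out = n_genes)
      cursor <- setNames(rep(20000, length(chroms)), chroms)
      for (k in seq_len(n_genes)) {
        i <- ord[k]
        gid <- gene_ids[i]
        bt <- biotypes[i]
        chrom <- chrom_of[k]
        strand <- sample(c("+", "-"), 1)
        if (bt == "protein_coding") {
          utr5 <- sample(60:150, 1)
          orf_len <- 3L * sample(110:220, 1)
          utr3 <- sample(600:1000, 1)
          spliced_len <- utr5 + orf_len + utr3
          n_exons <- sample(3:5, 1)
        } else {
          spliced_len <- sample(300:1200, 1)
          n_exons <- sample(2:4, 1)
        }
        arch <- draw_architecture(spliced_len, n_exons)
        gap <- if (runif(1) < 0.75) {
          sample(2000:40000, 1)
        } else {
          sample(120000:250000, 1)
        }
        gene_start <- cursor[[chrom]] + gap
        span <- sum(arch$exon_lens) + sum(arch$intron_lens)
        if (gene_start + span > config$chrom_length - 20000) {
          abort(paste0(
            "cannot place gene ", gid, " on ", chrom,
            "; increase chrom_length"
          ))
        }
        cursor[[chrom]] <- gene_start + span
        tid <- paste0(gid, ".t1")
        ex <- exon_tbl_from_arch(tid, gid, chrom, strand, gene_start, arch)
        spliced <- if (bt == "protein_coding") {
          cs_all[[gid]] <- tibble(
            transcript_id = tid, gene_id = gid,
            utr5 = utr5, orf = orf_len, utr3 = utr3
          )
          coding_spliced(utr5, orf_len, utr3)
        } else {
          orf_poor_dna(spliced_len)
        }
        chrom_chars[[chrom]] <- write_spliced(chrom_chars[[chrom]], ex, spliced)
        exons_all[[gid]] <- ex
        genes_all[[gid]] <- tibble(
          gene_id = gid, chrom = chrom, strand = strand,
          start = gene_start, end = gene_start + span, biotype = bt
        )
      }
    }
    genome <- vapply(chrom_chars, paste, character(1), collapse = "")
    annotation <- genome_annotation(
      genes = if (length(genes_all)) bind_rows(genes_all) else empty_genes(),
      exons = if (length(exons_all)) bind_rows(exons_all) else empty_exons()
    )
    list(
      genome = genome,
      annotation = annotation,
      coding_structure = if (length(cs_all)) bind_rows(cs_all) else empty_coding_structure()
    )
  })
}

empty_genes <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), biotype = character()
  )
}

empty_exons <- function() {
  tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer()
  )
}

empty_coding_structure <- function() {
  tibble(
    transcript_id = character(), gene_id = character(),
    utr5 = integer(), orf = integer(), utr3 = integer()
  )
}

#' Simulate labelled coding / noncoding training sequences
#'
#' Standalone sequence sets (no genome needed) for training the
#' coding-potential classifiers: coding sequences are ORF-poor UTRs around
#' a long in-frame ORF, noncoding sequences are ORF-poor throughout.
#'
#' @param n_each Sequences per class.
#' @param seed Integer seed.
#' @return Tibble with `id`, `sequence`, `label` (`"coding"`/`"noncoding"`).
#' @export
simulate_codpot_training <- function(n_each = 150L, seed = 1L) {
  with_seed(child_seed(seed, "codpot_training"), {
    coding <- map_chr(seq_len(n_each), function(i) {
      coding_spliced(
        sample(40:200, 1), 3L * sample(100:400, 1), sample(100:500, 1)
      )
    })
    noncoding <- map_chr(seq_len(n_each), function(i) {
      orf_poor_dna(sample(220:2000, 1))
    })
    tibble(
      id = c(sprintf("COD%d", seq_len(n_each)), sprintf("NONC%d", seq_len(n_each))),
      sequence = c(coding, noncoding),
      label = rep(c("coding", "noncoding"), each = n_each)
    )
  })
}
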