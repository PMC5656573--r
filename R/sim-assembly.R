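# interval [s,e) intersects any of a set of intervals?
hits_any <- function(s, e, starts, ends) {
  any(s < ends & e > starts)
}

#' Simulate an assembled transcriptome with planted truth
#'
#' Emulates the output of a de novo transcriptome assembly compared
#' against the reference: copies of reference transcripts (sense overlaps
#' and known-lncRNA duplicates), planted novel lncRNAs of the three
#' positional classes (antisense = exonic overlap on the opposite strand;
#' intergenic = >= 10 kb from any gene; intronic = span fully inside one
#' intron of a coding gene), and decoys (multi-exon transcripts carrying a
#' strong ORF, long mono-exonic transcripts, and multi-exon transcripts of
#' spliced length <= 200 nt).  Novel-lncRNA and decoy loci are written
#' into the genome (ORF-poor sequence for noncoding plants, a long ORF for
#' coding decoys), so the returned, edited genome supersedes the input
#' genome.
#'
#' @param reference Output of [simulate_reference()].
#' @param config The same [sim_config()].
#' @return List with `assembled` (a [genome_annotation()]; one gene per
#'   assembled transcript), `truth` (tibble: `transcript_id`, `role`,
#'   `true_class`, `decoy_type`), and `genome` (edited named character
#'   vector).
#' @export
simulate_assembly <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- reference$annotation
  with_seed(child_seed(config$seed, "assembly"), {
    chrom_chars <- lapply(reference$genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    genes <- ann$genes
    coding <- filter(genes, .data$biotype == "protein_coding")
    known <- filter(genes, .data$biotype == "lncRNA")
    exons_of <- function(gid) filter(ann$exons, .data$gene_id == gid) |> arrange(.data$start)

    out_exons <- list()
    truth <- list()
    occ <- list() # extra occupied intervals per chrom (novel/decoy loci)
    add_occ <- function(chrom, s, e) {
      occ[[chrom]] <<- bind_rows(occ[[chrom]], tibble(start = s, end = e))
    }
    add_tx <- function(tid, ex, role, true_class = NA_character_,
                       decoy_type = NA_character_) {
      out_exons[[tid]] <<- mutate(ex, transcript_id = tid, gene_id = tid)
      truth[[tid]] <<- tibble(
        transcript_id = tid, role = role,
        true_class = true_class, decoy_type = decoy_type
      )
    }

    # --- copies of reference transcripts -------------------------------
    n_pc_copy <- min(4L, nrow(coding))
    if (n_pc_copy > 0) {
      for (i in seq_len(n_pc_copy)) {
        ex <- exons_of(coding$gene_id[[i]])
        add_tx(paste0("ASM_PC_", i), select(ex, -"transcript_id", -"gene_id"),
          role = "sense_copy"
        )
      }
    }
    n_kn_copy <- min(3L, nrow(known))
    if (n_kn_copy > 0) {
      for (i in seq_len(n_kn_copy)) {
        ex <- exons_of(known$gene_id[[i]])
        add_tx(paste0("ASM_KN_", i), select(ex, -"transcript_id", -"gene_id"),
          role = "known_copy"
        )
      }
    }

    # --- planted novels ------------------------------------------------
    need_host <- config$n_novel_antisense + config$n_novel_intronic
    if (need_host > nrow(coding)) {
      abort("reference too sparse: not enough coding genes to host antisense/intronic plants")
    }
    host_ids <- sample(coding$gene_id, need_host)
    anti_hosts <- head(host_ids, config$n_novel_antisense)
    intr_hosts <- tail(host_ids, config$n_novel_intronic)

    flip <- function(s) if (s == "+") "-" else "+"

    for (i in seq_along(anti_hosts)) {
      g <- filter(coding, .data$gene_id == anti_hosts[[i]])
      ex <- exons_of(g$gene_id)
      host_exon <- ex[1, ]
      if (host_exon$end - host_exon$start < 70) host_exon <- ex[which.max(ex$end - ex$start), ]
      e1s <- host_exon$start + 5L
      e1e <- e1s + 60L
      intron_start <- host_exon$end
      e2s <- intron_start + 200L
      e2e <- e2s + sample(180:280, 1)
      e3s <- e2e + sample(150:250, 1)
      e3e <- e3s + sample(150:250, 1)
      tid <- paste0("NOV_X_", i)
      ex_tbl <- tibble(
        chrom = g$chrom, strand = flip(g$strand),
        start = c(e1s, e2s, e3s), end = c(e1e, e2e, e3e)
      )
      add_tx(tid, ex_tbl, role = "novel", true_class = "x")
      # ORF-scrub only the intronic exons; the exon inside the coding exon
      # stays untouched (it belongs to the host gene's CDS)
      intronic_part <- tibble(
        chrom = g$chrom, strand = ex_tbl$strand[[1]],
        start = c(e2s, e3s), end = c(e2e, e3e)
      )
      spl2 <- orf_poor_dna((e2e - e2s) + (e3e - e3s))
      chrom_chars[[g$chrom]] <- write_spliced(
        chrom_chars[[g$chrom]], intronic_part, spl2
      )
    }

    for (i in seq_along(intr_hosts)) {
      g <- filter(coding, .data$gene_id == intr_hosts[[i]])
      ex <- exons_of(g$gene_id)
      istart <- ex$end[[1]]
      iend <- ex$start[[2]]
      if (iend - istart < 1200) abort("reference too sparse for intronic placement")
      e1s <- istart + 300L
      e1e <- e1s + sample(150:220, 1)
      e2s <- e1e + sample(150:250, 1)
      e2e <- e2s + sample(150:220, 1)
      if (e2e > iend - 50L) abort("reference too sparse for intronic placement")
      strand <- sample(c("+", "-"), 1)
      tid <- paste0("NOV_I_", i)
      ex_tbl <- tibble(
        chrom = g$chrom, strand = strand,
        start = c(e1s, e2s), end = c(e1e, e2e)
      )
      add_tx(tid, ex_tbl, role = "novel", true_class = "i")
      spl <- orf_poor_dna((e1e - e1s) + (e2e - e2s))
      chrom_chars[[g$chrom]] <- write_spliced(chrom_chars[[g$chrom]], ex_tbl, spl)
    }

    place_free <- function(span, clearance_genes, clearance_occ = 200L) {
      for (try in seq_len(500L)) {
        chrom <- sample(names(chrom_chars), 1)
        pos <- as.integer(floor(runif(1, 20000, config$chrom_length - 20000 - span)))
        g_here <- filter(genes, .data$chrom == !!chrom)
        if (hits_any(
          pos - clearance_genes, pos + span + clearance_genes,
          g_here$start, g_here$end
        )) {
          next
        }
        o <- occ[[chrom]]
        if (!is.null(o) && nrow(o) > 0 &&
          hits_any(pos - clearance_occ, pos + span + clearance_occ, o$start, o$end)) {
          next
        }
        return(list(chrom = chrom, pos = pos))
      }
      abort("placement failure after bounded retries; increase chrom_length")
    }

    plant_intergenic_like <- function(tid, spliced, arch, clearance, role,
                                      true_class = NA_character_,
                                      decoy_type = NA_character_) {
      span <- sum(arch$exon_lens) + sum(arch$intron_lens)
      loc <- place_free(span, clearance)
      strand <- sample(c("+", "-"), 1)
      ex_tbl <- exon_tbl_from_arch(tid, tid, loc$chrom, strand, loc$pos, arch) |>
        select("chrom", "strand", "start", "end")
      add_tx(tid, ex_tbl, role = role, true_class = true_class, decoy_type = decoy_type)
      add_occ(loc$chrom, loc$pos, loc$pos + span)
      chrom_chars[[loc$chrom]] <<- write_spliced(chrom_chars[[loc$chrom]], ex_tbl, spliced)
    }

    for (i in seq_len(config$n_novel_intergenic)) {
      L <- sample(400:900, 1)
      arch <- draw_architecture(L, sample(2:3, 1),
        min_exon = 100L, intron_range = c(200L, 600L)
      )
      plant_intergenic_like(paste0("NOV_U_", i), orf_poor_dna(L), arch,
        clearance = 10000L, role = "novel", true_class = "u"
      )
    }

    # --- decoys --------------------------------------------------------
    for (i in seq_len(config$n_decoy_coding)) {
      utr5 <- 60L
      orf_len <- 3L * sample(140:180, 1)
      utr3 <- 120L
      L <- utr5 + orf_len + utr3
      arch <- draw_architecture(L, sample(2:3, 1),
        min_exon = 100L, intron_range = c(200L, 600L)
      )
      plant_intergenic_like(paste0("DEC_ORF_", i),
        coding_spliced(utr5, orf_len, utr3), arch,
        clearance = 2000L, role = "decoy", decoy_type = "coding_orf"
      )
    }
    for (i in seq_len(config$n_decoy_mono)) {
      L <- 1000L
      arch <- list(exon_lens = L, intron_lens = integer())
      plant_intergenic_like(paste0("DEC_MONO_", i), orf_poor_dna(L), arch,
        clearance = 2000L, role = "decoy", decoy_type = "mono_exonic"
      )
    }
    for (i in seq_len(config$n_decoy_short)) {
      arch <- list(exon_lens = c(90L, 100L), intron_lens = 300L)
      plant_intergenic_like(paste0("DEC_SHORT_", i), orf_poor_dna(190L), arch,
        clearance = 2000L, role = "decoy", decoy_type = "short"
      )
    }

    exons <- bind_rows(out_exons) |>
      select("transcript_id", "gene_id", "chrom", "strand", "start", "end")
    assembled <- genome_annotation(
      genes = genes_from_exons(exons, biotype = "other"),
      exons = exons
    )
    list(
      assembled = assembled,
      truth = bind_rows(truth),
      genome = vapply(chrom_chars, paste, character(1), collapse = "")
    )
  })
}
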