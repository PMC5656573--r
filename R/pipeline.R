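#' Pipeline configuration
#'
#' Collects the input paths and tunable thresholds of [run_all()] and
#' validates that every referenced file exists before any stage runs.
#'
#' @param paths Named list of input paths: `reference_gtf`,
#'   `assembled_gtf`, `genome_fa`, `known_lncrna_gtf`, `counts_tsv`,
#'   `samples_tsv`, `mirnas_fa`, `utrs_fa`, optionally `gene_sets_gmt`
#'   (e.g. `simulate_bundle()$paths`).
#' @param out_dir Output directory.
#' @param seed Integer seed used by every stochastic stage (classifier
#'   training data).
#' @param min_exons,min_length Discovery filter parameters.
#' @param p_max,min_abs_log2fc Differential-expression thresholds.
#' @param min_shared_mirnas,min_unique_sites,min_r ceRNA thresholds.
#' @param cis_window,trans_min_distance Co-expression windows in nt.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(paths, out_dir, seed = 1L,
                            min_exons = 2L, min_length = 200L,
                            p_max = 0.05, min_abs_log2fc = 1,
                            min_shared_mirnas = 2L, min_unique_sites = 8L,
                            min_r = 0.7,
                            cis_window = 1e5, trans_min_distance = 1e6) {
  required <- c(
    "reference_gtf", "assembled_gtf", "genome_fa", "known_lncrna_gtf",
    "counts_tsv", "samples_tsv", "mirnas_fa", "utrs_fa"
  )
  missing_names <- setdiff(required, names(paths))
  if (length(missing_names) > 0) {
    abort(paste0("pipeline_config: missing path(s): ", paste(missing_names, collapse = ", ")))
  }
  for (nm in c(required, intersect("gene_sets_gmt", names(paths)))) {
    if (!file.exists(paths[[nm]])) {
      abort(paste0("pipeline_config: file not found for ", nm, ": ", paths[[nm]]))
    }
  }
  stopifnot(p_max > 0, p_max < 1, min_abs_log2fc >= 0, min_exons >= 1)
  structure(
    list(
      paths = paths, out_dir = out_dir, seed = as.integer(seed),
      min_exons = min_exons, min_length = min_length,
      p_max = p_max, min_abs_log2fc = min_abs_log2fc,
      min_shared_mirnas = min_shared_mirnas,
      min_unique_sites = min_unique_sites, min_r = min_r,
      cis_window = cis_window, trans_min_distance = trans_min_distance
    ),
    class = "pipeline_config"
  )
}

stage_error <- function(stage, parent) {
  abort(paste0("stage '", stage, "' failed: ", conditionMessage(parent)))
}

#' Run the full lncRNA pipeline
#'
#' Executes discovery (classification + retention filter), the
#' two-classifier coding-potential gate, catalog merge and nomenclature,
#' two-test consensus differential expression per adjacent-group
#' contrast, cis/trans co-expression, ceRNA network construction per
#' contrast, and (when a GMT is supplied) hypergeometric
#' over-representation of the ceRNA target genes.  Writes per-stage
#' result tables plus a manifest (input hashes, seed, per-stage record
#' counts) into `config$out_dir`; the run is a pure function of
#' (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return A list of in-memory results; the manifest is in `$manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  funnel <- list()
  note <- function(stage, n_in, n_out) {
    funnel[[length(funnel) + 1L]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out
    )
    inform(paste0("[", stage, "] ", n_in, " -> ", n_out))
  }

  reference <- tryCatch(read_gtf(config$paths$reference_gtf),
    error = function(e) stage_error("read_reference", e)
  )
  assembled <- tryCatch(read_gtf(config$paths$assembled_gtf),
    error = function(e) stage_error("read_assembled", e)
  )
  genome_tbl <- read_fasta(config$paths$genome_fa)
  genome <- setNames(genome_tbl$sequence, genome_tbl$id)
  known <- read_gtf(config$paths$known_lncrna_gtf)
  counts <- read_counts(config$paths$counts_tsv)
  sample_sheet <- readr::read_tsv(config$paths$samples_tsv, show_col_types = FALSE)
  mirnas <- read_fasta(config$paths$mirnas_fa)
  utrs <- read_fasta(config$paths$utrs_fa)

  # --- discovery -------------------------------------------------------
  codes <- tryCatch(classify_transcripts(assembled, reference),
    error = function(e) stage_error("classify", e)
  )
  filt <- filter_candidates(assembled, codes, config$min_exons, config$min_length)
  note("class_and_structure_filter", nrow(filt), sum(filt$retained))

  # --- coding potential ------------------------------------------------
  cand_ids <- filt$transcript_id[filt$retained]
  cand_ann <- genome_annotation(
    genes = assembled$genes |> filter(.data$gene_id %in% cand_ids),
    exons = assembled$exons |> filter(.data$transcript_id %in% cand_ids)
  )
  cand_seqs <- extract_transcript_sequences(cand_ann, genome) |>
    transmute(id = .data$transcript_id, sequence = .data$sequence)
  model <- train_codpot_model(simulate_codpot_training(150L, seed = config$seed))
  cp <- tryCatch(codpot_classify(cand_seqs, model),
    error = function(e) stage_error("coding_potential", e)
  )
  keep_ids <- cp$id[cp$consensus_noncoding]
  note("coding_potential_gate", nrow(cp), length(keep_ids))

  # --- catalog merge + nomenclature ------------------------------------
  kept_ann <- genome_annotation(
    genes = cand_ann$genes |> filter(.data$gene_id %in% keep_ids),
    exons = cand_ann$exons |> filter(.data$transcript_id %in% keep_ids)
  )
  catalog <- merge_with_known(kept_ann, list(known = known), reference)
  catalog <- assign_nomenclature(catalog, reference)
  note("catalog_merge", length(keep_ids) + nrow(known$genes), nrow(catalog$records))

  # --- differential expression -----------------------------------------
  groups <- unique(sample_sheet$group)
  contrasts <- map(seq_len(length(groups) - 1L), function(i) groups[c(i, i + 1L)])
  de_results <- map(contrasts, function(ct) {
    tryCatch(
      run_de(counts, sample_sheet, ct, config$p_max, config$min_abs_log2fc),
      error = function(e) stage_error("differential_expression", e)
    )
  })
  names(de_results) <- map_chr(contrasts, ~ paste0(.x[[2]], "_vs_", .x[[1]]))
  for (nm in names(de_results)) {
    note(paste0("de_", nm), nrow(de_results[[nm]]), sum(de_results[[nm]]$consensus_call))
  }

  # --- co-expression ----------------------------------------------------
  sf <- estimate_size_factors(counts)
  profiles <- expression_profiles(counts, sf)
  lnc_genes <- intersect(unique(catalog$records$gene_id), rownames(counts))
  coding_genes <- reference$genes$gene_id[reference$genes$biotype == "protein_coding"]
  coding_genes <- intersect(coding_genes, rownames(counts))
  coex_ann <- genome_annotation(
    genes = bind_rows(
      reference$genes,
      catalog$annotation$genes |> filter(!.data$gene_id %in% reference$genes$gene_id)
    ),
    exons = bind_rows(
      reference$exons,
      catalog$annotation$exons |>
        filter(!.data$gene_id %in% reference$genes$gene_id)
    )
  )
  pairs <- tidyr::expand_grid(gene_a = lnc_genes, gene_b = coding_genes) |>
    classify_pairs(coex_ann, config$cis_window, config$trans_min_distance) |>
    correlate_pairs(profiles)
  coex_summary <- list(
    cis = correlation_summary(pairs, "cis"),
    trans = correlation_summary(pairs, "trans"),
    all = correlation_summary(pairs)
  )
  note("coexpression_pairs", length(lnc_genes) * length(coding_genes), nrow(pairs))

  # --- ceRNA networks ---------------------------------------------------
  lnc_tx <- catalog$annotation$exons |>
    filter(.data$gene_id %in% lnc_genes) |>
    distinct(.data$transcript_id, .data$gene_id)
  lnc_seq_ann <- genome_annotation(
    genes = catalog$annotation$genes |> filter(.data$gene_id %in% lnc_genes),
    exons = catalog$annotation$exons |> filter(.data$gene_id %in% lnc_genes)
  )
  lnc_seqs <- extract_transcript_sequences(lnc_seq_ann, genome) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    transmute(id = .data$gene_id, sequence = .data$sequence)
  networks <- imap(de_results, function(de, nm) {
    de_lnc <- intersect(de$gene_id[de$consensus_call], lnc_genes)
    net <- tryCatch(
      build_cerna_network(
        lnc_seqs, utrs, mirnas, profiles, de_lnc,
        min_shared_mirnas = config$min_shared_mirnas,
        min_unique_sites = config$min_unique_sites,
        min_r = config$min_r
      ),
      error = function(e) stage_error("cerna", e)
    )
    note(paste0("cerna_", nm), length(de_lnc) * nrow(utrs), nrow(net$edges))
    net
  })

  # --- enrichment -------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$paths$gene_sets_gmt)) {
    sets <- read_gmt(config$paths$gene_sets_gmt)
    targets <- unique(unlist(map(networks, ~ .x$edges$mrna_id)))
    if (length(targets) > 0) {
      enrichment <- hypergeometric_ora(targets, sets, coding_genes)
      note("enrichment", length(sets), nrow(enrichment))
    }
  }

  # --- outputs + manifest ----------------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(catalog$records, out("catalog.tsv"))
  write_gtf(catalog$annotation, out("catalog.gtf"))
  readr::write_tsv(
    filt |> left_join(select(cp, "id", "consensus_noncoding"),
      by = c("transcript_id" = "id")
    ),
    out("discovery_log.tsv")
  )
  for (nm in names(de_results)) {
    readr::write_tsv(as_tibble(de_results[[nm]]), out(paste0("de_", nm, ".tsv")))
  }
  readr::write_tsv(pairs, out("coexpression_pairs.tsv"))
  for (nm in names(networks)) {
    write_edge_table(networks[[nm]], out(paste0("cerna_", nm, "_edges.tsv")))
  }
  if (!is.null(enrichment)) readr::write_tsv(enrichment, out("enrichment.tsv"))
  funnel_tbl <- bind_rows(funnel)
  readr::write_tsv(funnel_tbl, out("funnel.tsv"))

  input_files <- unlist(config$paths)
  output_files <- list.files(config$out_dir, full.names = TRUE)
  output_files <- setdiff(output_files, out("manifest.json"))
  manifest <- list(
    seed = config$seed,
    thresholds = config[setdiff(names(config), c("paths", "out_dir"))],
    input_md5 = as.list(setNames(
      unname(tools::md5sum(input_files)), basename(input_files)
    )),
    output_md5 = as.list(setNames(
      unname(tools::md5sum(sort(output_files))), basename(sort(output_files))
    )),
    funnel = funnel_tbl
  )
  jsonlite::write_json(manifest, out("manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    catalog = catalog, discovery = filt, codpot = cp, de = de_results,
    pairs = pairs, coexpression_summary = coex_summary,
    networks = networks, enrichment = enrichment, manifest = manifest
  ))
}
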