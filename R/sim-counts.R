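#' Simulate a negative-binomial count matrix with planted truth
#'
#' Per gene g, a baseline mean `mu_g ~ log-normal(log 100, 1)`; counts are
#' `NB(mean = s_j * mu_g * 2^beta, dispersion = alpha)` with per-sample
#' size factors `s_j ~ Uniform(0.7, 1.3)` and `Var = mu + alpha * mu^2`.
#' Planted DE genes receive `beta = +/- de_log2fc` from the contrast group
#' onward (so each gene is differentially expressed in exactly one
#' adjacent-group contrast).  Planted ceRNA pairs (a DE lncRNA and a
#' protein-coding partner) share a per-sample latent log-scale factor
#' `z_j ~ Normal(0, 1.3)` on top of a shared group-effect pattern, so their
#' expected expression correlation across samples exceeds 0.8.
#'
#' @param annotation A [genome_annotation()] or a tibble with columns
#'   `gene_id` and `biotype`; one count row is generated per gene.
#' @param config A [sim_config()].
#' @param cerna_lnc_exclude lncRNA gene ids never used as planted ceRNA
#'   members (e.g. antisense transcripts whose loci cannot host seed-site
#'   edits without touching coding sequence).
#' @return List with `counts` (integer matrix), `sample_sheet` (tibble:
#'   `sample`, `group`), and `truth` (list: `size_factors`, `mu`,
#'   `de` tibble of `contrast`/`gene_id`/`true_log2fc`, `cerna_pairs`
#'   tibble of planted co-expressed pairs).
#' @export
simulate_counts <- function(annotation, config, cerna_lnc_exclude = character()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- if (inherits(annotation, "genome_annotation")) {
    annotation$genes
  } else {
    as_tibble(annotation)
  }
  if (config$n_groups < 2) abort("need at least 2 groups")
  if (config$n_samples_per_group < 2) abort("need at least 2 replicates per group")
  with_seed(child_seed(config$seed, "counts"), {
    n_genes <- nrow(genes)
    groups <- group_labels(config)
    sample_sheet <- tibble(
      sample = paste0(
        rep(groups, each = config$n_samples_per_group), "_r",
        rep(seq_len(config$n_samples_per_group), times = config$n_groups)
      ),
      group = rep(groups, each = config$n_samples_per_group)
    )
    n_samples <- nrow(sample_sheet)
    sf <- runif(n_samples, 0.7, 1.3)
    mu <- rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    names(mu) <- genes$gene_id

    beta <- matrix(0, n_genes, config$n_groups,
      dimnames = list(genes$gene_id, groups)
    )
    contrasts <- paste0(groups[-1], "_vs_", groups[-config$n_groups])
    is_lnc <- genes$biotype == "lncRNA"
    lnc_pool <- genes$gene_id[is_lnc]
    pc_pool <- genes$gene_id[!is_lnc]
    de_rows <- list()
    for (ci in seq_along(contrasts)) {
      n_lnc <- min(ceiling(config$n_de_genes / 2), length(lnc_pool))
      n_pc <- min(config$n_de_genes - n_lnc, length(pc_pool))
      picked <- c(
        if (n_lnc > 0) sample(lnc_pool, n_lnc) else character(),
        if (n_pc > 0) sample(pc_pool, n_pc) else character()
      )
      lnc_pool <- setdiff(lnc_pool, picked)
      pc_pool <- setdiff(pc_pool, picked)
      if (length(picked) > 0) {
        signs <- sample(c(-1, 1), length(picked), replace = TRUE)
        beta[picked, seq(ci + 1L, config$n_groups)] <- signs * config$de_log2fc
        de_rows[[ci]] <- tibble(
          contrast = contrasts[[ci]], gene_id = picked,
          true_log2fc = signs * config$de_log2fc
        )
      }
    }
    de <- if (length(de_rows)) bind_rows(de_rows) else {
      tibble(contrast = character(), gene_id = character(), true_log2fc = numeric())
    }

    # planted ceRNA pairs: DE lncRNAs from the first contrast paired with
    # previously non-DE coding genes that inherit the lncRNA's group
    # pattern plus a shared latent factor
    cerna_pairs <- tibble(
      triplet = integer(), lncrna_gene = character(),
      mrna_gene = character(), contrast = character()
    )
    zmat <- NULL
    if (config$n_cerna_triplets > 0 && length(contrasts) >= 1) {
      lnc_de1 <- filter(
        de, .data$contrast == contrasts[[1]],
        .data$gene_id %in% genes$gene_id[is_lnc],
        !.data$gene_id %in% cerna_lnc_exclude
      )
      n_trip <- min(config$n_cerna_triplets, nrow(lnc_de1), length(pc_pool))
      if (n_trip < config$n_cerna_triplets) {
        warn("fewer ceRNA triplets planted than requested (pool exhausted)")
      }
      if (n_trip > 0) {
        lncs <- lnc_de1$gene_id[seq_len(n_trip)]
        mrnas <- sample(pc_pool, n_trip)
        cerna_pairs <- tibble(
          triplet = seq_len(n_trip), lncrna_gene = lncs,
          mrna_gene = mrnas, contrast = contrasts[[1]]
        )
        beta[mrnas, ] <- beta[lncs, ]
        de <- bind_rows(de, tibble(
          contrast = contrasts[[1]], gene_id = mrnas,
          true_log2fc = lnc_de1$true_log2fc[seq_len(n_trip)]
        ))
        # keep pair members well expressed so NB noise does not drown the
        # latent factor
        mu[lncs] <- rlnorm(n_trip, meanlog = log(200), sdlog = 0.3)
        mu[mrnas] <- rlnorm(n_trip, meanlog = log(200), sdlog = 0.3)
        zmat <- matrix(rnorm(n_trip * n_samples, sd = 1.3), n_trip, n_samples)
      }
    }

    grp_idx <- match(sample_sheet$group, groups)
    mean_mat <- outer(mu, sf) * 2^beta[, grp_idx, drop = FALSE]
    if (!is.null(zmat)) {
      for (t in seq_len(nrow(cerna_pairs))) {
        f <- exp(zmat[t, ])
        mean_mat[cerna_pairs$lncrna_gene[[t]], ] <-
          mean_mat[cerna_pairs$lncrna_gene[[t]], ] * f
        mean_mat[cerna_pairs$mrna_gene[[t]], ] <-
          mean_mat[cerna_pairs$mrna_gene[[t]], ] * f
      }
    }
    counts <- matrix(0L, n_genes, n_samples,
      dimnames = list(genes$gene_id, sample_sheet$sample)
    )
    for (j in seq_len(n_samples)) {
      counts[, j] <- if (config$nb_dispersion > 0) {
        rnbinom(n_genes, mu = mean_mat[, j], size = 1 / config$nb_dispersion)
      } else {
        stats::rpois(n_genes, mean_mat[, j])
      }
    }
    list(
      counts = counts,
      sample_sheet = sample_sheet,
      truth = list(
        size_factors = setNames(sf, sample_sheet$sample),
        mu = mu,
        de = de,
        cerna_pairs = cerna_pairs,
        contrasts = contrasts
      )
    )
  })
}
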