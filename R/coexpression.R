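#' Expression profiles on the log2 scale
#'
#' @param counts Integer matrix, genes x samples.
#' @param size_factors Per-sample factors (default
#'   [estimate_size_factors()]).
#' @return Matrix of `log2(normalized count + 1)`.
#' @export
expression_profiles <- function(counts, size_factors = estimate_size_factors(counts)) {
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

#' Pearson correlation of two expression vectors
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Pearson product-moment coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("vectors of unequal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: zero variance")
  }
  cor(x, y, method = "pearson")
}

# gap in nt between two gene bodies (0 if overlapping), or NA if on
# different chromosomes
gene_gap <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_real_)
  max(0, a$start - b$end, b$start - a$end)
}

#' Classify gene pairs as cis / trans / neither
#'
#' A pair is `trans` when the genes sit on different chromosomes or the
#' gap between their gene bodies exceeds `trans_min_distance` (1 Mb);
#' `cis` when they share a chromosome and the gap is at most
#' `cis_window` (100 kb; overlap counts as gap 0); `neither` otherwise.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param annotation A [genome_annotation()] locating every gene.
#' @param cis_window Cis window in nt (inclusive).
#' @param trans_min_distance Trans distance in nt (exclusive).
#' @return `pairs` with `distance` (NA across chromosomes) and `class`
#'   (`"cis"`/`"trans"`/`"neither"`) added.
#' @export
classify_pairs <- function(pairs, annotation, cis_window = 1e5,
                           trans_min_distance = 1e6) {
  genes <- annotation$genes
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes$gene_id)
  if (length(missing) > 0) {
    abort(paste0("unknown gene id: ", missing[[1]]))
  }
  ga <- genes[match(pairs$gene_a, genes$gene_id), ]
  gb <- genes[match(pairs$gene_b, genes$gene_id), ]
  same_chrom <- ga$chrom == gb$chrom
  gap <- pmax(0, pmax(ga$start - gb$end, gb$start - ga$end))
  gap[!same_chrom] <- NA_real_
  pairs |>
    mutate(
      distance = gap,
      class = case_when(
        !same_chrom ~ "trans",
        gap > trans_min_distance ~ "trans",
        gap <= cis_window ~ "cis",
        TRUE ~ "neither"
      )
    )
}

#' Pearson correlation for gene pairs
#'
#' Pairs involving a zero-variance profile are excluded (returned in the
#' `excluded` attribute with a reason) rather than stored with an
#' undefined coefficient.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param profiles Matrix from [expression_profiles()] (genes in rows).
#' @return `pairs` with `r` added; excluded pairs dropped.
#' @export
correlate_pairs <- function(pairs, profiles) {
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(profiles))
  if (length(missing) > 0) abort(paste0("no expression profile for ", missing[[1]]))
  sds <- apply(profiles, 1, sd)
  zero_a <- sds[pairs$gene_a] == 0
  zero_b <- sds[pairs$gene_b] == 0
  excluded <- pairs[zero_a | zero_b, ] |>
    mutate(reason = "zero variance")
  kept <- pairs[!(zero_a | zero_b), ]
  r <- map2_dbl(
    kept$gene_a, kept$gene_b,
    function(a, b) cor(profiles[a, ], profiles[b, ])
  )
  out <- mutate(kept, r = r)
  attr(out, "excluded") <- excluded
  if (nrow(excluded) > 0) {
    inform(paste0(nrow(excluded), " pair(s) excluded: zero variance"))
  }
  out
}

#' Summary of a correlation pair set
#'
#' @param pairs Tibble with `r` (and `class` if `class_filter` is used).
#' @param class_filter Optional class to restrict to
#'   (`"cis"`/`"trans"`/`"neither"`).
#' @return List: `n_pairs`, `frac_r_gt_0.5`, `frac_r_lt_-0.5` (strict
#'   thresholds), and a `histogram` tibble of bin counts (width 0.1).
#' @export
correlation_summary <- function(pairs, class_filter = NULL) {
  if (!is.null(class_filter)) pairs <- filter(pairs, .data$class == class_filter)
  if (nrow(pairs) == 0) {
    return(list(
      n_pairs = 0L, frac_r_gt_0.5 = NA_real_, `frac_r_lt_-0.5` = NA_real_,
      histogram = tibble(bin_lo = numeric(), bin_hi = numeric(), n = integer())
    ))
  }
  breaks <- seq(-1, 1, by = 0.1)
  h <- hist(pairs$r, breaks = breaks, plot = FALSE)
  list(
    n_pairs = nrow(pairs),
    frac_r_gt_0.5 = mean(pairs$r > 0.5),
    `frac_r_lt_-0.5` = mean(pairs$r < -0.5),
    histogram = tibble(
      bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1), n = h$counts
    )
  )
}

#' Strongly correlated cis partners of a lncRNA
#'
#' Protein-coding genes classified `cis` relative to the lncRNA whose
#' expression correlation exceeds `r_min` (strict).
#'
#' @param lncrna_gene Gene id of the lncRNA.
#' @param annotation A [genome_annotation()] containing the lncRNA and
#'   the coding genes.
#' @param profiles Matrix from [expression_profiles()].
#' @param r_min Correlation cutoff (default 0.7, strict `>`).
#' @return Tibble: `gene_id`, `distance`, `r`, sorted by decreasing `r`.
#' @export
cis_partners <- function(lncrna_gene, annotation, profiles, r_min = 0.7) {
  coding <- filter(annotation$genes, .data$biotype == "protein_coding")
  coding <- filter(coding, .data$gene_id %in% rownames(profiles))
  if (!lncrna_gene %in% annotation$genes$gene_id) {
    abort(paste0("unknown gene id: ", lncrna_gene))
  }
  if (nrow(coding) == 0) return(tibble(gene_id = character(), distance = numeric(), r = numeric()))
  pairs <- tibble(gene_a = lncrna_gene, gene_b = coding$gene_id) |>
    classify_pairs(annotation) |>
    filter(.data$class == "cis")
  if (nrow(pairs) == 0) return(tibble(gene_id = character(), distance = numeric(), r = numeric()))
  pairs <- correlate_pairs(pairs, profiles)
  pairs |>
    filter(.data$r > r_min) |>
    transmute(gene_id = .data$gene_b, distance = .data$distance, r = .data$r) |>
    arrange(desc(.data$r))
}
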