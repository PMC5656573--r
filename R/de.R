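#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive genes of the ratio
#' between the sample's count and the gene's geometric mean across
#' samples; factors are rescaled to geometric mean 1.  When no gene is
#' positive in every sample, falls back to library-size ratios with a
#' warning.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  if (any(counts < 0)) abort("negative counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warn("no gene with all-positive counts; using library-size ratios")
    sf <- colSums(counts)
    sf <- sf / mean(sf)
  } else {
    lgeo <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt) {
      median(exp(log(cnt) - lgeo))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Method-of-moments common dispersion
#'
#' Per gene and group, solves `Var = mu + alpha * mu^2` on normalized
#' counts and averages the positive estimates; floored at 1e-8.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Character vector, one group label per column.
#' @param size_factors Per-sample factors (default
#'   [estimate_size_factors()]).
#' @return Scalar dispersion alpha.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       size_factors = estimate_size_factors(counts)) {
  if (max(table(groups)) < 2) abort("need >= 2 replicates in some group")
  norm <- sweep(counts, 2, size_factors, "/")
  ests <- c()
  for (g in unique(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ok <- m > 0
    ests <- c(ests, ((v - m) / m^2)[ok])
  }
  pos <- ests[ests > 0 & is.finite(ests)]
  if (length(pos) == 0) {
    warn("all genes underdispersed; dispersion floored at 1e-8")
    return(1e-8)
  }
  max(mean(pos), 1e-8)
}

# conditional NB probabilities of all partitions (a, t - a) of total t
# between two group sums: Y_A ~ NB(n_A * mu, size = n_A / alpha),
# Y_B ~ NB(n_B * mu, size = n_B / alpha), mu = t / (n_A + n_B)
exact_partition_probs <- function(t, n_a, n_b, alpha) {
  mu <- t / (n_a + n_b)
  a <- 0:t
  if (alpha > 0) {
    lp <- dnbinom(a, mu = n_a * mu, size = n_a / alpha, log = TRUE) +
      dnbinom(t - a, mu = n_b * mu, size = n_b / alpha, log = TRUE)
  } else {
    lp <- stats::dpois(a, n_a * mu, log = TRUE) +
      stats::dpois(t - a, n_b * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Conditional negative-binomial exact test
#'
#' Counts are normalised to a common effective library size
#' (pseudo-counts `round(count / size_factor)`) and summed per group.
#' Conditional on the total `t`, the two-sided p-value is the sum of the
#' probabilities of all partitions of `t` that are at most as likely as
#' the observed one, under group sums distributed
#' `NB(n_g * mu, dispersion alpha / n_g)`.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Character vector per column.
#' @param contrast Length-2 character: `c(reference_group, test_group)`.
#' @param alpha Common dispersion.
#' @param size_factors Per-sample factors.
#' @return Tibble: `gene_id`, `base_mean_a`, `base_mean_b`,
#'   `log2fc_exact` (pseudocount 0.5, reporting only), `p_exact`.
#' @export
nb_exact_test <- function(counts, groups, contrast, alpha,
                          size_factors = estimate_size_factors(counts)) {
  stopifnot(length(contrast) == 2, all(contrast %in% groups))
  ja <- which(groups == contrast[[1]])
  jb <- which(groups == contrast[[2]])
  pseudo <- round(sweep(counts, 2, size_factors, "/"))
  ya <- rowSums(pseudo[, ja, drop = FALSE])
  yb <- rowSums(pseudo[, jb, drop = FALSE])
  n_a <- length(ja)
  n_b <- length(jb)
  p <- map_dbl(seq_along(ya), function(i) {
    t <- ya[[i]] + yb[[i]]
    if (t == 0) return(1)
    probs <- exact_partition_probs(t, n_a, n_b, alpha)
    obs <- probs[[ya[[i]] + 1L]]
    min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
  })
  tibble(
    gene_id = rownames(counts),
    base_mean_a = ya / n_a,
    base_mean_b = yb / n_b,
    log2fc_exact = log2((yb / n_b + 0.5) / (ya / n_a + 0.5)),
    p_exact = p
  )
}

# per-group NB log-mean MLE with offsets; Newton with Fisher scoring
nb_group_mle <- function(y, sf, alpha, tol = 1e-10, max_iter = 100L) {
  beta <- log(max(mean(y / sf), 1e-8))
  for (it in seq_len(max_iter)) {
    mu <- sf * exp(beta)
    score <- sum((y - mu) / (1 + alpha * mu))
    info <- sum(mu / (1 + alpha * mu))
    step <- score / info
    beta <- beta + step
    if (abs(step) < tol) break
  }
  mu <- sf * exp(beta)
  list(beta = beta, info = sum(mu / (1 + alpha * mu)))
}

#' Negative-binomial Wald test
#'
#' Per gene, a two-mean NB GLM with log link and log size-factor offsets
#' is fitted by Newton iteration; the Wald statistic
#' `z = (beta_B - beta_A) / SE` is referred to the standard normal,
#' two-sided.  Genes with an all-zero group are fitted on counts + 0.5
#' and flagged.
#'
#' @inheritParams nb_exact_test
#' @return Tibble: `gene_id`, `log2fc`, `se_log2fc`, `p_wald`,
#'   `pseudo_flag`.
#' @export
nb_wald_test <- function(counts, groups, contrast, alpha,
                         size_factors = estimate_size_factors(counts)) {
  stopifnot(length(contrast) == 2, all(contrast %in% groups))
  ja <- which(groups == contrast[[1]])
  jb <- which(groups == contrast[[2]])
  res <- map(seq_len(nrow(counts)), function(i) {
    ya <- counts[i, ja]
    yb <- counts[i, jb]
    flag <- sum(ya) == 0 || sum(yb) == 0
    if (flag) {
      ya <- ya + 0.5
      yb <- yb + 0.5
    }
    fa <- nb_group_mle(ya, size_factors[ja], alpha)
    fb <- nb_group_mle(yb, size_factors[jb], alpha)
    delta <- fb$beta - fa$beta
    se <- sqrt(1 / fa$info + 1 / fb$info)
    tibble(
      log2fc = delta / log(2),
      se_log2fc = se / log(2),
      p_wald = 2 * pnorm(-abs(delta / se)),
      pseudo_flag = flag
    )
  }) |> list_rbind()
  bind_cols(tibble(gene_id = rownames(counts)), res)
}

#' Two-test consensus differential-expression call
#'
#' A gene is called differentially expressed only when *both* tests give
#' `p <= p_max` and the Wald fold-change estimate satisfies
#' `|log2FC| >= min_abs_log2fc` (boundaries inclusive).  BH-adjusted
#' q-values are reported for information; raw p-values gate the call.
#'
#' @param exact_res From [nb_exact_test()].
#' @param wald_res From [nb_wald_test()] on the same genes.
#' @param p_max Raw p-value threshold (default 0.05, inclusive).
#' @param min_abs_log2fc Fold-change threshold (default 1, inclusive).
#' @param contrast Optional contrast label stored on the result.
#' @return A `de_consensus` tibble: per-gene test results, per-test pass
#'   flags, `consensus_call` and `direction`.
#' @export
consensus_de <- function(exact_res, wald_res, p_max = 0.05,
                         min_abs_log2fc = 1, contrast = NULL) {
  if (!setequal(exact_res$gene_id, wald_res$gene_id)) {
    abort("exact and Wald results cover different gene sets")
  }
  res <- inner_join(exact_res, wald_res, by = "gene_id") |>
    mutate(
      q_exact = p.adjust(.data$p_exact, "BH"),
      q_wald = p.adjust(.data$p_wald, "BH"),
      passed_exact = .data$p_exact <= p_max,
      passed_wald = .data$p_wald <= p_max,
      passed_lfc = abs(.data$log2fc) >= min_abs_log2fc,
      consensus_call = .data$passed_exact & .data$passed_wald & .data$passed_lfc,
      direction = case_when(
        .data$consensus_call & .data$log2fc > 0 ~ "up",
        .data$consensus_call & .data$log2fc < 0 ~ "down",
        TRUE ~ NA_character_
      )
    )
  class(res) <- c("de_consensus", class(res))
  attr(res, "contrast") <- contrast
  attr(res, "thresholds") <- list(p_max = p_max, min_abs_log2fc = min_abs_log2fc)
  res
}

#' @export
glance.de_consensus <- function(x, ...) {
  tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_genes = nrow(x),
    n_de = sum(x$consensus_call),
    n_up = sum(x$direction == "up", na.rm = TRUE),
    n_down = sum(x$direction == "down", na.rm = TRUE)
  )
}

#' Full differential-expression analysis for one contrast
#'
#' Estimates size factors and common dispersion from the whole matrix,
#' runs both NB tests on the contrast and intersects them.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sample_sheet Tibble with `sample`, `group` (samples matching
#'   `colnames(counts)`).
#' @param contrast Length-2 character `c(reference_group, test_group)`.
#' @param p_max,min_abs_log2fc Consensus thresholds.
#' @return A `de_consensus` tibble (see [consensus_de()]); size factors
#'   and dispersion attached as attributes.
#' @export
run_de <- function(counts, sample_sheet, contrast,
                   p_max = 0.05, min_abs_log2fc = 1) {
  stopifnot(all(colnames(counts) == sample_sheet$sample))
  groups <- sample_sheet$group
  sf <- estimate_size_factors(counts)
  alpha <- estimate_common_dispersion(counts, groups, sf)
  ex <- nb_exact_test(counts, groups, contrast, alpha, sf)
  wa <- nb_wald_test(counts, groups, contrast, alpha, sf)
  res <- consensus_de(ex, wa, p_max, min_abs_log2fc,
    contrast = paste0(contrast[[2]], "_vs_", contrast[[1]])
  )
  attr(res, "size_factors") <- sf
  attr(res, "dispersion") <- alpha
  res
}
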