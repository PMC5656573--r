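SITE_PRIORITY <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)

#' Scan a target sequence for miRNA seed sites
#'
#' Canonical seed-match classes on the target (5'->3'):
#' an 8mer is the reverse complement of miRNA positions 2-8 followed by
#' an `A` (opposite miRNA position 1); a 7mer-m8 is the same 7-mer
#' without the `A`; a 7mer-A1 is the reverse complement of positions 2-7
#' plus the `A`; a 6mer is the seed complement alone.  Every matching
#' offset is reported once with its highest-priority type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); overlapping distinct offsets are
#' all reported.
#'
#' @param target_seq Target sequence (>= 8 nt).
#' @param mirna_seq miRNA sequence, 5'->3', DNA alphabet.
#' @param mirna_id Id recorded on the sites.
#' @return Tibble: `mirna_id`, `start` (0-based offset), `site_type`.
#' @export
find_seed_sites <- function(target_seq, mirna_seq, mirna_id = "miRNA") {
  if (nchar(target_seq) < 8) abort("target shorter than 8 nt")
  rc7 <- revcomp(mirna_seed7(mirna_seq))
  rc6 <- revcomp(mirna_seed6(mirna_seq))
  n <- nchar(target_seq)
  hits7 <- find_all_fixed(target_seq, rc7)
  hits6 <- find_all_fixed(target_seq, rc6)
  a_at <- function(p0, w) {
    p0 + w < n & substring(target_seq, p0 + w + 1L, p0 + w + 1L) == "A"
  }
  rows <- bind_rows(
    if (length(hits7)) {
      tibble(
        start = hits7,
        site_type = if_else(a_at(hits7, 7L), "8mer", "7mer-m8")
      )
    },
    if (length(hits6)) {
      tibble(
        start = hits6,
        site_type = if_else(a_at(hits6, 6L), "7mer-A1", "6mer")
      )
    }
  )
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(
      mirna_id = character(), start = integer(), site_type = character()
    ))
  }
  rows |>
    mutate(priority = SITE_PRIORITY[.data$site_type]) |>
    group_by(.data$start) |>
    slice_max(.data$priority, n = 1, with_ties = FALSE) |>
    ungroup() |>
    transmute(mirna_id = mirna_id, start = .data$start, site_type = .data$site_type) |>
    arrange(.data$start)
}

#' Seed sites for every (target, miRNA) combination
#'
#' @param targets Tibble (`id`, `sequence`).
#' @param mirnas Tibble (`id`, `sequence`).
#' @return Tibble: `target_id`, `mirna_id`, `start`, `site_type`.
#' @export
find_all_seed_sites <- function(targets, mirnas) {
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    for (m in seq_len(nrow(mirnas))) {
      s <- find_seed_sites(
        targets$sequence[[i]], mirnas$sequence[[m]], mirnas$id[[m]]
      )
      if (nrow(s) > 0) {
        rows[[length(rows) + 1L]] <- mutate(s, target_id = targets$id[[i]])
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      target_id = character(), mirna_id = character(),
      start = integer(), site_type = character()
    ))
  }
  bind_rows(rows) |> select("target_id", "mirna_id", "start", "site_type")
}

#' Unique binding sites of a pair, pooled over shared miRNAs
#'
#' Counts distinct (molecule, miRNA, offset) triples restricted to the
#' shared miRNAs, summed over the two molecules of the pair.
#'
#' @param sites_lnc,sites_mrna Site tibbles (`mirna_id`, `start`) for the
#'   lncRNA and the mRNA.
#' @param shared_mirnas Character vector of shared miRNA ids.
#' @return Integer count.
#' @export
count_unique_sites <- function(sites_lnc, sites_mrna, shared_mirnas) {
  n_l <- sites_lnc |>
    filter(.data$mirna_id %in% shared_mirnas) |>
    distinct(.data$mirna_id, .data$start) |>
    nrow()
  n_m <- sites_mrna |>
    filter(.data$mirna_id %in% shared_mirnas) |>
    distinct(.data$mirna_id, .data$start) |>
    nrow()
  n_l + n_m
}

#' Build the ceRNA network
#'
#' A lncRNA-mRNA pair is admitted when the two molecules share at least
#' `min_shared_mirnas` miRNAs (a shared miRNA has >= 1 seed site on each
#' molecule), carry at least `min_unique_sites` unique binding sites
#' pooled over both molecules and the shared miRNAs (strictly more when
#' `strict_sites = TRUE`), and their expression correlation exceeds
#' `min_r` (strict).  mRNA sites are restricted to the supplied 3'UTR
#' sequences; lncRNAs are scanned full-length.  lncRNA candidates are
#' restricted to a supplied set of differentially expressed lncRNAs.
#'
#' @param lnc_seqs Tibble (`id`, `sequence`) of lncRNA transcripts; ids
#'   must match rows of `profiles`.
#' @param utr_seqs Tibble (`id`, `sequence`) of mRNA 3'UTRs; ids must
#'   match rows of `profiles`.
#' @param mirnas Tibble (`id`, `sequence`).
#' @param profiles Expression matrix from [expression_profiles()].
#' @param de_lnc_set Character vector of DE lncRNA ids to consider.
#' @param min_shared_mirnas,min_unique_sites,min_r Admission thresholds
#'   (defaults 2, 8, 0.7).
#' @param strict_sites Require strictly more than `min_unique_sites`.
#' @param per_molecule When `TRUE`, require `min_unique_sites` on each
#'   molecule separately instead of pooled.
#' @return A `cerna_network`: list with `edges`, `skipped` (pairs without
#'   expression), and the thresholds used.
#' @export
build_cerna_network <- function(lnc_seqs, utr_seqs, mirnas, profiles,
                                de_lnc_set,
                                min_shared_mirnas = 2L,
                                min_unique_sites = 8L,
                                min_r = 0.7,
                                strict_sites = FALSE,
                                per_molecule = FALSE) {
  lncs <- filter(lnc_seqs, .data$id %in% de_lnc_set)
  sites_lnc <- find_all_seed_sites(lncs, mirnas)
  sites_utr <- find_all_seed_sites(utr_seqs, mirnas)
  edges <- list()
  skipped <- list()
  pass_sites <- function(n) if (strict_sites) n > min_unique_sites else n >= min_unique_sites
  for (lnc in lncs$id) {
    sl <- filter(sites_lnc, .data$target_id == lnc)
    for (mrna in utr_seqs$id) {
      sm <- filter(sites_utr, .data$target_id == mrna)
      shared <- intersect(unique(sl$mirna_id), unique(sm$mirna_id))
      if (length(shared) < min_shared_mirnas) next
      if (per_molecule) {
        nl <- count_unique_sites(sl, sl[0, ], shared)
        nm <- count_unique_sites(sm[0, ], sm, shared)
        n_sites <- nl + nm
        if (!(pass_sites(nl) && pass_sites(nm))) next
      } else {
        n_sites <- count_unique_sites(sl, sm, shared)
        if (!pass_sites(n_sites)) next
      }
      if (!lnc %in% rownames(profiles) || !mrna %in% rownames(profiles)) {
        skipped[[length(skipped) + 1L]] <- tibble(
          lncrna_id = lnc, mrna_id = mrna, reason = "missing expression"
        )
        next
      }
      r <- cor(profiles[lnc, ], profiles[mrna, ])
      if (is.na(r) || r <= min_r) next
      edges[[length(edges) + 1L]] <- tibble(
        lncrna_id = lnc, mrna_id = mrna,
        shared_mirna_ids = list(sort(shared)),
        n_shared_mirnas = length(shared),
        n_unique_sites = n_sites,
        pearson_r = r
      )
    }
  }
  skipped <- if (length(skipped)) bind_rows(skipped) else {
    tibble(lncrna_id = character(), mrna_id = character(), reason = character())
  }
  if (nrow(skipped) > 0) {
    inform(paste0(nrow(skipped), " pair(s) skipped: missing expression"))
  }
  structure(
    list(
      edges = if (length(edges)) bind_rows(edges) else tibble(
        lncrna_id = character(), mrna_id = character(),
        shared_mirna_ids = list(), n_shared_mirnas = integer(),
        n_unique_sites = integer(), pearson_r = numeric()
      ),
      skipped = skipped,
      thresholds = list(
        min_shared_mirnas = min_shared_mirnas,
        min_unique_sites = min_unique_sites,
        min_r = min_r, strict_sites = strict_sites,
        per_molecule = per_molecule
      )
    ),
    class = "cerna_network"
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat(
    "<cerna_network> ", s$n_edges, " edges, ", s$n_lncrnas, " lncRNAs, ",
    s$n_mrnas, " mRNAs\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.cerna_network <- function(x, ...) x$edges

#' @export
glance.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  tibble(n_edges = s$n_edges, n_lncrnas = s$n_lncrnas, n_mrnas = s$n_mrnas)
}

#' Tallies of a ceRNA network
#'
#' @param network A `cerna_network`.
#' @return List: `n_edges`, `n_lncrnas`, `n_mrnas`, and a `degree` tibble
#'   (`node`, `side`, `degree`).
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  e <- network$edges
  degree <- bind_rows(
    e |> count(node = .data$lncrna_id, name = "degree") |> mutate(side = "lncRNA"),
    e |> count(node = .data$mrna_id, name = "degree") |> mutate(side = "mRNA")
  )
  list(
    n_edges = nrow(e),
    n_lncrnas = length(unique(e$lncrna_id)),
    n_mrnas = length(unique(e$mrna_id)),
    degree = degree
  )
}
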