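# all 0-based start offsets of fixed pattern `pat` in `s`, overlapping included
find_all_fixed <- function(s, pat) {
  n <- nchar(s)
  w <- nchar(pat)
  if (n < w) return(integer())
  starts <- 1:(n - w + 1L)
  which(substring(s, starts, starts + w - 1L) == pat) - 1L
}

mirna_seed6 <- function(seq) substr(seq, 2L, 7L)
mirna_seed7 <- function(seq) substr(seq, 2L, 8L)

#' Simulate miRNA sequences
#'
#' Random 22-nt sequences with pairwise-distinct seed hexamers; seeds
#' whose reverse complement occurs in the stop-codon motif used by the
#' noncoding sequence generators are rejected, so seed matches never
#' collide with the ORF-poor scaffold.
#'
#' @param n Number of miRNAs.
#' @param seed Integer seed.
#' @return Tibble with `id`, `sequence` (DNA alphabet, 5'->3').
#' @export
simulate_mirnas <- function(n, seed = 1L) {
  motif_rep <- paste(rep(STOP_MOTIF, 3), collapse = "")
  with_seed(child_seed(seed, "mirnas"), {
    seqs <- character(0)
    seen6 <- character(0)
    while (length(seqs) < n) {
      cand <- random_dna(22L)
      s6 <- mirna_seed6(cand)
      if (s6 %in% seen6) next
      if (grepl(revcomp(s6), motif_rep, fixed = TRUE)) next
      seqs <- c(seqs, cand)
      seen6 <- c(seen6, s6)
    }
    tibble(id = sprintf("MIR%d", seq_len(n)), sequence = seqs)
  })
}

site_sequence <- function(mirna_seq, type) {
  switch(type,
    "8mer" = paste0(revcomp(mirna_seed7(mirna_seq)), "A"),
    "7mer-m8" = revcomp(mirna_seed7(mirna_seq)),
    "7mer-A1" = paste0(revcomp(mirna_seed6(mirna_seq)), "A"),
    "6mer" = revcomp(mirna_seed6(mirna_seq)),
    abort(paste0("unknown site type: ", type))
  )
}

#' Plant miRNA response elements into host sequences
#'
#' For every planted triplet (lncRNA, mRNA 3'UTR, two shared miRNAs),
#' exact reverse-complement seed matches (site types drawn from 8mer,
#' 7mer-m8, 7mer-A1) are written at recorded non-overlapping positions:
#' two sites per miRNA on the lncRNA and three on the 3'UTR, so each
#' planted pair carries at least ten unique sites.  All host sequences are
#' then scrubbed of spurious seed-core matches (any reverse-complement
#' seed hexamer not overlapping a planted site is disrupted), so
#' negative-control pairs share at most one miRNA by construction.
#'
#' @param lnc_seqs,utr_seqs Tibbles (`id`, `sequence`) of lncRNA
#'   transcripts and mRNA 3'UTRs.  All of them are scrubbed; only those
#'   named in `triplets` receive planted sites.
#' @param mirnas Tibble (`id`, `sequence`) from [simulate_mirnas()].
#' @param triplets Tibble with `lncrna_id`, `mrna_id` and a `mirna_ids`
#'   list column (two miRNA ids per row).
#' @param config A [sim_config()] (seed source).
#' @return List: edited `lnc_seqs` and `utr_seqs`, `sites` (tibble of
#'   planted sites: `molecule_id`, `molecule_type`, `mirna_id`, `start`
#'   0-based, `site_type`), and `triplets`.
#' @export
plant_mre_sites <- function(lnc_seqs, utr_seqs, mirnas, triplets, config) {
  with_seed(child_seed(config$seed, "mre"), {
    seqs <- c(
      setNames(lnc_seqs$sequence, lnc_seqs$id),
      setNames(utr_seqs$sequence, utr_seqs$id)
    )
    mol_type <- c(
      setNames(rep("lncRNA", nrow(lnc_seqs)), lnc_seqs$id),
      setNames(rep("mRNA", nrow(utr_seqs)), utr_seqs$id)
    )
    mirna_seq <- setNames(mirnas$sequence, mirnas$id)
    planted <- setNames(
      replicate(length(seqs), tibble(start = integer(), end = integer()),
        simplify = FALSE
      ),
      names(seqs)
    )
    sites <- list()
    types_pool <- c("8mer", "7mer-m8", "7mer-A1")

    plant_one <- function(mol, mid, n_sites) {
      s <- seqs[[mol]]
      for (k in seq_len(n_sites)) {
        type <- sample(types_pool, 1)
        site <- site_sequence(mirna_seq[[mid]], type)
        w <- nchar(site)
        ok <- FALSE
        for (try in seq_len(100L)) {
          p0 <- sample.int(nchar(s) - w + 1L, 1) - 1L # 0-based
          iv <- planted[[mol]]
          if (nrow(iv) == 0 || !hits_any(p0 - 2L, p0 + w + 2L, iv$start, iv$end)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) abort(paste0("insufficient sequence length to plant sites in ", mol))
        substr(s, p0 + 1L, p0 + w) <- site
        planted[[mol]] <<- bind_rows(planted[[mol]], tibble(start = p0, end = p0 + w))
        sites[[length(sites) + 1L]] <<- tibble(
          molecule_id = mol, molecule_type = mol_type[[mol]],
          mirna_id = mid, start = p0, site_type = type
        )
      }
      seqs[[mol]] <<- s
    }

    for (t in seq_len(nrow(triplets))) {
      mids <- triplets$mirna_ids[[t]]
      for (mid in mids) {
        plant_one(triplets$lncrna_id[[t]], mid, 2L)
        plant_one(triplets$mrna_id[[t]], mid, 3L)
      }
    }

    # scrub spurious seed-core matches everywhere (outside planted sites)
    cores <- setNames(revcomp(mirna_seed6(mirna_seq)), names(mirna_seq))
    bases <- c("A", "C", "G", "T")
    for (iter in seq_len(30L)) {
      dirty <- FALSE
      for (mol in names(seqs)) {
        iv <- planted[[mol]]
        for (core in cores) {
          hits <- find_all_fixed(seqs[[mol]], core)
          for (p0 in hits) {
            if (nrow(iv) > 0 && hits_any(p0, p0 + 6L, iv$start, iv$end)) next
            pos <- p0 + 4L # 1-based index of a middle base
            old <- substr(seqs[[mol]], pos, pos)
            substr(seqs[[mol]], pos, pos) <- sample(setdiff(bases, old), 1)
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
    }

    sites <- bind_rows(sites)
    is_lnc <- mol_type[names(seqs)] == "lncRNA"
    list(
      lnc_seqs = tibble(
        id = names(seqs)[is_lnc],
        sequence = unname(unlist(seqs[is_lnc]))
      ),
      utr_seqs = tibble(
        id = names(seqs)[!is_lnc],
        sequence = unname(unlist(seqs[!is_lnc]))
      ),
      sites = sites,
      triplets = triplets
    )
  })
}
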