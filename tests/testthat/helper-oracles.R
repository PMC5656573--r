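# Independent brute-force oracles and tiny fixture builders.  These are
# deliberately naive (base-level loops, straight-line lookups) so they share
# no code path with the package implementation they check.

# -- annotation builders ----------------------------------------------------

ann_from_exons <- function(exons, biotypes = NULL) {
  genes <- exons |>
    dplyr::group_by(gene_id, chrom, strand) |>
    dplyr::summarise(start = min(start), end = max(end), .groups = "drop")
  genes$biotype <- if (is.null(biotypes)) "protein_coding" else unname(biotypes[genes$gene_id])
  genome_annotation(genes, exons)
}

one_tx <- function(tid, chrom, strand, starts, ends, gid = tid) {
  tibble::tibble(
    transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
    start = as.integer(starts), end = as.integer(ends)
  )
}

# random multi-exon annotation (no genome attached)
random_reference <- function(n_genes, seed, chrom_n = 2, span = 200000L) {
  set.seed(seed)
  exons <- list()
  biotypes <- c()
  for (i in seq_len(n_genes)) {
    gid <- paste0("G", i)
    chrom <- paste0("chr", sample.int(chrom_n, 1))
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:4, 1)
    pos <- sample.int(span, 1)
    starts <- ends <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      ends[k] <- pos + sample(50:300, 1)
      pos <- ends[k] + sample(100:2000, 1)
    }
    exons[[gid]] <- one_tx(paste0(gid, ".t"), chrom, strand, starts, ends, gid)
    biotypes[gid] <- sample(c("protein_coding", "lncRNA"), 1, prob = c(0.7, 0.3))
  }
  ann_from_exons(dplyr::bind_rows(exons), biotypes)
}

random_transcripts <- function(n, seed, chrom_n = 2, span = 200000L) {
  set.seed(seed)
  exons <- list()
  for (i in seq_len(n)) {
    tid <- paste0("T", i)
    chrom <- paste0("chr", sample.int(chrom_n, 1))
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:3, 1)
    pos <- sample.int(span, 1)
    starts <- ends <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      ends[k] <- pos + sample(30:400, 1)
      pos <- ends[k] + sample(50:1500, 1)
    }
    exons[[tid]] <- one_tx(tid, chrom, strand, starts, ends)
  }
  ann_from_exons(dplyr::bind_rows(exons), NULL)
}

# -- base-level classification oracle --------------------------------------

# enumerate every exonic base of every reference transcript into per-
# (chrom, strand, biotype) base sets, then test the spec's precedence rules
# literally
oracle_classify_one <- function(tx_exons, reference) {
  ref <- reference$exons |>
    dplyr::left_join(
      dplyr::select(reference$genes, gene_id, biotype),
      by = "gene_id"
    )
  t_chrom <- tx_exons$chrom[[1]]
  t_strand <- tx_exons$strand[[1]]
  t_bases <- unlist(mapply(function(s, e) seq(s, e - 1), tx_exons$start, tx_exons$end,
    SIMPLIFY = FALSE
  ))
  ref_here <- ref[ref$chrom == t_chrom, ]
  base_set <- function(rows) {
    if (nrow(rows) == 0) return(integer())
    unlist(mapply(function(s, e) seq(s, e - 1), rows$start, rows$end, SIMPLIFY = FALSE))
  }
  sense_coding <- base_set(ref_here[ref_here$strand == t_strand &
    ref_here$biotype == "protein_coding", ])
  if (any(t_bases %in% sense_coding)) return("sense_overlap")
  anti_all <- base_set(ref_here[ref_here$strand != t_strand, ])
  if (any(t_bases %in% anti_all)) return("x")
  # intronic: span within one intron of some reference transcript
  span_lo <- min(tx_exons$start)
  span_hi <- max(tx_exons$end)
  for (tid in unique(ref_here$transcript_id)) {
    ex <- ref_here[ref_here$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) next
    for (k in seq_len(nrow(ex) - 1)) {
      if (span_lo >= ex$end[k] && span_hi <= ex$start[k + 1]) return("i")
    }
  }
  "u"
}

# -- exhaustive ORF oracle ---------------------------------------------------

oracle_orf <- function(seq) {
  L <- nchar(seq)
  best_len <- 0L
  best_start <- NA_integer_
  for (s in seq_len(max(L - 2, 0))) {
    if (substr(seq, s, s + 2) != "ATG") next
    len <- NA
    p <- s
    while (p + 2 <= L) {
      cod <- substr(seq, p, p + 2)
      if (p > s && cod %in% c("TAA", "TAG", "TGA")) {
        len <- p + 2 - s + 1
        break
      }
      p <- p + 3
    }
    if (is.na(len)) len <- floor((L - s + 1) / 3) * 3
    if (len > best_len || (len == best_len && !is.na(best_start) && s - 1 < best_start)) {
      best_len <- len
      best_start <- s - 1L
    }
  }
  if (best_len == 0) return(NULL)
  list(start = best_start, length = best_len)
}

# -- straight-line Fickett oracle -------------------------------------------

# independent table-lookup computation (tables re-typed, loop structure
# different from the implementation)
oracle_fickett <- function(seq) {
  pos_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  cont_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
  pos_prob <- rbind(
    A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
    C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.38),
    G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.66, 0.63, 0.48, 0.40),
    T = c(0.51, 0.60, 0.69, 0.64, 0.53, 0.54, 0.44, 0.51, 0.40, 0.30)
  )
  cont_prob <- rbind(
    A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
    C = c(0.50, 0.63, 0.59, 0.50, 0.46, 0.45, 0.47, 0.56, 0.59, 0.33),
    G = c(0.21, 0.40, 0.58, 0.59, 0.55, 0.44, 0.40, 0.39, 0.24, 0.23),
    T = c(0.30, 0.49, 0.56, 0.53, 0.48, 0.48, 0.34, 0.20, 0.09, 0.51)
  )
  pos_w <- c(A = 0.22, C = 0.23, G = 0.24, T = 0.18)
  cont_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  ch <- strsplit(seq, "")[[1]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    c0 <- 0; c1 <- 0; c2 <- 0; n_b <- 0
    for (i in seq_along(ch)) {
      if (ch[i] != b) next
      n_b <- n_b + 1
      r <- (i - 1) %% 3
      if (r == 0) c0 <- c0 + 1 else if (r == 1) c1 <- c1 + 1 else c2 <- c2 + 1
    }
    pv <- max(c0, c1, c2) / (min(c0, c1, c2) + 1)
    cv <- n_b / sum(ch != "N")
    pi <- 1; while (pv < pos_para[pi]) pi <- pi + 1
    ci <- 1; while (cv < cont_para[ci]) ci <- ci + 1
    total <- total + pos_prob[b, pi] * pos_w[[b]] + cont_prob[b, ci] * cont_w[[b]]
  }
  unname(total)
}

# -- naive seed-site oracle --------------------------------------------------

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_sites <- function(target, mirna) {
  rc7 <- oracle_revcomp(substr(mirna, 2, 8))
  rc6 <- oracle_revcomp(substr(mirna, 2, 7))
  n <- nchar(target)
  out <- list()
  for (p in seq_len(n)) {
    type <- NULL
    if (p + 6 <= n && substr(target, p, p + 6) == rc7) {
      type <- if (p + 7 <= n && substr(target, p + 7, p + 7) == "A") "8mer" else "7mer-m8"
    } else if (p + 5 <= n && substr(target, p, p + 5) == rc6) {
      type <- if (p + 6 <= n && substr(target, p + 6, p + 6) == "A") "7mer-A1" else "6mer"
    }
    if (!is.null(type)) {
      out[[length(out) + 1]] <- data.frame(start = p - 1L, site_type = type)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), site_type = character()))
  }
  do.call(rbind, out)
}

# -- conditional exact-test oracle ------------------------------------------

oracle_exact_p <- function(ya, yb, n_a, n_b, alpha) {
  t <- ya + yb
  if (t == 0) return(1)
  mu <- t / (n_a + n_b)
  pr <- numeric(t + 1)
  for (a in 0:t) {
    pr[a + 1] <- dnbinom(a, mu = n_a * mu, size = n_a / alpha) *
      dnbinom(t - a, mu = n_b * mu, size = n_b / alpha)
  }
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[ya + 1] * (1 + 1e-12)]))
}
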