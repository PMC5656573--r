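all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste, collapse = ""))
}

inframe_hexamers <- function(seq) {
  L <- nchar(seq)
  if (L < 6) return(character())
  starts <- seq.int(1L, L - 5L, by = 3L)
  h <- substring(seq, starts, starts + 5L)
  h[!str_detect(h, "N")]
}

#' Train a hexamer usage-bias model
#'
#' Counts in-frame hexamers (step 3) over the coding training sequences
#' (typically ORFs/CDS) and the noncoding training sequences, converts
#' them to Laplace-smoothed frequencies, and stores the log-ratio
#' `log(f_coding / f_noncoding)` for each of the 4096 hexamers.
#'
#' @param coding_seqs,noncoding_seqs Character vectors of training
#'   sequences.
#' @param pseudocount Additive smoothing count (> 0; default 1 keeps all
#'   log-ratios finite).
#' @return A `hexamer_model`: named numeric vector of 4096 log-ratios.
#' @export
train_hexamer_model <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0 || length(noncoding_seqs) == 0) {
    abort("both training sets must be non-empty")
  }
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  hx <- all_hexamers()
  count_set <- function(seqs) {
    tab <- table(unlist(lapply(seqs, inframe_hexamers)))
    cnt <- setNames(rep(0, length(hx)), hx)
    cnt[names(tab)] <- as.numeric(tab)
    cnt
  }
  cc <- count_set(coding_seqs)
  nc <- count_set(noncoding_seqs)
  fc <- (cc + pseudocount) / (sum(cc) + pseudocount * length(hx))
  fn <- (nc + pseudocount) / (sum(nc) + pseudocount * length(hx))
  structure(log(fc / fn), class = "hexamer_model")
}

#' Hexamer usage-bias score of an ORF
#'
#' Mean log-ratio over the in-frame (step 3) hexamers of the sequence.
#'
#' @param orf_seq ORF (or full-transcript) sequence; scores 0 with a
#'   warning below 6 nt.
#' @param model A `hexamer_model` from [train_hexamer_model()].
#' @return Mean log-ratio (positive = coding-like usage).
#' @export
hexamer_score <- function(orf_seq, model) {
  h <- inframe_hexamers(orf_seq)
  if (length(h) == 0) {
    warn("hexamer_score: sequence shorter than 6 nt; scoring 0")
    return(0)
  }
  mean(unclass(model)[h])
}
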