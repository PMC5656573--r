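# Fickett (1982) TESTCODE lookup tables as adopted by the CPAT method.
# Rows are the published parameter bins (position ratios, content
# fractions, descending); entries are the probability that a sequence
# with that parameter value is coding.
FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)

FICKETT_POSITION_PROB <- list(
  A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
  C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.38),
  G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.66, 0.63, 0.48, 0.40),
  T = c(0.51, 0.60, 0.69, 0.64, 0.53, 0.54, 0.44, 0.51, 0.40, 0.30)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.22, C = 0.23, G = 0.24, T = 0.18)

FICKETT_CONTENT_PROB <- list(
  A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
  C = c(0.50, 0.63, 0.59, 0.50, 0.46, 0.45, 0.47, 0.56, 0.59, 0.33),
  G = c(0.21, 0.40, 0.58, 0.59, 0.55, 0.44, 0.40, 0.39, 0.24, 0.23),
  T = c(0.30, 0.49, 0.56, 0.53, 0.48, 0.48, 0.34, 0.20, 0.09, 0.51)
)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

fickett_lookup <- function(value, para, prob) {
  prob[[which(value >= para)[[1]]]]
}

#' Fickett TESTCODE statistic
#'
#' For each base B, the position parameter is the maximum count of B
#' among the three codon positions divided by (minimum count + 1), and
#' the content parameter is the base's frequency; each is converted to a
#' coding probability through the published lookup tables and combined
#' with the published per-parameter weights.  `N` bases are excluded from
#' all counts, so the score is invariant to N-padding.
#'
#' @param seq Sequence over `{A,C,G,T,N}`, length >= 6 (a warning is
#'   issued below 200 nt, the calibration range of the tables).
#' @return The TESTCODE score (a weighted sum of table probabilities).
#' @export
fickett_testcode <- function(seq) {
  if (is.na(seq) || nchar(seq) < 6) abort("sequence shorter than 6 nt")
  if (nchar(seq) < 200) {
    warn("fickett_testcode: sequence shorter than 200 nt (table calibration range)")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence contains characters outside {A,C,G,T,N}")
  }
  keep <- chars != "N"
  total <- sum(keep)
  if (total == 0) abort("sequence contains only N")
  phase <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == b & phase == p & keep), numeric(1))
    pos_val <- max(cnt) / (min(cnt) + 1)
    cont_val <- sum(cnt) / total
    score <- score +
      fickett_lookup(pos_val, FICKETT_POSITION_PARA, FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(cont_val, FICKETT_CONTENT_PARA, FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  score
}
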