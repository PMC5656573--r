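#' Longest ATG-initiated open reading frame
#'
#' Scans the three sense frames of a spliced transcript sequence for the
#' longest ORF starting at ATG and ending at a stop codon; a trailing ORF
#' that runs off the 3' end without a stop counts, truncated to complete
#' codons.  Ties are broken by smaller start offset.
#'
#' @param seq Spliced transcript sequence over `{A,C,G,T,N}`.
#' @return Tibble with one row (`start`, `end` 0-based half-open offsets,
#'   `frame`, `length`) or zero rows if the sequence has no ATG.
#' @export
find_longest_orf <- function(seq) {
  if (is.na(seq) || nchar(seq) == 0) abort("empty sequence")
  L <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, L, by = 3L)
    starts <- starts[starts + 2L <= L]
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0) next
    stops <- which(codons %in% STOP_CODONS)
    for (a in atg) {
      s_after <- stops[stops >= a]
      if (length(s_after) > 0) {
        len <- (s_after[[1]] - a + 1L) * 3L
      } else {
        len <- (length(codons) - a + 1L) * 3L
      }
      start0 <- starts[[a]] - 1L
      if (is.null(best) || len > best$length ||
        (len == best$length && start0 < best$start)) {
        best <- tibble(
          start = start0, end = start0 + len,
          frame = frame, length = len
        )
      }
    }
  }
  if (is.null(best)) {
    return(tibble(
      start = integer(), end = integer(),
      frame = integer(), length = integer()
    ))
  }
  best
}

orf_subsequence <- function(seq) {
  orf <- find_longest_orf(seq)
  if (nrow(orf) == 0) return("")
  substr(seq, orf$start + 1L, orf$end)
}
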