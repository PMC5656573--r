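#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`, so downstream
#' code works on one DNA alphabet `{A,C,G,T,N}` regardless of whether the
#' source stored DNA or RNA (miRNA catalogs typically ship RNA).
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(id = character(), sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][[1]]))
  }
  seqs <- chartr("u", "t", as.character(set))
  seqs <- chartr("U", "T", toupper(seqs))
  if (any(nchar(seqs) == 0)) abort("FASTA record with empty sequence")
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `sequence` (or a named
#'   character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- tibble(id = names(records), sequence = unname(records))
  }
  set <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
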