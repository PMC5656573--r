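#' Read a gene-by-sample count matrix
#'
#' @param path TSV whose first column holds gene ids and remaining columns
#'   integer counts, one per sample.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tab[[1]])
  if (any(m < 0)) abort("negative entries in count matrix")
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix, genes in rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  tab <- bind_cols(
    tibble(gene_id = rownames(counts)),
    as_tibble(counts)
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write a ceRNA network edge table
#'
#' One row per lncRNA-mRNA pair, sorted by `(lncrna_id, mrna_id)`, with
#' the shared miRNA ids comma-joined in sorted order.
#'
#' @param network A `cerna_network` (see [build_cerna_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  edges <- network$edges |>
    mutate(
      shared_mirna_list = map_chr(
        .data$shared_mirna_ids,
        ~ paste(sort(.x), collapse = ",")
      )
    ) |>
    select(
      "lncrna_id", "mrna_id", "n_shared_mirnas", "n_unique_sites",
      "pearson_r", "shared_mirna_list"
    ) |>
    arrange(.data$lncrna_id, .data$mrna_id)
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Read a ceRNA network edge table written by [write_edge_table()]
#'
#' @param path Path to the TSV.
#' @return Tibble with the edge fields; `shared_mirna_ids` restored as a
#'   list column.
#' @export
read_edge_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      lncrna_id = readr::col_character(),
      mrna_id = readr::col_character(),
      n_shared_mirnas = readr::col_integer(),
      n_unique_sites = readr::col_integer(),
      pearson_r = readr::col_double(),
      shared_mirna_list = readr::col_character()
    )
  )
  tab$shared_mirna_ids <- map(
    tab$shared_mirna_list,
    ~ if (is.na(.x) || .x == "") character() else strsplit(.x, ",", fixed = TRUE)[[1]]
  )
  tab
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (set name, description, then member ids, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- map_chr(lines, ~ strsplit(.x, "\t", fixed = TRUE)[[1]][[1]])
  sets
}
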