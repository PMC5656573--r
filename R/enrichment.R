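#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability
#' `P(X >= k)` of observing `k` query genes in the set given the
#' universe, with BH correction across sets.  Query and sets are first
#' intersected with the universe (logged when genes are dropped); empty
#' sets are dropped with a warning.
#'
#' @param query_set Character vector of gene ids.
#' @param collection Named list of character vectors (gene sets).
#' @param universe Character vector: the background universe (e.g. all
#'   protein-coding genes of the annotation).
#' @return Tibble: `set`, `set_size`, `overlap`, `expected`, `p`, `q_bh`,
#'   sorted by `p`.
#' @export
hypergeometric_ora <- function(query_set, collection, universe) {
  query <- intersect(unique(query_set), universe)
  if (length(query) == 0) abort("empty query after intersection with universe")
  if (length(query) < length(unique(query_set))) {
    inform(paste0(
      length(unique(query_set)) - length(query),
      " query gene(s) outside the universe dropped"
    ))
  }
  sizes <- lengths(lapply(collection, intersect, universe))
  if (any(sizes == 0)) {
    warn(paste0(sum(sizes == 0), " empty gene set(s) dropped"))
    collection <- collection[sizes > 0]
  }
  if (length(collection) == 0) {
    return(tibble(
      set = character(), set_size = integer(), overlap = integer(),
      expected = numeric(), p = numeric(), q_bh = numeric()
    ))
  }
  N <- length(unique(universe))
  n <- length(query)
  res <- imap(collection, function(members, nm) {
    members <- intersect(members, universe)
    K <- length(unique(members))
    k <- length(intersect(query, members))
    tibble(
      set = nm, set_size = K, overlap = k,
      expected = n * K / N,
      # P(X >= k), upper tail
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  }) |> list_rbind()
  res |>
    mutate(q_bh = p.adjust(.data$p, "BH")) |>
    arrange(.data$p)
}
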