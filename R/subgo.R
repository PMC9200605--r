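#' Enumerate rooted sub-ontologies
#'
#' Every term roots one candidate sub-ontology: the term together with its
#' full descendant closure. Sub-ontologies smaller than `min_nodes` are
#' dropped; the rest are returned sorted by root id, so a run over the same
#' ontology is always ordered identically.
#'
#' @param dag A `go_dag`.
#' @param min_nodes Minimum node count (root included); `1` keeps leaf-rooted
#'   singletons.
#' @param namespace Optional namespace filter (e.g. `"biological_process"`).
#' @return A tibble with one row per sub-ontology: `root`, `root_name`,
#'   `namespace`, `n_nodes`, and a `nodes` list-column of term ids.
#' @export
enumerate_subgos <- function(dag, min_nodes = 1L, namespace = NULL) {
  stopifnot(min_nodes >= 1L)
  terms <- dag$terms
  if (!is.null(namespace)) terms <- filter(terms, .data$namespace %in% !!namespace)

  # accumulate descendant closures bottom-up along reverse topological order
  desc <- vector("list", nrow(dag$terms))
  names(desc) <- dag$terms$term
  for (t in rev(dag$topo_order)) {
    d <- t
    for (ch in dag$children[[t]]) d <- c(d, desc[[ch]])
    desc[[t]] <- unique(d)
  }

  out <- tibble(
    root = terms$term,
    root_name = terms$name,
    namespace = terms$namespace,
    nodes = unname(desc[terms$term])
  ) %>%
    mutate(n_nodes = lengths(.data$nodes)) %>%
    filter(.data$n_nodes >= min_nodes) %>%
    arrange(.data$root) %>%
    select("root", "root_name", "namespace", "n_nodes", "nodes")
  out
}

#' Restrict a term set to a sub-ontology
#'
#' @param term_set Character vector of term ids.
#' @param subgo_nodes Character vector of sub-ontology node ids (a `nodes`
#'   entry from [enumerate_subgos()]).
#' @return The intersection, preserving the order of `term_set`.
#' @export
restrict_term_set <- function(term_set, subgo_nodes) {
  term_set[term_set %in% subgo_nodes]
}
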