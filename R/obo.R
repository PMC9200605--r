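#' Parse an OBO 1.2 ontology file
#'
#' Reads a flat OBO file (format-version 1.2) into an ontology DAG. Both
#' `is_a` and `relationship: part_of` lines are treated as parent edges;
#' other relationship types are ignored. Obsolete terms are dropped, and
#' `alt_id`s are mapped back to their canonical term so that edges written
#' against a secondary id still resolve.
#'
#' @param path Path to an OBO file.
#' @return A `go_dag` object: a list with
#'   * `terms`: tibble with columns `term`, `name`, `namespace`;
#'   * `parents`, `children`: named lists of character vectors;
#'   * `ancestors`: named list of self-inclusive ancestor sets;
#'   * `alt_ids`: named character vector mapping alternate to canonical ids.
#' @details The graph is verified acyclic at load time; a cycle raises an
#'   error naming one offending edge. A parent id that matches no `[Term]`
#'   stanza (directly or via `alt_id`) is also an error.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) abort(paste0("OBO file not found: ", path))
  parse_obo_lines(readLines(path, warn = FALSE))
}

parse_obo_lines <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  # split into stanzas; header is everything before the first stanza marker
  stanza_starts <- grep("^\\[", lines)
  header <- if (length(stanza_starts)) lines[seq_len(stanza_starts[1] - 1)] else lines
  fv <- grep("^format-version:", header, value = TRUE)
  if (length(fv) && !grepl("1\\.2", fv[1])) {
    warn(paste0("expected OBO format-version 1.2, found: ", sub("^format-version:\\s*", "", fv[1])))
  }
  default_ns <- sub("^default-namespace:\\s*", "", grep("^default-namespace:", header, value = TRUE))
  if (!length(default_ns)) default_ns <- "biological_process"

  term_idx <- stanza_starts[lines[stanza_starts] == "[Term]"]
  bounds <- c(stanza_starts, length(lines) + 1L)
  recs <- lapply(term_idx, function(s) {
    e <- bounds[which(bounds == s) + 1L] - 1L
    chunk <- lines[(s + 1L):e]
    chunk <- chunk[nzchar(chunk)]
    get <- function(key) {
      v <- chunk[startsWith(chunk, paste0(key, ":"))]
      v <- sub(paste0("^", key, ":\\s*"), "", v)
      sub("\\s*!.*$", "", v) # strip trailing comments
    }
    rel <- get("relationship")
    part_of <- sub("^part_of\\s+", "", rel[startsWith(rel, "part_of")])
    list(
      id = get("id")[1],
      name = if (length(get("name"))) get("name")[1] else NA_character_,
      namespace = if (length(get("namespace"))) get("namespace")[1] else default_ns[1],
      is_a = get("is_a"),
      part_of = part_of,
      alt_id = get("alt_id"),
      obsolete = any(get("is_obsolete") == "true")
    )
  })
  recs <- recs[!vapply(recs, function(r) is.na(r$id) || !nzchar(r$id), logical(1))]
  if (!length(recs)) abort("no [Term] stanzas found")

  obsolete_ids <- vapply(recs[vapply(recs, `[[`, logical(1), "obsolete")], `[[`, character(1), "id")
  recs <- recs[!vapply(recs, `[[`, logical(1), "obsolete")]
  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort(paste0("duplicate term ids: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", ")))

  alt <- unlist(lapply(recs, function(r) setNames(rep(r$id, length(r$alt_id)), r$alt_id)))
  canonical <- function(x) {
    hit <- !is.na(match(x, names(alt)))
    x[hit] <- alt[x[hit]]
    x
  }

  parents <- lapply(recs, function(r) {
    p <- canonical(unique(c(r$is_a, r$part_of)))
    p <- setdiff(p, obsolete_ids)
    dangling <- setdiff(p, ids)
    if (length(dangling)) abort(paste0("term ", r$id, " references unknown parent id(s): ",
      paste(dangling, collapse = ", ")))
    p
  })
  names(parents) <- ids

  new_go_dag(
    terms = tibble(
      term = ids,
      name = vapply(recs, `[[`, character(1), "name"),
      namespace = vapply(recs, `[[`, character(1), "namespace")
    ),
    parents = parents,
    alt_ids = if (is.null(alt)) character(0) else alt
  )
}

# Build and validate a go_dag from a terms tibble plus a parents list.
new_go_dag <- function(terms, parents, alt_ids = character(0)) {
  ids <- terms$term
  parents <- parents[ids]
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)

  # Kahn topological order; leftovers imply a cycle
  indeg <- lengths(parents)
  order <- character(0)
  queue <- ids[indeg == 0L]
  indeg_left <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]]) {
      indeg_left[ch] <- indeg_left[ch] - 1L
      if (indeg_left[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    cyc <- ids[indeg_left > 0L]
    bad <- cyc[1]
    bad_parent <- intersect(parents[[bad]], cyc)[1]
    abort(paste0("ontology contains a cycle; offending edge: ", bad, " -> ", bad_parent))
  }

  # self-inclusive ancestor closures in topological order
  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  for (t in order) {
    anc <- t
    for (p in parents[[t]]) anc <- c(anc, ancestors[[p]])
    ancestors[[t]] <- unique(anc)
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         ancestors = ancestors, topo_order = order, alt_ids = alt_ids),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  ns <- table(x$terms$namespace)
  cat("<go_dag> ", nrow(x$terms), " terms, ",
      sum(lengths(x$parents)), " parent edges\n", sep = "")
  cat("  namespaces: ", paste0(names(ns), " (", ns, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ancestors and descendants of ontology terms
#'
#' `term_ancestors()` returns the ancestor closure of a term (following
#' parent edges), `term_descendants()` the descendant closure (reversed
#' edges). Both are self-inclusive by default, matching the convention used
#' for common-ancestor searches and sub-ontology membership.
#'
#' @param dag A `go_dag`.
#' @param term A single term id (alternate ids are resolved).
#' @param include_self Include `term` itself in the result?
#' @return Character vector of term ids.
#' @export
term_ancestors <- function(dag, term, include_self = TRUE) {
  term <- resolve_term(dag, term)
  anc <- dag$ancestors[[term]]
  if (include_self) anc else setdiff(anc, term)
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(dag, term, include_self = TRUE) {
  term <- resolve_term(dag, term)
  seen <- character(0)
  queue <- term
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, dag$children[[t]])
  }
  if (include_self) seen else setdiff(seen, term)
}

resolve_term <- function(dag, term) {
  if (term %in% dag$terms$term) return(term)
  if (term %in% names(dag$alt_ids)) return(unname(dag$alt_ids[[term]]))
  abort(paste0("unknown term id: ", term))
}

# namespace roots: terms without parents
dag_roots <- function(dag) dag$terms$term[lengths(dag$parents[dag$terms$term]) == 0L]
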