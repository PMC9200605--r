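#' Read a gene-to-term annotation map
#'
#' Accepts either a two-column TSV (`gene`, `term id`) or a GAF 2.x file
#' (comment lines start with `!`; column 3 is the gene symbol, column 4 the
#' qualifier, column 5 the term). GAF rows with a `NOT` qualifier are
#' dropped.
#'
#' @param path Path to the annotation file.
#' @return Tibble with columns `gene`, `term`, one row per annotation.
#' @export
read_gene2go <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(body)) abort(paste0("no annotation rows in ", path))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (ncol1 >= 15L) { # GAF 2.x
    keep <- !vapply(fields, function(f) grepl("\\bNOT\\b", f[4]), logical(1))
    fields <- fields[keep]
    out <- tibble(
      gene = vapply(fields, `[[`, character(1), 3L),
      term = vapply(fields, `[[`, character(1), 5L)
    )
  } else if (ncol1 >= 2L) {
    out <- tibble(
      gene = vapply(fields, `[[`, character(1), 1L),
      term = vapply(fields, `[[`, character(1), 2L)
    )
    # tolerate a header row
    if (tolower(out$gene[1]) %in% c("gene", "gene_symbol", "symbol")) out <- out[-1, ]
  } else {
    abort(paste0("cannot interpret ", path, ": expected 2-column TSV or GAF 2.x"))
  }
  distinct(out)
}

# Drop annotations whose term is absent from the ontology (after alt_id
# resolution); warn once with the count.
validate_gene2go <- function(gene2go, dag) {
  term <- gene2go$term
  hit_alt <- !is.na(match(term, names(dag$alt_ids)))
  term[hit_alt] <- dag$alt_ids[term[hit_alt]]
  known <- term %in% dag$terms$term
  if (any(!known)) {
    warn(paste0(sum(!known), " annotation row(s) reference term ids absent from the ontology; dropped"))
  }
  distinct(tibble(gene = gene2go$gene[known], term = term[known]))
}

#' Information content of ontology terms from an annotation corpus
#'
#' Propagates each gene's annotations to all ancestors, then sets
#' `p(t)` to the fraction of annotated genes reaching `t` and
#' `IC(t) = -ln p(t)`. Terms no gene reaches get add-one smoothed content,
#' `IC = ln(corpus_size + 1)`, so they remain finite and maximally
#' informative. With every gene propagating to the namespace root, the root
#' has IC 0 and IC is monotone non-decreasing from ancestors to descendants.
#'
#' Alternatively (`mode = "structure"`) the corpus is ignored and
#' `p(t) = |descendants(t) ∪ {t}| / |namespace terms|`, a purely topological
#' fallback for when no annotation corpus is trusted.
#'
#' @param dag A `go_dag`.
#' @param gene2go Tibble with columns `gene`, `term` (ignored for
#'   `mode = "structure"`).
#' @param mode `"corpus"` (default) or `"structure"`.
#' @return An `ic_table`: tibble with columns `term`, `n_genes`, `p`, `ic`,
#'   carrying the corpus size in attribute `corpus_size`.
#' @export
compute_ic <- function(dag, gene2go = NULL, mode = c("corpus", "structure")) {
  mode <- match.arg(mode)
  ids <- dag$terms$term
  if (mode == "structure") {
    ns <- dag$terms$namespace
    ns_size <- table(ns)[ns]
    n_desc <- vapply(ids, function(t) length(term_descendants(dag, t)), integer(1))
    p <- as.numeric(n_desc) / as.numeric(ns_size)
    out <- tibble(term = ids, n_genes = NA_integer_, p = p, ic = -log(p))
    attr(out, "corpus_size") <- NA_integer_
    class(out) <- c("ic_table", class(out))
    return(out)
  }

  if (is.null(gene2go) || nrow(gene2go) == 0L) abort("empty annotation corpus")
  ann <- validate_gene2go(gene2go, dag)
  if (nrow(ann) == 0L) abort("empty annotation corpus after dropping unknown terms")

  by_gene <- split(ann$term, ann$gene)
  n_corpus <- length(by_gene)
  counts <- setNames(integer(length(ids)), ids)
  for (terms in by_gene) {
    reached <- unique(unlist(dag$ancestors[terms], use.names = FALSE))
    counts[reached] <- counts[reached] + 1L
  }
  p <- ifelse(counts > 0L, counts / n_corpus, 1 / (n_corpus + 1))
  out <- tibble(term = ids, n_genes = unname(counts), p = unname(p), ic = -log(unname(p)))
  attr(out, "corpus_size") <- n_corpus
  class(out) <- c("ic_table", class(out))
  out
}

# named IC lookup vector
ic_vector <- function(ic) setNames(ic$ic, ic$term)
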