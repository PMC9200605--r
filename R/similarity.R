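#' Most informative common ancestor of two terms
#'
#' Finds the shared ancestor (self-inclusive) of `t1` and `t2` carrying the
#' highest information content. When `restrict` is supplied the search space
#' is intersected with those nodes, which is how similarity is confined to a
#' sub-ontology: ancestors outside it cannot contribute, so signal local to
#' the sub-ontology is not flattened by the global root. Ties are broken by
#' the lexicographically smallest term id to keep runs reproducible.
#'
#' @param dag A `go_dag`.
#' @param ic An `ic_table` from [compute_ic()].
#' @param t1,t2 Term ids.
#' @param restrict Optional character vector of sub-ontology node ids.
#' @return The MICA term id, or `NA_character_` when no common ancestor lies
#'   within the restriction.
#' @export
mica <- function(dag, ic, t1, t2, restrict = NULL) {
  a1 <- term_ancestors(dag, t1)
  a2 <- term_ancestors(dag, t2)
  common <- intersect(a1, a2)
  if (!is.null(restrict)) common <- intersect(common, restrict)
  if (!length(common)) return(NA_character_)
  icv <- ic_vector(ic)[common]
  cand <- common[icv == max(icv)]
  sort(cand)[1]
}

#' Lin semantic similarity between two terms
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))`, which is 1 for identical informative
#' terms and 0 when the only shared ancestor is uninformative (IC 0) or when
#' no common ancestor exists inside the restriction. The ratio is
#' independent of the logarithm base used for IC.
#'
#' @inheritParams mica
#' @return Similarity in `[0, 1]`.
#' @export
lin_similarity <- function(dag, ic, t1, t2, restrict = NULL) {
  m <- mica(dag, ic, t1, t2, restrict)
  if (is.na(m)) return(0)
  icv <- ic_vector(ic)
  denom <- icv[[resolve_term(dag, t1)]] + icv[[resolve_term(dag, t2)]]
  if (denom <= 0) return(0)
  min(1, 2 * icv[[m]] / denom)
}

#' Best-match-average similarity between two term sets
#'
#' Each term of one set is matched to its most similar term in the other
#' set; the two directional means are averaged. Empty sets (e.g. after
#' restriction to a sub-ontology that a sample does not touch) score 0
#' against anything — eligibility filtering happens downstream, not here.
#'
#' @inheritParams mica
#' @param set_a,set_b Character vectors of term ids. Callers restrict them
#'   to the sub-ontology first (see [restrict_term_set()]); any stray terms
#'   are intersected away here as well.
#' @return Similarity in `[0, 1]`.
#' @export
set_similarity <- function(dag, ic, set_a, set_b, restrict = NULL) {
  if (!is.null(restrict)) {
    set_a <- restrict_term_set(set_a, restrict)
    set_b <- restrict_term_set(set_b, restrict)
  }
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) return(0)
  terms <- union(set_a, set_b)
  L <- term_lin_matrix(dag, ic, terms, restrict)
  ia <- match(set_a, terms); ib <- match(set_b, terms)
  sub <- L[ia, ib, drop = FALSE]
  0.5 * (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max)))
}

# Lin similarity matrix over a vector of terms, restricted (or not) to a
# sub-ontology's node set. Candidate ancestors are the restriction nodes, or
# the union of full ancestor sets when unrestricted.
term_lin_matrix <- function(dag, ic, terms, restrict = NULL) {
  terms <- vapply(terms, function(t) resolve_term(dag, t), character(1))
  anc_sets <- dag$ancestors[terms]
  cand <- if (is.null(restrict)) unique(unlist(anc_sets, use.names = FALSE)) else restrict
  icv <- ic_vector(ic)
  A <- matrix(FALSE, nrow = length(terms), ncol = length(cand))
  for (i in seq_along(terms)) A[i, ] <- cand %in% anc_sets[[i]]
  M <- mica_ic_matrix_cpp(A, unname(icv[cand]))
  ict <- unname(icv[terms])
  denom <- outer(ict, ict, `+`)
  L <- ifelse(is.na(M) | denom <= 0, 0, 2 * M / denom)
  L[L > 1] <- 1
  L[L < 0] <- 0
  dimnames(L) <- list(terms, terms)
  L
}

# Shared similarity context over the terms the cohort actually uses.
# Candidates are every ontology term, ordered by id so that the index
# tie-break in the compiled merge realises "smallest term id wins" for
# equal-IC common ancestors. Holds the global MICA IC table (M), the
# winning candidate per pair (W), and the global Lin matrix (L); sub-
# ontology restrictions reuse these and only re-derive pairs whose global
# winner falls outside the restriction.
make_sim_context <- function(dag, ic, used_terms) {
  cand <- sort(dag$terms$term)
  icv <- ic_vector(ic)[cand]
  used_terms <- vapply(used_terms, function(t) resolve_term(dag, t), character(1))
  anc_idx <- lapply(used_terms, function(t) {
    idx <- match(dag$ancestors[[t]], cand)
    idx[order(-icv[idx], idx)] - 1L
  })
  tabs <- lin_tables_cpp(anc_idx, unname(icv))
  ic_used <- unname(icv[match(used_terms, cand)])
  denom <- outer(ic_used, ic_used, `+`)
  L <- ifelse(is.na(tabs$M) | denom <= 0, 0, 2 * tabs$M / denom)
  L[L > 1] <- 1; L[L < 0] <- 0
  list(terms = unname(used_terms), cand = cand, ic_cand = unname(icv),
       ic_used = ic_used, anc_idx = anc_idx, M = tabs$M, W = tabs$W,
       denom = denom, L = L)
}

# Lin matrix over a subset of context terms, restricted to a sub-ontology.
# sub_idx: integer indices into ctx$terms; nodes: character node ids.
ctx_lin_submatrix <- function(ctx, sub_idx, nodes = NULL) {
  L <- ctx$L[sub_idx, sub_idx, drop = FALSE]
  if (is.null(nodes)) return(L)
  in_nodes <- ctx$cand %in% nodes
  W <- ctx$W[sub_idx, sub_idx, drop = FALSE]
  # pairs whose global winner is outside the restriction need a re-derive
  redo <- which(W >= 0L & !in_nodes[W + 1L], arr.ind = TRUE)
  redo <- redo[redo[, 1] <= redo[, 2], , drop = FALSE]
  if (nrow(redo)) {
    pairs <- cbind(sub_idx[redo[, 1]] - 1L, sub_idx[redo[, 2]] - 1L)
    m <- mica_restricted_pairs_cpp(ctx$anc_idx, ctx$ic_cand, in_nodes, pairs)
    d <- ctx$denom[cbind(sub_idx[redo[, 1]], sub_idx[redo[, 2]])]
    v <- ifelse(is.na(m) | d <= 0, 0, pmin(1, pmax(0, 2 * m / d)))
    L[redo] <- v
    L[redo[, c(2, 1), drop = FALSE]] <- v
  }
  L
}

# Best-match-average matrix from a Lin matrix and per-sample index sets
# (indices into the rows of L). Row-max table in C++, directional means via
# a BLAS product.
bma_from_lin <- function(L, sets_idx) {
  n <- length(sets_idx)
  sizes <- lengths(sets_idx)
  S <- matrix(0, n, n)
  nonempty <- sizes > 0L
  if (any(nonempty)) {
    C <- set_rowmax_cpp(L, sets_idx) # T x n
    Mn <- matrix(0, n, nrow(L))
    for (i in which(nonempty)) Mn[i, sets_idx[[i]]] <- 1 / sizes[i]
    D <- Mn %*% C # D[i, j] = mean over set i of best match in set j
    S <- 0.5 * (D + t(D))
    S[!nonempty, ] <- 0
    S[, !nonempty] <- 0
  }
  diag(S) <- as.numeric(nonempty)
  S
}

#' Pairwise sample similarity matrix within one sub-ontology
#'
#' Restricts every sample's term set to the sub-ontology, then computes the
#' best-match-average Lin similarity for each unordered sample pair with the
#' common-ancestor search confined to the sub-ontology (or spanning the full
#' ontology with `mica_scope = "global"`). Samples whose restricted set is
#' empty get zero rows and a zero diagonal; non-empty samples have diagonal
#' 1.
#'
#' @param cohort An annotated cohort tibble (see [annotate_cohort()]) with a
#'   `terms` list-column.
#' @param subgo_nodes Character vector of sub-ontology node ids.
#' @param dag A `go_dag`.
#' @param ic An `ic_table`.
#' @param mica_scope `"subgo"` (default) or `"global"`.
#' @return Symmetric numeric matrix with sample ids as dimnames and an
#'   `eligible` attribute (logical: non-empty restricted set per sample).
#' @export
similarity_matrix <- function(cohort, subgo_nodes, dag, ic,
                              mica_scope = c("subgo", "global")) {
  mica_scope <- match.arg(mica_scope)
  stopifnot("terms" %in% names(cohort))
  sets <- lapply(cohort$terms, restrict_term_set, subgo_nodes = subgo_nodes)
  used <- sort(unique(unlist(sets, use.names = FALSE)))
  n <- nrow(cohort)
  if (!length(used)) {
    S <- matrix(0, n, n, dimnames = list(cohort$sample_id, cohort$sample_id))
    attr(S, "eligible") <- setNames(rep(FALSE, n), cohort$sample_id)
    return(S)
  }
  ctx <- make_sim_context(dag, ic, used)
  L <- ctx_lin_submatrix(ctx, seq_along(used),
                         nodes = if (mica_scope == "subgo") subgo_nodes else NULL)
  idx <- lapply(sets, function(s) match(s, used))
  S <- bma_from_lin(L, idx)
  dimnames(S) <- list(cohort$sample_id, cohort$sample_id)
  attr(S, "eligible") <- setNames(lengths(sets) > 0L, cohort$sample_id)
  S
}
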