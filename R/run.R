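#' Run the sub-ontology functional analysis over a cohort
#'
#' The core loop: for every sub-ontology, restrict each sample's term set to
#' it, build the pairwise best-match-average Lin similarity matrix, cut a
#' Ward tree into two groups, and test the cluster-by-phenotype 2x2 table
#' with Fisher's exact test. Benjamini-Hochberg FDR is computed across all
#' *tested* sub-ontologies (skipped ones do not enter the family). A
#' sub-ontology is tested only when at least `min_eligible` samples in each
#' phenotype class have a non-empty restricted term set; the rest are
#' reported with `status = "skipped"`.
#'
#' @param cohort Annotated cohort tibble ([annotate_cohort()]); needs at
#'   least 4 samples and both phenotype classes.
#' @param dag A `go_dag`.
#' @param ic An `ic_table` from [compute_ic()].
#' @param gene2go Annotation tibble (`gene`, `term`) used to report the
#'   genes under each significant root.
#' @param subgos Optional sub-ontology table from [enumerate_subgos()];
#'   enumerated from `dag` when `NULL`.
#' @param min_subgo_nodes Minimum sub-ontology size when enumerating
#'   (default 2: a single-term sub-ontology reduces to term presence, which
#'   the per-term baseline already covers).
#' @param namespace Optional namespace filter for enumeration.
#' @param min_eligible Minimum samples with non-empty restricted sets
#'   required in each class (default 2).
#' @param mica_scope Confine the common-ancestor search to the
#'   sub-ontology (`"subgo"`, default) or search the full ontology
#'   (`"global"`).
#' @param ward_method Ward linkage variant, see [ward_two_clusters()].
#' @return A `subgofa_result`: tibble with one row per sub-ontology, sorted
#'   by FDR, then p, then root id (tested rows first). Columns: `root`,
#'   `root_name`, `n_nodes`, `status`, `n_eligible`, `n_eligible_case`,
#'   `n_eligible_ctrl`, `cluster1_case`, `cluster1_ctrl`, `cluster2_case`,
#'   `cluster2_ctrl`, `p_value`, `fdr`, `zero_margin`, `degenerate`, plus
#'   list-columns `genes_under_root` and `clusters` (named integer vector
#'   per sample).
#' @export
run_subgofa <- function(cohort, dag, ic, gene2go,
                        subgos = NULL, min_subgo_nodes = 2L, namespace = NULL,
                        min_eligible = 2L,
                        mica_scope = c("subgo", "global"),
                        ward_method = c("ward.D2", "ward.D")) {
  mica_scope <- match.arg(mica_scope)
  ward_method <- match.arg(ward_method)
  stopifnot("terms" %in% names(cohort), nrow(cohort) >= 4L)
  if (!all(c("case", "ctrl") %in% cohort$label)) {
    abort("cohort must contain both 'case' and 'ctrl' samples")
  }
  if (is.null(subgos)) subgos <- enumerate_subgos(dag, min_subgo_nodes, namespace)
  if (nrow(subgos) == 0L) {
    warn("no sub-ontologies to test")
  }

  ann <- validate_gene2go(gene2go, dag)
  observed_genes <- unique(unlist(cohort$genes, use.names = FALSE))
  ann_obs <- ann[ann$gene %in% observed_genes, , drop = FALSE]
  is_case <- cohort$label == "case"

  # one shared context over every term the cohort carries; per-sub-GO work
  # then only re-derives MICAs whose global winner leaves the restriction
  used_all <- sort(unique(unlist(cohort$terms, use.names = FALSE)))
  ctx <- if (length(used_all)) make_sim_context(dag, ic, used_all) else NULL
  sets_all <- lapply(cohort$terms, function(s) match(intersect(s, used_all), used_all))

  rows <- lapply(seq_len(nrow(subgos)), function(i) {
    nodes <- subgos$nodes[[i]]
    in_sub <- used_all %in% nodes
    sets <- lapply(sets_all, function(s) s[in_sub[s]])
    eligible <- lengths(sets) > 0L
    n_el_case <- sum(eligible & is_case)
    n_el_ctrl <- sum(eligible & !is_case)
    base <- tibble(
      root = subgos$root[i], root_name = subgos$root_name[i],
      n_nodes = subgos$n_nodes[i],
      n_eligible = sum(eligible),
      n_eligible_case = n_el_case, n_eligible_ctrl = n_el_ctrl
    )
    if (n_el_case < min_eligible || n_el_ctrl < min_eligible) {
      return(mutate(base, status = "skipped",
        cluster1_case = NA_integer_, cluster1_ctrl = NA_integer_,
        cluster2_case = NA_integer_, cluster2_ctrl = NA_integer_,
        p_value = NA_real_, zero_margin = NA, degenerate = NA,
        genes_under_root = list(character(0)),
        clusters = list(NULL)))
    }
    sub_idx <- which(in_sub)
    L <- ctx_lin_submatrix(ctx, sub_idx,
                           nodes = if (mica_scope == "subgo") nodes else NULL)
    sets_sub <- lapply(sets, function(s) match(s, sub_idx))
    S <- bma_from_lin(L, sets_sub)
    dimnames(S) <- list(cohort$sample_id, cohort$sample_id)
    cl <- ward_two_clusters(S, method = ward_method)
    tab <- matrix(c(
      sum(cl == 1L & is_case), sum(cl == 1L & !is_case),
      sum(cl == 2L & is_case), sum(cl == 2L & !is_case)
    ), nrow = 2, byrow = TRUE)
    p <- fisher_exact_2x2(tab)
    genes <- sort(unique(ann_obs$gene[ann_obs$term %in% nodes]))
    mutate(base, status = "tested",
      cluster1_case = tab[1, 1], cluster1_ctrl = tab[1, 2],
      cluster2_case = tab[2, 1], cluster2_ctrl = tab[2, 2],
      p_value = as.numeric(p), zero_margin = attr(p, "zero_margin"),
      degenerate = attr(cl, "degenerate"),
      genes_under_root = list(genes),
      clusters = list(cl))
  })
  res <- bind_rows(rows)
  subgo_nodes <- setNames(subgos$nodes, subgos$root)
  if (nrow(res) == 0L || !any(res$status == "tested")) {
    warn("no eligible sub-ontologies were tested")
    res$fdr <- rep(NA_real_, nrow(res))
    return(new_subgofa_result(res, cohort, mica_scope, ward_method, min_eligible, subgo_nodes))
  }
  res$fdr <- NA_real_
  tested <- res$status == "tested"
  res$fdr[tested] <- bh_fdr(res$p_value[tested])
  res <- arrange(res, .data$status != "tested", .data$fdr, .data$p_value, .data$root)
  res <- select(res, "root", "root_name", "n_nodes", "status", "n_eligible",
    "n_eligible_case", "n_eligible_ctrl",
    "cluster1_case", "cluster1_ctrl", "cluster2_case", "cluster2_ctrl",
    "p_value", "fdr", "zero_margin", "degenerate", "genes_under_root", "clusters")
  new_subgofa_result(res, cohort, mica_scope, ward_method, min_eligible, subgo_nodes)
}

new_subgofa_result <- function(res, cohort, mica_scope, ward_method, min_eligible,
                               subgo_nodes = NULL) {
  structure(res,
    class = c("subgofa_result", class(tibble())),
    subgo_nodes = subgo_nodes,
    n_samples = nrow(cohort),
    n_case = sum(cohort$label == "case"),
    n_ctrl = sum(cohort$label == "ctrl"),
    mica_scope = mica_scope, ward_method = ward_method,
    min_eligible = min_eligible)
}

#' @export
print.subgofa_result <- function(x, ...) {
  tested <- sum(x$status == "tested")
  cat("<subgofa_result> ", nrow(x), " sub-ontologies (", tested, " tested), ",
      attr(x, "n_case"), " cases / ", attr(x, "n_ctrl"), " controls\n", sep = "")
  sig <- sum(x$fdr < 0.05 & x$status == "tested", na.rm = TRUE)
  cat("  roots at FDR < 0.05: ", sig, "\n", sep = "")
  NextMethod()
}

#' Tidy a sub-ontology analysis result
#'
#' Drops the list-columns, leaving one plain row per sub-ontology.
#'
#' @param x A `subgofa_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.subgofa_result <- function(x, ...) {
  out <- as_tibble(x)
  out$n_genes_under_root <- lengths(out$genes_under_root)
  select(out, -"genes_under_root", -"clusters")
}

#' One-row summary of a sub-ontology analysis
#'
#' @param x A `subgofa_result`.
#' @param fdr_threshold Threshold used for the significant-root count.
#' @param ... Unused.
#' @return A one-row tibble: sample counts, numbers of tested / skipped /
#'   significant sub-ontologies and the smallest FDR.
#' @export
glance.subgofa_result <- function(x, fdr_threshold = 0.05, ...) {
  tested <- x$status == "tested"
  tibble(
    n_samples = attr(x, "n_samples"),
    n_case = attr(x, "n_case"),
    n_ctrl = attr(x, "n_ctrl"),
    n_subgos = nrow(x),
    n_tested = sum(tested),
    n_skipped = sum(!tested),
    n_significant = sum(tested & x$fdr < fdr_threshold, na.rm = TRUE),
    min_fdr = if (any(tested)) min(x$fdr[tested]) else NA_real_
  )
}

#' Write analysis results as TSV files
#'
#' Writes `results.tsv` (one row per sub-ontology, gene lists collapsed
#' with commas) and, for each root below the FDR threshold, a
#' `clusters_<root>.tsv` with the per-sample cluster assignment.
#'
#' @param x A `subgofa_result`.
#' @param dir Output directory (created if needed).
#' @param fdr_threshold Threshold selecting roots that get cluster files.
#' @return `dir`, invisibly.
#' @export
write_subgofa_results <- function(x, dir, fdr_threshold = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- tidy(x)
  flat$genes_under_root <- vapply(as_tibble(x)$genes_under_root,
                                  paste, character(1), collapse = ",")
  readr::write_tsv(flat, file.path(dir, "results.tsv"))
  sig <- which(x$status == "tested" & x$fdr < fdr_threshold)
  for (i in sig) {
    cl <- x$clusters[[i]]
    readr::write_tsv(
      tibble(sample_id = names(cl), cluster = as.integer(cl)),
      file.path(dir, paste0("clusters_", gsub("[^A-Za-z0-9]", "_", x$root[i]), ".tsv")))
  }
  invisible(dir)
}
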