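#' Conventional per-feature Fisher baselines
#'
#' `fisher_per_gene()` tests, for every gene observed in at least one
#' sample's mosaic regions, whether carrying the gene separates cases from
#' controls; `fisher_per_term()` does the same for ontology terms in the
#' samples' derived term sets. Presence is binary per sample (mosaic events
#' carry no dosage here). Both apply a two-sided Fisher's exact test to the
#' presence-by-class 2x2 table and Benjamini-Hochberg FDR across all tested
#' features.
#'
#' @param cohort Annotated cohort tibble with `genes` (and for terms,
#'   `terms`) list-columns.
#' @param gene2go Optional annotation tibble (`gene`, `term`). When given
#'   to `fisher_per_term()`, the term-to-gene map (restricted to genes seen
#'   in the cohort) is attached so [selected_genes()] can translate
#'   significant terms into genes.
#' @return A `feature_fisher` tibble: `feature`, `present_case`,
#'   `present_ctrl`, `absent_case`, `absent_ctrl`, `p_value`, `fdr`, sorted
#'   by FDR then p then feature.
#' @export
fisher_per_gene <- function(cohort) {
  feature_fisher(cohort, "genes", feature_type = "gene")
}

#' @rdname fisher_per_gene
#' @export
fisher_per_term <- function(cohort, gene2go = NULL) {
  res <- feature_fisher(cohort, "terms", feature_type = "term")
  if (!is.null(gene2go)) {
    observed <- unique(unlist(cohort$genes, use.names = FALSE))
    map <- gene2go[gene2go$gene %in% observed, , drop = FALSE]
    attr(res, "term2gene") <- split(map$gene, map$term)
  }
  res
}

feature_fisher <- function(cohort, col, feature_type) {
  stopifnot(col %in% names(cohort))
  is_case <- cohort$label == "case"
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  long <- tibble(
    sample = rep(cohort$sample_id, lengths(cohort[[col]])),
    case = rep(is_case, lengths(cohort[[col]])),
    feature = unlist(cohort[[col]], use.names = FALSE)
  ) %>% distinct()
  if (nrow(long) == 0L) {
    out <- tibble(feature = character(0), present_case = integer(0),
      present_ctrl = integer(0), absent_case = integer(0),
      absent_ctrl = integer(0), p_value = numeric(0), fdr = numeric(0))
  } else {
    counts <- long %>%
      group_by(.data$feature) %>%
      summarise(present_case = sum(.data$case), present_ctrl = sum(!.data$case),
                .groups = "drop") %>%
      mutate(absent_case = n_case - .data$present_case,
             absent_ctrl = n_ctrl - .data$present_ctrl)
    counts$p_value <- vapply(seq_len(nrow(counts)), function(i) {
      as.numeric(fisher_exact_2x2(c(counts$present_case[i], counts$present_ctrl[i],
                                    counts$absent_case[i], counts$absent_ctrl[i])))
    }, numeric(1))
    counts$fdr <- bh_fdr(counts$p_value)
    out <- arrange(counts, .data$fdr, .data$p_value, .data$feature)
  }
  structure(out,
    class = c("feature_fisher", class(tibble())),
    feature_type = feature_type, n_case = n_case, n_ctrl = n_ctrl)
}

#' @export
print.feature_fisher <- function(x, ...) {
  cat("<feature_fisher> ", nrow(x), " ", attr(x, "feature_type"),
      " features, ", attr(x, "n_case"), " cases / ", attr(x, "n_ctrl"),
      " controls\n", sep = "")
  NextMethod()
}

#' @export
tidy.feature_fisher <- function(x, ...) as_tibble(x)

#' @export
glance.feature_fisher <- function(x, fdr_threshold = 0.05, ...) {
  tibble(feature_type = attr(x, "feature_type"), n_features = nrow(x),
         n_significant = sum(x$fdr < fdr_threshold),
         min_fdr = if (nrow(x)) min(x$fdr) else NA_real_)
}

#' Genes selected by a method at a significance threshold
#'
#' Translates a result object into the gene set the method "detects" at a
#' p or FDR cutoff, for detection-ratio evaluation:
#' * `subgofa_result` — union, over significant roots, of genes whose
#'   annotation intersects the sub-ontology and that occur in at least one
#'   sample's region gene list;
#' * per-gene baseline — the significant genes themselves;
#' * per-term baseline — genes (seen in the cohort) annotated with a
#'   significant term (requires `fisher_per_term(..., gene2go = )`).
#'
#' @param x A `subgofa_result` or `feature_fisher`.
#' @param threshold Significance cutoff (inclusive).
#' @param mode `"fdr"` or `"p"`.
#' @param ... Passed to methods.
#' @return Character vector of gene symbols (possibly empty).
#' @export
selected_genes <- function(x, threshold, mode = c("fdr", "p"), ...) {
  UseMethod("selected_genes")
}

#' @export
selected_genes.subgofa_result <- function(x, threshold, mode = c("fdr", "p"), ...) {
  mode <- match.arg(mode)
  v <- if (mode == "fdr") x$fdr else x$p_value
  sel <- which(x$status == "tested" & !is.na(v) & v <= threshold)
  sort(unique(unlist(x$genes_under_root[sel], use.names = FALSE)))
}

#' @export
selected_genes.feature_fisher <- function(x, threshold, mode = c("fdr", "p"), ...) {
  mode <- match.arg(mode)
  v <- if (mode == "fdr") x$fdr else x$p_value
  feats <- x$feature[!is.na(v) & v <= threshold]
  if (attr(x, "feature_type") == "gene") return(sort(unique(feats)))
  t2g <- attr(x, "term2gene")
  if (is.null(t2g)) abort("per-term baseline needs gene2go to map terms to genes; rerun fisher_per_term(cohort, gene2go)")
  sort(unique(unlist(t2g[feats], use.names = FALSE)))
}

#' Detection ratio against a disease-gene list
#'
#' The fraction of a method's selected genes that appear in a curated
#' disease-gene list (case-insensitive matching). An empty selection has no
#' defined ratio and returns `NA`, mirroring the "not applicable" outcome
#' when a baseline rejects every feature at a strict threshold.
#'
#' @param selected Character vector of selected gene symbols.
#' @param disease_genes Character vector of disease-associated symbols.
#' @return A single value in `[0, 1]`, or `NA`.
#' @export
detection_ratio <- function(selected, disease_genes) {
  selected <- unique(toupper(selected))
  if (!length(selected)) return(NA_real_)
  mean(selected %in% toupper(disease_genes))
}

#' Detection-ratio sweep across significance thresholds
#'
#' Evaluates each method's detection ratio at a series of p or FDR
#' thresholds, the comparison used to contrast the sub-ontology analysis
#' with the conventional baselines.
#'
#' @param results Named list of result objects accepted by
#'   [selected_genes()].
#' @param thresholds Numeric vector of cutoffs.
#' @param disease_genes Character vector of disease-associated symbols.
#' @param mode `"fdr"` or `"p"`.
#' @return Long tibble: `method`, `mode`, `threshold`, `n_selected`,
#'   `n_hit`, `ratio`.
#' @export
threshold_sweep <- function(results, thresholds, disease_genes,
                            mode = c("fdr", "p")) {
  mode <- match.arg(mode)
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- lapply(names(results), function(m) {
    lapply(thresholds, function(th) {
      sel <- selected_genes(results[[m]], th, mode)
      tibble(method = m, mode = mode, threshold = th,
             n_selected = length(sel),
             n_hit = sum(unique(toupper(sel)) %in% toupper(disease_genes)),
             ratio = detection_ratio(sel, disease_genes))
    })
  })
  bind_rows(unlist(rows, recursive = FALSE))
}

#' Sample-frequency distribution of significant terms
#'
#' For each significant feature — the member terms of significant
#' sub-ontology roots, or the significant terms of the per-term baseline —
#' counts how many samples carry it, and bins the counts with a fixed bin
#' width (default 20 samples). Low bins are where rare functions live; the
#' sub-ontology analysis is designed to keep them visible.
#'
#' @param x A `subgofa_result` or a term-level `feature_fisher`.
#' @param cohort Annotated cohort tibble (supplies the term sets).
#' @param threshold Significance cutoff (inclusive).
#' @param mode `"fdr"` or `"p"`.
#' @param bin_width Bin width in samples.
#' @return Tibble `feature`, `n_samples`, `bin_lo`, `bin_hi`, `bin` (a
#'   label like `"[0,20)"`); zero rows when nothing is significant.
#' @export
term_frequency_distribution <- function(x, cohort, threshold = 0.05,
                                        mode = c("fdr", "p"), bin_width = 20L) {
  mode <- match.arg(mode)
  stopifnot("terms" %in% names(cohort))
  if (inherits(x, "subgofa_result")) {
    v <- if (mode == "fdr") x$fdr else x$p_value
    sel <- which(x$status == "tested" & !is.na(v) & v <= threshold)
    present <- unique(unlist(cohort$terms, use.names = FALSE))
    feats <- sort(unique(unlist(lapply(sel, function(i) {
      # member terms of the significant root's sub-ontology, as carried by samples
      intersect(term_descendants_cached(x, i), present)
    }), use.names = FALSE)))
  } else if (inherits(x, "feature_fisher") && attr(x, "feature_type") == "term") {
    v <- if (mode == "fdr") x$fdr else x$p_value
    feats <- x$feature[!is.na(v) & v <= threshold]
  } else {
    abort("x must be a subgofa_result or a term-level feature_fisher")
  }
  if (!length(feats)) {
    return(tibble(feature = character(0), n_samples = integer(0),
                  bin_lo = integer(0), bin_hi = integer(0), bin = character(0)))
  }
  n_samples <- vapply(feats, function(t) {
    sum(vapply(cohort$terms, function(s) t %in% s, logical(1)))
  }, integer(1))
  bin_lo <- (n_samples %/% bin_width) * bin_width
  tibble(feature = feats, n_samples = unname(n_samples),
         bin_lo = as.integer(bin_lo), bin_hi = as.integer(bin_lo + bin_width),
         bin = paste0("[", bin_lo, ",", bin_lo + bin_width, ")"))
}

# member terms come from the sub-ontology node sets stored on the result
term_descendants_cached <- function(x, i) {
  nodes <- attr(x, "subgo_nodes")
  if (!is.null(nodes)) return(nodes[[x$root[i]]])
  abort("subgofa_result lacks stored sub-ontology node sets")
}
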