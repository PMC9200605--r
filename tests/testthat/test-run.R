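# hand-built 4-sample cohort over the toy ontology: two samples carry {c},
# two carry {e}; under the root sub-ontology the similarity is two blocks
toy_cohort <- function() {
  tibble::tibble(
    sample_id = c("p1", "p2", "q1", "q2"),
    label = c("case", "case", "ctrl", "ctrl"),
    sex = "M", age = 60,
    regions = list(tibble::tibble(chrom = "chr1", start = 0, end = 1)),
    genes = list("g1", "g1", "g3", "g3"),
    terms = list("GO:c", "GO:c", "GO:e", "GO:e"))
}

test_that("identical restricted sets give block similarity with unit blocks", {
  dag <- toy_dag()
  ic <- compute_ic(dag, toy_gene2go())
  S <- similarity_matrix(toy_cohort(), term_descendants(dag, "GO:r"), dag, ic)
  expect_equal(S["p1", "p2"], 1)
  expect_equal(S["q1", "q2"], 1)
  expect_equal(S["p1", "q1"], 0) # MICA of c and e is the zero-IC root
  expect_equal(unname(diag(S)), rep(1, 4))
})

test_that("the full run separates the toy blocks and orders results", {
  dag <- toy_dag()
  ic <- compute_ic(dag, toy_gene2go())
  res <- run_subgofa(toy_cohort(), dag, ic, toy_gene2go(),
                     min_subgo_nodes = 1L, min_eligible = 1L)
  expect_s3_class(res, "subgofa_result")
  tested <- res[res$status == "tested", ]
  expect_true(all(diff(tested$fdr) >= -1e-15))
  root_row <- res[res$root == "GO:r", ]
  # perfect case/ctrl split at the root sub-ontology
  expect_equal(root_row$p_value, as.numeric(fisher_exact_2x2(c(2, 0, 0, 2))))
  expect_equal(sort(c(root_row$cluster1_case, root_row$cluster2_case)), c(0L, 2L))
  # table always sums to the cohort size
  expect_true(all(tested$cluster1_case + tested$cluster1_ctrl +
                  tested$cluster2_case + tested$cluster2_ctrl == 4L))
  expect_true(all(tested$fdr >= tested$p_value - 1e-15))
})

test_that("cases and controls with identical term sets yield no signal", {
  coh <- toy_cohort()
  coh$terms <- list("GO:c", "GO:e", "GO:c", "GO:e")
  coh$label <- c("case", "case", "ctrl", "ctrl")
  dag <- toy_dag()
  ic <- compute_ic(dag, toy_gene2go())
  res <- run_subgofa(coh, dag, ic, toy_gene2go(),
                     min_subgo_nodes = 1L, min_eligible = 1L)
  tested <- res[res$status == "tested", ]
  expect_true(all(tested$fdr >= 1 - 1e-12))
})

test_that("p-values are invariant to sample order", {
  cfg <- fixture_config(seed = 12, n_terms = 60L, n_genes = 100L,
                        n_case = 8L, n_ctrl_pool = 24L, n_ctrl_sampled = 8L)
  fx <- generate_fixture(cfg)
  cohort <- annotate_cohort(fx$cohort, fx$gene_track, fx$gene2go, fx$dag)
  ic <- compute_ic(fx$dag, fx$gene2go)
  res1 <- suppressWarnings(run_subgofa(cohort, fx$dag, ic, fx$gene2go))
  withr::with_seed(12, perm <- sample(nrow(cohort)))
  res2 <- suppressWarnings(run_subgofa(cohort[perm, ], fx$dag, ic, fx$gene2go))
  t1 <- tidy(res1); t2 <- tidy(res2)
  shared <- intersect(t1$root[t1$status == "tested"], t2$root[t2$status == "tested"])
  expect_gt(length(shared), 0)
  expect_equal(t1$p_value[match(shared, t1$root)],
               t2$p_value[match(shared, t2$root)], tolerance = 1e-12)
})

test_that("transposing cluster labels leaves the Fisher p unchanged", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      tab <- matrix(rpois(4, 8), 2)
      expect_equal(as.numeric(fisher_exact_2x2(tab)),
                   as.numeric(fisher_exact_2x2(tab[2:1, ])), tolerance = 1e-14)
    }
  })
})

test_that("eligibility thresholds mark sub-ontologies as skipped", {
  coh <- toy_cohort()
  coh$terms <- list("GO:c", "GO:c", "GO:e", "GO:e") # nothing under GO:a for ctrl
  dag <- toy_dag()
  ic <- compute_ic(dag, toy_gene2go())
  res <- run_subgofa(coh, dag, ic, toy_gene2go(),
                     min_subgo_nodes = 1L, min_eligible = 2L)
  expect_equal(res$status[res$root == "GO:a"], "skipped")
  expect_true(is.na(res$p_value[res$root == "GO:a"]))
  # skipped rows are excluded from the FDR family
  tested <- res[res$status == "tested", ]
  expect_equal(sort(tested$fdr), sort(bh_fdr(tested$p_value)), tolerance = 1e-12)
})

test_that("tidy and glance summarise the result object", {
  dag <- toy_dag()
  ic <- compute_ic(dag, toy_gene2go())
  res <- run_subgofa(toy_cohort(), dag, ic, toy_gene2go(),
                     min_subgo_nodes = 1L, min_eligible = 1L)
  td <- tidy(res)
  expect_false("clusters" %in% names(td))
  expect_true("n_genes_under_root" %in% names(td))
  g <- glance(res)
  expect_equal(g$n_samples, 4L)
  expect_equal(g$n_tested + g$n_skipped, nrow(res))
})
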