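toy_setup <- function() {
  dag <- toy_dag()
  ic <- compute_ic(dag, toy_gene2go())
  list(dag = dag, ic = ic, icv = setNames(ic$ic, ic$term))
}

test_that("MICA picks the most informative common ancestor, self-inclusively", {
  s <- toy_setup()
  expect_equal(mica(s$dag, s$ic, "GO:c", "GO:d"), "GO:a")
  expect_equal(mica(s$dag, s$ic, "GO:c", "GO:e"), "GO:r")
  expect_equal(mica(s$dag, s$ic, "GO:f", "GO:f"), "GO:f")
  # restricted to sub-ontology of a, c and d share only a
  sub_a <- term_descendants(s$dag, "GO:a")
  expect_equal(mica(s$dag, s$ic, "GO:c", "GO:d", restrict = sub_a), "GO:a")
  # c and e share nothing inside sub(a)
  expect_true(is.na(mica(s$dag, s$ic, "GO:c", "GO:e", restrict = sub_a)))
})

test_that("Lin similarity reproduces the hand-computed toy values", {
  s <- toy_setup()
  expect_equal(lin_similarity(s$dag, s$ic, "GO:c", "GO:d"),
               2 * (-log(0.8)) / (2 * (-log(0.4))), tolerance = 1e-12)
  expect_equal(round(lin_similarity(s$dag, s$ic, "GO:c", "GO:d"), 4), 0.2435)
  expect_equal(lin_similarity(s$dag, s$ic, "GO:f", "GO:f"), 1)
  expect_equal(lin_similarity(s$dag, s$ic, "GO:c", "GO:e"), 0) # MICA is root, IC 0
})

test_that("set similarity: identity, single pair, empty sets", {
  s <- toy_setup()
  expect_equal(set_similarity(s$dag, s$ic, c("GO:c", "GO:d"), c("GO:c", "GO:d")), 1)
  expect_equal(set_similarity(s$dag, s$ic, "GO:c", "GO:d"),
               lin_similarity(s$dag, s$ic, "GO:c", "GO:d"))
  expect_equal(set_similarity(s$dag, s$ic, "GO:c", character(0)), 0)
  expect_equal(set_similarity(s$dag, s$ic, character(0), character(0)), 0)
})

test_that("set similarity is symmetric, bounded, and matches a naive BMA", {
  for (seed in c(4, 5)) {
    cfg <- fixture_config(seed = seed, n_terms = 40L, n_genes = 60L)
    fx <- generate_ontology(cfg)
    ann <- generate_annotation(fx$dag, cfg)
    ic <- compute_ic(fx$dag, ann$gene2go)
    terms <- fx$dag$terms$term
    withr::with_seed(seed, {
      for (rep in 1:10) {
        a <- sample(terms, sample(1:6, 1))
        b <- sample(terms, sample(1:6, 1))
        sab <- set_similarity(fx$dag, ic, a, b)
        expect_equal(sab, set_similarity(fx$dag, ic, b, a))
        expect_gte(sab, 0); expect_lte(sab, 1)
        ref <- oracle_bma(a, b, function(t1, t2) lin_similarity(fx$dag, ic, t1, t2))
        expect_equal(sab, ref, tolerance = 1e-12)
      }
    })
  }
})

test_that("restricting to the namespace-root sub-ontology changes nothing", {
  cfg <- fixture_config(seed = 6, n_terms = 40L, n_genes = 60L)
  fx <- generate_ontology(cfg)
  ann <- generate_annotation(fx$dag, cfg)
  ic <- compute_ic(fx$dag, ann$gene2go)
  all_nodes <- fx$dag$terms$term
  withr::with_seed(6, {
    for (rep in 1:20) {
      t1 <- sample(all_nodes, 1); t2 <- sample(all_nodes, 1)
      expect_equal(lin_similarity(fx$dag, ic, t1, t2, restrict = all_nodes),
                   lin_similarity(fx$dag, ic, t1, t2))
    }
  })
})

test_that("similarity_matrix agrees with per-pair scalar computation", {
  cfg <- fixture_config(seed = 7, n_terms = 50L, n_genes = 80L,
                        n_case = 6L, n_ctrl_pool = 20L, n_ctrl_sampled = 6L)
  fx <- generate_fixture(cfg)
  cohort <- annotate_cohort(fx$cohort, fx$gene_track, fx$gene2go, fx$dag)
  ic <- compute_ic(fx$dag, fx$gene2go)
  sg <- enumerate_subgos(fx$dag, min_nodes = 2)
  withr::with_seed(7, idx <- sample(nrow(sg), 5))
  for (i in idx) {
    nodes <- sg$nodes[[i]]
    S <- similarity_matrix(cohort, nodes, fx$dag, ic)
    expect_true(isSymmetric(unname(S)))
    expect_true(all(S >= 0 & S <= 1))
    sets <- lapply(cohort$terms, restrict_term_set, subgo_nodes = nodes)
    expect_equal(unname(diag(S)), as.numeric(lengths(sets) > 0))
    for (k in 1:5) {
      ij <- withr::with_seed(i * 10 + k, sample(nrow(cohort), 2))
      ref <- set_similarity(fx$dag, ic, sets[[ij[1]]], sets[[ij[2]]], restrict = nodes)
      expect_equal(S[ij[1], ij[2]], ref, tolerance = 1e-10)
    }
  }
})

test_that("row-max fast path equals the reference pairwise kernel", {
  withr::with_seed(11, {
    T <- 12L
    L <- matrix(runif(T * T), T, T); L <- (L + t(L)) / 2; diag(L) <- 1
    sets <- lapply(1:8, function(i) {
      if (i == 3) integer(0) else sample.int(T, sample(1:5, 1))
    })
    fast <- subgofa:::bma_from_lin(L, sets)
    ref <- subgofa:::bma_matrix_cpp(L, sets)
    expect_equal(fast, ref, tolerance = 1e-12)
  })
})
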