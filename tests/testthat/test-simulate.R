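small_cfg <- function(seed = 2, ...) {
  defaults <- list(seed = seed, n_terms = 30L, n_genes = 50L,
                   n_case = 8L, n_ctrl_pool = 30L, n_ctrl_sampled = 8L)
  do.call(fixture_config, utils::modifyList(defaults, list(...)))
}

test_that("generators are pure functions of the config seed", {
  a <- generate_ontology(small_cfg())
  b <- generate_ontology(small_cfg())
  expect_identical(a$obo_lines, b$obo_lines)
  ann_a <- generate_annotation(a$dag, small_cfg())
  ann_b <- generate_annotation(b$dag, small_cfg())
  expect_identical(ann_a$gene_track, ann_b$gene_track)
  expect_identical(ann_a$gene2go, ann_b$gene2go)
  fx_a <- generate_fixture(small_cfg())
  fx_b <- generate_fixture(small_cfg())
  expect_identical(fx_a$cohort, fx_b$cohort)
  # a different seed gives a different world
  expect_false(identical(generate_ontology(small_cfg(seed = 3))$obo_lines, a$obo_lines))
})

test_that("generated OBO round-trips through the parser", {
  dir <- withr::local_tempdir()
  ont <- generate_ontology(small_cfg(), path = file.path(dir, "x.obo"))
  reparsed <- parse_obo(file.path(dir, "x.obo"))
  expect_equal(reparsed$terms, ont$dag$terms)
  expect_equal(reparsed$parents, ont$dag$parents)
})

test_that("max_parents = 1 yields a tree with a single root", {
  ont <- generate_ontology(small_cfg(seed = 5, max_parents = 1L))
  n_par <- lengths(ont$dag$parents)
  expect_equal(sum(n_par == 0L), 1L)
  expect_true(all(n_par[n_par > 0L] == 1L))
})

test_that("gene intervals are disjoint and annotations point into the DAG", {
  ont <- generate_ontology(small_cfg())
  ann <- generate_annotation(ont$dag, small_cfg())
  expect_true(all(ann$gene2go$term %in% ont$dag$terms$term))
  by_chrom <- split(ann$gene_track, ann$gene_track$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$end[-nrow(g)] <= g$start[-1]))
  }
  expect_true(all(ann$gene_track$start < ann$gene_track$end))
})

test_that("fixture files on disk feed the readers and re-annotate identically", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(small_cfg(), dir = dir)
  dag <- parse_obo(fx$paths$obo)
  track <- read_gene_track(fx$paths$gene_track)
  g2g <- read_gene2go(fx$paths$gene2go)
  coh <- read_cohort(fx$paths$regions, fx$paths$phenotypes)
  expect_equal(nrow(coh), nrow(fx$cohort))
  ann_disk <- annotate_cohort(coh, track, g2g, dag)
  ann_mem <- annotate_cohort(fx$cohort, fx$gene_track, fx$gene2go, fx$dag)
  expect_equal(ann_disk$terms[match(ann_mem$sample_id, ann_disk$sample_id)],
               ann_mem$terms)
})

test_that("the planted effect forces cases onto genes under the planted root", {
  fx <- generate_fixture(small_cfg(seed = 7, effect = 1,
                                   planted_gene_range = c(2L, 30L)))
  expect_false(is.null(fx$planted_root))
  expect_gt(length(fx$disease_genes), 0)
  cohort <- annotate_cohort(fx$cohort, fx$gene_track, fx$gene2go, fx$dag)
  nodes <- term_descendants(fx$dag, fx$planted_root)
  cases <- cohort[cohort$label == "case", ]
  hit <- vapply(cases$terms, function(ts) length(intersect(ts, nodes)) > 0, logical(1))
  expect_true(all(hit))
})

test_that("a null cohort carries no planted structure", {
  fx <- generate_fixture(small_cfg(seed = 8, effect = 0))
  expect_null(fx$planted_root)
  expect_equal(length(fx$disease_genes), 0L)
})

test_that("matched sampling reproduces the case sex/age-decade distribution", {
  cases <- tibble::tibble(
    sample_id = sprintf("c%02d", 1:20),
    label = "case", sex = rep(c("M", "F"), 10),
    age = rep(c(55, 63, 71, 78), 5))
  pool <- dplyr::mutate(cases[rep(1:20, 4), ],
                        sample_id = sprintf("p%02d", 1:80), label = "ctrl")
  got <- matched_control_sample(pool, cases, n = 20, seed = 3)
  expect_equal(nrow(got), 20L)
  bin <- function(df) sort(paste(df$sex, df$age %/% 10))
  expect_equal(bin(got), bin(cases))
})

test_that("an all-male pool falls back with a warning", {
  cases <- tibble::tibble(sample_id = c("c1", "c2"), label = "case",
                          sex = c("M", "F"), age = c(60, 60))
  pool <- tibble::tibble(sample_id = sprintf("p%d", 1:10), label = "ctrl",
                         sex = "M", age = 60)
  expect_warning(got <- matched_control_sample(pool, cases, n = 2, seed = 1),
                 "fell back")
  expect_equal(nrow(got), 2L)
  expect_true(all(got$sex == "M"))
  expect_error(suppressWarnings(matched_control_sample(pool[1, ], cases, n = 2)),
               "smaller")
})

test_that("matched controls stay balanced in sex and age across seeds", {
  p_sex <- numeric(0); p_age <- numeric(0)
  for (s in 1:5) {
    fx <- generate_fixture(small_cfg(seed = s + 20, n_case = 40L,
                                     n_ctrl_pool = 200L, n_ctrl_sampled = 40L))
    cases <- fx$cohort[fx$cohort$label == "case", ]
    ctrls <- fx$cohort[fx$cohort$label == "ctrl", ]
    tab <- table(factor(c(cases$sex, ctrls$sex), levels = c("M", "F")),
                 rep(c("case", "ctrl"), c(nrow(cases), nrow(ctrls))))
    p_sex <- c(p_sex, suppressWarnings(stats::chisq.test(tab)$p.value))
    p_age <- c(p_age, stats::t.test(cases$age, ctrls$age)$p.value)
  }
  expect_gte(mean(p_sex > 0.05), 0.8)
  expect_gte(mean(p_age > 0.05), 0.8)
})
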