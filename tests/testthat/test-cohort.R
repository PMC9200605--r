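write_cohort_files <- function(regions, phenos, env = parent.frame()) {
  rp <- withr::local_tempfile(fileext = ".bed", .local_envir = env)
  pp <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(regions, rp)
  writeLines(c("sample_id\tlabel\tsex\tage", phenos), pp)
  list(regions = rp, phenotypes = pp)
}

test_that("cohort read-back keeps every phenotype row with its regions", {
  f <- write_cohort_files(
    c("chr1\t100\t500\ts1", "chr2\t0\t50\ts1",
      "chr1\t10\t20\ts2", "chr1\t30\t40\ts2", "chr3\t5\t6\ts3"),
    c("s1\tcase\tM\t63", "s2\tctrl\tF\t70", "s3\tcase\tF\t58"))
  coh <- read_cohort(f$regions, f$phenotypes)
  expect_equal(nrow(coh), 3L)
  expect_equal(vapply(coh$regions, nrow, integer(1)), c(2L, 2L, 1L))
  expect_setequal(coh$label, c("case", "ctrl"))
})

test_that("malformed coordinates, orphan samples and bad labels error", {
  f <- write_cohort_files("chr1\t500\t100\ts1", "s1\tcase\tM\t60")
  expect_error(read_cohort(f$regions, f$phenotypes), "line")
  f <- write_cohort_files("chr1\t1\t2\tghost", "s1\tcase\tM\t60")
  expect_error(read_cohort(f$regions, f$phenotypes), "ghost")
  f <- write_cohort_files("chr1\t1\t2\ts1", "s1\tpatient\tM\t60")
  expect_error(read_cohort(f$regions, f$phenotypes), "label")
})

test_that("1-based inclusive region tables convert on load", {
  f <- write_cohort_files("chr1\t101\t500\ts1", "s1\tcase\tM\t60")
  coh <- read_cohort(f$regions, f$phenotypes, one_based = TRUE)
  expect_equal(coh$regions[[1]]$start, 100)
  expect_equal(coh$regions[[1]]$end, 500)
})

make_annotation_env <- function() {
  dag <- toy_dag()
  gene_track <- tibble::tibble(
    symbol = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(300, 450, 100), end = c(400, 600, 200))
  gene2go <- tibble::tibble(
    gene = c("g1", "g2", "g3"), term = c("GO:c", "GO:e", "GO:d"))
  list(dag = dag, gene_track = gene_track, gene2go = gene2go)
}

test_that("any 1 bp overlap pulls in a gene; empty regions give empty sets", {
  e <- make_annotation_env()
  coh <- tibble::tibble(
    sample_id = c("s1", "s2"), label = c("case", "ctrl"),
    sex = "M", age = 60,
    regions = list(
      tibble::tibble(chrom = "chr1", start = 100, end = 500),
      tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0))))
  ann <- annotate_cohort(coh, e$gene_track, e$gene2go, e$dag)
  # g1 fully contained, g2 straddles the boundary at 450-500
  expect_setequal(ann$genes[[1]], c("g1", "g2"))
  expect_setequal(ann$terms[[1]], c("GO:c", "GO:e"))
  expect_equal(ann$genes[[2]], character(0))
  expect_equal(ann$terms[[2]], character(0))
})

test_that("a gene touching zero bases of any region is excluded", {
  e <- make_annotation_env()
  coh <- tibble::tibble(
    sample_id = "s1", label = "case", sex = "F", age = 61,
    regions = list(tibble::tibble(chrom = "chr1", start = 100, end = 300)))
  ann <- annotate_cohort(coh, e$gene_track, e$gene2go, e$dag)
  expect_equal(ann$genes[[1]], character(0)) # g1 starts exactly at region end
})

test_that("annotation is order-independent and unions over regions", {
  e <- make_annotation_env()
  r <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(100, 50), end = c(500, 150))
  coh <- function(regions) tibble::tibble(
    sample_id = "s", label = "case", sex = "M", age = 59, regions = list(regions))
  a1 <- annotate_cohort(coh(r), e$gene_track, e$gene2go, e$dag)
  a2 <- annotate_cohort(coh(r[2:1, ]), e$gene_track[3:1, ], e$gene2go, e$dag)
  expect_equal(a1$terms[[1]], a2$terms[[1]])
  # union property: whole sample = union of single-region sub-samples
  singles <- lapply(1:2, function(i) {
    annotate_cohort(coh(r[i, ]), e$gene_track, e$gene2go, e$dag)$terms[[1]]
  })
  expect_setequal(a1$terms[[1]], unique(unlist(singles)))
})

test_that("event frequencies normalise to events per 1000 Mb", {
  lengths <- tibble::tibble(chrom = c("chrA", "chrB"),
                            length_bp = c(1e9, 5e8)) # 1000 Mb and 500 Mb
  coh <- tibble::tibble(
    sample_id = c("s1", "s2"), label = c("case", "case"),
    sex = "M", age = 60,
    regions = list(
      tibble::tibble(chrom = c("chrA", "chrA"), start = c(0, 10), end = c(5, 20)),
      tibble::tibble(chrom = "chrB", start = 0, end = 10)))
  fr <- event_frequency_summary(coh, lengths)
  expect_equal(fr$events_per_1000mb[fr$chrom == "chrA" & fr$label == "case"], 2)
  expect_equal(fr$events_per_1000mb[fr$chrom == "chrB" & fr$label == "case"], 2)
  expect_equal(fr$events_per_1000mb[fr$label == "ctrl"], c(0, 0))

  empty <- coh[0, ]
  fr0 <- event_frequency_summary(empty, lengths)
  expect_true(all(fr0$n_events == 0))

  bad <- coh
  bad$regions[[1]]$chrom <- "chrZ"
  expect_error(event_frequency_summary(bad, lengths), "chrZ")
})
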