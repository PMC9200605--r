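#' Read a mosaicism cohort: regions plus phenotypes
#'
#' Regions are BED3+1 (`chrom`, `start`, `end`, `sample_id`; 0-based,
#' half-open) and phenotypes a TSV with header
#' (`sample_id`, `label`, `sex`, `age`). Set `one_based = TRUE` for region
#' tables in 1-based inclusive coordinates (the biomaRt convention); they
#' are converted to 0-based half-open on load. Every region must belong to
#' a phenotyped sample; samples without regions are kept with an empty
#' region list (a message reports how many).
#'
#' @param regions_path Path to the BED3+1 region file (no header).
#' @param phenotype_path Path to the phenotype TSV (with header).
#' @param one_based Regions file uses 1-based inclusive coordinates?
#' @return A cohort tibble: `sample_id`, `label` (`case`/`ctrl`), `sex`,
#'   `age`, and a `regions` list-column of tibbles (`chrom`, `start`,
#'   `end`).
#' @export
read_cohort <- function(regions_path, phenotype_path, one_based = FALSE) {
  pheno <- readr::read_tsv(phenotype_path, col_types = readr::cols(
    sample_id = readr::col_character(), label = readr::col_character(),
    sex = readr::col_character(), age = readr::col_double()
  ))
  bad <- setdiff(unique(pheno$label), c("case", "ctrl"))
  if (length(bad)) abort(paste0("unknown phenotype label(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(pheno$sample_id)) abort("duplicate sample ids in phenotype table")
  pheno$sex[!pheno$sex %in% c("M", "F")] <- "unknown"

  reg <- readr::read_tsv(regions_path,
    col_names = c("chrom", "start", "end", "sample_id"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), sample_id = readr::col_character()
    ))
  if (one_based) reg$start <- reg$start - 1
  bad_coord <- which(!is.finite(reg$start) | !is.finite(reg$end) | reg$end <= reg$start)
  if (length(bad_coord)) {
    abort(paste0("malformed region coordinates (end <= start) at line(s): ",
      paste(head(bad_coord, 5L), collapse = ", ")))
  }
  orphans <- setdiff(unique(reg$sample_id), pheno$sample_id)
  if (length(orphans)) {
    abort(paste0("region rows reference sample(s) absent from the phenotype table: ",
      paste(head(orphans, 5L), collapse = ", ")))
  }

  reg_split <- split(reg[c("chrom", "start", "end")], reg$sample_id)
  empty <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  regions <- lapply(pheno$sample_id, function(s) {
    r <- reg_split[[s]]
    if (is.null(r)) empty else as_tibble(r)
  })
  n_empty <- sum(vapply(regions, nrow, integer(1)) == 0L)
  if (n_empty > 0L) inform(paste0(n_empty, " sample(s) carry no mosaic regions"))
  mutate(pheno, regions = regions)
}

#' Read a gene coordinate track (BED4)
#'
#' Columns `chrom`, `start`, `end`, `symbol` (0-based half-open, no
#' header). Duplicate symbols keep their first occurrence; later ones are
#' dropped with a message.
#'
#' @param path Path to the BED4 file.
#' @param one_based Gene table uses 1-based inclusive coordinates?
#' @return Tibble `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_track <- function(path, one_based = FALSE) {
  g <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "symbol"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), symbol = readr::col_character()
    ))
  if (one_based) g$start <- g$start - 1
  if (any(g$end <= g$start)) abort("gene track contains intervals with end <= start")
  dup <- duplicated(g$symbol)
  if (any(dup)) {
    inform(paste0(sum(dup), " duplicate gene symbol(s) dropped (first occurrence kept)"))
    g <- g[!dup, ]
  }
  select(g, "symbol", "chrom", "start", "end")
}

#' Read a chromosome length table
#'
#' Two-column TSV, no header: chromosome name and length in base pairs.
#'
#' @param path Path to the TSV.
#' @return Tibble `chrom`, `length_bp`.
#' @export
read_chrom_lengths <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length_bp"),
    col_types = readr::cols(chrom = readr::col_character(),
                            length_bp = readr::col_double()))
}

#' Annotate cohort samples with genes and ontology terms
#'
#' Overlaps every sample's mosaic regions with the gene track (any overlap
#' of at least 1 bp includes the gene; strand is ignored, as mosaic events
#' are strand-agnostic), collects the overlapped gene symbols, and derives
#' the sample's term set as the union of those genes' annotations,
#' restricted to terms present in the ontology. Genes without annotations
#' contribute nothing. Interval overlap is delegated to
#' [GenomicRanges::findOverlaps()].
#'
#' @param cohort Cohort tibble from [read_cohort()] (or one sample row).
#' @param gene_track Tibble from [read_gene_track()].
#' @param gene2go Tibble `gene`, `term` (see [read_gene2go()]).
#' @param dag A `go_dag` used to validate terms.
#' @return The cohort with `genes` and `terms` list-columns added.
#' @export
annotate_cohort <- function(cohort, gene_track, gene2go, dag) {
  ann <- validate_gene2go(gene2go, dag)
  ann_by_gene <- split(ann$term, ann$gene)
  genes_gr <- GenomicRanges::GRanges(
    seqnames = gene_track$chrom,
    ranges = IRanges::IRanges(start = gene_track$start + 1, end = gene_track$end)
  )
  res <- lapply(cohort$regions, function(r) {
    if (nrow(r) == 0L) return(list(genes = character(0), terms = character(0)))
    reg_gr <- GenomicRanges::GRanges(
      seqnames = r$chrom,
      ranges = IRanges::IRanges(start = r$start + 1, end = r$end)
    )
    hits <- GenomicRanges::findOverlaps(reg_gr, genes_gr, minoverlap = 1L)
    genes <- sort(unique(gene_track$symbol[S4Vectors::subjectHits(hits)]))
    terms <- sort(unique(unlist(ann_by_gene[genes], use.names = FALSE)))
    if (is.null(terms)) terms <- character(0)
    list(genes = genes, terms = terms)
  })
  mutate(cohort,
    genes = lapply(res, `[[`, "genes"),
    terms = lapply(res, `[[`, "terms"))
}

#' @rdname annotate_cohort
#' @param record A single-row cohort tibble.
#' @export
annotate_sample <- function(record, gene_track, gene2go, dag) {
  annotate_cohort(record, gene_track, gene2go, dag)
}

#' Mosaic event frequency per chromosome, scaled to events per 1000 Mb
#'
#' Counts regions per chromosome and phenotype class and normalises by the
#' chromosome length, expressed per 1000 Mb (1e9 bp), so chromosomes of
#' different sizes are comparable.
#'
#' @param cohort Cohort tibble with a `regions` list-column.
#' @param chrom_lengths Tibble `chrom`, `length_bp` (see
#'   [read_chrom_lengths()]).
#' @return Long tibble `chrom`, `label`, `n_events`, `events_per_1000mb`,
#'   including zero rows for chromosome/label pairs without events.
#' @export
event_frequency_summary <- function(cohort, chrom_lengths) {
  reg <- tidyr::unnest(select(cohort, "sample_id", "label", "regions"), "regions")
  if (nrow(reg) == 0L) {
    reg <- tibble(sample_id = character(0), label = character(0),
                  chrom = character(0), start = numeric(0), end = numeric(0))
  }
  missing <- setdiff(unique(reg$chrom), chrom_lengths$chrom)
  if (length(missing)) {
    abort(paste0("chromosome(s) missing from the length table: ",
      paste(missing, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(chrom = chrom_lengths$chrom, label = c("case", "ctrl"))
  counts <- count(reg, .data$chrom, .data$label, name = "n_events")
  grid %>%
    left_join(counts, by = c("chrom", "label")) %>%
    mutate(n_events = ifelse(is.na(.data$n_events), 0L, .data$n_events)) %>%
    left_join(chrom_lengths, by = "chrom") %>%
    mutate(events_per_1000mb = .data$n_events / (.data$length_bp / 1e9)) %>%
    select("chrom", "label", "n_events", "events_per_1000mb")
}
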