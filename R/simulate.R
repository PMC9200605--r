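#' Configuration for the synthetic fixture generators
#'
#' One list drives the whole synthetic test surface: ontology, gene track,
#' annotation map, and a case/control mosaicism cohort with a planted
#' functional signal. Defaults mirror the study conditions the pipeline is
#' meant for: an analysis dataset capped at 200 samples (100 cases plus 100
#' age/sex-matched controls drawn from a larger non-disease pool), mosaic
#' segments in the multi-megabase range, and a leaf-biased annotation map so
#' that low-frequency terms — the regime the method targets — actually
#' exist. Case age/sex defaults follow a lung-cancer-like cohort
#' (52% male, age 67.25 +/- 9.5); the control pool is drawn broader and then
#' matched.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   config including this seed.
#' @param n_terms,max_parents Ontology size and maximum parents per term.
#' @param n_genes Number of genes on the track.
#' @param terms_per_gene Length-2 range of direct annotations per gene.
#' @param n_chromosomes,chrom_length_bp Genome layout.
#' @param n_case,n_ctrl_pool,n_ctrl_sampled Cohort sizes: cases, the
#'   non-disease pool, and the matched controls drawn from it.
#' @param regions_per_sample Length-2 range of mosaic regions per sample.
#' @param region_length_bp Length-2 range of region lengths (bp).
#' @param planted_root Term id whose sub-ontology carries the planted
#'   signal; `NULL` picks a mid-sized root deterministically (see
#'   [choose_planted_root()]).
#' @param effect Fraction of cases whose first region is forced to cover a
#'   gene annotated under the planted root (0 = null cohort).
#' @param planted_term_max_genes Cap on genes per member term when the
#'   planted root is auto-chosen (see [choose_planted_root()]).
#' @param planted_size_range,planted_gene_range,planted_target_nodes
#'   Module-size windows forwarded to [choose_planted_root()].
#' @param age_mean,age_sd,sex_ratio Named length-2 vectors (`case`,
#'   `ctrl`) of age distribution and male fraction per class.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_terms = 150L, max_parents = 3L,
                           n_genes = 300L, terms_per_gene = c(1L, 3L),
                           n_chromosomes = 4L, chrom_length_bp = 1e8,
                           n_case = 100L, n_ctrl_pool = 300L, n_ctrl_sampled = 100L,
                           regions_per_sample = c(1L, 3L),
                           region_length_bp = c(2e6, 8e6),
                           planted_root = NULL, effect = 1,
                           planted_term_max_genes = Inf,
                           planted_size_range = c(2L, 20L),
                           planted_gene_range = c(3L, 15L),
                           planted_target_nodes = 6L,
                           age_mean = c(case = 67.25, ctrl = 66),
                           age_sd = c(case = 9.5, ctrl = 11),
                           sex_ratio = c(case = 0.521, ctrl = 0.5)) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
    max_parents = as.integer(max_parents), n_genes = as.integer(n_genes),
    terms_per_gene = as.integer(terms_per_gene),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_case = as.integer(n_case), n_ctrl_pool = as.integer(n_ctrl_pool),
    n_ctrl_sampled = as.integer(n_ctrl_sampled),
    regions_per_sample = as.integer(regions_per_sample),
    region_length_bp = as.numeric(region_length_bp),
    planted_root = planted_root, effect = as.numeric(effect),
    planted_term_max_genes = as.numeric(planted_term_max_genes),
    planted_size_range = as.integer(planted_size_range),
    planted_gene_range = as.integer(planted_gene_range),
    planted_target_nodes = as.integer(planted_target_nodes),
    age_mean = age_mean, age_sd = age_sd, sex_ratio = sex_ratio)
  stopifnot(cfg$n_terms >= 2L, cfg$max_parents >= 1L, cfg$n_genes >= 1L,
            cfg$effect >= 0, cfg$effect <= 1,
            all(c("case", "ctrl") %in% names(cfg$age_mean)))
  structure(cfg, class = "fixture_config")
}

# derived sub-seeds keep the generators independent of call order
derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483563)

# sample() that never interprets a length-1 numeric as 1:x
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Generate a random acyclic ontology and serialize it as OBO 1.2
#'
#' Term `i` (1-based beyond the root) draws between 1 and `max_parents`
#' parents uniformly from earlier terms, which guarantees acyclicity with a
#' single root. About one extra parent edge in five is emitted as
#' `relationship: part_of` rather than `is_a`, exercising both edge types.
#' The returned DAG is parsed back from the generated OBO text, so a
#' round-trip through [parse_obo()] is built in.
#'
#' @param config A [fixture_config()].
#' @param path Optional path for the OBO file; omitted = not written.
#' @return List with `dag` (a `go_dag`), `obo_lines` (character), and
#'   `path` (or `NA`).
#' @export
generate_ontology <- function(config, path = NULL) {
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_terms
    ids <- sprintf("SGO:%07d", seq_len(n) - 1L)
    parent_idx <- vector("list", n)
    rel_type <- vector("list", n)
    for (i in seq_len(n - 1L) + 1L) {
      k <- sample.int(cfg$max_parents, 1L)
      k <- min(k, i - 1L)
      pars <- sort(sample.int(i - 1L, k))
      rel <- c("is_a", ifelse(stats::runif(max(0L, k - 1L)) < 0.2, "part_of", "is_a"))
      parent_idx[[i]] <- pars
      rel_type[[i]] <- rel[seq_len(k)]
    }
    lines <- c("format-version: 1.2",
               "default-namespace: biological_process", "")
    for (i in seq_len(n)) {
      stanza <- c("[Term]",
                  paste0("id: ", ids[i]),
                  paste0("name: synthetic term ", i - 1L),
                  "namespace: biological_process")
      for (j in seq_along(parent_idx[[i]])) {
        p <- ids[parent_idx[[i]][j]]
        stanza <- c(stanza, if (rel_type[[i]][j] == "is_a") {
          paste0("is_a: ", p, " ! synthetic term ", parent_idx[[i]][j] - 1L)
        } else {
          paste0("relationship: part_of ", p)
        })
      }
      lines <- c(lines, stanza, "")
    }
  })
  if (!is.null(path)) writeLines(lines, path)
  list(dag = parse_obo_lines(lines), obo_lines = lines,
       path = if (is.null(path)) NA_character_ else path)
}

#' Generate a gene track and gene-to-term annotation map
#'
#' Genes are laid out non-overlapping along the chromosomes with uniform
#' spacing plus jitter. Each gene draws its direct annotations with
#' probability proportional to `1 / (1 + #descendants)`, biasing them
#' toward leaves so rare, specific functions exist in the corpus.
#'
#' @param dag A `go_dag`.
#' @param config A [fixture_config()].
#' @param dir Optional directory; writes `genes.bed` (BED4) and
#'   `gene2go.tsv` when given.
#' @return List with `gene_track`, `gene2go` tibbles and file `paths`.
#' @export
generate_annotation <- function(dag, config, dir = NULL) {
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    n <- cfg$n_genes
    chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    chrom_of <- rep(chroms, length.out = n)
    per_chrom <- table(factor(chrom_of, levels = chroms))
    rows <- lapply(chroms, function(ch) {
      m <- as.integer(per_chrom[[ch]])
      if (m == 0L) return(NULL)
      spacing <- cfg$chrom_length_bp / m
      jitter <- stats::runif(m, -0.2, 0.2) * spacing
      start <- pmax(0, round((seq_len(m) - 1L) * spacing + 0.1 * spacing + jitter))
      len <- round(stats::runif(m, 0.1, 0.4) * spacing)
      tibble(chrom = ch, start = start, end = pmin(start + len, cfg$chrom_length_bp))
    })
    track <- bind_rows(rows)
    ord <- sample.int(n) # shuffle so symbol order is independent of position
    track <- mutate(track, symbol = sprintf("GENE%04d", ord))
    # leaf bias: weight by inverse descendant count
    n_desc <- vapply(dag$terms$term,
      function(t) length(term_descendants(dag, t, include_self = FALSE)), integer(1))
    w <- 1 / (1 + n_desc)
    gene2go <- bind_rows(lapply(track$symbol, function(g) {
      k <- resample(seq(cfg$terms_per_gene[1], cfg$terms_per_gene[2]), 1L)
      tibble(gene = g, term = sample(dag$terms$term, k, prob = w))
    }))
  })
  track <- select(arrange(track, .data$chrom, .data$start),
                  "symbol", "chrom", "start", "end")
  gene2go <- arrange(distinct(gene2go), .data$gene, .data$term)
  paths <- list(gene_track = NA_character_, gene2go = NA_character_)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths$gene_track <- file.path(dir, "genes.bed")
    readr::write_tsv(select(track, "chrom", "start", "end", "symbol"),
                     paths$gene_track, col_names = FALSE)
    paths$gene2go <- file.path(dir, "gene2go.tsv")
    readr::write_tsv(gene2go, paths$gene2go, col_names = FALSE)
  }
  list(gene_track = track, gene2go = gene2go, paths = paths)
}

#' Choose a planted signal root deterministically
#'
#' Picks a compact "disease module": among sub-ontologies of moderate size
#' (default 2-20 nodes) whose annotated gene count lies in `gene_range`,
#' the one whose node count is closest to `target_nodes`; ties break to the
#' smallest root id. The gene cap matters: a planted module spanning a
#' large share of the genome would be touched by most random control
#' regions and would not represent a specific low-frequency function.
#'
#' @param dag A `go_dag`.
#' @param gene2go Annotation tibble.
#' @param size_range Admissible node-count range.
#' @param gene_range Admissible range for the number of genes annotated
#'   under the root.
#' @param target_nodes Preferred node count.
#' @param max_genes_per_term Reject modules containing a member term
#'   annotated to more than this many genes. `Inf` (default) disables the
#'   check; a small cap forces every member term to be individually rare,
#'   the regime where conventional per-term tests lose power.
#' @return A term id.
#' @export
choose_planted_root <- function(dag, gene2go, size_range = c(2L, 20L),
                                gene_range = c(3L, 15L), target_nodes = 6L,
                                max_genes_per_term = Inf) {
  subgos <- enumerate_subgos(dag, min_nodes = size_range[1])
  subgos <- filter(subgos, .data$n_nodes <= size_range[2])
  if (nrow(subgos) == 0L) abort("no sub-ontology in the requested size range")
  genes_per_term <- table(gene2go$term)
  n_genes <- vapply(subgos$nodes, function(nodes) {
    length(unique(gene2go$gene[gene2go$term %in% nodes]))
  }, integer(1))
  max_share <- vapply(subgos$nodes, function(nodes) {
    hit <- genes_per_term[intersect(nodes, names(genes_per_term))]
    if (!length(hit)) 0L else as.integer(max(hit))
  }, integer(1))
  cand <- subgos[n_genes >= gene_range[1] & n_genes <= gene_range[2] &
                   max_share <= max_genes_per_term, ]
  if (nrow(cand) == 0L) abort("no sub-ontology with a suitable annotated gene count to plant a signal")
  cand <- arrange(cand, abs(.data$n_nodes - target_nodes), .data$root)
  cand$root[1]
}

#' Generate a case/control mosaicism cohort with a planted signal
#'
#' Controls (and the unaffected fraction of cases) draw their mosaic
#' regions uniformly over the genome. A fraction `effect` of cases has its
#' first region re-centred on a randomly chosen gene annotated under the
#' planted sub-ontology root, so those cases share a functional module
#' while everything else stays exchangeable. Ages are normal and sexes
#' Bernoulli per class.
#'
#' @param dag A `go_dag`.
#' @param annotation Output of [generate_annotation()].
#' @param config A [fixture_config()]; `planted_root` is resolved via
#'   [choose_planted_root()] when `NULL` and `effect > 0`.
#' @param dir Optional directory; writes `regions.bed`, `phenotypes.tsv`,
#'   `chrom_lengths.tsv`, `disease_genes.txt` when given.
#' @return List with `cohort` (cases plus the full control pool; the
#'   matched analysis cohort is drawn later), `planted_root`,
#'   `disease_genes` (genes under the planted root, the synthetic stand-in
#'   for a curated disease-gene list), `chrom_lengths`, and file `paths`.
#' @export
generate_cohort <- function(dag, annotation, config, dir = NULL) {
  cfg <- config
  track <- annotation$gene_track
  gene2go <- annotation$gene2go
  planted_root <- cfg$planted_root
  if (is.null(planted_root) && cfg$effect > 0) {
    planted_root <- choose_planted_root(
      dag, gene2go,
      size_range = cfg$planted_size_range,
      gene_range = cfg$planted_gene_range,
      target_nodes = cfg$planted_target_nodes,
      max_genes_per_term = cfg$planted_term_max_genes)
  }
  planted_genes <- character(0)
  if (!is.null(planted_root)) {
    nodes <- term_descendants(dag, planted_root)
    planted_genes <- sort(unique(gene2go$gene[gene2go$term %in% nodes]))
    if (cfg$effect > 0 && length(planted_genes) == 0L) {
      abort(paste0("no gene annotated under planted root ", planted_root))
    }
  }
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  chrom_lengths <- tibble(chrom = chroms, length_bp = cfg$chrom_length_bp)

  withr::with_seed(derive_seed(cfg$seed, 3L), {
    draw_region <- function() {
      len <- stats::runif(1, cfg$region_length_bp[1], cfg$region_length_bp[2])
      ch <- sample(chroms, 1L)
      start <- floor(stats::runif(1, 0, cfg$chrom_length_bp - len))
      tibble(chrom = ch, start = start, end = floor(start + len))
    }
    planted_region <- function() {
      g <- track[track$symbol == resample(planted_genes, 1L), ]
      len <- stats::runif(1, cfg$region_length_bp[1], cfg$region_length_bp[2])
      mid <- (g$start + g$end) / 2
      start <- max(0, floor(mid - len / 2))
      tibble(chrom = g$chrom, start = start,
             end = min(floor(start + len), cfg$chrom_length_bp))
    }
    make_samples <- function(n, label, prefix) {
      n_reg <- resample(seq(cfg$regions_per_sample[1], cfg$regions_per_sample[2]),
                      n, replace = TRUE)
      affected <- label == "case" & seq_len(n) <= round(cfg$effect * n)
      regions <- lapply(seq_len(n), function(i) {
        regs <- bind_rows(lapply(seq_len(n_reg[i]), function(j) draw_region()))
        if (affected[i]) regs[1, ] <- planted_region()
        regs
      })
      sex <- ifelse(stats::rbinom(n, 1, cfg$sex_ratio[[label]]) == 1L, "M", "F")
      age <- round(stats::rnorm(n, cfg$age_mean[[label]], cfg$age_sd[[label]]), 1)
      tibble(
        sample_id = sprintf("%s%04d", prefix, seq_len(n)),
        label = label,
        sex = sex,
        age = age,
        regions = regions
      )
    }
    cases <- make_samples(cfg$n_case, "case", "case_")
    pool <- make_samples(cfg$n_ctrl_pool, "ctrl", "ctrl_")
  })
  cohort <- bind_rows(cases, pool)

  paths <- list(regions = NA_character_, phenotypes = NA_character_,
                chrom_lengths = NA_character_, disease_genes = NA_character_)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths$regions <- file.path(dir, "regions.bed")
    reg <- tidyr::unnest(select(cohort, "sample_id", "regions"), "regions")
    readr::write_tsv(select(reg, "chrom", "start", "end", "sample_id"),
                     paths$regions, col_names = FALSE)
    paths$phenotypes <- file.path(dir, "phenotypes.tsv")
    readr::write_tsv(select(cohort, "sample_id", "label", "sex", "age"),
                     paths$phenotypes)
    paths$chrom_lengths <- file.path(dir, "chrom_lengths.tsv")
    readr::write_tsv(chrom_lengths, paths$chrom_lengths, col_names = FALSE)
    paths$disease_genes <- file.path(dir, "disease_genes.txt")
    writeLines(planted_genes, paths$disease_genes)
  }
  list(cohort = cohort, planted_root = planted_root,
       disease_genes = planted_genes, chrom_lengths = chrom_lengths,
       paths = paths)
}

#' Draw age/sex-matched controls from a pool
#'
#' Stratifies the pool by sex and age decade and draws controls with
#' per-bin quotas proportional to the case distribution
#' (largest-remainder rounding, so quotas always sum to `n`). When a bin
#' cannot fill its quota the deficit falls back to the nearest non-empty
#' age bin of the same sex, then of the other sex (with a warning), so the
#' draw degrades gracefully on skewed pools. Emulates matched-control
#' sampling from a non-disease cohort.
#'
#' @param pool Cohort tibble of candidate controls.
#' @param cases Cohort tibble of cases defining the target distribution.
#' @param n Number of controls to draw (`<= nrow(pool)`).
#' @param seed Integer seed for the within-bin draws.
#' @return `n` rows of `pool`.
#' @export
matched_control_sample <- function(pool, cases, n, seed = 1L) {
  if (nrow(pool) < n) abort("control pool smaller than requested sample")
  bin_of <- function(df) paste(df$sex, pmin(pmax(df$age %/% 10, 0), 12), sep = "|")
  case_bins <- table(bin_of(cases))
  quota_raw <- as.numeric(case_bins) / sum(case_bins) * n
  quota <- floor(quota_raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    frac_order <- order(quota_raw - quota, names(case_bins), decreasing = TRUE)
    quota[frac_order[seq_len(rem)]] <- quota[frac_order[seq_len(rem)]] + 1L
  }
  names(quota) <- names(case_bins)

  pool_bins <- bin_of(pool)
  taken <- logical(nrow(pool))
  picked <- integer(0)
  fallback_used <- FALSE
  split_bin <- function(b) {
    parts <- strsplit(b, "|", fixed = TRUE)[[1]]
    list(sex = parts[1], dec = as.numeric(parts[2]))
  }
  withr::with_seed(as.integer(seed), {
    for (b in names(quota)) {
      need <- quota[[b]]
      if (need == 0L) next
      avail <- which(pool_bins == b & !taken)
      take <- if (length(avail) <= need) avail else sample(avail, need)
      taken[take] <- TRUE
      picked <- c(picked, take)
      deficit <- need - length(take)
      while (deficit > 0L) {
        fallback_used <- TRUE
        tb <- split_bin(b)
        open <- which(!taken)
        if (!length(open)) abort("control pool exhausted during matched sampling")
        ob <- lapply(pool_bins[open], split_bin)
        dist <- vapply(ob, function(o) {
          abs(o$dec - tb$dec) + ifelse(o$sex == tb$sex, 0, 100)
        }, numeric(1))
        near <- open[dist == min(dist)]
        take2 <- if (length(near) <= deficit) near else sample(near, deficit)
        taken[take2] <- TRUE
        picked <- c(picked, take2)
        deficit <- deficit - length(take2)
      }
    }
  })
  if (fallback_used) {
    warn("matched sampling fell back to neighbouring sex/age bins for some quotas")
  }
  pool[sort(picked), ]
}

#' Generate a complete synthetic analysis fixture
#'
#' Chains the generators: ontology, gene track and annotation, cases plus
#' control pool, then an age/sex-matched control draw, yielding the
#' analysis cohort (cases + matched controls) and, optionally, every input
#' file the pipeline reads.
#'
#' @param config A [fixture_config()].
#' @param dir Optional directory for the on-disk fixture.
#' @return List: `dag`, `gene_track`, `gene2go`, `cohort` (the analysis
#'   cohort), `pool` (full control pool), `planted_root`, `disease_genes`,
#'   `chrom_lengths`, `paths` (named file paths, `NA` when not written).
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  ont <- generate_ontology(config, path = if (is.null(dir)) NULL else {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    file.path(dir, "ontology.obo")
  })
  ann <- generate_annotation(ont$dag, config, dir)
  coh <- generate_cohort(ont$dag, ann, config, dir = NULL)
  cases <- filter(coh$cohort, .data$label == "case")
  pool <- filter(coh$cohort, .data$label == "ctrl")
  ctrls <- matched_control_sample(pool, cases, config$n_ctrl_sampled,
                                  seed = derive_seed(config$seed, 4L))
  cohort <- bind_rows(cases, ctrls)

  paths <- c(list(obo = ont$path), ann$paths, coh$paths)
  if (!is.null(dir)) {
    reg <- tidyr::unnest(select(cohort, "sample_id", "regions"), "regions")
    paths$regions <- file.path(dir, "regions.bed")
    readr::write_tsv(select(reg, "chrom", "start", "end", "sample_id"),
                     paths$regions, col_names = FALSE)
    paths$phenotypes <- file.path(dir, "phenotypes.tsv")
    readr::write_tsv(select(cohort, "sample_id", "label", "sex", "age"),
                     paths$phenotypes)
    paths$chrom_lengths <- file.path(dir, "chrom_lengths.tsv")
    readr::write_tsv(coh$chrom_lengths, paths$chrom_lengths, col_names = FALSE)
    paths$disease_genes <- file.path(dir, "disease_genes.txt")
    writeLines(coh$disease_genes, paths$disease_genes)
  }
  list(dag = ont$dag, gene_track = ann$gene_track, gene2go = ann$gene2go,
       cohort = cohort, pool = pool, planted_root = coh$planted_root,
       disease_genes = coh$disease_genes, chrom_lengths = coh$chrom_lengths,
       paths = paths)
}

#' Fixture preset for the rare-function regime
#'
#' A larger, sparser world than [fixture_config()] defaults: 800 terms and
#' 1000 genes with 1-2 annotations each, smaller mosaic regions, and a wide
#' planted module (20-40 genes under a root of around a dozen terms, each
#' member term annotated to at most 5 genes). With a 0.35 case effect the
#' affected cases scatter across the module, so every individual signal
#' term is carried by well under 10% of the 200 samples - too rare for a
#' per-term presence test to reach significance - while the module as a
#' whole still separates the classes, which is the setting the
#' sub-ontology analysis is built for.
#'
#' @param seed Integer seed.
#' @param effect Fraction of affected cases.
#' @return A `fixture_config`.
#' @export
low_frequency_config <- function(seed = 1L, effect = 0.35) {
  fixture_config(seed = seed, n_terms = 800L, n_genes = 1000L,
                 terms_per_gene = c(1L, 2L),
                 regions_per_sample = c(1L, 2L), region_length_bp = c(1e6, 3e6),
                 effect = effect, planted_term_max_genes = 5,
                 planted_size_range = c(5L, 25L),
                 planted_gene_range = c(20L, 40L),
                 planted_target_nodes = 12L)
}
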