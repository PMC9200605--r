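# Shared fixtures and independent oracles for the test suite.

# Seven-term toy ontology: root r; a,b under r; c,d under a; e under b;
# f under both c (is_a) and d (part_of).
toy_obo_lines <- function() {
  c("format-version: 1.2",
    "",
    "[Term]", "id: GO:r", "name: root", "namespace: biological_process",
    "",
    "[Term]", "id: GO:a", "name: branch a", "namespace: biological_process",
    "is_a: GO:r ! root",
    "",
    "[Term]", "id: GO:b", "name: branch b", "namespace: biological_process",
    "is_a: GO:r",
    "",
    "[Term]", "id: GO:c", "name: leaf c", "namespace: biological_process",
    "is_a: GO:a",
    "",
    "[Term]", "id: GO:d", "name: leaf d", "namespace: biological_process",
    "is_a: GO:a",
    "",
    "[Term]", "id: GO:e", "name: leaf e", "namespace: biological_process",
    "is_a: GO:b",
    "",
    "[Term]", "id: GO:f", "name: leaf f", "namespace: biological_process",
    "is_a: GO:c", "relationship: part_of GO:d",
    "")
}

toy_obo_file <- function(lines = toy_obo_lines()) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_dag <- function() parse_obo(toy_obo_file())

# five-gene corpus used for the hand-derived IC values
toy_gene2go <- function() {
  tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    term = c("GO:c", "GO:d", "GO:e", "GO:f", "GO:a"))
}

# ---- independent oracles -------------------------------------------------

# ancestor closure by naive repeated expansion over an edge list
oracle_ancestors <- function(parents, term) {
  anc <- term
  repeat {
    nxt <- unique(c(anc, unlist(parents[anc], use.names = FALSE)))
    if (length(nxt) == length(anc)) return(anc)
    anc <- nxt
  }
}

# brute-force MICA: enumerate full ancestor sets, restrict, maximise IC,
# break ties by smallest id
oracle_mica <- function(parents, icv, t1, t2, restrict = NULL) {
  common <- intersect(oracle_ancestors(parents, t1), oracle_ancestors(parents, t2))
  if (!is.null(restrict)) common <- intersect(common, restrict)
  if (!length(common)) return(NA_character_)
  best <- max(icv[common])
  sort(common[icv[common] == best])[1]
}

oracle_lin <- function(parents, icv, t1, t2, restrict = NULL) {
  m <- oracle_mica(parents, icv, t1, t2, restrict)
  if (is.na(m)) return(0)
  denom <- icv[[t1]] + icv[[t2]]
  if (denom <= 0) return(0)
  min(1, 2 * icv[[m]] / denom)
}

# exact two-sided Fisher p for a 2x2 table: hypergeometric weights as exact
# integers recovered from log-binomials (all weights < 2^53 for n <= 40, so
# rounding restores the exact integer), summed where w <= w_observed
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  w <- round(exp(lchoose(r1, ks) + lchoose(r2, c1 - ks)))
  w_obs <- w[ks == a]
  min(1, sum(w[w <= w_obs]) / sum(w))
}

# literal Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# naive best-match-average from a similarity lookup function
oracle_bma <- function(set_a, set_b, sim_fun) {
  if (!length(set_a) || !length(set_b)) return(0)
  best_a <- vapply(set_a, function(t1) max(vapply(set_b, function(t2) sim_fun(t1, t2), numeric(1))), numeric(1))
  best_b <- vapply(set_b, function(t2) max(vapply(set_a, function(t1) sim_fun(t1, t2), numeric(1))), numeric(1))
  0.5 * (mean(best_a) + mean(best_b))
}
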