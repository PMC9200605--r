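# Pascal-triangle binomial table, exact in doubles for n <= 55 (all entries
# below 2^53). Built once and cached.
pascal_env <- new.env(parent = emptyenv())

pascal_table <- function(n_max) {
  key <- as.character(n_max)
  if (!is.null(pascal_env[[key]])) return(pascal_env[[key]])
  B <- matrix(0, n_max + 1L, n_max + 1L)
  B[, 1L] <- 1
  for (i in 2L:(n_max + 1L)) {
    for (j in 2L:i) B[i, j] <- B[i - 1L, j - 1L] + B[i - 1L, j]
  }
  pascal_env[[key]] <- B
  B
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value: with margins fixed, the sum of
#' hypergeometric probabilities of all tables whose point probability does
#' not exceed that of the observed table. For totals up to 55 the
#' hypergeometric weights are exact integers (built by Pascal-recurrence
#' addition, each below 2^53), so the comparison and the sum are exact; for
#' larger tables the weights are compared in log space with a 1e-7 relative
#' guard against floating-point ties, the convention used by
#' [stats::fisher.test()].
#'
#' A table with an empty row or column margin admits no test; its p-value
#' is 1 and the `zero_margin` attribute is set.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` read row-wise.
#' @return p-value in `[0, 1]` with logical attribute `zero_margin`.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- if (is.matrix(table)) as.vector(t(table)) else as.vector(table)
  x <- as.integer(round(as.numeric(x)))
  if (length(x) != 4L || any(is.na(x)) || any(x < 0)) {
    abort("need a 2x2 table of non-negative counts")
  }
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
  if (r1 == 0L || r2 == 0L || c1 == 0L || (b + d) == 0L) {
    return(structure(1, zero_margin = TRUE))
  }
  ks <- max(0L, c1 - r2):min(r1, c1)
  if (n <= 55L) {
    B <- pascal_table(55L)
    w <- B[r1 + 1L, ks + 1L] * B[r2 + 1L, c1 - ks + 1L]
    w_obs <- w[ks == a]
    p <- sum(w[w <= w_obs]) / sum(w)
  } else {
    lw <- dhyper(ks, r1, r2, c1, log = TRUE)
    lw_obs <- lw[ks == a]
    p <- sum(exp(lw[lw <= lw_obs + log1p(1e-7)]))
  }
  structure(min(1, p), zero_margin = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order. A thin wrapper over
#' [stats::p.adjust()] kept as a named surface so the multiple-testing rule
#' used across the pipeline lives in one place.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}
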