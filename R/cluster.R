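#' Two-group Ward clustering of a similarity matrix
#'
#' Converts similarity to distance (`d = 1 - s`), runs agglomerative
#' clustering with Ward linkage on the precomputed distance matrix via
#' [stats::hclust()], and cuts the tree at two groups. `"ward.D2"` (the
#' squared-distance update on the supplied dissimilarities) is the default;
#' `"ward.D"` is available for the classical update. The procedure is fully
#' deterministic for a given input.
#'
#' With two samples each becomes its own cluster. When every pairwise
#' distance is identical (e.g. all samples share one restricted term set)
#' the split is still deterministic but carries no information; the result
#' is flagged via the `degenerate` attribute.
#'
#' @param sim Symmetric similarity matrix in `[0, 1]` with sample ids as
#'   dimnames (see [similarity_matrix()]).
#' @param method `"ward.D2"` or `"ward.D"`.
#' @return Named integer vector of cluster labels (1 or 2), attribute
#'   `degenerate` set when all pairwise distances coincide.
#' @export
ward_two_clusters <- function(sim, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  n <- nrow(sim)
  stopifnot(n >= 2L, n == ncol(sim))
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- as.dist(1 - sim)
  degenerate <- max(d) - min(d) < .Machine$double.eps^0.5
  if (n == 2L) {
    cl <- setNames(c(1L, 2L), ids)
    attr(cl, "degenerate") <- degenerate
    return(cl)
  }
  hc <- hclust(d, method = method)
  cl <- cutree(hc, k = 2L)
  cl <- setNames(as.integer(cl), ids)
  attr(cl, "degenerate") <- degenerate
  cl
}
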