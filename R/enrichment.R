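#' Hypergeometric over-representation of a gene set collection
#'
#' For each set in the collection, tests whether the query is enriched
#' for that set's members against a finite universe: with N universe
#' genes, K of them in the set, and a query of size n sharing k genes
#' with the set, p = P[X >= k] for X ~ Hypergeometric(N, K, n) (upper
#' tail, so k = 0 gives p = 1 exactly). p-values are Benjamini-Hochberg
#' adjusted across all tested sets. Collection sets are intersected with
#' the universe before testing; the recommended universe is the set of
#' genes detectable in the expression data that produced the query, not
#' the genome.
#'
#' @param query Character vector of gene identifiers (upper-cased for
#'   matching); must be a subset of the universe.
#' @param collection A \code{GeneSetCollection}.
#' @param universe Character vector, the background gene set; defaults to
#'   the collection's own universe attribute if present.
#' @return Data frame sorted by q then p with columns set, k, K, n, N,
#'   p, q.
#' @export
hypergeom_enrich <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(universe)) universe <- attr(collection, "universe")
  if (is.null(universe) || length(universe) == 0)
    stop("empty universe", call. = FALSE)
  universe <- unique(toupper(as.character(universe)))
  query <- unique(toupper(as.character(query)))
  if (length(query) == 0) stop("empty query", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) " ...", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  sets <- lapply(collection, function(s) intersect(s, universe))
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(query, s)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(collection), k = unname(k), K = unname(K),
                    n = n, N = N,
                    p = pmin(pmax(p, .Machine$double.xmin), 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p, out$set), , drop = FALSE]
}
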