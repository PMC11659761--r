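#' Tissue-by-tissue similarity of aging signatures
#'
#' A tissue's aging signature is its vector of per-gene age-correlation
#' coefficients. Signatures are aligned on the genes common to every
#' tissue's call table, correlated pairwise (Pearson), and the tissues
#' clustered by average-linkage hierarchical clustering on the distance
#' 1 - r. Groups come either from cutting the tree at \code{k} or from a
#' fixed, externally supplied assignment (so downstream stages need not
#' depend on clustering reproducibility).
#'
#' @param tables Named list of \code{AgingCallTable}, one per tissue
#'   (>= 2 tissues).
#' @param k Number of groups to cut the tree into (ignored when
#'   \code{groups} is supplied).
#' @param groups Optional fixed assignment: named character vector
#'   tissue -> group label.
#' @param min_common Minimum size of the common gene set (default 100);
#'   below this a signature correlation is meaningless.
#' @return A \code{TissueSimilarity}: list with \code{similarity} (tissue
#'   x tissue correlation matrix), \code{groups} (named vector), and
#'   \code{tree} (\code{hclust} object).
#' @export
tissue_signature_similarity <- function(tables, k = 4, groups = NULL,
                                        min_common = 100) {
  if (length(tables) < 2) stop("need >= 2 tissues", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("`tables` must be a named list (tissue labels)", call. = FALSE)
  common <- Reduce(intersect, lapply(tables, function(t) t$gene))
  if (length(common) < min_common)
    stop(sprintf("only %d genes common to all tissues (< %d): signature correlation meaningless",
                 length(common), min_common), call. = FALSE)
  sig <- vapply(tables, function(t) t$r[match(common, t$gene)],
                numeric(length(common)))
  sim <- stats::cor(sig)
  tree <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  if (is.null(groups)) {
    cut <- stats::cutree(tree, k = k)
    groups <- stats::setNames(paste0("group_", cut), names(cut))
  } else {
    missing <- setdiff(names(tables), names(groups))
    if (length(missing) > 0)
      stop("fixed grouping missing tissues: ",
           paste(missing, collapse = ", "), call. = FALSE)
    groups <- groups[names(tables)]
  }
  structure(list(similarity = sim, groups = groups, tree = tree,
                 n_common_genes = length(common)),
            class = "TissueSimilarity")
}

#' @export
print.TissueSimilarity <- function(x, ...) {
  cat(sprintf("TissueSimilarity: %d tissues, %d groups (%d common genes)\n",
              nrow(x$similarity), length(unique(x$groups)),
              x$n_common_genes))
  invisible(x)
}

#' Intersect per-tissue aging calls within tissue groups
#'
#' "Group aging genes" of a direction are the genes called in that
#' direction in every member tissue of the group. Venn region counts are
#' reported for every non-empty subset of member tissues (genes called in
#' exactly that subset), so the intersection count equals the region
#' covering all members.
#'
#' @param tables Named list of \code{AgingCallTable}, one per tissue.
#' @param groups Named character vector tissue -> group label; every
#'   group member must have a call table.
#' @param direction \code{"up"} or \code{"down"}.
#' @return Named list (one element per group) of \code{GroupAgingGenes}:
#'   list with \code{group}, \code{direction}, \code{tissues},
#'   \code{genes} (the intersection) and \code{venn} (named integer
#'   vector of region counts, names like \code{"t1&t2"}).
#' @export
group_intersection <- function(tables, groups, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (length(groups) == 0) stop("empty group assignment", call. = FALSE)
  out <- list()
  for (grp in unique(groups)) {
    members <- names(groups)[groups == grp]
    if (length(members) == 0) stop("empty group: ", grp, call. = FALSE)
    if (!all(members %in% names(tables)))
      stop("group ", grp, " members missing call tables: ",
           paste(setdiff(members, names(tables)), collapse = ", "),
           call. = FALSE)
    called <- lapply(tables[members],
                     function(t) t$gene[t$call == direction])
    inter <- Reduce(intersect, called)
    all_genes <- unique(unlist(called))
    membership <- vapply(called, function(s) all_genes %in% s,
                         logical(length(all_genes)))
    if (length(all_genes) == 1)
      membership <- matrix(membership, nrow = 1,
                           dimnames = list(NULL, members))
    region <- apply(membership, 1, function(m)
      paste(members[m], collapse = "&"))
    venn <- table(factor(region, levels = unlist(lapply(
      seq_along(members), function(sz)
        utils::combn(members, sz, paste, collapse = "&")))))
    out[[grp]] <- structure(list(
      group = grp, direction = direction, tissues = members,
      genes = sort(inter),
      venn = stats::setNames(as.integer(venn), names(venn))),
      class = "GroupAgingGenes")
  }
  out
}

#' @export
print.GroupAgingGenes <- function(x, ...) {
  cat(sprintf("GroupAgingGenes: %s [%s] %d tissues -> %d genes\n",
              x$group, x$direction, length(x$tissues), length(x$genes)))
  invisible(x)
}

#' Cross-cohort validation of aging-gene calls
#'
#' A gene is validated when it is called in the given direction in at
#' least \code{k_min} discovery tissues AND shows a same-direction
#' significant correlation (its \code{call} field) in at least one
#' validation cohort. Validation call tables are expected to have been
#' screened with \code{log_age = TRUE} when the validation cohorts use
#' log-scale expression.
#'
#' @param calls Named list of discovery \code{AgingCallTable}.
#' @param validation List of validation \code{AgingCallTable}.
#' @param k_min Minimum number of discovery tissues calling the gene
#'   (convention: 3 for up, 6 for down).
#' @param direction \code{"up"} or \code{"down"}.
#' @return List with \code{candidates} (genes called in >= k_min
#'   discovery tissues), \code{validated} (the subset confirmed in >= 1
#'   validation table) and \code{n_candidates}, \code{n_validated}.
#' @export
cross_validate <- function(calls, validation, k_min,
                           direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (k_min > length(calls))
    stop(sprintf("k_min (%d) exceeds number of discovery tissues (%d)",
                 k_min, length(calls)), call. = FALSE)
  counts <- table(unlist(lapply(calls,
                                function(t) t$gene[t$call == direction])))
  candidates <- sort(names(counts)[counts >= k_min])
  confirmed <- unique(unlist(lapply(validation,
                                    function(t) t$gene[t$call == direction])))
  validated <- intersect(candidates, confirmed)
  list(candidates = candidates, validated = validated,
       n_candidates = length(candidates), n_validated = length(validated))
}
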