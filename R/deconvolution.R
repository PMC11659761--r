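#' Build a cell-type signature matrix from labeled single-cell profiles
#'
#' For each cell type, candidate markers are ranked by the difference
#' between that type's mean log2 expression and the maximum mean among
#' the other types; the top \code{markers_per_type} genes with a positive
#' difference are selected. Signature entries are per-type mean log2
#' expression over cells, restricted to the union of selected markers.
#'
#' @param sc_expr An \code{ExpressionMatrix} of single cells (raw input is
#'   moved to log2(x+1)).
#' @param cell_labels Character vector of cell-type labels, one per
#'   column of \code{sc_expr}; every type needs >= \code{min_cells} cells.
#' @param markers_per_type Markers selected per type (default 50).
#' @param min_cells Minimum cells per type (default 20).
#' @return A \code{CellSignatureMatrix}: marker genes x cell types matrix
#'   of mean log2 expression with a \code{markers} attribute (named list
#'   of each type's selected markers).
#' @export
build_signature <- function(sc_expr, cell_labels, markers_per_type = 50,
                            min_cells = 20) {
  stopifnot(inherits(sc_expr, "ExpressionMatrix"))
  if (length(cell_labels) != ncol(sc_expr))
    stop("cell_labels must match single-cell columns", call. = FALSE)
  types <- unique(cell_labels)
  if (length(types) < 2) stop("need >= 2 cell types", call. = FALSE)
  counts <- table(cell_labels)
  if (any(counts < min_cells))
    stop("cell type(s) below ", min_cells, " cells: ",
         paste(names(counts)[counts < min_cells], collapse = ", "),
         call. = FALSE)
  vals <- unclass(to_log2(sc_expr))
  means <- vapply(types, function(ty)
    rowMeans(vals[, cell_labels == ty, drop = FALSE], na.rm = TRUE),
    numeric(nrow(vals)))
  markers <- list()
  for (ty in types) {
    others <- means[, setdiff(types, ty), drop = FALSE]
    score <- means[, ty] - apply(others, 1, max)
    pos <- score > 0
    if (!any(pos))
      stop("cell type '", ty, "' has no positive-difference marker gene",
           call. = FALSE)
    ord <- order(score, decreasing = TRUE)
    ord <- ord[pos[ord]]
    markers[[ty]] <- rownames(vals)[utils::head(ord, markers_per_type)]
  }
  sel <- sort(unique(unlist(markers)))
  sig <- means[sel, , drop = FALSE]
  for (i in seq_len(ncol(sig) - 1)) for (j in seq(i + 1, ncol(sig)))
    if (isTRUE(all.equal(sig[, i], sig[, j], check.attributes = FALSE)))
      stop("signature columns identical for types '", types[i], "' and '",
           types[j], "'", call. = FALSE)
  structure(sig, markers = markers,
            class = c("CellSignatureMatrix", "matrix"))
}

#' @export
print.CellSignatureMatrix <- function(x, ...) {
  cat(sprintf("CellSignatureMatrix: %d markers x %d cell types (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Estimate cell-type fractions from bulk profiles
#'
#' Per bulk sample, solves the non-negative least-squares problem
#' min ||S f - b||_2 subject to f >= 0 on the linear expression scale
#' (log2-flagged inputs and the log2 signature are exponentiated first),
#' then renormalizes f to sum to one. Renormalization makes the estimate
#' invariant to positive rescaling of the bulk sample. The residual norm
#' of each fit is reported.
#'
#' @param bulk An \code{ExpressionMatrix} of bulk samples.
#' @param sig A \code{CellSignatureMatrix} from \code{\link{build_signature}}.
#' @return A \code{CellFractions}: samples x cell-types matrix, each row
#'   non-negative and summing to 1, with a \code{residuals} attribute
#'   (per-sample residual norm).
#' @export
estimate_fractions <- function(bulk, sig) {
  stopifnot(inherits(bulk, "ExpressionMatrix"),
            inherits(sig, "CellSignatureMatrix"))
  common <- intersect(rownames(sig), rownames(bulk))
  if (length(common) < ncol(sig))
    stop(sprintf("bulk shares only %d marker genes with the signature (< %d cell types)",
                 length(common), ncol(sig)), call. = FALSE)
  A <- 2^unclass(sig)[common, , drop = FALSE]
  bvals <- unclass(bulk)[common, , drop = FALSE]
  if (expr_scale(bulk) == "log2") bvals <- 2^bvals
  n <- ncol(bvals)
  frac <- matrix(NA_real_, nrow = n, ncol = ncol(sig),
                 dimnames = list(colnames(bvals), colnames(sig)))
  resid <- stats::setNames(numeric(n), colnames(bvals))
  for (j in seq_len(n)) {
    b <- bvals[, j]
    if (all(b == 0, na.rm = TRUE))
      stop("undefined fractions: bulk sample '", colnames(bvals)[j],
           "' is all zero", call. = FALSE)
    ok <- !is.na(b)
    fit <- pracma::lsqnonneg(A[ok, , drop = FALSE], b[ok])
    f <- fit$x
    if (sum(f) <= 0)
      stop("undefined fractions: NNLS returned the zero vector for sample '",
           colnames(bvals)[j], "'", call. = FALSE)
    frac[j, ] <- f / sum(f)
    resid[j] <- sqrt(sum(fit$resid.norm))
  }
  structure(frac, residuals = resid,
            class = c("CellFractions", "matrix"))
}

#' @export
print.CellFractions <- function(x, ...) {
  cat(sprintf("CellFractions: %d samples x %d cell types\n",
              nrow(x), ncol(x)))
  print(utils::head(round(unclass(x), 3)))
  invisible(x)
}

#' Compare cell-type fractions between sample groups
#'
#' Splits samples into two groups — by donor age (default split at 60
#' years, the age after which neuron loss is expected) or by physical-
#' activity arm — and reports, per cell type, the group means, their
#' difference, and a two-sided unequal-variance t p-value.
#'
#' @param fractions A \code{CellFractions}.
#' @param samples A \code{SampleTable} covering the bulk samples.
#' @param by \code{"age"} or \code{"activity"}.
#' @param age_split Age boundary in years (group a: age > split; group b:
#'   age <= split).
#' @param arms For \code{by = "activity"}: the two arms contrasted,
#'   default \code{c("high", "low")} (a minus b).
#' @param min_n Minimum samples per group (default 3).
#' @return Data frame: cell_type, mean_a, mean_b, difference, p, n_a, n_b.
#' @export
compare_fractions <- function(fractions, samples, by = c("age", "activity"),
                              age_split = 60, arms = c("high", "low"),
                              min_n = 3) {
  by <- match.arg(by)
  stopifnot(inherits(fractions, "CellFractions"))
  smp <- samples[match(rownames(fractions), samples$sample_id), ]
  if (by == "age") {
    ga <- rownames(fractions)[!is.na(smp$age) & smp$age > age_split]
    gb <- rownames(fractions)[!is.na(smp$age) & smp$age <= age_split]
  } else {
    arm <- stratify_activity(samples)
    ga <- intersect(rownames(fractions), names(arm)[arm == arms[1]])
    gb <- intersect(rownames(fractions), names(arm)[arm == arms[2]])
  }
  if (length(ga) < min_n || length(gb) < min_n)
    stop(sprintf("group below minimum size (%d vs %d, need >= %d each)",
                 length(ga), length(gb), min_n), call. = FALSE)
  res <- lapply(colnames(fractions), function(ct) {
    fa <- fractions[ga, ct]; fb <- fractions[gb, ct]
    identical_groups <- isTRUE(all.equal(sort(unname(fa)), sort(unname(fb))))
    p <- if (stats::var(fa) + stats::var(fb) == 0) {
      if (mean(fa) == mean(fb)) 1 else NA_real_
    } else stats::t.test(fa, fb)$p.value
    data.frame(cell_type = ct, mean_a = mean(fa), mean_b = mean(fb),
               difference = mean(fa) - mean(fb), p = p,
               n_a = length(fa), n_b = length(fb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
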