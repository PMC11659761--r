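#' Normalize expression to stratum control means
#'
#' Within each stratum (e.g. brain area), every gene is normalized to the
#' mean of that stratum's control samples: divided by it on the raw scale
#' or shifted by it on the log2 scale. Control-arm stratum means therefore
#' become 1 (raw) or 0 (log2), making case/control contrasts comparable
#' across strata.
#'
#' @param expr An \code{ExpressionMatrix}.
#' @param control_ids Sample identifiers of the control arm.
#' @param strata Named character vector sample_id -> stratum covering
#'   every column of \code{expr}.
#' @return An \code{ExpressionMatrix} on the same scale.
#' @export
normalize_to_control_mean <- function(expr, control_ids, strata) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  ids <- colnames(expr)
  if (!all(ids %in% names(strata)))
    stop("strata must cover every sample in the expression matrix",
         call. = FALSE)
  strata <- strata[ids]
  vals <- unclass(expr)
  lg <- expr_scale(expr) == "log2"
  for (st in unique(strata)) {
    cols <- ids[strata == st]
    ctrl <- intersect(cols, control_ids)
    if (length(ctrl) < 2)
      stop(sprintf("stratum '%s' has %d control sample(s); need >= 2",
                   st, length(ctrl)), call. = FALSE)
    ctrl_mean <- rowMeans(vals[, ctrl, drop = FALSE], na.rm = TRUE)
    if (lg) {
      vals[, cols] <- vals[, cols, drop = FALSE] - ctrl_mean
    } else {
      if (any(ctrl_mean == 0, na.rm = TRUE))
        stop(sprintf("stratum '%s' has genes with zero control mean; cannot divide",
                     st), call. = FALSE)
      vals[, cols] <- vals[, cols, drop = FALSE] / ctrl_mean
    }
  }
  expression_matrix(vals, scale = expr_scale(expr))
}

#' Genewise two-group contrast (Welch's t on log2 values)
#'
#' log2 fold change is the difference of group means (a minus b) on the
#' log2 scale; the p-value is a two-sided unequal-variance (Welch) t test
#' with Welch-Satterthwaite degrees of freedom, computed genewise from
#' group means and variances. Genes with zero variance in both groups (or
#' too few unmasked samples) have an undefined p and are flagged rather
#' than dropped silently.
#'
#' @param expr An \code{ExpressionMatrix}; raw-scale input is moved to
#'   log2(x+1).
#' @param group_a_ids,group_b_ids Sample identifiers of the two groups
#'   (>= 3 each); for a disease contrast a = case, b = control, for an
#'   intervention contrast a = high activity, b = low.
#' @return A \code{DiffTable}: data frame with gene, log2fc, p, n_a, n_b
#'   and a logical \code{flagged} column for undefined tests.
#' @export
two_group_diff <- function(expr, group_a_ids, group_b_ids) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  vals <- unclass(to_log2(expr))
  a <- intersect(group_a_ids, colnames(vals))
  b <- intersect(group_b_ids, colnames(vals))
  if (length(a) < 3 || length(b) < 3)
    stop(sprintf("each group needs >= 3 samples (got %d and %d)",
                 length(a), length(b)), call. = FALSE)
  if (length(intersect(a, b)) > 0)
    stop("groups overlap", call. = FALSE)
  va <- vals[, a, drop = FALSE]; vb <- vals[, b, drop = FALSE]
  na <- rowSums(!is.na(va)); nb <- rowSums(!is.na(vb))
  ma <- rowMeans(va, na.rm = TRUE); mb <- rowMeans(vb, na.rm = TRUE)
  sa2 <- apply(va, 1, stats::var, na.rm = TRUE)
  sb2 <- apply(vb, 1, stats::var, na.rm = TRUE)
  lfc <- ma - mb
  se2 <- sa2 / na + sb2 / nb
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((sa2 / na)^2 / (na - 1) + (sb2 / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  flagged <- !is.finite(p) | na < 2 | nb < 2
  p[flagged] <- NA_real_
  p[!flagged] <- pmin(pmax(p[!flagged], .Machine$double.xmin), 1)
  out <- data.frame(gene = rownames(vals), log2fc = lfc, p = p,
                    n_a = na, n_b = nb, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DiffTable", "data.frame")
  out
}
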