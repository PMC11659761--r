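#' Pearson correlation with a t-based two-sided p-value
#'
#' The workhorse of the aging screen: sample Pearson coefficient between
#' two vectors after pairwise removal of masked entries, with the exact
#' t transform \code{t = r * sqrt((n-2) / (1-r^2))} referred to a t
#' distribution on n-2 degrees of freedom for the two-sided p-value.
#' Constant input is an error, never a silent r = 0: genes that are flat
#' in a tissue must be skipped with a logged reason by the caller.
#'
#' @param x,y Numeric vectors of equal length; NA entries are masked
#'   pairwise.
#' @return List with \code{r}, \code{p} (two-sided, in (0,1]) and \code{n}
#'   (pairs used).
#' @examples
#' pearson_with_p(c(1, 2, 3), c(2, 4, 6))$r   # 1
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  r <- stats::cor(x, y)
  p <- pearson_p_from_r(r, n)
  list(r = r, p = p, n = n)
}

# Vectorised two-sided p from r and n via the t transform; |r| = 1 maps to
# the smallest representable positive double so p stays in (0, 1].
pearson_p_from_r <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Screen one tissue for age-correlated genes
#'
#' Correlates every gene's expression with donor age and calls aging
#' genes with direction-specific significance thresholds: upregulated
#' aging genes have r > 0 and p < \code{alpha_up} (default 0.05),
#' downregulated aging genes have r < 0 and the more stringent
#' p < \code{alpha_down} (default 0.01). Raw-scale matrices are moved to
#' log2(x+1) first; with \code{log_age} the age covariate is
#' log-transformed before correlation (the convention used when
#' validating against microarray cohorts). Genes constant across the
#' tissue's samples, or with fewer than \code{min_n} unmasked samples,
#' are skipped with a logged reason.
#'
#' @param expr An \code{ExpressionMatrix}.
#' @param samples A \code{SampleTable} with ages.
#' @param alpha_up,alpha_down Raw-p thresholds for up / down calls.
#' @param log_age Log-transform age before correlating.
#' @param age_window Numeric length-2: donors outside this age range are
#'   excluded (default 40-69 years). \code{NULL} keeps all ages.
#' @param min_n Minimum unmasked samples for a gene to be usable.
#' @param adjust \code{"none"} (default; raw-p thresholds) or \code{"BH"}
#'   to threshold Benjamini-Hochberg adjusted p-values instead.
#' @return An \code{AgingCallTable}: data frame with columns gene, r, p,
#'   n, call (up/down/none), plus attributes \code{tissue} and
#'   \code{skipped} (data frame of skipped genes and reasons).
#' @export
screen_tissue <- function(expr, samples, alpha_up = 0.05, alpha_down = 0.01,
                          log_age = FALSE, age_window = c(40, 69),
                          min_n = 10, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  al <- align_samples(expr, samples)
  smp <- al$samples
  keep <- !is.na(smp$age)
  if (!is.null(age_window))
    keep <- keep & smp$age >= age_window[1] & smp$age <= age_window[2]
  if (sum(keep) < max(min_n, 3))
    stop(sprintf("tissue has only %d usable samples after join/age filter",
                 sum(keep)), call. = FALSE)
  vals <- unclass(to_log2(al$expr))[, keep, drop = FALSE]
  age <- smp$age[keep]
  if (log_age) age <- log(age)

  n_gene <- rowSums(!is.na(vals))
  # pairwise-complete Pearson r of every gene against age
  r <- suppressWarnings(
    as.vector(stats::cor(t(vals), age, use = "pairwise.complete.obs")))
  sds <- apply(vals, 1, stats::sd, na.rm = TRUE)
  usable <- n_gene >= min_n & !is.na(sds) & sds > 0 & !is.na(r)
  skipped <- data.frame(
    gene = rownames(vals)[!usable],
    reason = ifelse(n_gene[!usable] < min_n, "too_few_samples", "constant"),
    stringsAsFactors = FALSE)
  if (nrow(skipped) > 0)
    message(sprintf("screen_tissue: skipped %d gene(s) (%s)", nrow(skipped),
                    paste(names(table(skipped$reason)), collapse = ", ")))
  g <- rownames(vals)[usable]
  r <- r[usable]; n_used <- n_gene[usable]
  p <- pearson_p_from_r(r, n_used)
  p_call <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  call <- rep("none", length(g))
  call[r > 0 & p_call < alpha_up] <- "up"
  call[r < 0 & p_call < alpha_down] <- "down"
  out <- data.frame(gene = g, r = r, p = p, n = n_used, call = call,
                    stringsAsFactors = FALSE)
  tis <- unique(smp$tissue[keep])
  attr(out, "tissue") <- if (length(tis) == 1) tis else NA_character_
  attr(out, "skipped") <- skipped
  class(out) <- c("AgingCallTable", "data.frame")
  out
}

#' Write / read an aging call table (TSV: gene, r, p, n, call)
#' @param calls An \code{AgingCallTable}.
#' @param path File path.
#' @export
write_call_table <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("AgingCallTable", "data.frame")
  out
}
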