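#' Expression matrix container
#'
#' A validated genes-by-samples numeric matrix carrying an explicit scale
#' flag. All downstream stages of the pipeline consume this container.
#' Masked (missing) entries are stored as \code{NA}; accidental \code{NaN}
#' or infinite values are rejected at construction so that a missing value
#' is always a deliberate mask.
#'
#' @param values Numeric matrix with gene identifiers as row names and
#'   sample identifiers as column names.
#' @param scale Either \code{"raw"} (non-negative counts/intensities) or
#'   \code{"log2"} (already log2-transformed).
#' @return An object of class \code{ExpressionMatrix}: the matrix with a
#'   \code{scale} attribute.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("G", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, scale = "raw")
#' dim(em)
#' @export
expression_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  bad <- is.nan(values) | is.infinite(values)
  if (any(bad, na.rm = TRUE))
    stop("expression values must be finite or NA (explicit mask); found ",
         sum(bad, na.rm = TRUE), " NaN/Inf entries", call. = FALSE)
  structure(values, scale = scale, class = c("ExpressionMatrix", "matrix"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x), ncol(x), expr_scale(x)))
  nm <- sum(is.na(x))
  if (nm > 0) cat(sprintf("  %d masked entries\n", nm))
  invisible(x)
}

#' Scale flag of an expression matrix
#' @param x An \code{ExpressionMatrix}.
#' @return \code{"raw"} or \code{"log2"}.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "raw" else s
}

#' Convert an expression matrix to the log2 scale
#'
#' Raw values are transformed as \code{log2(x + 1)}; the fixed pseudocount
#' makes the transform total on non-negative input. Matrices already
#' flagged \code{log2} are returned unchanged.
#'
#' @param x An \code{ExpressionMatrix}.
#' @return An \code{ExpressionMatrix} on the log2 scale.
#' @export
to_log2 <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (expr_scale(x) == "log2") return(x)
  if (any(x < 0, na.rm = TRUE))
    stop("raw-scale matrix contains negative values; cannot log-transform",
         call. = FALSE)
  expression_matrix(log2(unclass(x) + 1), scale = "log2")
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: first column gene identifier, header row of sample
#' identifiers. GCT 1.2 layout as produced by GTEx-style exports:
#' \code{#1.2} version line, a line with declared row and column counts,
#' then a TSV with \code{Name} and \code{Description} columns.
#' Duplicate gene rows are rejected, never silently collapsed; a GCT whose
#' declared dimensions disagree with its body is rejected as corrupt.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"gct"}.
#' @param scale Scale flag to attach (\code{"raw"} or \code{"log2"}).
#' @return An \code{ExpressionMatrix}.
#' @export
read_expression <- function(path, format = c("tsv", "gct"),
                            scale = c("raw", "log2")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gct") return(read_gct(path, scale))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed TSV expression file (need gene column + >=1 sample): ",
         path, call. = FALSE)
  gid <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gid
  expression_matrix(vals, scale = scale)
}

read_gct <- function(path, scale) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !startsWith(hdr[1L], "#1.2"))
    stop("malformed GCT header: expected '#1.2' on line 1 of ", path,
         call. = FALSE)
  counts <- suppressWarnings(as.integer(strsplit(hdr[2L], "\t")[[1L]]))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stop("malformed GCT header: line 2 must carry row and column counts",
         call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 2L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("malformed GCT body: expected Name, Description and sample columns",
         call. = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1L]])
  if (nrow(vals) != counts[1L] || ncol(vals) != counts[2L])
    stop(sprintf(
      "GCT integrity error: declared %d x %d but found %d x %d in %s",
      counts[1L], counts[2L], nrow(vals), ncol(vals), path), call. = FALSE)
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to TSV or GCT
#'
#' @param x An \code{ExpressionMatrix}.
#' @param path Output file path.
#' @param format \code{"tsv"} or \code{"gct"}.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  format <- match.arg(format)
  vals <- unclass(x)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(vals), ncol(vals), sep = "\t")), con)
    df <- data.frame(Name = rownames(vals), Description = rownames(vals),
                     vals, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Join an expression matrix with a sample table
#'
#' Restricts both objects to the intersection of their sample identifiers
#' (exact string match) and reports how many samples each side lost.
#'
#' @param expr An \code{ExpressionMatrix}.
#' @param samples A sample table (see \code{\link{sample_table}}).
#' @return List with elements \code{expr}, \code{samples} (aligned in the
#'   same sample order), \code{n_dropped_expr}, \code{n_dropped_samples}.
#' @export
align_samples <- function(expr, samples) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  common <- intersect(colnames(expr), samples$sample_id)
  nd_e <- ncol(expr) - length(common)
  nd_s <- nrow(samples) - length(common)
  if (nd_e > 0 || nd_s > 0)
    message(sprintf(
      "align_samples: kept %d shared samples (dropped %d from expression, %d from metadata)",
      length(common), nd_e, nd_s))
  if (length(common) == 0)
    stop("no shared samples between expression matrix and sample table",
         call. = FALSE)
  e <- expression_matrix(unclass(expr)[, common, drop = FALSE],
                         scale = expr_scale(expr))
  s <- samples[match(common, samples$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  list(expr = e, samples = s, n_dropped_expr = nd_e, n_dropped_samples = nd_s)
}
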