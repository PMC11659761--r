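#' Gene-set collection
#'
#' Named sets of gene identifiers with an optional explicit background
#' (universe). Members are upper-cased on construction so that matching
#' against expression data is exact string comparison.
#'
#' @param sets Named list of character vectors; empty sets are rejected.
#' @param universe Optional character vector, the background gene set.
#' @return An object of class \code{GeneSetCollection} (a named list with a
#'   \code{universe} attribute).
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0) stop("empty gene-set collection", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
  if (any(lengths(sets) == 0))
    stop("empty gene sets rejected: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "),
         call. = FALSE)
  if (!is.null(universe)) universe <- unique(toupper(as.character(universe)))
  structure(sets, universe = universe, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n", length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-delimited fields
#' \code{name <tab> description <tab> member...}. Lines with fewer than
#' three fields are a format error reported with the line number;
#' duplicate set names are rejected.
#'
#' @param path GMT file path.
#' @return A \code{GeneSetCollection}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0)
    stop(sprintf("GMT format error: line %d has fewer than 3 fields in %s",
                 short[1L], path), call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets)
}

#' Write a gene-set collection to GMT
#' @param collection A \code{GeneSetCollection}.
#' @param path Output file path.
#' @param descriptions Optional character vector of per-set descriptions;
#'   defaults to the set names.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  nm <- names(collection)
  if (is.null(descriptions)) descriptions <- nm
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(nm[i], descriptions[i], collection[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
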