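#' Syntropic deregulation of aging genes in a disease contrast
#'
#' An aging gene is syntropically deregulated when the disease contrast
#' moves it further in its aging direction: same-signed log2 fold change
#' with p below \code{alpha}. The denominator is the set of aging genes
#' of the requested direction that are present (and testable) in the
#' disease dataset; genes absent from the contrast are excluded, never
#' counted as misses.
#'
#' @param aging_calls An \code{AgingCallTable} (discovery tissue).
#' @param diff A \code{DiffTable} from the case-vs-control contrast.
#' @param direction \code{"up"} or \code{"down"} aging genes.
#' @param alpha Significance threshold on the contrast p-value.
#' @return A \code{SyntropyReport}: list with \code{tissue},
#'   \code{direction}, \code{n_aging_detected}, \code{n_syntropic},
#'   \code{proportion} and the syntropic \code{genes}.
#' @export
syntropy <- function(aging_calls, diff, direction = c("down", "up"),
                     alpha = 0.05) {
  direction <- match.arg(direction)
  aging <- aging_calls$gene[aging_calls$call == direction]
  d <- diff[match(aging, diff$gene), , drop = FALSE]
  present <- !is.na(d$gene) & !d$flagged & is.finite(d$log2fc)
  d <- d[present, , drop = FALSE]
  if (nrow(d) == 0)
    stop("undefined proportion: no aging genes of direction '", direction,
         "' detected in the contrast", call. = FALSE)
  same_sign <- if (direction == "down") d$log2fc < 0 else d$log2fc > 0
  hit <- same_sign & !is.na(d$p) & d$p < alpha
  structure(list(
    tissue = attr(aging_calls, "tissue"), direction = direction,
    n_aging_detected = nrow(d), n_syntropic = sum(hit),
    proportion = sum(hit) / nrow(d), genes = d$gene[hit]),
    class = "SyntropyReport")
}

#' @export
print.SyntropyReport <- function(x, ...) {
  cat(sprintf("SyntropyReport [%s]: %d / %d aging genes further %sregulated (%.1f%%)\n",
              x$direction, x$n_syntropic, x$n_aging_detected, x$direction,
              100 * x$proportion))
  invisible(x)
}

#' Stratify samples into physical-activity arms
#'
#' Actigraphy cut-offs follow the convention high > 2.1e5 counts/day and
#' moderate in (1e5, 2.1e5] counts/day (boundary values are moderate, per
#' the half-open interval); everything at or below 1e5 is low. Samples
#' without an activity value are excluded with a logged count.
#'
#' @param samples A \code{SampleTable} with an \code{activity} column.
#' @param high_cut,moderate_cut Cut-offs in units of \code{scale}
#'   counts/day (defaults 2.1 and 1.0).
#' @param scale Unit scale, default 1e5 counts/day.
#' @return Named character vector sample_id -> arm
#'   (\code{"high"/"moderate"/"low"}); samples lacking activity omitted.
#' @examples
#' st <- sample_table(data.frame(sample_id = c("a", "b", "c"),
#'                               activity = c(2.2e5, 2.1e5, 0.5e5)))
#' stratify_activity(st)  # high, moderate, low
#' @export
stratify_activity <- function(samples, high_cut = 2.1, moderate_cut = 1.0,
                              scale = 1e5) {
  act <- samples$activity
  miss <- is.na(act)
  if (any(miss))
    message(sprintf("stratify_activity: excluded %d sample(s) without activity",
                    sum(miss)))
  act <- act[!miss]
  ids <- samples$sample_id[!miss]
  arm <- ifelse(act > high_cut * scale, "high",
                ifelse(act > moderate_cut * scale, "moderate", "low"))
  stats::setNames(arm, ids)
}

#' Rescue (reversal) of aging genes under an intervention contrast
#'
#' A down-aging gene is rescued when the intervention contrast (e.g. high
#' minus low physical activity) raises it significantly: log2 fold change
#' above \code{log2(fold_min)} with p < \code{alpha}; symmetric for
#' up-aging genes. Aging genes not detected in the intervention dataset
#' are excluded from the denominator.
#'
#' @param aging_calls An \code{AgingCallTable}.
#' @param diff A \code{DiffTable}, intervention arm contrast oriented so
#'   that positive log2fc means higher under the intervention.
#' @param direction Aging direction of the genes considered.
#' @param alpha Significance threshold (default 0.05).
#' @param fold_min Minimum fold change for a rescue call; 1.0 (any
#'   significant opposite change) for bulk contrasts, 1.1 by convention
#'   for cell-resolved contrasts.
#' @return A \code{RescueReport}: list with \code{direction},
#'   \code{n_aging_detected}, \code{n_rescued}, \code{proportion} and the
#'   rescued \code{genes}.
#' @export
rescue <- function(aging_calls, diff, direction = c("down", "up"),
                   alpha = 0.05, fold_min = 1.0) {
  direction <- match.arg(direction)
  if (fold_min < 1) stop("fold_min must be >= 1", call. = FALSE)
  aging <- aging_calls$gene[aging_calls$call == direction]
  d <- diff[match(aging, diff$gene), , drop = FALSE]
  present <- !is.na(d$gene) & !d$flagged & is.finite(d$log2fc)
  d <- d[present, , drop = FALSE]
  if (nrow(d) == 0)
    stop("undefined proportion: no aging genes of direction '", direction,
         "' detected in the intervention contrast", call. = FALSE)
  thr <- log2(fold_min)
  opposite <- if (direction == "down") d$log2fc > thr else d$log2fc < -thr
  hit <- opposite & !is.na(d$p) & d$p < alpha
  structure(list(
    tissue = attr(aging_calls, "tissue"), direction = direction,
    n_aging_detected = nrow(d), n_rescued = sum(hit),
    proportion = sum(hit) / nrow(d), genes = d$gene[hit]),
    class = "RescueReport")
}

#' @export
print.RescueReport <- function(x, ...) {
  cat(sprintf("RescueReport [%s aging genes]: %d / %d rescued (%.1f%%)\n",
              x$direction, x$n_rescued, x$n_aging_detected,
              100 * x$proportion))
  invisible(x)
}
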