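#' ROC curve of quality scores against external labels
#'
#' Sweeps retention thresholds over `{0}`, every observed probability, and a
#' value just above the maximum (retaining nothing), and counts at each
#' threshold the fraction of truly high-quality spectra retained (TPR) and
#' the fraction of poor-quality spectra retained (FPR). A spectrum is
#' retained when its score is `>= threshold`, matching [classify_quality()].
#'
#' @param p_high numeric vector of high-quality probabilities, named by
#'   spectrum id (or supply `ids`).
#' @param labels data.frame with columns `id`, `label` as from
#'   [read_labels()]; every scored id must be labelled and both classes must
#'   be present.
#' @param ids optional character vector of ids aligned with `p_high`.
#' @return A data.frame with one row per threshold: `threshold`, `tpr`,
#'   `fpr`, `tnr` (= 1 - fpr), ordered by increasing threshold.
#' @export
roc_curve <- function(p_high, labels, ids = NULL) {
  if (is.null(ids)) ids <- names(p_high)
  if (is.null(ids)) stop("spectrum ids are required (names of p_high or 'ids')")
  lab <- labels$label[match(ids, labels$id)]
  if (anyNA(lab))
    stop("unlabelled spectrum id(s): ",
         paste(utils::head(ids[is.na(lab)], 5), collapse = ", "))
  is_high <- lab == "high"
  n_high <- sum(is_high); n_poor <- sum(!is_high)
  if (n_high == 0L || n_poor == 0L)
    stop("labels must contain both classes for ROC analysis")
  thresholds <- sort(unique(c(0, p_high, max(p_high) + 1e-9)))
  tpr <- vapply(thresholds, function(th) sum(p_high[is_high] >= th) / n_high, 0)
  fpr <- vapply(thresholds, function(th) sum(p_high[!is_high] >= th) / n_poor, 0)
  data.frame(threshold = thresholds, tpr = tpr, fpr = fpr, tnr = 1 - fpr)
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) curve returned by [roc_curve()].
#'
#' @param curve a data.frame from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]; y <- curve$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Best poor-spectrum elimination rate at a retention floor
#'
#' Among ROC points retaining at least `tpr_floor` of the truly high-quality
#' spectra, returns the largest true negative rate (fraction of poor-quality
#' spectra eliminated).
#'
#' @param curve a data.frame from [roc_curve()].
#' @param tpr_floor minimum acceptable true positive rate, e.g. 0.90.
#' @return The maximum `tnr` among qualifying points.
#' @export
tnr_at_tpr <- function(curve, tpr_floor) {
  if (nrow(curve) == 0L) stop("empty ROC curve")
  ok <- curve$tpr >= tpr_floor
  if (!any(ok)) stop("no ROC point reaches tpr >= ", tpr_floor)
  max(curve$tnr[ok])
}

#' Database-search time saving from pre-search filtering
#'
#' If only the spectra called high quality are submitted to the search
#' engine, the fraction of search time saved is
#' `1 - n_high_called / n_total` (search time taken proportional to the
#' number of spectra searched).
#'
#' @param n_high_called number of spectra called high quality (searched).
#' @param n_total total number of spectra in the dataset.
#' @return The saved fraction in `[0, 1]`.
#' @examples
#' search_savings(10042, 22576)  # ~0.56
#' @export
search_savings <- function(n_high_called, n_total) {
  if (n_total <= 0) stop("'n_total' must be positive")
  if (n_high_called < 0 || n_high_called > n_total)
    stop("'n_high_called' must be between 0 and n_total")
  1 - n_high_called / n_total
}

#' Write ROC points as tab-separated text
#'
#' @param curve data.frame from [roc_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_table <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
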