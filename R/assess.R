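#' Assess the quality of tandem mass spectra
#'
#' The main fitting function: computes the ten quality features for every
#' spectrum (see [quality-features]), binarizes each feature by the
#' top-percentile rule ([assign_by_percentile()]), builds the bipartite
#' spectrum-group ensemble graph ([build_graph()]), and solves the consensus
#' optimization ([consensus_solve()]) to obtain each spectrum's probability
#' of being high quality. No training labels are used at any point.
#'
#' @param spectra list of [spectrum()] objects (at least 2, so the percentile
#'   split is defined).
#' @param percentile per-feature percentage of spectra assigned to the
#'   high-quality class (default 50: top half by feature value).
#' @param alpha confidence weight on the initial per-feature labels
#'   (default 90).
#' @param epsilon convergence tolerance of the alternating solver
#'   (default 1e-6).
#' @param max_iter iteration cap of the solver (default 1000).
#' @param threshold probability cut-off for the final high/poor call
#'   (default 0.5; a spectrum with `p_high >= threshold` is called high).
#' @param constants a [mass_constants()] object.
#'
#' @return An object of class `ms2q_fit` with components
#'   \describe{
#'     \item{features}{the n x 10 feature table (data.frame with `id`).}
#'     \item{assignments}{the n x 10 per-feature class matrix.}
#'     \item{graph}{the [build_graph()] ensemble graph.}
#'     \item{consensus}{the [consensus_solve()] result (U, Q, costs, ...).}
#'     \item{p_high}{named numeric vector of high-quality probabilities.}
#'     \item{calls}{data.frame `id`, `p_high`, `p_poor`, `call`.}
#'     \item{cutoffs}{per-feature class-1 value cut-offs (used by `predict`).}
#'     \item{params}{the tuning parameters used.}
#'   }
#'   Methods: [print.ms2q_fit()], [summary.ms2q_fit()], [plot.ms2q_fit()],
#'   [fitted.ms2q_fit()], [coef.ms2q_fit()], [predict.ms2q_fit()].
#' @examples
#' d <- simulate_dataset(sim_config(n_high = 10, n_poor = 40, seed = 7))
#' fit <- assess_quality(d$spectra)
#' fit
#' head(fitted(fit))
#' @export
assess_quality <- function(spectra, percentile = 50, alpha = 90,
                           epsilon = 1e-6, max_iter = 1000L,
                           threshold = 0.5, constants = mass_constants()) {
  if (length(spectra) < 2L)
    stop("need at least 2 spectra: the percentile split is undefined otherwise")
  features <- compute_feature_matrix(spectra, constants)
  fmat <- as.matrix(features[feature_names])
  assignments <- apply(fmat, 2L, assign_by_percentile, p = percentile)
  graph <- build_graph(assignments)
  consensus <- consensus_solve(graph, consensus_params(alpha, epsilon, max_iter))
  p_high <- stats::setNames(consensus$U[, 1], features$id)
  calls <- classify_quality(consensus, threshold, ids = features$id)
  # smallest feature value placed in class 1: new value >= cutoff -> class 1
  cutoffs <- vapply(seq_len(ncol(fmat)), function(f)
    min(fmat[assignments[, f] == 1L, f]), 0)
  names(cutoffs) <- feature_names
  structure(list(
    features = features, assignments = assignments, graph = graph,
    consensus = consensus, p_high = p_high, calls = calls, cutoffs = cutoffs,
    params = list(percentile = percentile, alpha = alpha, epsilon = epsilon,
                  max_iter = max_iter, threshold = threshold,
                  constants = constants),
    call = match.call()
  ), class = "ms2q_fit")
}

#' @describeIn assess_quality one-line overview of the fit.
#' @param x,object an `ms2q_fit` object.
#' @param ... passed on / ignored.
#' @export
print.ms2q_fit <- function(x, ...) {
  cc <- x$consensus
  cat("Unsupervised MS/MS spectral quality assessment\n")
  cat(sprintf("  spectra: %d   features: %d   percentile: %g%%   alpha: %g\n",
              x$graph$n, x$graph$m, x$params$percentile, x$params$alpha))
  cat(sprintf("  consensus: %d iterations, %s, final cost %.4f\n",
              cc$iterations, if (cc$converged) "converged" else "NOT converged",
              cc$costs[length(cc$costs)]))
  tab <- table(x$calls$call)
  cat(sprintf("  calls at threshold %.2f: %d high, %d poor\n",
              x$params$threshold, tab[["high"]], tab[["poor"]]))
  invisible(x)
}

#' @describeIn assess_quality fuller report: feature ranges, probability
#'   distribution, convergence diagnostics.
#' @export
summary.ms2q_fit <- function(object, ...) {
  s <- list(
    n = object$graph$n,
    params = object$params,
    consensus = object$consensus,
    p_high_quantiles = stats::quantile(object$p_high,
                                       c(0, .05, .25, .5, .75, .95, 1)),
    call_table = table(object$calls$call),
    feature_summary = do.call(rbind, lapply(feature_names, function(f)
      data.frame(feature = f,
                 min = min(object$features[[f]]),
                 median = stats::median(object$features[[f]]),
                 max = max(object$features[[f]]),
                 class1_cutoff = object$cutoffs[[f]])))
  )
  class(s) <- "summary.ms2q_fit"
  s
}

#' @export
print.summary.ms2q_fit <- function(x, ...) {
  cat(sprintf("MS/MS quality assessment of %d spectra\n", x$n))
  cat(sprintf("alpha = %g, percentile = %g%%, threshold = %.2f\n",
              x$params$alpha, x$params$percentile, x$params$threshold))
  cc <- x$consensus
  cat(sprintf("consensus: %d iterations (%s), cost %.4f -> %.4f\n\n",
              cc$iterations, if (cc$converged) "converged" else "not converged",
              cc$costs[1], cc$costs[length(cc$costs)]))
  cat("p(high quality) quantiles:\n")
  print(round(x$p_high_quantiles, 4))
  cat("\ncalls:\n")
  print(x$call_table)
  cat("\nper-feature value range and class-1 cut-off:\n")
  df <- x$feature_summary
  df[-1] <- lapply(df[-1], function(v) signif(v, 5))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @describeIn assess_quality the vector of high-quality probabilities
#'   (named by spectrum id).
#' @export
fitted.ms2q_fit <- function(object, ...) object$p_high

#' @describeIn assess_quality the fitted group probability matrix `Q`,
#'   annotated with each group's feature and class.
#' @export
coef.ms2q_fit <- function(object, ...) {
  q <- object$consensus$Q
  colnames(q) <- c("p_high", "p_poor")
  cbind(object$graph$groups, as.data.frame(q))
}

#' @describeIn assess_quality score new spectra against the fitted model:
#'   features are binarized with the per-feature cut-offs learned at fit time
#'   and each spectrum's probability is the mean of the fitted group
#'   probabilities of the groups it falls into.
#' @param newdata list of [spectrum()] objects; `NULL` returns the fitted
#'   calls table.
#' @export
predict.ms2q_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$calls)
  features <- compute_feature_matrix(newdata, object$params$constants)
  fmat <- as.matrix(features[feature_names])
  m <- ncol(fmat)
  cls <- vapply(seq_len(m), function(f)
    ifelse(fmat[, f] >= object$cutoffs[[f]], 1L, 2L),
    integer(nrow(fmat)))
  cls <- matrix(cls, nrow = nrow(fmat))
  Q <- object$consensus$Q
  p_high <- vapply(seq_len(nrow(fmat)), function(i) {
    j <- (seq_len(m) - 1L) * 2L + cls[i, ]
    mean(Q[j, 1])
  }, 0)
  classify_quality(p_high, object$params$threshold, ids = features$id)
}

#' @describeIn assess_quality diagnostics: consensus cost trajectory and the
#'   distribution of high-quality probabilities.
#' @export
plot.ms2q_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$consensus$costs), x$consensus$costs, type = "b",
                 xlab = "iteration", ylab = "cost J(U, Q)",
                 main = "Consensus convergence", pch = 16)
  graphics::hist(x$p_high, breaks = 30, xlab = "p(high quality)",
                 main = "Spectrum quality probabilities", col = "grey70")
  graphics::abline(v = x$params$threshold, lty = 2)
  invisible(x)
}

#' Retain the spectra called high quality
#'
#' Convenience filter for the pre-search pipeline: keeps the spectra whose
#' fitted probability meets the threshold.
#'
#' @param fit an [assess_quality()] fit.
#' @param spectra the same list of spectra the model was fitted on.
#' @param threshold optional override of the fitted call threshold.
#' @return The retained sub-list of `spectra`.
#' @export
filter_high_quality <- function(fit, spectra, threshold = NULL) {
  th <- if (is.null(threshold)) fit$params$threshold else threshold
  keep <- fit$p_high >= th
  ids <- vapply(spectra, `[[`, "", "id")
  if (!identical(ids, names(fit$p_high)))
    stop("'spectra' do not match the fitted spectra (ids differ)")
  spectra[keep]
}
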