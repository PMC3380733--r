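#' Binarize feature values by a top-percentile rule
#'
#' Spectra whose value ranks in the top `p` percent (ranking by descending
#' value) are assigned class 1 (high quality); the rest class 2 (poor
#' quality). Exactly `ceiling(n * p / 100)` spectra receive class 1. Ties at
#' the percentile boundary are broken by input position (stable sort by value
#' descending, position ascending), so the assignment is reproducible.
#'
#' @param values numeric vector of feature values (one per spectrum).
#' @param p percentage in (0, 100); default 50.
#' @return Integer vector of class indices in `{1, 2}`, aligned with `values`.
#' @examples
#' assign_by_percentile(c(1, 2, 3, 4), 50)  # 2 2 1 1
#' @export
assign_by_percentile <- function(values, p = 50) {
  n <- length(values)
  if (n < 1L) stop("'values' must be non-empty")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 100)
    stop("'p' must be a percentage strictly between 0 and 100")
  n_high <- ceiling(n * p / 100)
  ord <- order(-values, seq_len(n), method = "radix")
  cls <- rep.int(2L, n)
  cls[ord[seq_len(n_high)]] <- 1L
  cls
}

#' Build the bipartite spectrum-group ensemble graph
#'
#' Given `n` spectra each assigned to one of two classes by each of `m`
#' features, every (feature, class) combination forms a group node, giving
#' `v = 2m` groups ordered (feature 1 class 1, feature 1 class 2, feature 2
#' class 1, ...). The binary affinity matrix `A` (n x v) records membership:
#' `A[i, j] = 1` iff spectrum i was placed in group j, so every row of `A`
#' sums to `m`. The initial group label matrix `Y` (v x 2) is the one-hot
#' encoding of each group's class, so every row of `Y` sums to 1.
#'
#' @param assignments n x m matrix (or data.frame) of class indices in
#'   `{1, 2}`; column f holds the class assigned by feature f.
#' @return An object of class `ensemble_graph`: list with elements `A`, `Y`,
#'   `groups` (data.frame: group index, feature index, class index), and the
#'   dimensions `n`, `m`, `v`, `k`.
#' @examples
#' asg <- cbind(c(1, 1, 2), c(2, 1, 1))
#' g <- build_graph(asg)
#' rowSums(g$A)  # all equal m = 2
#' @export
build_graph <- function(assignments) {
  assignments <- as.matrix(assignments)
  if (!all(assignments %in% c(1L, 2L)))
    stop("assignments must contain only class indices 1 or 2")
  n <- nrow(assignments); m <- ncol(assignments)
  if (n < 1L || m < 1L) stop("need at least one spectrum and one feature")
  k <- 2L
  v <- k * m
  A <- matrix(0L, n, v)
  for (f in seq_len(m)) {
    j <- (f - 1L) * k + assignments[, f]
    A[cbind(seq_len(n), j)] <- 1L
  }
  groups <- data.frame(
    group = seq_len(v),
    feature_index = rep(seq_len(m), each = k),
    class_index = rep.int(seq_len(k), m)
  )
  Y <- matrix(0L, v, k)
  Y[cbind(groups$group, groups$class_index)] <- 1L
  g <- structure(list(A = A, Y = Y, groups = groups,
                      n = n, m = m, v = v, k = k),
                 class = "ensemble_graph")
  stopifnot(all(rowSums(A) == m), all(rowSums(Y) == 1L))
  g
}

#' @export
print.ensemble_graph <- function(x, ...) {
  cat(sprintf("Ensemble graph: %d spectra x %d groups (%d features, %d classes)\n",
              x$n, x$v, x$m, x$k))
  invisible(x)
}

#' A five-spectrum, six-feature worked example
#'
#' A small hand-checkable assignment table (5 spectra, 6 binary assessors)
#' used throughout the documentation and tests to illustrate the bipartite
#' graph construction and the consensus solve.
#'
#' @return A 5 x 6 integer matrix of class indices with spectra in rows
#'   (`s1`..`s5`) and features in columns (`F1`..`F6`).
#' @examples
#' g <- build_graph(toy_assignments())
#' dim(g$A)  # 5 x 12
#' @export
toy_assignments <- function() {
  m <- rbind(
    F1 = c(1, 1, 2, 2, 2),
    F2 = c(1, 1, 2, 2, 2),
    F3 = c(2, 1, 2, 1, 2),
    F4 = c(1, 2, 1, 2, 2),
    F5 = c(1, 2, 2, 1, 2),
    F6 = c(2, 1, 1, 2, 2)
  )
  a <- t(m)
  storage.mode(a) <- "integer"
  rownames(a) <- paste0("s", 1:5)
  a
}
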