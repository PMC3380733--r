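#' Consensus cost function
#'
#' The objective of the constrained consensus optimization:
#' \deqn{J(U, Q) = \sum_z \sum_i \sum_j a_{ij} (u_{iz} - q_{jz})^2
#'   + \alpha \sum_z \sum_j (q_{jz} - y_{jz})^2}
#' The first term penalizes disagreement between a spectrum's class
#' probabilities and those of the groups it belongs to; the second anchors
#' the group probabilities to their initial labels with confidence `alpha`.
#' The cost is zero exactly when all per-feature assessments agree perfectly.
#'
#' @param graph an [build_graph()] ensemble graph.
#' @param U n x k matrix of spectrum class probabilities (rows in the simplex).
#' @param Q v x k matrix of group class probabilities (rows in the simplex).
#' @param alpha positive confidence weight on the initial labels.
#' @return The non-negative cost value.
#' @export
consensus_cost <- function(graph, U, Q, alpha) {
  .check_shapes(graph, U, Q)
  A <- graph$A
  ra <- rowSums(A); ca <- colSums(A)
  term1 <- sum(ra * rowSums(U^2)) + sum(ca * rowSums(Q^2)) -
    2 * sum((crossprod(U, A)) * t(Q))
  term2 <- alpha * sum((Q - graph$Y)^2)
  term1 + term2
}

.check_shapes <- function(graph, U, Q) {
  if (!is.matrix(U) || nrow(U) != graph$n || ncol(U) != graph$k)
    stop("U must be an n x k matrix conforming to the graph")
  if (!is.matrix(Q) || nrow(Q) != graph$v || ncol(Q) != graph$k)
    stop("Q must be a v x k matrix conforming to the graph")
  invisible(TRUE)
}

#' One alternating update of the spectrum probabilities
#'
#' Minimizes the consensus cost over `U` for fixed `Q`:
#' `u_iz = (1/m) * sum_j a_ij q_jz`, the mean of `q_jz` over the m groups
#' containing spectrum i. Row-stochasticity of `Q` is inherited by `U`.
#'
#' @inheritParams consensus_cost
#' @return The updated n x k matrix `U`.
#' @export
update_U <- function(graph, Q) {
  A <- graph$A
  rs <- rowSums(A)
  if (any(rs == 0)) stop("affinity matrix has an empty row (spectrum in no group)")
  (A %*% Q) / rs
}

#' One alternating update of the group probabilities
#'
#' Minimizes the consensus cost over `Q` for fixed `U`:
#' `q_jz = (sum_i a_ij u_iz + alpha * y_jz) / (alpha + sum_i a_ij)`,
#' a confidence-weighted average of the members' probabilities and the
#' group's initial label. An empty group keeps `q_j = y_j` exactly.
#'
#' @inheritParams consensus_cost
#' @return The updated v x k matrix `Q`.
#' @export
update_Q <- function(graph, U, alpha) {
  if (alpha <= 0) stop("'alpha' must be positive")
  A <- graph$A
  cs <- colSums(A)
  (crossprod(A, U) + alpha * graph$Y) / (alpha + cs)
}

#' Parameters of the consensus solver
#'
#' @param alpha positive confidence weight on the initial group labels
#'   (default 90).
#' @param epsilon convergence tolerance on the Frobenius norm of
#'   `U^t - U^(t-1)` (default 1e-6).
#' @param max_iter iteration cap (default 1000); hitting it flags
#'   non-convergence without raising an error.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(alpha = 90, epsilon = 1e-6, max_iter = 1000L) {
  stopifnot(alpha > 0, epsilon > 0, max_iter >= 1L)
  structure(list(alpha = alpha, epsilon = epsilon,
                 max_iter = as.integer(max_iter)),
            class = "consensus_params")
}

#' Solve the consensus optimization by alternating minimization
#'
#' Starting from `Q^0 = Y`, alternates [update_U()] and [update_Q()] until the
#' Frobenius norm of successive `U` iterates falls below `epsilon` or
#' `max_iter` is reached. Every iterate is row-stochastic by construction, and
#' the cost `J(U^t, Q^t)` is non-increasing, so the iteration converges to a
#' stationary point of the constrained problem.
#'
#' @param graph an [build_graph()] ensemble graph.
#' @param params a [consensus_params()] object.
#' @return An object of class `consensus_result`: list with the fixed-point
#'   matrices `U` (n x k) and `Q` (v x k), the per-iteration cost trajectory
#'   `costs`, the number of `iterations`, and a `converged` flag.
#' @examples
#' g <- build_graph(toy_assignments())
#' r <- consensus_solve(g, consensus_params(alpha = 90))
#' round(r$U, 4)
#' @export
consensus_solve <- function(graph, params = consensus_params()) {
  if (!all(rowSums(graph$Y) == 1) || !all(graph$Y %in% c(0, 1)))
    stop("initial label matrix Y must be one-hot per row")
  Q <- graph$Y * 1.0
  U_prev <- NULL
  costs <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(params$max_iter)) {
    iter <- t
    U <- update_U(graph, Q)
    Q <- update_Q(graph, U, params$alpha)
    costs[t] <- consensus_cost(graph, U, Q, params$alpha)
    if (t > 1L && costs[t] > costs[t - 1L] + 1e-9 * (1 + abs(costs[t - 1L])))
      stop("internal error: cost increased between iterations")
    if (!is.null(U_prev) && sqrt(sum((U - U_prev)^2)) <= params$epsilon) {
      converged <- TRUE
      U_prev <- U
      break
    }
    U_prev <- U
  }
  structure(list(U = U_prev, Q = Q, costs = costs,
                 iterations = iter, converged = converged),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus solve: %d spectra, %d iterations, %s (final cost %.6g)\n",
              nrow(x$U), x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$costs[length(x$costs)]))
  invisible(x)
}

#' Threshold consensus probabilities into quality calls
#'
#' A spectrum is called high quality iff its probability of class 1 (high)
#' is at least `threshold` (the boundary case counts as high).
#'
#' @param result a [consensus_solve()] result, or a numeric vector of
#'   high-quality probabilities.
#' @param threshold probability cut-off in `[0, 1]` (default 0.5); values
#'   above 1 call nothing high, 0 calls everything high.
#' @param ids optional character vector of spectrum ids.
#' @return A data.frame with columns `id`, `p_high`, `p_poor`, `call`
#'   (factor `high`/`poor`).
#' @export
classify_quality <- function(result, threshold = 0.5, ids = NULL) {
  p_high <- if (inherits(result, "consensus_result")) result$U[, 1] else result
  if (threshold < 0) stop("'threshold' must be non-negative")
  n <- length(p_high)
  if (is.null(ids)) ids <- names(p_high)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(
    id = ids,
    p_high = as.numeric(p_high),
    p_poor = 1 - as.numeric(p_high),
    call = factor(ifelse(p_high >= threshold, "high", "poor"),
                  levels = c("high", "poor")),
    row.names = NULL
  )
}
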