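toy_graph <- function() build_graph(toy_assignments())

test_that("the cost function matches its hand-computed values", {
  g <- toy_graph()
  Y <- g$Y * 1.0
  # unanimous instance: cost 0 at the unanimous hard labels
  ug <- build_graph(matrix(rep(c(1L, 2L, 1L), 4), 3, 4))
  Uhard <- cbind(c(1, 0, 1), c(0, 1, 0))
  expect_equal(consensus_cost(ug, Uhard, ug$Y * 1.0, 90), 0)
  # Q = Y makes the anchor term exactly zero for any U
  U <- matrix(runif(5), 5); U <- cbind(U, 1 - U)
  expect_equal(consensus_cost(g, U, Y, 123),
               consensus_cost(g, U, Y, 0.001), tolerance = 1e-12)
  # all-half U with Q = Y: each of the 30 edges contributes 0.5
  expect_equal(consensus_cost(g, matrix(0.5, 5, 2), Y, 90), 15.0)
  expect_error(consensus_cost(g, matrix(0.5, 4, 2), Y, 90), "n x k")
})

test_that("the U update averages group probabilities over memberships", {
  g <- toy_graph()
  U <- update_U(g, g$Y * 1.0)
  expect_equal(U[1, 1], 4 / 6, tolerance = 1e-12)  # s1: 4 of 6 high calls
  expect_equal(U[5, ], c(0, 1))                    # s5: unanimous poor
  expect_equal(unname(rowSums(U)), rep(1, 5))
  ug <- build_graph(matrix(1L, 2, 3))              # unanimous high spectra
  expect_equal(update_U(ug, ug$Y * 1.0)[1, ], c(1, 0))
  # an empty affinity row violates the row-sum identity
  g_bad <- g; g_bad$A[2, ] <- 0L
  expect_error(update_U(g_bad, g$Y * 1.0), "empty row")
})

test_that("the Q update is the confidence-weighted member average", {
  g <- toy_graph()
  U <- update_U(g, g$Y * 1.0)
  Q <- update_Q(g, U, 90)
  expect_equal(Q[1, 1], (4 / 6 + 4 / 6 + 90) / 92, tolerance = 1e-12)
  expect_equal(unname(rowSums(Q)), rep(1, 12))
  # empty group keeps its initial label exactly
  eg <- build_graph(matrix(1L, 3, 2))  # class-2 groups are empty
  Qe <- update_Q(eg, update_U(eg, eg$Y * 1.0), 42)
  expect_equal(Qe[2, ], c(0, 1))
  expect_equal(Qe[4, ], c(0, 1))
  # alpha = 1 with members at one half
  hg <- build_graph(matrix(c(1L, 1L), 2, 1))
  Qh <- update_Q(hg, matrix(0.5, 2, 2), 1)
  expect_equal(Qh[1, 1], 2 / 3, tolerance = 1e-12)
  expect_error(update_Q(g, U, 0), "positive")
})

test_that("the alternating solver reaches the linear fixed point and the global minimizer", {
  g <- toy_graph()
  res <- consensus_solve(g, consensus_params(alpha = 90, epsilon = 1e-10))
  expect_true(res$converged)
  lin <- oracle_linear_fixed_point(g, 90)
  expect_lt(max(abs(res$U - lin$U)), 1e-6)
  expect_lt(max(abs(res$Q - lin$Q)), 1e-6)
  num <- oracle_optim_min(g, 90)
  expect_lt(max(abs(res$U - num$U)), 1e-5)
  expect_lt(abs(consensus_cost(g, res$U, res$Q, 90) - num$value), 1e-6)
})

test_that("perfect agreement converges to zero cost and hard labels", {
  cls <- c(1L, 2L, 2L, 1L)
  ug <- build_graph(matrix(rep(cls, 5), 4, 5))
  res <- consensus_solve(ug, consensus_params(alpha = 90, epsilon = 1e-12))
  expect_true(res$converged)
  expect_equal(res$costs[length(res$costs)], 0, tolerance = 1e-18)
  expect_equal(res$U, cbind(cls == 1L, cls == 2L) * 1.0, ignore_attr = TRUE)
})

test_that("iterates stay row-stochastic and the cost never increases", {
  withr::local_seed(17)
  for (r in 1:30) {
    n <- sample(2:40, 1); m <- sample(2:10, 1)
    g <- build_graph(random_assignments(n, m))
    res <- consensus_solve(g)
    expect_true(res$converged)
    expect_lte(res$iterations, 1000)
    expect_true(all(res$U >= 0 & res$U <= 1))
    expect_equal(unname(rowSums(res$U)), rep(1, n), tolerance = 1e-12)
    expect_equal(unname(rowSums(res$Q)), rep(1, 2 * m), tolerance = 1e-12)
    expect_true(all(diff(res$costs) <= 1e-9))
  }
})

test_that("large alpha pins the groups to their initial labels", {
  withr::local_seed(23)
  g <- build_graph(random_assignments(20, 6))
  res <- consensus_solve(g, consensus_params(alpha = 1e8, epsilon = 1e-12))
  expect_lt(max(abs(res$Q - g$Y)), 1e-5)
  expect_lt(max(abs(res$U - update_U(g, g$Y * 1.0))), 1e-5)
})

test_that("relabelling spectra permutes the solution consistently", {
  withr::local_seed(29)
  asg <- random_assignments(12, 5)
  perm <- sample(12)
  r1 <- consensus_solve(build_graph(asg), consensus_params(epsilon = 1e-10))
  r2 <- consensus_solve(build_graph(asg[perm, ]),
                        consensus_params(epsilon = 1e-10))
  expect_equal(r2$U, r1$U[perm, ], tolerance = 1e-8)
})

test_that("hitting the iteration cap flags non-convergence without error", {
  g <- toy_graph()
  res <- consensus_solve(g, consensus_params(epsilon = 1e-15, max_iter = 2))
  expect_false(res$converged)
  expect_equal(res$iterations, 2)
})

test_that("quality calls threshold probabilities with the >= convention", {
  calls <- classify_quality(c(a = 0.9, b = 0.5, c = 0.49), threshold = 0.5)
  expect_equal(as.character(calls$call), c("high", "high", "poor"))
  expect_equal(calls$id, c("a", "b", "c"))
  expect_equal(calls$p_poor, c(0.1, 0.5, 0.51))
  expect_true(all(classify_quality(runif(5), 0)$call == "high"))
  expect_true(all(classify_quality(runif(5), 1.01)$call == "poor"))
})
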