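# Independent brute-force oracles: naive double loops / direct solves,
# deliberately sharing no code with the package implementation.

# complementary pairs against target S: pair count and per-peak participation
oracle_sum_pairs <- function(s, constants) {
  mz <- s$peaks$mz
  z <- s$precursor_charge
  M <- s$precursor_mz * z - z * constants$proton
  S <- switch(constants$pair_sum_convention,
              uncharged = M, protonated = M + constants$proton,
              by = M + 2 * constants$proton)
  n <- length(mz)
  count <- 0L
  part <- logical(n)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(mz[i] + mz[j] - S) <= constants$tolerance) {
      count <- count + 1L
      part[i] <- part[j] <- TRUE
    }
  }
  list(count = count, participates = part)
}

oracle_f1 <- function(s, constants) {
  p <- oracle_sum_pairs(s, constants)$participates
  normi <- s$peaks$intensity / sum(s$peaks$intensity)
  sum(normi[p])
}

oracle_f6 <- function(s, constants) oracle_sum_pairs(s, constants)$count

# pairs whose difference is within tol of any target (counted once per pair)
oracle_diff_count <- function(s, targets, tol) {
  mz <- s$peaks$mz
  n <- length(mz)
  count <- 0L
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (any(abs(abs(mz[j] - mz[i]) - targets) <= tol)) count <- count + 1L
  }
  count
}

oracle_f5 <- function(s, constants) {
  mz <- s$peaks$mz
  normi <- s$peaks$intensity / sum(s$peaks$intensity)
  n <- length(mz)
  total <- 0
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (any(abs(abs(mz[j] - mz[i]) - constants$residue_masses) <=
            constants$tolerance))
      total <- total + normi[i] + normi[j]
  }
  total
}

# direct solve of the linear fixed-point system obtained by substituting the
# U-update into the Q-update
oracle_linear_fixed_point <- function(graph, alpha) {
  A <- graph$A * 1.0
  Y <- graph$Y * 1.0
  m <- graph$m
  Dinv <- diag(1 / (alpha + colSums(A)))
  lhs <- diag(graph$n) - (A %*% Dinv %*% t(A)) / m
  U <- sapply(1:graph$k, function(z)
    solve(lhs, (alpha / m) * A %*% Dinv %*% Y[, z]))
  Q <- Dinv %*% (t(A) %*% U + alpha * Y)
  list(U = U, Q = Q)
}

# generic numerical constrained minimizer of the consensus cost (k = 2:
# parametrized by the class-1 probabilities, box-constrained to [0, 1])
oracle_optim_min <- function(graph, alpha) {
  A <- graph$A * 1.0
  Y <- graph$Y * 1.0
  n <- graph$n; v <- graph$v
  costfun <- function(par) {
    u1 <- par[1:n]; q1 <- par[n + (1:v)]
    U <- cbind(u1, 1 - u1); Q <- cbind(q1, 1 - q1)
    tot <- 0
    for (z in 1:2) for (i in 1:n) for (j in 1:v)
      tot <- tot + A[i, j] * (U[i, z] - Q[j, z])^2
    tot + alpha * sum((Q - Y)^2)
  }
  fit <- optim(rep(0.5, n + v), costfun, method = "L-BFGS-B",
               lower = 0, upper = 1,
               control = list(maxit = 500, factr = 1e4))
  list(U = cbind(fit$par[1:n], 1 - fit$par[1:n]),
       Q = cbind(fit$par[n + (1:v)], 1 - fit$par[n + (1:v)]),
       value = fit$value)
}
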