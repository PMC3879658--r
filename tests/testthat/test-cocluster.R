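test_that("log likelihood matches closed forms and the naive double-loop oracle", {
  set.seed(1)
  # uniform memberships: (PQ^T)_ij = c/(mn)
  m <- 5; n <- 7; cc <- 2
  A <- matrix(rpois(m * n, 4), m, n)
  P <- matrix(1 / m, m, cc); Q <- matrix(1 / n, n, cc)
  expect_equal(log_likelihood(A, P, Q), 2 * sum(A) * log(cc / (m * n)),
               tolerance = 1e-12)
  expect_equal(log_likelihood(matrix(0, m, n), P, Q), 0)
  for (rep in 1:20) {
    A <- matrix(rexp(12), 3, 4)
    pq <- random_pq(3, 4, 2)
    expect_equal(log_likelihood(A, pq$P, pq$Q), naive_loglik(A, pq$P, pq$Q),
                 tolerance = 1e-10)
  }
  # support mismatch is an explicit -Inf, not an error
  P0 <- rbind(c(1, 0), c(0, 1)); Q0 <- rbind(c(1, 0), c(0, 1))
  A0 <- rbind(c(0, 5), c(1, 0))
  expect_identical(log_likelihood(A0, P0, Q0), -Inf)
})

test_that("em_step matches the explicit-responsibility oracle and fixes block-diagonal optima", {
  set.seed(2)
  for (rep in 1:10) {
    A <- matrix(rexp(4) + 0.1, 2, 2)
    pq <- random_pq(2, 2, 2)
    st <- em_step(A, pq$P, pq$Q)
    or <- explicit_em_oracle(A, pq$P, pq$Q)
    expect_equal(st$P, or$P, tolerance = 1e-12)
    expect_equal(st$Q, or$Q, tolerance = 1e-12)
  }
  # exact block-diagonal matrix with matching hard memberships is a fixed point
  A <- rbind(c(2, 2, 0, 0), c(2, 2, 0, 0), c(0, 0, 3, 3))
  P <- rbind(c(0.5, 0), c(0.5, 0), c(0, 1))
  Q <- rbind(c(0.5, 0), c(0.5, 0), c(0, 0.5), c(0, 0.5))
  st <- em_step(A, P, Q)
  expect_equal(st$P, P, tolerance = 1e-12)
  expect_equal(st$Q, Q, tolerance = 1e-12)
})

test_that("the EM step never decreases the likelihood and keeps columns stochastic", {
  set.seed(3)
  for (rep in 1:100) {
    m <- sample(2:6, 1); n <- sample(2:6, 1); cc <- sample(1:3, 1)
    A <- matrix(rexp(m * n) * rbinom(m * n, 1, 0.8), m, n)
    if (all(A == 0)) A[1, 1] <- 1
    pq <- random_pq(m, n, cc)
    st <- em_step(A, pq$P, pq$Q)
    expect_gte(log_likelihood(A, st$P, st$Q) - log_likelihood(A, pq$P, pq$Q), -1e-9)
    expect_lt(max(abs(colSums(st$P) - 1)), 1e-10)
    expect_lt(max(abs(colSums(st$Q) - 1)), 1e-10)
  }
})

test_that("the leading factor 2 in the printed updates cancels under normalization", {
  set.seed(4)
  A <- matrix(rexp(20), 4, 5)
  pq <- random_pq(4, 5, 3)
  st <- em_step(A, pq$P, pq$Q)
  # update with the explicit 2x factor, then normalize
  R <- tcrossprod(pq$P, pq$Q)
  ratio <- A / R
  P2 <- 2 * pq$P * (ratio %*% pq$Q)
  Q2 <- 2 * pq$Q * (t(ratio) %*% pq$P)
  expect_equal(st$P, sweep(P2, 2, colSums(P2), "/"), tolerance = 1e-14)
  expect_equal(st$Q, sweep(Q2, 2, colSums(Q2), "/"), tolerance = 1e-14)
})

test_that("c = 1 reproduces the analytic maximizer (normalized margins)", {
  set.seed(5)
  A <- matrix(runif(35), 5, 7)
  fit <- cocluster(A, 1, seed = 9, n_restarts = 2)
  expect_equal(fit$P[, 1], rowSums(A) / sum(A), tolerance = 1e-8)
  expect_equal(fit$Q[, 1], colSums(A) / sum(A), tolerance = 1e-8)
})

test_that("fitting recovers planted blocks, is seeded, and is scale invariant", {
  A <- matrix(0, 6, 8)
  A[1:3, 1:4] <- 1
  A[4:6, 5:8] <- 1.5
  fit <- cocluster(A, 2, seed = 3)
  asg <- hard_assignments(fit)
  expect_equal(length(unique(asg$rows$cluster[1:3])), 1)
  expect_equal(length(unique(asg$rows$cluster[4:6])), 1)
  expect_false(asg$rows$cluster[1] == asg$rows$cluster[4])
  expect_equal(length(unique(asg$columns$cluster[1:4])), 1)
  expect_false(asg$columns$cluster[1] == asg$columns$cluster[5])
  # seeded determinism
  fit2 <- cocluster(A, 2, seed = 3)
  expect_identical(fit$P, fit2$P)
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$loglik_trace, fit2$loglik_trace)
  # the multinomial optimizer depends only on A's normalized pattern
  fit3 <- cocluster(2 * A, 2, seed = 3)
  expect_equal(fit$P, fit3$P, tolerance = 1e-12)
  expect_equal(fit$Q, fit3$Q, tolerance = 1e-12)
  # monotone trace
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("traces are non-decreasing across many random fits", {
  set.seed(6)
  for (rep in 1:20) {
    m <- sample(4:7, 1); n <- sample(4:8, 1)
    A <- matrix(rexp(m * n), m, n)
    fit <- cocluster(A, sample(2:3, 1), seed = rep, n_restarts = 2, max_iter = 60)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik)))
  }
})

test_that("the block factorization HH~ reproduces the bipartite adjacency pattern", {
  set.seed(7)
  pq <- random_pq(4, 6, 2)
  P <- pq$P; Q <- pq$Q
  m <- nrow(P); n <- nrow(Q); cc <- ncol(P)
  H <- rbind(cbind(P, matrix(0, m, cc)), cbind(matrix(0, n, cc), Q))
  Ht <- rbind(cbind(matrix(0, cc, m), t(Q)), cbind(t(P), matrix(0, cc, n)))
  W <- H %*% Ht
  expect_equal(W[1:m, 1:m], matrix(0, m, m))
  expect_equal(W[(m + 1):(m + n), (m + 1):(m + n)], matrix(0, n, n))
  expect_equal(W[1:m, (m + 1):(m + n)], tcrossprod(P, Q))
  expect_equal(W[(m + 1):(m + n), 1:m], t(tcrossprod(P, Q)))
})

test_that("degenerate inputs are handled explicitly", {
  A <- matrix(c(1, 0, 2, 0, 0, 0), 2, 3)  # row 2 and column 3 are all zero
  expect_warning(fit <- cocluster(A, 1, seed = 1, n_restarts = 1), "all-zero")
  expect_equal(fit$dropped_cols, 3L)
  expect_equal(fit$dropped_rows, 2L)
  expect_equal(fit$Q[3, 1], 0)  # re-embedded as zero membership
  expect_equal(fit$P[2, 1], 0)
  expect_error(cocluster(matrix(0, 2, 2), 1), "entirely zero")
  expect_error(cocluster(matrix(1, 2, 2), 0), "positive")
})

test_that("hard assignments take the argmax and log exact ties toward low indices", {
  model <- structure(list(
    P = rbind(c(0.9, 0.1), c(0.5, 0.5)),
    Q = rbind(c(0.2, 0.8), c(0.6, 0.4)),
    c = 2L, row_ids = c("r1", "r2"), col_ids = c("c1", "c2"),
    gene_ids = NULL), class = "cocluster_model")
  suppressMessages(asg <- hard_assignments(model))
  expect_equal(asg$rows$cluster, c(1L, 1L))  # tie at row 2 -> cluster 1
  expect_equal(asg$ties$rows, 2L)
  expect_equal(asg$columns$cluster, c(2L, 1L))
})

test_that("model summaries expose the fit in broom style", {
  set.seed(8)
  A <- matrix(rexp(24), 4, 6)
  fit <- cocluster(A, 2, seed = 2, n_restarts = 2)
  g <- glance(fit)
  expect_equal(g$c, 2L)
  expect_true(g$converged)
  td <- tidy(fit)
  expect_equal(nrow(td), (4 + 6) * 2)
  expect_equal(sum(td$membership[td$side == "gene" & td$cluster == 1]), 1,
               tolerance = 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
})
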