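#' Log likelihood of the bipartite multinomial co-clustering model
#'
#' The nonnegative matrix `A` is viewed as the weighted bipartite graph
#' between genes (rows) and mesh elements (columns); with column-stochastic
#' indicator matrices `P` (m x c) and `Q` (n x c) the model log likelihood of
#' the graph's adjacency matrix is
#' \deqn{L = 2 \sum_{ij} A_{ij} \log (P Q^\top)_{ij}.}
#' Entries with `A_ij = 0` contribute nothing (0 log 0 = 0). If some
#' `A_ij > 0` where `(PQ^T)_ij = 0`, the likelihood is reported as `-Inf`.
#'
#' @param A Nonnegative numeric matrix (m x n).
#' @param P,Q Column-stochastic indicator matrices (m x c, n x c).
#' @return Scalar log likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(A, P, Q) {
  A <- unclass_matrix(A)
  check_pq(A, P, Q)
  R <- tcrossprod(P, Q)
  pos <- A > 0
  if (any(R[pos] == 0)) return(-Inf)
  2 * sum(A[pos] * log(R[pos]))
}

unclass_matrix <- function(A) {
  if (inherits(A, "expression_matrix")) class(A) <- "matrix"
  as.matrix(A)
}

check_pq <- function(A, P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q),
            nrow(P) == nrow(A), nrow(Q) == ncol(A), ncol(P) == ncol(Q))
  if (any(A < 0)) rlang::abort("A must be nonnegative")
  invisible(TRUE)
}

#' One EM step of the co-clustering algorithm
#'
#' E-step responsibilities \eqn{\phi_{ijk} = \hat P_{ik}\hat Q_{jk} /
#' (\hat P \hat Q^\top)_{ij}} are folded into the multiplicative M-step
#' updates
#' \deqn{P_{ik} \leftarrow \sum_j \hat P_{ik}\hat Q_{jk} A_{ij} /
#' (\hat P \hat Q^\top)_{ij}}
#' (and symmetrically for `Q`), after which both matrices are normalized to
#' column sums of one. The update never decreases the log likelihood. Any
#' constant factor in front of the updates (the model's natural constant is
#' 2) cancels in the normalization.
#'
#' @param A Nonnegative matrix.
#' @param P,Q Current column-stochastic indicator matrices.
#' @return List with updated `P` and `Q`.
#' @export
em_step <- function(A, P, Q) {
  A <- unclass_matrix(A)
  check_pq(A, P, Q)
  R <- tcrossprod(P, Q)
  ratio <- matrix(0, nrow(A), ncol(A))
  pos <- A > 0
  ratio[pos] <- A[pos] / pmax(R[pos], .Machine$double.xmin)
  Pn <- P * (ratio %*% Q)
  Qn <- Q * (crossprod(ratio, P))
  csp <- colSums(Pn); csq <- colSums(Qn)
  dead <- which(csp <= 0 | !is.finite(csp) | csq <= 0 | !is.finite(csq))
  csp[csp <= 0 | !is.finite(csp)] <- 1
  csq[csq <= 0 | !is.finite(csq)] <- 1
  out <- list(P = sweep(Pn, 2, csp, "/"), Q = sweep(Qn, 2, csq, "/"))
  if (length(dead)) attr(out, "dead_columns") <- dead
  out
}

normalize_columns <- function(M) {
  cs <- colSums(M)
  cs[cs <= 0 | !is.finite(cs)] <- 1
  sweep(M, 2, cs, "/")
}

#' Fit the co-clustering model by EM
#'
#' Alternates EM steps from seeded Dirichlet initializations until the
#' relative log-likelihood change falls below `tol` (or `max_iter` is hit,
#' which is flagged), keeping the best of `n_restarts` runs by final log
#' likelihood. Rows or columns of `A` that are entirely zero are dropped
#' before fitting and reported; a cluster column whose normalization constant
#' underflows is reinitialized from the Dirichlet prior once and frozen if it
#' dies again.
#'
#' @param A Nonnegative matrix (an `expression_matrix` or plain matrix).
#' @param c Number of co-clusters (>= 1).
#' @param seed Integer seed controlling all restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of random restarts.
#' @return A `cocluster_model`: list with `P`, `Q`, `c`, `loglik_trace` (of
#'   the winning restart; non-decreasing), `loglik`, `converged`, `seed`,
#'   `dropped_rows`, `dropped_cols`, plus the row/column identifiers of `A`.
#' @export
cocluster <- function(A, c, seed = 1, tol = 1e-8, max_iter = 500, n_restarts = 5) {
  gene_ids <- attr(A, "gene_ids")
  A <- unclass_matrix(A)
  if (!is.numeric(c) || c < 1) rlang::abort("c must be a positive integer")
  c <- as.integer(c)
  if (any(A < 0)) rlang::abort("A must be nonnegative")
  if (all(A == 0)) rlang::abort("A is entirely zero; nothing to cluster")
  keep_r <- rowSums(A) > 0
  keep_c <- colSums(A) > 0
  dropped_rows <- which(!keep_r); dropped_cols <- which(!keep_c)
  if (length(dropped_rows) || length(dropped_cols)) {
    rlang::warn(sprintf("dropping %d all-zero row(s) and %d all-zero column(s) before fitting",
                        length(dropped_rows), length(dropped_cols)))
  }
  Af <- A[keep_r, keep_c, drop = FALSE]
  m <- nrow(Af); n <- ncol(Af)
  rng_state <- set_local_seed(as.integer(seed %% 2147483647))
  on.exit(restore_seed(rng_state), add = TRUE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    P <- dirichlet_columns(m, c)
    Q <- dirichlet_columns(n, c)
    trace <- log_likelihood(Af, P, Q)
    converged <- FALSE
    frozen <- rep(FALSE, c)
    for (it in seq_len(max_iter)) {
      st <- em_step(Af, P, Q)
      st <- revive_dead_columns(st, m, n, frozen)
      frozen <- st$frozen
      P <- st$P; Q <- st$Q
      L <- log_likelihood(Af, P, Q)
      trace <- c(trace, L)
      prev <- trace[length(trace) - 1]
      if (is.finite(L) && is.finite(prev) &&
          abs(L - prev) <= tol * max(abs(prev), 1)) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(P = P, Q = Q, loglik = trace[length(trace)],
                   loglik_trace = trace, converged = converged, restart = r)
    }
  }
  # re-embed dropped rows/columns as zero membership
  P <- matrix(0, nrow(A), c); P[keep_r, ] <- best$P
  Q <- matrix(0, ncol(A), c); Q[keep_c, ] <- best$Q
  structure(list(P = P, Q = Q, c = c, loglik = best$loglik,
                 loglik_trace = best$loglik_trace, converged = best$converged,
                 best_restart = best$restart, seed = as.integer(seed),
                 tol = tol, max_iter = max_iter, n_restarts = n_restarts,
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols,
                 row_ids = rownames(A) %||% as.character(seq_len(nrow(A))),
                 gene_ids = gene_ids,
                 col_ids = colnames(A) %||% as.character(seq_len(ncol(A)))),
            class = "cocluster_model")
}

dirichlet_columns <- function(nr, nc) {
  M <- matrix(stats::rgamma(nr * nc, shape = 1), nr, nc)
  normalize_columns(M)
}

# dead-cluster policy: one Dirichlet reinitialization per column, then freeze
revive_dead_columns <- function(st, m, n, frozen) {
  dead <- attr(st, "dead_columns")
  dead <- dead[!frozen[dead]]
  if (length(dead)) {
    rlang::warn(sprintf("reinitializing dead cluster column(s): %s",
                        paste(dead, collapse = ",")))
    for (k in dead) {
      st$P[, k] <- dirichlet_columns(m, 1)
      st$Q[, k] <- dirichlet_columns(n, 1)
      frozen[k] <- TRUE
    }
  }
  st$frozen <- frozen
  st
}

#' @export
print.cocluster_model <- function(x, ...) {
  cat(sprintf("<cocluster_model> c = %d, %d genes x %d elements, logLik %.4f (%s, restart %d)\n",
              x$c, nrow(x$P), nrow(x$Q), x$loglik,
              if (x$converged) "converged" else "max_iter reached", x$best_restart))
  invisible(x)
}

#' Harden soft co-cluster memberships into labels
#'
#' Row `i` receives `argmax_k P[i, k]`; column `j` receives
#' `argmax_k Q[j, k]`. Exact ties go to the lowest cluster index and are
#' recorded in the `ties` attribute. Soft memberships are retained.
#'
#' @param model A fitted `cocluster_model`.
#' @return A `cocluster_assignment`: list of tibbles `rows` (`row_id`,
#'   `gene_id`, `cluster`) and `columns` (`element`, `cluster`), plus `P`,
#'   `Q`.
#' @export
hard_assignments <- function(model) {
  stopifnot(inherits(model, "cocluster_model"))
  lab <- function(M) max.col(M, ties.method = "first")
  tie_rows <- function(M) {
    which(apply(M, 1, function(r) sum(r == max(r)) > 1L))
  }
  rl <- lab(model$P); cl <- lab(model$Q)
  ties <- list(rows = tie_rows(model$P), columns = tie_rows(model$Q))
  if (length(ties$rows) || length(ties$columns)) {
    rlang::inform(sprintf("argmax ties broken toward lowest cluster index (%d row(s), %d column(s))",
                          length(ties$rows), length(ties$columns)))
  }
  structure(list(
    rows = tibble::tibble(row_id = model$row_ids,
                          gene_id = model$gene_ids %||% model$row_ids,
                          cluster = rl),
    columns = tibble::tibble(element = seq_len(nrow(model$Q)), cluster = cl),
    P = model$P, Q = model$Q, c = model$c, ties = ties),
    class = "cocluster_assignment")
}

#' @export
print.cocluster_assignment <- function(x, ...) {
  cat(sprintf("<cocluster_assignment> %d rows, %d columns into %d co-clusters\n",
              nrow(x$rows), nrow(x$columns), x$c))
  invisible(x)
}

#' Per-entity memberships of a fitted co-cluster model
#'
#' @param x A `cocluster_model`.
#' @param ... Unused.
#' @return A long tibble: `side` ("gene" or "element"), `id`, `cluster`,
#'   `membership` (the indicator-matrix entry).
#' @method tidy cocluster_model
#' @export
tidy.cocluster_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(side = "gene",
                   id = rep(x$row_ids, times = x$c),
                   cluster = rep(seq_len(x$c), each = nrow(x$P)),
                   membership = as.numeric(x$P)),
    tibble::tibble(side = "element",
                   id = rep(x$col_ids, times = x$c),
                   cluster = rep(seq_len(x$c), each = nrow(x$Q)),
                   membership = as.numeric(x$Q)))
}

#' One-row fit summary of a co-cluster model
#'
#' @param x A `cocluster_model`.
#' @param ... Unused.
#' @return A one-row tibble: `c`, `loglik`, `n_iter`, `converged`,
#'   `best_restart`, `n_restarts`.
#' @method glance cocluster_model
#' @export
glance.cocluster_model <- function(x, ...) {
  tibble::tibble(c = x$c, loglik = x$loglik,
                 n_iter = length(x$loglik_trace) - 1L,
                 converged = x$converged, best_restart = x$best_restart,
                 n_restarts = x$n_restarts)
}

#' @rdname autoplot.tri_mesh
#' @method autoplot cocluster_model
#' @export
autoplot.cocluster_model <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace) - 1L,
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EM iteration", y = "log likelihood",
                  title = sprintf("Co-clustering EM trace (c = %d)", object$c)) +
    ggplot2::theme_minimal()
}
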