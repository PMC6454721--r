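#' Positive and negative parts of a real matrix
#'
#' `pos_part(X)` is \eqn{(|X| + X)/2} and `neg_part(X)` is
#' \eqn{(|X| - X)/2}; both are elementwise nonnegative and
#' `pos_part(X) - neg_part(X)` reconstructs `X`. These operators split the
#' mixed-sign terms of the multiplicative update into numerator and
#' denominator contributions.
#'
#' @param X A numeric matrix.
#' @return A nonnegative matrix of the same shape.
#' @export
pos_part <- function(X) (abs(X) + X) / 2

#' @rdname pos_part
#' @export
neg_part <- function(X) (abs(X) - X) / 2

#' BRSNMF objective value
#'
#' Evaluates
#' \deqn{\|A - WH^T\|_F^2 + \alpha\,tr(H \mathbf{1} H^T)
#'   - \beta\,tr(H^T(\sigma I - \eta(A^- + L^+))H),}
#' where \eqn{\mathbf{1}} is the k x k all-ones matrix. The first term is the
#' Semi-NMF reconstruction error, the \eqn{\alpha} term penalizes rows of `H`
#' spread over several communities (sparsity), and the \eqn{\beta} term
#' rewards communities that avoid internal degressive edges (`A^-`) and avoid
#' cutting enhancive edges (the Laplacian `L^+`).
#'
#' @param A Symmetric signed adjacency (numeric matrix).
#' @param W m x k real centroid matrix.
#' @param H m x k nonnegative indicator matrix.
#' @param alpha,beta,eta,sigma Regularization weights (all default 1).
#' @param Aminus,Lplus Optional precomputed negative part and positive-part
#'   Laplacian of `A` (recomputed when missing).
#' @return A single number.
#' @export
brsnmf_objective <- function(A, W, H, alpha = 1, beta = 1, eta = 1, sigma = 1,
                             Aminus = NULL, Lplus = NULL) {
  if (nrow(A) != nrow(H) || nrow(A) != nrow(W) || ncol(W) != ncol(H)) {
    stop_invalid("Shape mismatch between A, W and H.")
  }
  if (is.null(Aminus)) Aminus <- neg_part(A)
  if (is.null(Lplus)) {
    Ap <- pos_part(A)
    Lplus <- diag(rowSums(Ap)) - Ap
  }
  R <- A - tcrossprod(W, H)
  rec <- sum(R * R)
  k <- ncol(H)
  rs <- rowSums(H)
  tr_s <- sum(rs * rs) # tr(H 1 H^T) = sum_i (sum_j h_ij)^2
  M <- sigma * H - eta * ((Aminus %*% H) + (Lplus %*% H))
  tr_g <- sum(H * M) # tr(H^T (sigma I - eta (A^- + L^+)) H)
  rec + alpha * tr_s - beta * tr_g
}

#' Least-squares centroid update
#'
#' Solves \eqn{W \leftarrow A H (H^T H)^{-1}}, the exact minimizer of the
#' reconstruction error for fixed `H`. A small ridge
#' (\eqn{\lambda = 10^{-8}\,tr(H^T H)/k}) is added before inversion because
#' multiplicative updates drive entries of `H` to exact zeros, which can make
#' \eqn{H^T H} singular.
#'
#' @inheritParams brsnmf_objective
#' @return The updated m x k matrix `W`.
#' @export
update_centroids <- function(A, H) {
  HtH <- crossprod(H)
  k <- ncol(H)
  lambda <- 1e-8 * sum(diag(HtH)) / k
  inv <- tryCatch(solve(HtH + diag(lambda, k)),
                  error = function(e) NULL)
  if (is.null(inv)) {
    stop_numerical("Indicator matrix H^T H is singular even after ridging.")
  }
  A %*% H %*% inv
}

# One multiplicative H step for BRSNMF. The mixed-sign factors are split at
# the matrix level, as the majorization argument requires: W^T W into
# (W^T W)^+ - (W^T W)^-, and L^+ into its elementwise parts, which are
# exactly pos_part(L^+) = D^+ and neg_part(L^+) = A^+. With
# alpha = beta = 0 the added terms are exact zero matrices so the iterate is
# bit-for-bit the Semi-NMF update.
update_indicators <- function(A, W, H, alpha, beta, eta, sigma,
                              Aminus, Lplus, eps = 1e-12) {
  AtW <- crossprod(A, W)
  WtW <- crossprod(W)
  num <- pos_part(AtW) + H %*% neg_part(WtW) +
    beta * eta * (neg_part(Lplus) %*% H) + beta * sigma * H
  den <- neg_part(AtW) + H %*% pos_part(WtW) +
    alpha * matrix(rowSums(H), nrow(H), ncol(H)) +
    beta * eta * (Aminus %*% H) + beta * eta * (pos_part(Lplus) %*% H)
  Hn <- H * sqrt(num / (den + eps))
  if (any(!is.finite(Hn))) {
    stop_numerical("Multiplicative update produced non-finite entries in H.")
  }
  Hn
}

update_indicators_seminmf <- function(A, W, H, eps = 1e-12) {
  AtW <- crossprod(A, W)
  WtW <- crossprod(W)
  num <- pos_part(AtW) + H %*% neg_part(WtW)
  den <- neg_part(AtW) + H %*% pos_part(WtW)
  Hn <- H * sqrt(num / (den + eps))
  if (any(!is.finite(Hn))) {
    stop_numerical("Multiplicative update produced non-finite entries in H.")
  }
  Hn
}

# seeded initialization shared by brsnmf() and semi_nmf(): k-means on the
# rows of A (indicator + 0.2, the standard Semi-NMF recipe), or uniform
# random; W then comes from the exact centroid update
init_factors <- function(A, k, seed, init = c("kmeans", "random")) {
  init <- match.arg(init)
  m <- nrow(A)
  H <- withr::with_seed(seed, {
    if (init == "kmeans") {
      km <- tryCatch(
        suppressWarnings(kmeans(A, centers = k, nstart = 10, iter.max = 50)),
        error = function(e) NULL
      )
      if (is.null(km)) {
        matrix(runif(m * k), m, k)
      } else {
        ind <- matrix(0, m, k)
        ind[cbind(seq_len(m), km$cluster)] <- 1
        ind + 0.2
      }
    } else {
      matrix(runif(m * k), m, k)
    }
  })
  W <- update_centroids(A, H)
  list(W = W, H = H)
}

#' Balance-regularized semi-nonnegative matrix factorization
#'
#' Factorizes a signed DDI adjacency as \eqn{A \approx W H^T} with real
#' centroids `W` and nonnegative community indicators `H`, minimizing the
#' objective of [brsnmf_objective()] by alternating the exact least-squares
#' centroid update with a multiplicative indicator update. The balance
#' regularizer steers the factorization toward partitions in which
#' communities avoid internal degressive edges and between-community
#' enhancive edges, the structure predicted by weak balance theory; the
#' sparsity term keeps each drug committed to few communities, which in
#' practice evens out community sizes.
#'
#' With `alpha = beta = 0` the iteration reduces exactly (iterate for
#' iterate, given the same seed) to [semi_nmf()].
#'
#' @param net A [signed_network()], or a symmetric numeric matrix.
#' @param k Number of communities (latent dimension). Defaults to
#'   `default_latent_dim(net)`, i.e. numerical rank of A divided by 10.
#' @param alpha Sparsity weight (default 1).
#' @param beta Balance weight (default 1).
#' @param eta,sigma Balance-kernel weights (default 1); `sigma` rewards
#'   indicator mass, `eta` scales the graph term. Exposed for completeness
#'   but normally left at 1.
#' @param max_iter Maximum number of alternating updates (default 500).
#' @param tol Relative objective change declaring convergence (default 1e-6).
#' @param seed Integer seed for the initialization.
#' @param eps Denominator floor in the multiplicative update (default 1e-12).
#' @param init `"kmeans"` (default) or `"random"` initialization of `H`.
#' @return A `brsnmf_fit` with elements `W`, `H`, `objective` (per-iteration
#'   trace, starting at the initialization), `converged`, `iterations`,
#'   `labels`, `method`, and `config`.
#' @examples
#' sim <- planted_signed_network(community_sizes = c(15, 15), seed = 7)
#' fit <- brsnmf(sim$network, k = 2, seed = 7)
#' glance(fit)
#' @export
brsnmf <- function(net, k = NULL, alpha = 1, beta = 1, eta = 1, sigma = 1,
                   max_iter = 500, tol = 1e-6, seed = 1, eps = 1e-12,
                   init = c("kmeans", "random")) {
  init <- match.arg(init)
  fit_signed_factorization(net, k, alpha, beta, eta, sigma, max_iter, tol,
                           seed, eps, init, method = "brsnmf")
}

#' Semi-nonnegative matrix factorization baseline
#'
#' Plain Semi-NMF: \eqn{A \approx W H^T} with real `W` and nonnegative `H`,
#' alternating the least-squares centroid update with the unregularized
#' multiplicative indicator update. This is the comparison baseline for
#' [brsnmf()]; it shares the same initialization and stopping rule.
#'
#' @inheritParams brsnmf
#' @return A `brsnmf_fit` (with `method = "seminmf"`).
#' @export
semi_nmf <- function(net, k = NULL, max_iter = 500, tol = 1e-6, seed = 1,
                     eps = 1e-12, init = c("kmeans", "random")) {
  init <- match.arg(init)
  fit_signed_factorization(net, k, alpha = 0, beta = 0, eta = 1, sigma = 1,
                           max_iter, tol, seed, eps, init, method = "seminmf")
}

fit_signed_factorization <- function(net, k, alpha, beta, eta, sigma,
                                     max_iter, tol, seed, eps, init, method) {
  if (inherits(net, "signed_network") || is.data.frame(net)) {
    net <- as_signed_network(net)
    A <- net$adjacency
    labels <- net$labels
  } else if (is.matrix(net)) {
    A <- net
    if (!isTRUE(all.equal(A, t(A)))) {
      stop_invalid("Input matrix must be symmetric.")
    }
    labels <- rownames(A)
    if (is.null(labels)) labels <- paste0("v", seq_len(nrow(A)))
  } else {
    stop_invalid("`net` must be a signed_network, edge table, or matrix.")
  }
  storage.mode(A) <- "double"
  m <- nrow(A)
  if (is.null(k)) k <- default_latent_dim(A)
  if (k < 1 || k > m) stop_invalid("`k` must be between 1 and the number of nodes.")

  seminmf <- method == "seminmf"
  Aminus <- neg_part(A)
  Ap <- pos_part(A)
  Lplus <- diag(rowSums(Ap)) - Ap

  fac <- init_factors(A, k, seed, init)
  W <- fac$W
  H <- fac$H
  obj <- brsnmf_objective(A, W, H, alpha, beta, eta, sigma, Aminus, Lplus)
  trace <- numeric(max_iter + 1)
  trace[1] <- obj
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    W <- update_centroids(A, H)
    H <- if (seminmf) {
      update_indicators_seminmf(A, W, H, eps)
    } else {
      update_indicators(A, W, H, alpha, beta, eta, sigma, Aminus, Lplus, eps)
    }
    new_obj <- brsnmf_objective(A, W, H, alpha, beta, eta, sigma, Aminus, Lplus)
    trace[it + 1] <- new_obj
    if (abs(new_obj - obj) <= tol * max(1, abs(obj))) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  structure(list(
    W = `dimnames<-`(W, list(labels, NULL)),
    H = `dimnames<-`(H, list(labels, NULL)),
    objective = trace[seq_len(it + 1)],
    converged = converged,
    iterations = it,
    labels = labels,
    method = method,
    config = list(k = k, alpha = alpha, beta = beta, eta = eta, sigma = sigma,
                  max_iter = max_iter, tol = tol, seed = seed, eps = eps,
                  init = init)
  ), class = "brsnmf_fit")
}

#' Default latent dimension
#'
#' Numerical rank of the adjacency (singular values above `1e-8` times the
#' largest) divided by 10 and rounded, the setting found best for cold-start
#' prediction; at least 1.
#'
#' @param net A [signed_network()] or numeric matrix.
#' @param tol Relative singular-value tolerance for the numerical rank.
#' @return A positive integer.
#' @export
default_latent_dim <- function(net, tol = 1e-8) {
  A <- if (is.matrix(net)) net else as_signed_network(net)$adjacency
  d <- svd(A, nu = 0, nv = 0)$d
  r <- sum(d > tol * max(d, 1e-300))
  max(1L, as.integer(round(r / 10)))
}

#' Hard community assignment from the indicator matrix
#'
#' Assigns each drug to the community with the largest indicator entry in its
#' row of `H` (ties broken toward the lowest column index). Empty communities
#' are dropped and the indices compacted to `1..k`, with a warning.
#'
#' @param x A `brsnmf_fit` or a nonnegative indicator matrix with row names.
#' @return A tibble with columns `drug` and `community` and attribute `k`.
#' @export
assign_communities <- function(x) {
  H <- if (inherits(x, "brsnmf_fit")) x$H else x
  if (!is.matrix(H) || any(H < 0)) {
    stop_invalid("`x` must be a brsnmf_fit or a nonnegative matrix.")
  }
  zero_rows <- which(rowSums(H) == 0)
  if (length(zero_rows) > 0) {
    stop_numerical(sprintf(
      "Unassignable nodes (all-zero indicator rows): %s.",
      paste(head(zero_rows, 5), collapse = ", ")
    ))
  }
  idx <- max.col(H, ties.method = "first")
  used <- sort(unique(idx))
  if (length(used) < ncol(H)) {
    warn(sprintf("%d of %d communities are empty; indices compacted.",
                 ncol(H) - length(used), ncol(H)))
  }
  z <- match(idx, used)
  labels <- rownames(H)
  if (is.null(labels)) labels <- paste0("v", seq_len(nrow(H)))
  out <- tibble(drug = labels, community = z)
  attr(out, "k") <- length(used)
  out
}
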