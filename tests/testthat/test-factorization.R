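test_that("positive/negative part operators split and reconstruct", {
  X <- matrix(c(-2, 3, 0, 1.5), 2, 2)
  expect_equal(pos_part(X) - neg_part(X), X)
  expect_true(all(pos_part(X) >= 0) && all(neg_part(X) >= 0))
  expect_equal(pos_part(-X), neg_part(X))
  Y <- abs(X)
  expect_equal(pos_part(Y), Y)
  expect_equal(neg_part(Y), matrix(0, 2, 2))
})

test_that("objective equals an independently coded sum of its three terms", {
  withr::with_seed(42, {
    A <- random_signed_matrix(6, seed = 9) + 0
    W <- matrix(rnorm(12), 6, 2)
    H <- matrix(runif(12), 6, 2)
  })
  alpha <- 0.7; beta <- 1.3; eta <- 0.5; sigma <- 2
  # naive term-by-term oracle
  rec <- sum((A - W %*% t(H))^2)
  ones <- matrix(1, 2, 2)
  tr_s <- sum(diag(H %*% ones %*% t(H)))
  Am <- (abs(A) - A) / 2
  Ap <- (abs(A) + A) / 2
  Lp <- diag(colSums(Ap)) - Ap
  K <- sigma * diag(6) - eta * (Am + Lp)
  tr_g <- sum(diag(t(H) %*% K %*% H))
  expect_equal(brsnmf_objective(A, W, H, alpha, beta, eta, sigma),
               rec + alpha * tr_s - beta * tr_g)
  # alpha = beta = 0 with exact factorization -> 0
  Hx <- matrix(runif(12), 6, 2)
  expect_equal(brsnmf_objective(Hx %*% t(Hx), Hx, Hx, 0, 0, 1, 1), 0)
  # H = 0, beta = 0 -> ||A||_F^2
  expect_equal(brsnmf_objective(A, W, matrix(0, 6, 2), 1, 0, 1, 1),
               sum(A^2))
  expect_error(brsnmf_objective(A, W, matrix(0, 5, 2), 1, 0, 1, 1),
               class = "ddi_validation_error")
})

test_that("centroid update solves the least-squares subproblem", {
  A <- random_signed_matrix(8, seed = 5) + 0
  expect_equal(update_centroids(A, diag(8)), A, tolerance = 1e-6)

  ones <- matrix(1, 8, 1)
  expect_equal(update_centroids(A, ones), rowSums(A) / 8,
               tolerance = 1e-6, ignore_attr = TRUE)

  H <- withr::with_seed(2, matrix(runif(16), 8, 2))
  W <- update_centroids(A, H)
  W_oracle <- t(qr.solve(H, t(A))) # normal-equation oracle
  expect_equal(W, W_oracle, tolerance = 1e-6)
})

test_that("the H update preserves zeros, nonnegativity, and descent", {
  A <- random_signed_matrix(5, seed = 13) + 0
  Am <- neg_part(A); Ap <- pos_part(A)
  Lp <- diag(rowSums(Ap)) - Ap
  withr::with_seed(7, {
    W <- matrix(rnorm(10), 5, 2)
    H <- matrix(runif(10), 5, 2)
  })
  H[2, 1] <- 0
  H2 <- ddibalance:::update_indicators(A, W, H, 1, 1, 1, 1, Am, Lp)
  expect_true(all(H2 >= 0))
  expect_identical(H2[2, 1], 0)
  expect_lte(brsnmf_objective(A, W, H2, 1, 1, 1, 1),
             brsnmf_objective(A, W, H, 1, 1, 1, 1) + 1e-10)
  # all-zero H is a fixed point
  expect_equal(ddibalance:::update_indicators(A, W, matrix(0, 5, 2),
                                              1, 1, 1, 1, Am, Lp),
               matrix(0, 5, 2))
  # alpha = beta = 0 reduces bit-for-bit to the Semi-NMF update
  expect_identical(ddibalance:::update_indicators(A, W, H, 0, 0, 1, 1, Am, Lp),
                   ddibalance:::update_indicators_seminmf(A, W, H))
})

test_that("Semi-NMF recovers a planted nonnegative factorization", {
  # orthogonal block indicator: A = H H^T is exactly rank k
  H0 <- matrix(0, 12, 3)
  H0[cbind(1:12, rep(1:3, each = 4))] <- rep(c(1, 2, 1.5, 1), 3)
  A <- H0 %*% t(H0)
  fit <- semi_nmf(A, k = 3, seed = 1, tol = 1e-12, max_iter = 2000)
  rel_err <- norm(A - fit$W %*% t(fit$H), "F") / norm(A, "F")
  expect_lt(rel_err, 1e-6)

  # k = m gives near-exact reconstruction of a signed matrix
  As <- random_signed_matrix(6, seed = 3) + 0
  fit_full <- semi_nmf(As, k = 6, seed = 2, tol = 1e-12, max_iter = 3000)
  expect_lt(norm(As - fit_full$W %*% t(fit_full$H), "F") / norm(As, "F"), 1e-3)

  d <- diff(fit$objective)
  expect_true(all(d <= 1e-9 * pmax(1, abs(fit$objective[-length(fit$objective)]))))
})

test_that("BRSNMF recovers planted blocks and permutes equivariantly", {
  sim <- planted_signed_network(c(20, 20), 0.8, 0.8, 1, 0, 0.05, seed = 3)
  fit <- brsnmf(sim$network, k = 2, seed = 3)
  part <- assign_communities(fit)
  expect_equal(adjusted_rand(part$community, sim$partition$community), 1)

  # permuting the nodes permutes the partition
  A <- sim$network$adjacency
  perm <- withr::with_seed(8, sample(nrow(A)))
  fitp <- brsnmf(signed_network(A[perm, perm]), k = 2, seed = 3)
  partp <- assign_communities(fitp)
  expect_equal(adjusted_rand(partp$community, part$community[perm]), 1)
})

test_that("a weakly balanced block is recovered as one community with negative delta_w", {
  sim <- planted_signed_network(c(20, 20, 20), 0.8, 0.8, c(1, 1, -1), 0, 0.05,
                                seed = 5)
  fit <- brsnmf(sim$network, k = 3, seed = 5)
  part <- assign_communities(fit)
  # community containing most weak-block drugs
  weak_drugs <- sim$partition$drug[sim$partition$community == 3]
  weak_comm <- as.integer(names(which.max(
    table(part$community[part$drug %in% weak_drugs])
  )))
  members <- part$drug[part$community == weak_comm]
  expect_gt(mean(weak_drugs %in% members), 0.9)
  rep_ <- balance_report(sim$network, part)
  expect_lt(rep_$communities$delta_w[rep_$communities$community == weak_comm], 0)
})

test_that("community assignment takes the row argmax with deterministic ties", {
  H <- diag(3)
  rownames(H) <- paste0("d", 1:3)
  expect_identical(assign_communities(H)$community, 1:3)

  H2 <- matrix(c(0.2, 0.2, 0.1, 0.3), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  expect_identical(assign_communities(H2)$community, c(1L, 2L))

  # empty community is compacted with a warning
  H3 <- matrix(c(1, 0, 0, 0, 0, 0, 2, 3), 4, 2,
               dimnames = list(paste0("d", 1:4), NULL))
  H3[2, 1] <- 0.5; H3[2, 2] <- 0.1
  H4 <- cbind(H3, 0)
  expect_warning(p <- assign_communities(H4), "empty")
  expect_identical(sort(unique(p$community)), 1:2)

  expect_error(assign_communities(matrix(c(1, 0, 0, 0), 2, 2,
                                         dimnames = list(c("a", "b"), NULL))),
               class = "ddi_numerical_error")
})

test_that("default latent dimension follows rank(A)/10", {
  H0 <- matrix(0, 30, 20)
  H0[cbind(1:30, rep(1:20, length.out = 30))] <- 1
  A <- H0 %*% t(H0)
  diag(A) <- 0 # keep it adjacency-like; rank stays near 20
  r <- sum(svd(A)$d > 1e-8 * max(svd(A)$d))
  expect_identical(default_latent_dim(A), max(1L, as.integer(round(r / 10))))
  expect_identical(default_latent_dim(matrix(0, 3, 3) + 0), 1L)
})
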