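test_that("uncentered PLS matches no-intercept least squares at full rank", {
  withr::with_seed(1, {
    X <- matrix(rnorm(60), 20, 3)
    B0 <- matrix(rnorm(6), 3, 2)
  })
  Y <- X %*% B0
  fit <- ddibalance:::pls_fit(X, Y, ncomp = 3)
  expect_equal(X %*% fit$B, Y, tolerance = 1e-8)
  expect_equal(fit$B, B0, tolerance = 1e-6, ignore_attr = TRUE)

  # regressing a matrix on itself reproduces it exactly
  H <- withr::with_seed(2, matrix(runif(30), 10, 3))
  self <- ddibalance:::pls_fit(H, H, ncomp = 3)
  expect_lt(norm(H %*% self$B - H, "F") / norm(H, "F"), 1e-6)
})

test_that("uncentered PLS agrees with mixOmics on pre-centered data", {
  withr::with_seed(5, {
    X <- scale(matrix(rnorm(200), 40, 5), scale = FALSE)
    Y <- scale(X %*% matrix(rnorm(10), 5, 2) + 0.1 * matrix(rnorm(80), 40, 2),
               scale = FALSE)
  })
  colnames(X) <- paste0("x", 1:5); colnames(Y) <- paste0("y", 1:2)
  for (nc in c(1, 2, 4)) {
    mine <- X %*% ddibalance:::pls_fit(X, Y, ncomp = nc)$B
    oracle_fit <- mixOmics::pls(X, Y, ncomp = nc, scale = FALSE,
                                mode = "regression")
    oracle <- predict(oracle_fit, X)$predict[, , nc]
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-6)
  }
})

test_that("cold-start training and prediction form a linear pipeline", {
  bench <- coldstart_benchmark(seed = 11)
  model <- coldstart_train(bench$network, bench$features, k = 3, seed = 11)
  expect_identical(ncol(model$B), ncol(model$W))

  Fx <- feature_matrix(bench$features)[1:5, , drop = FALSE]
  pred <- predict(model, Fx)
  expect_identical(dim(pred$scores), c(5L, 120L))
  expect_true(all(is.finite(pred$scores)))

  # all-zero feature row scores exactly zero; scaling scales; superposition
  z <- matrix(0, 1, 60, dimnames = list("zero", colnames(Fx)))
  expect_equal(max(abs(predict(model, z)$scores)), 0)
  expect_equal(predict(model, 2 * Fx)$scores, 2 * pred$scores)
  Fy <- feature_matrix(bench$features)[6:10, , drop = FALSE]
  rownames(Fy) <- rownames(Fx)
  expect_equal(predict(model, Fx + Fy)$scores,
               pred$scores + predict(model, Fy)$scores,
               tolerance = 1e-10)

  # permuting drug order of both inputs permutes the model outputs
  perm <- withr::with_seed(4, sample(120))
  net_p <- signed_network(bench$network$adjacency[perm, perm])
  model_p <- coldstart_train(net_p, bench$features[perm, ], k = 3, seed = 11)
  pred_p <- predict(model_p, Fx)
  expect_equal(unname(pred_p$scores[, bench$network$labels]),
               unname(pred$scores[, bench$network$labels]), tolerance = 1e-6)

  expect_error(predict(model, Fx[, 1:10]), class = "ddi_validation_error")
  expect_error(coldstart_train(bench$network, bench$features[1:50, ], k = 3),
               class = "ddi_validation_error")
})

test_that("ranking metrics reproduce the worked toy example and perfect scores", {
  pred <- new_prediction(matrix(c(2.0, -1.5, 0.1, -0.2), 1, 4))
  truth <- matrix(c(1, -1, 0, 0), 1, 4)
  ev <- evaluate_ranking(truth, pred, n_list = c(1, 2))
  expect_equal(ev$topn$top_accuracy[ev$topn$n == 1], 1)
  expect_equal(ev$topn$bottom_accuracy[ev$topn$n == 1], 1)
  expect_equal(ev$summary$auroc, 1)
  expect_equal(ev$summary$mpr, mean(c(0, 1 / 3)))

  # scores equal to the labels: every metric is perfect
  L <- matrix(c(1, 0, -1, 0, 1, -1, 0, 0, 1, -1, 0, 0), 3, 4)
  ev2 <- evaluate_ranking(L, new_prediction(L + 0), n_list = c(2))
  expect_equal(ev2$summary$auroc, 1)
  expect_equal(ev2$summary$aupr, 1)
  expect_equal(ev2$topn$top_accuracy, 1)
  expect_equal(ev2$topn$bottom_accuracy, 1)

  # no positives: AUPR undefined
  z <- matrix(0, 1, 4)
  ev3 <- suppressWarnings(evaluate_ranking(z, new_prediction(z + 0.1)))
  expect_true(is.na(ev3$summary$aupr))
})

test_that("AUROC/AUPR/MPR agree with brute-force oracles (with ties)", {
  for (s in 1:4) {
    withr::with_seed(s, {
      score <- round(runif(40), 1) # rounding forces ties
      pos <- runif(40) < 0.3
    })
    if (!any(pos) || all(pos)) next
    expect_equal(ranking_auroc(score, pos), auroc_bruteforce(score, pos))
    expect_equal(ranking_aupr(score, pos), aupr_bruteforce(score, pos))
    expect_equal(ranking_auroc(-score, pos), 1 - ranking_auroc(score, pos))
    expect_equal(ranking_auroc(score, pos),
                 as.numeric(pROC::auc(pROC::roc(
                   pos, score, quiet = TRUE,
                   levels = c(FALSE, TRUE), direction = "<"
                 ))))
  }
  # frozen reference values (scikit-learn average_precision_score / roc_auc_score)
  y <- c(1, 0, 1, 1, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0) == 1
  s <- c(0.9, 0.8, 0.7, 0.7, 0.6, 0.5, 0.5, 0.5, 0.4, 0.35, 0.3, 0.3,
         0.25, 0.2, 0.2, 0.15, 0.1, 0.1, 0.05, 0.0)
  expect_equal(ranking_aupr(s, y), 0.6361111111111111, tolerance = 1e-12)
  expect_equal(ranking_auroc(s, y), 0.7619047619047619, tolerance = 1e-12)

  withr::with_seed(9, {
    scores <- matrix(rnorm(60), 4, 15)
    labels <- matrix(sample(c(-1, 0, 1), 60, TRUE), 4, 15)
  })
  expect_equal(mean_percentile_rank(scores, labels),
               mpr_bruteforce(scores, labels))
})

test_that("random scores give chance-level AUROC and MPR", {
  aucs <- mprs <- numeric(20)
  for (s in 1:20) {
    withr::with_seed(700 + s, {
      sc <- matrix(rnorm(200), 4, 50)
      lb <- matrix(sample(c(-1, 0, 1), 200, TRUE, prob = c(.2, .6, .2)), 4, 50)
    })
    aucs[s] <- ranking_auroc(abs(as.vector(sc)), abs(as.vector(lb)) == 1)
    mprs[s] <- mean_percentile_rank(sc, lb)
  }
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  expect_equal(mean(mprs), 0.5, tolerance = 0.05)
})

test_that("drug-level cross-validation partitions drugs, never pairs", {
  sim <- planted_signed_network(c(12, 12), 0.9, 0.3, 1, 0, 0, seed = 2)
  feats <- community_linked_features(sim$partition, p = 12, seed = 2)
  cv <- coldstart_cv(sim$network, feats, k = 2, n_folds = 4, seed = 9,
                     n_list = 5, max_iter = 100)
  expect_identical(nrow(cv), 4L)
  expect_identical(sum(cv$n_test), 24L)

  loo <- coldstart_cv(sim$network, feats, k = 2, scheme = "loocv",
                      n_list = 2, max_iter = 50)
  expect_identical(nrow(loo), 24L)
  expect_true(all(loo$n_test == 1L))

  gl <- glance(cv)
  expect_identical(gl$n_folds, 4L)
  expect_true(is.numeric(gl$auroc))
})
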