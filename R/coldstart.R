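#' Convert a feature table to a binary feature matrix
#'
#' Feature tables are tibbles whose first column (`drug`) holds the drug
#' labels and whose remaining columns are binary indicators (for example,
#' one column per drug-binding protein).
#'
#' @param features A data frame (first column drug labels, rest binary) or an
#'   already-formed numeric matrix with row names.
#' @return A numeric 0/1 matrix with drugs as row names.
#' @export
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    F_ <- features
    if (is.null(rownames(F_))) {
      stop_invalid("Feature matrix must carry drug labels as row names.")
    }
  } else if (is.data.frame(features)) {
    if (ncol(features) < 2) {
      stop_invalid("Feature table needs a drug column plus feature columns.")
    }
    labs <- as.character(features[[1]])
    F_ <- as.matrix(features[, -1, drop = FALSE])
    storage.mode(F_) <- "double"
    rownames(F_) <- labs
  } else {
    stop_invalid("`features` must be a data frame or matrix.")
  }
  if (anyDuplicated(rownames(F_))) {
    stop_invalid(sprintf(
      "Duplicate drug labels in feature table: %s.",
      paste(head(unique(rownames(F_)[duplicated(rownames(F_))]), 5),
            collapse = ", ")
    ))
  }
  bad <- which(!(F_ %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(F_))
    stop_invalid(sprintf(
      "Feature values must be 0/1; first offender at row %d (%s), column %d (%s).",
      rc[1], rownames(F_)[rc[1]], rc[2], colnames(F_)[rc[2]]
    ))
  }
  F_
}

#' Train a cold-start DDI predictor
#'
#' Fits [brsnmf()] on the signed adjacency of drugs with known interactions,
#' then regresses the latent community indicator `H` on the binary drug
#' features by an uncentered partial least squares regression, `H = F B`.
#' The pair `(W, B)` then scores interactions for drugs never seen in the
#' network from their features alone.
#'
#' @param net A [signed_network()] of the training drugs.
#' @param features Feature table for exactly the training drugs (see
#'   [feature_matrix()]). Labels must match the network's nodes (any order).
#' @param k Latent dimension; defaults to [default_latent_dim()] of the
#'   network (numerical rank / 10).
#' @param ncomp Number of PLS components; defaults to
#'   `min(k, p, m - 1)`.
#' @param ... Further arguments passed to [brsnmf()] (`alpha`, `beta`,
#'   `seed`, ...).
#' @return A `coldstart_model` with elements `W`, `B`, `H`, `fit`,
#'   `labels`, `feature_names`, `k`, `ncomp`.
#' @examples
#' bench <- coldstart_benchmark(seed = 3)
#' model <- coldstart_train(bench$network, bench$features, k = 3, seed = 3)
#' @export
coldstart_train <- function(net, features, k = NULL, ncomp = NULL, ...) {
  net <- as_signed_network(net)
  F_ <- feature_matrix(features)
  if (!setequal(rownames(F_), net$labels)) {
    stop_invalid("Feature drug labels do not match the network's drugs.")
  }
  F_ <- F_[net$labels, , drop = FALSE]
  if (is.null(k)) k <- default_latent_dim(net)
  fit <- brsnmf(net, k = k, ...)
  m <- nrow(F_)
  p <- ncol(F_)
  if (is.null(ncomp)) ncomp <- min(k, p, m - 1)
  pls <- pls_fit(F_, fit$H, ncomp)
  structure(list(
    W = fit$W, B = pls$B, H = fit$H, fit = fit,
    labels = net$labels, feature_names = colnames(F_),
    k = k, ncomp = pls$ncomp
  ), class = "coldstart_model")
}

#' @export
print.coldstart_model <- function(x, ...) {
  cat(sprintf(
    "<coldstart_model> %d training drugs, %d features, k = %d, %d PLS components\n",
    length(x$labels), length(x$feature_names), x$k, x$ncomp
  ))
  invisible(x)
}

#' @rdname coldstart_train
#' @param x A `coldstart_model`.
#' @export
glance.coldstart_model <- function(x, ...) {
  tibble(
    n_train = length(x$labels), n_features = length(x$feature_names),
    k = x$k, ncomp = x$ncomp,
    brsnmf_objective = tail(x$fit$objective, 1),
    converged = x$fit$converged
  )
}

#' Score interactions for new drugs
#'
#' Maps query features into the latent space, \eqn{H_x = F_x B}, and scores
#' every (query, training) pair by \eqn{A_x = H_x W^T}. Strongly positive
#' scores suggest enhancive interactions, strongly negative scores degressive
#' interactions, and near-zero scores non-interaction; no fixed cutoffs are
#' applied anywhere — downstream evaluation is rank-based.
#'
#' @param object A `coldstart_model`.
#' @param features Feature table for the query drugs; feature columns must
#'   match the training features by name.
#' @param ... Unused.
#' @return A `ddi_prediction` with the n x m score matrix (`scores`), the
#'   latent rows (`H_x`), and the model labels. `tidy()` returns the ranked
#'   pair list.
#' @export
predict.coldstart_model <- function(object, features, ...) {
  Fx <- feature_matrix_numeric(features)
  if (!identical(colnames(Fx), object$feature_names)) {
    if (setequal(colnames(Fx), object$feature_names)) {
      Fx <- Fx[, object$feature_names, drop = FALSE]
    } else {
      stop_invalid("Query feature columns do not match the training features.")
    }
  }
  Hx <- Fx %*% object$B
  scores <- Hx %*% t(object$W)
  colnames(scores) <- object$labels
  structure(list(scores = scores, H_x = Hx,
                 query = rownames(Fx), target = object$labels),
            class = "ddi_prediction")
}

# like feature_matrix() but tolerates non-binary numeric values, so that
# predict() stays a genuinely linear map (superposition-testable)
feature_matrix_numeric <- function(features) {
  if (is.matrix(features)) {
    F_ <- features
    if (is.null(rownames(F_))) {
      stop_invalid("Feature matrix must carry drug labels as row names.")
    }
  } else if (is.data.frame(features)) {
    labs <- as.character(features[[1]])
    F_ <- as.matrix(features[, -1, drop = FALSE])
    storage.mode(F_) <- "double"
    rownames(F_) <- labs
  } else {
    stop_invalid("`features` must be a data frame or matrix.")
  }
  F_
}

#' @export
print.ddi_prediction <- function(x, ...) {
  cat(sprintf("<ddi_prediction> %d query x %d target scores in [%.3g, %.3g]\n",
              nrow(x$scores), ncol(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' @rdname predict.coldstart_model
#' @param x A `ddi_prediction`.
#' @export
tidy.ddi_prediction <- function(x, ...) {
  df <- tibble(
    query = rep(x$query, times = length(x$target)),
    target = rep(x$target, each = length(x$query)),
    score = as.vector(x$scores)
  )
  df <- dplyr::arrange(df, dplyr::desc(.data$score), .data$query, .data$target)
  df$rank <- seq_len(nrow(df))
  df
}

#' Rank-based metrics for signed interaction prediction
#'
#' Evaluates predicted scores against signed truth labels
#' (`+1` enhancive, `-1` degressive, `0` no known interaction) pooled over
#' all (query, target) pairs:
#' \itemize{
#'   \item top-n accuracy: fraction of `+1` labels among the `n` highest
#'     scores (and bottom-n accuracy of `-1` labels among the `n` lowest),
#'     with ties broken deterministically by (query, target) label order;
#'   \item AUROC / AUPR for detecting interactions (`|label| = 1` vs 0) with
#'     `|score|` as the ranking statistic — AUROC is the exact Mann-Whitney
#'     statistic, AUPR the average precision;
#'   \item MPR: mean percentile rank (0 = top of the list) of the true
#'     interactions within each query drug's candidates sorted by decreasing
#'     `|score|`.
#' }
#'
#' @param truth Signed labels: an n x m matrix aligned with the prediction's
#'   query/target order, or a data frame with columns `query`, `target`,
#'   `label`.
#' @param pred A `ddi_prediction` from [predict.coldstart_model()].
#' @param n_list Cutoffs for top-/bottom-n accuracy.
#' @return A `ddi_ranking_eval`: list with `summary` (one-row tibble:
#'   `auroc`, `aupr`, `mpr`, `n_pairs`, `n_interactions`) and `topn`
#'   (tibble with `n`, `top_accuracy`, `bottom_accuracy`).
#' @export
evaluate_ranking <- function(truth, pred, n_list = c(5, 10, 20, 30, 40, 50)) {
  stopifnot(inherits(pred, "ddi_prediction"))
  L <- truth_matrix(truth, pred)
  if (!all(L %in% c(-1, 0, 1))) {
    stop_invalid("Truth labels must be in {-1, 0, +1}.")
  }
  df <- tibble(
    query = rep(pred$query, times = length(pred$target)),
    target = rep(pred$target, each = length(pred$query)),
    score = as.vector(pred$scores),
    label = as.vector(L)
  )
  ord <- order(-df$score, df$query, df$target)
  lab_sorted <- df$label[ord]
  n_pairs <- nrow(df)
  topn <- dplyr::bind_rows(lapply(n_list, function(n) {
    n_eff <- min(n, n_pairs)
    tibble(
      n = n,
      top_accuracy = mean(lab_sorted[seq_len(n_eff)] == 1),
      bottom_accuracy = mean(rev(lab_sorted)[seq_len(n_eff)] == -1)
    )
  }))
  interacting <- abs(df$label) == 1
  auroc <- ranking_auroc(abs(df$score), interacting)
  aupr <- ranking_aupr(abs(df$score), interacting)
  mpr <- mean_percentile_rank(pred$scores, L)
  structure(list(
    summary = tibble(auroc = auroc, aupr = aupr, mpr = mpr,
                     n_pairs = n_pairs, n_interactions = sum(interacting)),
    topn = topn
  ), class = "ddi_ranking_eval")
}

#' @export
print.ddi_ranking_eval <- function(x, ...) {
  cat("<ddi_ranking_eval>\n")
  print(x$summary, ...)
  print(x$topn, ...)
  invisible(x)
}

#' @rdname evaluate_ranking
#' @param x A `ddi_ranking_eval`.
#' @param ... Unused.
#' @export
tidy.ddi_ranking_eval <- function(x, ...) x$topn

#' @rdname evaluate_ranking
#' @export
glance.ddi_ranking_eval <- function(x, ...) x$summary

truth_matrix <- function(truth, pred) {
  if (is.matrix(truth)) {
    if (!all(dim(truth) == dim(pred$scores))) {
      stop_invalid("Truth matrix dimensions do not match the prediction.")
    }
    return(truth)
  }
  if (is.data.frame(truth)) {
    need <- c("query", "target", "label")
    if (!all(need %in% names(truth))) {
      stop_invalid("Truth table needs columns query, target, label.")
    }
    L <- matrix(0, length(pred$query), length(pred$target),
                dimnames = list(pred$query, pred$target))
    qi <- match(as.character(truth$query), pred$query)
    ti <- match(as.character(truth$target), pred$target)
    keep <- !is.na(qi) & !is.na(ti)
    L[cbind(qi[keep], ti[keep])] <- truth$label[keep]
    return(L)
  }
  stop_invalid("`truth` must be a matrix or data frame.")
}

#' AUROC by the Mann-Whitney rank statistic
#'
#' @param score Numeric ranking statistic (higher = more likely positive).
#' @param positive Logical vector of true class memberships.
#' @return AUROC in `[0, 1]`; `NA` if either class is empty.
#' @export
ranking_auroc <- function(score, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: the mean, over true positives taken in decreasing score
#' order, of the precision at each positive's rank. Ties are handled by
#' averaging precision over the tied block.
#'
#' @inheritParams ranking_auroc
#' @return AUPR in `[0, 1]`; `NA` (with a warning) if there are no positives.
#' @export
ranking_aupr <- function(score, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive)
  if (n_pos == 0) {
    warn("AUPR undefined: no positive labels.")
    return(NA_real_)
  }
  ord <- order(-score)
  s <- score[ord]
  y <- positive[ord]
  # collapse tied-score blocks: precision/recall only change between blocks
  blocks <- cumsum(!duplicated(s))
  tp_in_block <- tapply(y, blocks, sum)
  n_in_block <- tapply(y, blocks, length)
  tp_cum <- cumsum(tp_in_block)
  n_cum <- cumsum(n_in_block)
  prec <- tp_cum / n_cum
  rec <- tp_cum / n_pos
  prev_rec <- c(0, head(rec, -1))
  sum(prec * (rec - prev_rec))
}

#' Mean percentile ranking of true interactions
#'
#' For each query drug, candidates are sorted by decreasing `|score|`; each
#' true interaction's percentile is `(rank - 1) / (m - 1)` (0 = ranked
#' first). The mean over all true interactions is returned; smaller is
#' better, 0.5 is the chance level.
#'
#' @param scores n x m score matrix.
#' @param labels n x m signed truth matrix.
#' @return MPR in `[0, 1]`; `NA` if there are no true interactions.
#' @export
mean_percentile_rank <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  m <- ncol(scores)
  if (m < 2) return(NA_real_)
  pct <- numeric(0)
  for (i in seq_len(nrow(scores))) {
    hits <- which(abs(labels[i, ]) == 1)
    if (length(hits) == 0) next
    r <- rank(-abs(scores[i, ]), ties.method = "average")
    pct <- c(pct, (r[hits] - 1) / (m - 1))
  }
  if (length(pct) == 0) return(NA_real_)
  mean(pct)
}

#' Drug-level cross-validation of the cold-start pipeline
#'
#' Splits drugs (never pairs) into folds. Each round removes the fold's
#' drugs and every interaction touching them, trains
#' [coldstart_train()] on the remaining induced network, predicts the removed
#' drugs' interaction rows from their features alone, and evaluates against
#' the removed interactions with [evaluate_ranking()]. This is the genuine
#' cold-start protocol: held-out drugs are invisible to the factorization.
#'
#' @param net A [signed_network()].
#' @param features Feature table covering all drugs in `net`.
#' @param k Latent dimension passed to [coldstart_train()].
#' @param scheme `"nfold"` (default) or `"loocv"` (one fold per drug).
#' @param n_folds Number of folds for `"nfold"`.
#' @param seed Integer seed for the fold assignment (and the per-fold
#'   factorization seeds derived from it).
#' @param n_list Cutoffs for top-/bottom-n accuracy.
#' @param ... Further arguments passed to [coldstart_train()].
#' @return A `ddi_cv` tibble with one row per fold: `fold`, `n_test`,
#'   `auroc`, `aupr`, `mpr`, and `top_<n>` / `bottom_<n>` accuracy columns.
#'   `glance()` averages the folds.
#' @export
coldstart_cv <- function(net, features, k = NULL, scheme = c("nfold", "loocv"),
                         n_folds = 10, seed = 1, n_list = c(5, 10), ...) {
  scheme <- match.arg(scheme)
  net <- as_signed_network(net)
  F_ <- feature_matrix(features)
  if (!setequal(rownames(F_), net$labels)) {
    stop_invalid("Feature drug labels do not match the network's drugs.")
  }
  F_ <- F_[net$labels, , drop = FALSE]
  m <- length(net$labels)
  if (m < 3) stop_invalid("Cross-validation needs at least 3 drugs.")
  folds <- if (scheme == "loocv") {
    seq_len(m)
  } else {
    withr::with_seed(seed, sample(rep(seq_len(n_folds), length.out = m)))
  }
  A <- net$adjacency
  out <- lapply(sort(unique(folds)), function(f) {
    test_idx <- which(folds == f)
    train_idx <- setdiff(seq_len(m), test_idx)
    if (length(train_idx) < max(3, if (is.null(k)) 1 else k)) {
      stop_invalid(sprintf("Fold %d leaves too few training drugs.", f))
    }
    train_net <- new_signed_network_from_matrix(
      A[train_idx, train_idx, drop = FALSE], net$labels[train_idx]
    )
    # cold-start hygiene: no held-out drug may appear in the training network
    stopifnot(length(intersect(train_net$labels, net$labels[test_idx])) == 0)
    model <- coldstart_train(train_net, F_[train_idx, , drop = FALSE],
                             k = k, seed = seed + f, ...)
    pred <- predict(model, F_[test_idx, , drop = FALSE])
    truth <- A[test_idx, train_idx, drop = FALSE]
    storage.mode(truth) <- "double"
    ev <- evaluate_ranking(truth, pred, n_list = n_list)
    wide <- ev$topn
    acc <- c(setNames(wide$top_accuracy, paste0("top_", wide$n)),
             setNames(wide$bottom_accuracy, paste0("bottom_", wide$n)))
    dplyr::bind_cols(
      tibble(fold = f, n_test = length(test_idx)),
      ev$summary[, c("auroc", "aupr", "mpr")],
      as_tibble(as.list(acc))
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("ddi_cv", class(res))
  attr(res, "scheme") <- scheme
  attr(res, "seed") <- seed
  res
}

#' @rdname coldstart_cv
#' @param x A `ddi_cv` result.
#' @export
glance.ddi_cv <- function(x, ...) {
  num <- dplyr::select(as_tibble(x), -dplyr::all_of(c("fold", "n_test")))
  dplyr::bind_cols(
    tibble(n_folds = nrow(x)),
    dplyr::summarise(num, dplyr::across(dplyr::everything(),
                                        ~ mean(.x, na.rm = TRUE)))
  )
}

#' @rdname coldstart_cv
#' @param object A `ddi_cv` result.
#' @export
autoplot.ddi_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), dplyr::all_of(c("fold", "auroc", "aupr", "mpr"))),
    -dplyr::all_of("fold"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}
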