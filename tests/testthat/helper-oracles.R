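# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (plain loops, no shared helpers).

random_signed_matrix <- function(m, seed, prob = c(0.2, 0.5, 0.3)) {
  withr::with_seed(seed, {
    A <- matrix(sample(c(-1L, 0L, 1L), m * m, replace = TRUE, prob = prob), m, m)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0L
    A
  })
}

census_bruteforce <- function(A) {
  m <- nrow(A)
  counts <- c(PPP = 0, NNP = 0, NNN = 0, PPN = 0)
  if (m < 3) return(counts)
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (l in (j + 1):m) {
    s <- c(A[i, j], A[i, l], A[j, l])
    if (any(s == 0)) next
    nn <- sum(s < 0)
    counts[c("PPP", "PPN", "NNP", "NNN")[nn + 1]] <-
      counts[c("PPP", "PPN", "NNP", "NNN")[nn + 1]] + 1
  }
  counts
}

cbi_bruteforce <- function(A, z) {
  ks <- unique(z)
  num <- 0; den <- 0
  for (c in ks) {
    members <- which(z == c)
    nc <- length(members)
    tri <- 0; ppn <- 0
    if (nc >= 3) {
      cc <- census_bruteforce(A[members, members, drop = FALSE])
      tri <- sum(cc); ppn <- cc["PPN"]
    }
    bal <- if (tri > 0) 1 - ppn / tri else 1
    num <- num + nc * bal
    den <- den + nc
  }
  as.numeric(num / den)
}

auroc_bruteforce <- function(score, positive) {
  ps <- score[positive]
  ns <- score[!positive]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

aupr_bruteforce <- function(score, positive) {
  # walk thresholds from high to low, accumulating precision * recall-step
  th <- sort(unique(score), decreasing = TRUE)
  npos <- sum(positive)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    sel <- score >= t
    prec <- sum(positive[sel]) / sum(sel)
    rec <- sum(positive[sel]) / npos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

mpr_bruteforce <- function(scores, labels) {
  m <- ncol(scores)
  pct <- c()
  for (i in seq_len(nrow(scores))) {
    r <- rank(-abs(scores[i, ]), ties.method = "average")
    for (j in seq_len(m)) {
      if (abs(labels[i, j]) == 1) pct <- c(pct, (r[j] - 1) / (m - 1))
    }
  }
  mean(pct)
}

new_prediction <- function(scores, query = NULL, target = NULL) {
  if (is.null(query)) query <- paste0("q", seq_len(nrow(scores)))
  if (is.null(target)) target <- paste0("t", seq_len(ncol(scores)))
  structure(list(scores = scores, H_x = NULL, query = query, target = target),
            class = "ddi_prediction")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
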