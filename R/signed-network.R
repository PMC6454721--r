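#' Signed drug-drug interaction networks
#'
#' A `signed_network` stores an undirected network whose edges carry a
#' pharmacological polarity: `+1` for enhancive interactions (one drug
#' increases the effect of the other) and `-1` for degressive interactions.
#' Internally it holds an ordered vector of node labels and a symmetric
#' integer adjacency matrix with entries in `{-1, 0, +1}` and a zero
#' diagonal.
#'
#' @param edges A data frame with three columns (drug a, drug b, sign), a
#'   symmetric numeric matrix with entries in `{-1, 0, +1}`, or an existing
#'   `signed_network`. Column names are not interpreted; order is.
#' @param labels Optional character vector fixing the node order. Defaults to
#'   first appearance in the edge list (or the matrix dimnames).
#'
#' @details
#' Edge lists are validated strictly: self-loops are rejected, signs must be
#' `+1` or `-1`, and duplicate pairs are collapsed when their signs agree but
#' rejected (naming the offending pair) when they conflict.
#'
#' @return A `signed_network` object.
#' @examples
#' net <- signed_network(tibble::tibble(
#'   a = c("d1", "d2", "d1"), b = c("d2", "d3", "d3"), sign = c(1, -1, -1)
#' ))
#' net
#' @export
signed_network <- function(edges, labels = NULL) {
  if (inherits(edges, "signed_network")) {
    return(edges)
  }
  if (is.matrix(edges)) {
    return(new_signed_network_from_matrix(edges, labels))
  }
  if (!is.data.frame(edges)) {
    stop_invalid("`edges` must be a data frame, matrix, or signed_network.")
  }
  if (ncol(edges) < 3) {
    stop_invalid("Edge table needs three columns: drug a, drug b, sign.")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  s <- suppressWarnings(as.numeric(as.character(edges[[3]])))
  bad <- which(is.na(s) | !(s %in% c(-1, 1)))
  if (length(bad) > 0) {
    stop_invalid(sprintf(
      "Edge sign must be +1 or -1; offending rows: %s.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  loops <- which(a == b)
  if (length(loops) > 0) {
    stop_invalid(sprintf(
      "Self-loops are not allowed; offending rows: %s (%s).",
      paste(head(loops, 5), collapse = ", "),
      paste(head(a[loops], 5), collapse = ", ")
    ))
  }
  if (is.null(labels)) {
    labels <- unique(as.vector(rbind(a, b)))
  } else {
    labels <- as.character(labels)
    missing <- setdiff(c(a, b), labels)
    if (length(missing) > 0) {
      stop_invalid(sprintf(
        "Edge list mentions nodes absent from `labels`: %s.",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
  }
  m <- length(labels)
  ia <- match(a, labels)
  ib <- match(b, labels)
  # canonical unordered pair key to detect duplicates
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  if (anyDuplicated(key)) {
    ks <- split(s, key)
    conflicting <- names(ks)[vapply(ks, function(x) length(unique(x)) > 1L, logical(1))]
    if (length(conflicting) > 0) {
      ij <- as.integer(unlist(strsplit(conflicting[1], " ")))
      stop_invalid(sprintf(
        "Conflicting duplicate signs for pair (%s, %s).",
        labels[ij[1]], labels[ij[2]]
      ))
    }
    keep <- !duplicated(key)
    ia <- ia[keep]; ib <- ib[keep]; s <- s[keep]
  }
  A <- matrix(0L, m, m, dimnames = list(labels, labels))
  A[cbind(ia, ib)] <- as.integer(s)
  A[cbind(ib, ia)] <- as.integer(s)
  structure(list(labels = labels, adjacency = A), class = "signed_network")
}

new_signed_network_from_matrix <- function(A, labels = NULL) {
  if (nrow(A) != ncol(A)) {
    stop_invalid("Adjacency matrix must be square.")
  }
  if (is.null(labels)) {
    labels <- rownames(A)
    if (is.null(labels)) labels <- paste0("v", seq_len(nrow(A)))
  }
  if (length(labels) != nrow(A)) {
    stop_invalid("`labels` length must match the matrix dimension.")
  }
  if (!all(A %in% c(-1, 0, 1))) {
    stop_invalid("Adjacency entries must be in {-1, 0, +1}.")
  }
  if (!isTRUE(all(A == t(A)))) {
    stop_invalid("Adjacency matrix must be symmetric.")
  }
  if (any(diag(A) != 0)) {
    stop_invalid("Adjacency diagonal must be zero (no self-loops).")
  }
  storage.mode(A) <- "integer"
  dimnames(A) <- list(labels, labels)
  structure(list(labels = as.character(labels), adjacency = A),
            class = "signed_network")
}

#' @rdname signed_network
#' @param x Object to coerce.
#' @export
as_signed_network <- function(x, labels = NULL) {
  signed_network(x, labels = labels)
}

#' @export
print.signed_network <- function(x, ...) {
  e <- network_edges(x)
  cat(sprintf(
    "<signed_network> %d drugs, %d interactions (%d enhancive, %d degressive)\n",
    length(x$labels), nrow(e), sum(e$sign > 0), sum(e$sign < 0)
  ))
  invisible(x)
}

#' Edge table of a signed network
#'
#' @param net A [signed_network()].
#' @return A tibble with columns `drug_a`, `drug_b`, `sign`, one row per
#'   unordered interacting pair, ordered by node position.
#' @export
network_edges <- function(net) {
  net <- as_signed_network(net)
  A <- net$adjacency
  idx <- which(upper.tri(A) & A != 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble(
    drug_a = net$labels[idx[, 1]],
    drug_b = net$labels[idx[, 2]],
    sign = as.integer(A[idx])
  )
}

#' Split a signed adjacency into its positive and negative parts
#'
#' Returns the nonnegative matrices \eqn{A^+ = (|A| + A)/2} and
#' \eqn{A^- = (|A| - A)/2}, so that `plus - minus` reconstructs the signed
#' adjacency and `plus * minus == 0` elementwise.
#'
#' @param net A [signed_network()].
#' @return A list with elements `plus` and `minus`.
#' @export
split_signs <- function(net) {
  net <- as_signed_network(net)
  A <- net$adjacency
  list(plus = (abs(A) + A) / 2, minus = (abs(A) - A) / 2)
}

#' Signed Laplacian of the positive part
#'
#' Computes \eqn{L^+ = D^+ - A^+}, where \eqn{D^+} is the diagonal degree
#' matrix of the positive part \eqn{A^+}. \eqn{L^+} is symmetric positive
#' semidefinite with zero row sums; it penalizes cutting positive (enhancive)
#' edges when used as a community regularizer.
#'
#' @param net A [signed_network()].
#' @return An m x m numeric matrix.
#' @export
signed_laplacian_plus <- function(net) {
  Ap <- split_signs(net)$plus
  diag(rowSums(Ap)) - Ap
}

#' Shuffle edge signs uniformly at random
#'
#' Keeps the support graph (which pairs interact) fixed and assigns a uniform
#' random permutation of the observed sign multiset to the edges. This is the
#' null model used to ask whether the observed triad composition could arise
#' from sign-blind wiring: the counts of enhancive and degressive edges are
#' preserved exactly, only their placement is randomized.
#'
#' @param net A [signed_network()].
#' @param seed Integer seed; the shuffle is reproducible given the seed.
#' @return A new `signed_network` on the same support.
#' @export
shuffle_signs <- function(net, seed) {
  net <- as_signed_network(net)
  A <- net$adjacency
  idx <- which(upper.tri(A) & A != 0L)
  perm <- withr::with_seed(seed, sample(A[idx]))
  B <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  B[idx] <- perm
  B <- B + t(B)
  structure(list(labels = net$labels, adjacency = B), class = "signed_network")
}
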