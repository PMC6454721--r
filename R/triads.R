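#' Triad census of a signed network
#'
#' Counts every unordered triple of nodes whose three pairwise edges are all
#' present, classified by the multiset of edge signs: `PPP` (all enhancive),
#' `NNP` (two degressive, one enhancive; identical to PNN), `NNN` (all
#' degressive) and `PPN` (one degressive). Under weak structural balance the
#' first three are balanced and only `PPN` is frustrated.
#'
#' @param net A [signed_network()] (or anything coercible).
#' @return A `triad_census` tibble with columns `triad`, `n_negative`,
#'   `count`, `fraction`, ordered PPP, NNP, NNN, PPN. The fraction column is
#'   `NaN`-free: with zero triangles all fractions are 0.
#' @examples
#' triad_census(fig1_toy())
#' @export
triad_census <- function(net) {
  net <- as_signed_network(net)
  nneg <- triangle_negative_counts(net$adjacency)
  counts <- tabulate(nneg + 1L, nbins = 4L) # index = #negative edges + 1
  new_triad_census(counts)
}

# counts of negative edges per triangle, one entry per triangle
triangle_negative_counts <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(abs(A) != 0, mode = "undirected",
                                           diag = FALSE)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
  if (ncol(tri) == 0) {
    return(integer(0))
  }
  s1 <- A[cbind(tri[1, ], tri[2, ])]
  s2 <- A[cbind(tri[1, ], tri[3, ])]
  s3 <- A[cbind(tri[2, ], tri[3, ])]
  as.integer((s1 < 0) + (s2 < 0) + (s3 < 0))
}

# counts indexed by number of negative edges (0..3)
new_triad_census <- function(counts) {
  total <- sum(counts)
  out <- tibble(
    triad = c("PPP", "NNP", "NNN", "PPN"),
    n_negative = c(0L, 2L, 3L, 1L),
    count = as.integer(counts[c(1L, 3L, 4L, 2L)]),
    fraction = if (total > 0) counts[c(1L, 3L, 4L, 2L)] / total else rep(0, 4)
  )
  class(out) <- c("triad_census", class(out))
  attr(out, "total_triads") <- as.integer(total)
  out
}

#' Total number of triads in a census
#'
#' @param census A [triad_census()] result.
#' @return Integer triangle count of the unsigned support graph.
#' @export
total_triads <- function(census) {
  attr(census, "total_triads")
}

#' Expected triad-sign composition under uniform sign shuffling
#'
#' Closed-form null distribution of triad sign patterns when the observed
#' numbers of enhancive (`n_pos`) and degressive (`n_neg`) edges are
#' reassigned to the support graph uniformly at random. The three edges of a
#' triangle are then three draws without replacement from the sign multiset,
#' so the probability of seeing `j` degressive edges is hypergeometric:
#' \deqn{P(j) = \binom{E^-}{j}\binom{E^+}{3-j} / \binom{E}{3}.}
#' The expectation is exact for every triangle regardless of how triangles
#' share edges, hence also for the mean fraction over the network.
#'
#' @param n_pos,n_neg Numbers of enhancive and degressive edges (may be large;
#'   computed on the log scale).
#' @return A tibble with columns `triad`, `n_negative`, `expected_fraction`.
#' @examples
#' triad_shuffle_expectation(125298, 55278)
#' @export
triad_shuffle_expectation <- function(n_pos, n_neg) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_pos + n_neg >= 3)
  e <- n_pos + n_neg
  pj <- function(j) exp(lchoose(n_neg, j) + lchoose(n_pos, 3 - j) - lchoose(e, 3))
  tibble(
    triad = c("PPP", "NNP", "NNN", "PPN"),
    n_negative = c(0L, 2L, 3L, 1L),
    expected_fraction = c(pj(0), pj(2), pj(3), pj(1))
  )
}

#' Monte-Carlo sign-shuffle null for the triad composition
#'
#' Estimates the expected triad-sign fractions of a signed network under the
#' uniform sign-shuffle null by repeatedly permuting the edge sign multiset
#' on the fixed support and re-classifying every triangle. Triangles are
#' enumerated once; each shuffle only permutes the per-edge sign vector, so
#' thousands of shuffles are cheap even on large supports.
#'
#' @param net A [signed_network()].
#' @param n_shuffles Number of random sign permutations.
#' @param seed Integer seed.
#' @return A tibble with columns `triad`, `n_negative`, `mean_fraction`,
#'   `mc_se` (standard error of the mean over shuffles), and
#'   `expected_fraction` (the closed form from
#'   [triad_shuffle_expectation()]), plus attributes `n_triangles` and
#'   `n_shuffles`.
#' @export
triad_sign_null <- function(net, n_shuffles = 2000, seed = 1) {
  net <- as_signed_network(net)
  A <- net$adjacency
  g <- igraph::graph_from_adjacency_matrix(abs(A) != 0, mode = "undirected",
                                           diag = FALSE)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
  n_tri <- ncol(tri)
  if (n_tri == 0) {
    stop_invalid("Network has no triangles; the triad null is undefined.")
  }
  # per-edge signs in igraph's edge order, and each triangle's three edge ids
  el <- igraph::as_edgelist(g, names = FALSE)
  signs <- A[el]
  e1 <- igraph::get_edge_ids(g, as.vector(tri[c(1, 2), ]))
  e2 <- igraph::get_edge_ids(g, as.vector(tri[c(1, 3), ]))
  e3 <- igraph::get_edge_ids(g, as.vector(tri[c(2, 3), ]))
  fracs <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- sample(signs)
      neg <- s < 0
      nneg <- neg[e1] + neg[e2] + neg[e3]
      tabulate(nneg + 1L, nbins = 4L) / n_tri
    }, numeric(4))
  })
  means <- rowMeans(fracs)
  ses <- apply(fracs, 1, stats::sd) / sqrt(n_shuffles)
  ord <- c(1L, 3L, 4L, 2L) # 0,2,3,1 negatives -> PPP, NNP, NNN, PPN
  out <- tibble(
    triad = c("PPP", "NNP", "NNN", "PPN"),
    n_negative = c(0L, 2L, 3L, 1L),
    mean_fraction = means[ord],
    mc_se = ses[ord],
    expected_fraction = triad_shuffle_expectation(
      sum(signs > 0), sum(signs < 0)
    )$expected_fraction
  )
  attr(out, "n_triangles") <- n_tri
  attr(out, "n_shuffles") <- n_shuffles
  out
}

#' Random triangle-rich support network with prescribed sign counts
#'
#' Draws an Erdos-Renyi G(n, M) support with `n_pos + n_neg` edges and
#' assigns a random permutation of the sign multiset to them. Useful for
#' sign-shuffle null experiments that only fix the edge sign counts, e.g.
#' emulating a network whose enhancive/degressive totals are known but whose
#' wiring is not.
#'
#' @param n_pos,n_neg Numbers of enhancive and degressive edges.
#' @param n_nodes Number of nodes; must satisfy
#'   `choose(n_nodes, 2) >= n_pos + n_neg`.
#' @param seed Integer seed.
#' @return A [signed_network()].
#' @export
random_support_network <- function(n_pos, n_neg, n_nodes, seed = 1) {
  e <- n_pos + n_neg
  if (choose(n_nodes, 2) < e) {
    stop_invalid("Too few nodes to place the requested number of edges.")
  }
  withr::with_seed(seed, {
    g <- igraph::sample_gnm(n_nodes, e)
    el <- igraph::as_edgelist(g, names = FALSE)
    s <- sample(c(rep(1L, n_pos), rep(-1L, n_neg)))
    A <- matrix(0L, n_nodes, n_nodes)
    A[el] <- s
    A[el[, c(2, 1)]] <- s
    signed_network(A, labels = paste0("v", seq_len(n_nodes)))
  })
}

#' @export
print.triad_census <- function(x, ...) {
  cat(sprintf("<triad_census> %d triads\n", total_triads(x)))
  NextMethod()
}

#' @rdname triad_census
#' @param object A `triad_census`.
#' @param ... Unused.
#' @export
autoplot.triad_census <- function(object, ...) {
  df <- as_tibble(object)
  df$triad <- factor(df$triad, levels = c("PPP", "NNP", "NNN", "PPN"))
  df$balance <- ifelse(df$triad == "PPN", "unbalanced", "balanced")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$triad, y = .data$fraction,
                                   fill = .data$balance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "triad sign pattern", y = "fraction of triads",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
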