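#' Planted-partition generator for signed networks
#'
#' Samples a signed network with a known community structure following the
#' generalized weak-balance model: within-community pairs carry an edge with
#' probability `within_edge_prob` and the community's sign (`+1` for a
#' strongly balanced block, `-1` for a weakly balanced one);
#' between-community pairs carry an edge with probability
#' `between_edge_prob`, degressive except for a `between_positive_rate`
#' fraction. Finally a `flip_rate` fraction of all edge signs is flipped
#' uniformly at random (noise).
#'
#' The defaults (three communities of 40, dense positive blocks, sparser
#' negative background, 5% stray positives and 5% flips) produce networks
#' with roughly 69% enhancive edges, matching the sign imbalance typical of
#' curated DDI extracts.
#'
#' @param community_sizes Integer vector of community sizes.
#' @param within_edge_prob,between_edge_prob Edge probabilities in `[0, 1]`.
#' @param within_sign `+1` or `-1` per community (recycled).
#' @param between_positive_rate Fraction of between-community edges that are
#'   enhancive (balance violations).
#' @param flip_rate Fraction of edge signs flipped at random.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A list with `network` (a [signed_network()]) and `partition`
#'   (tibble with `drug`, `community`).
#' @examples
#' sim <- planted_signed_network(seed = 1)
#' cbi(sim$network, sim$partition)
#' @export
planted_signed_network <- function(community_sizes = c(40, 40, 40),
                                   within_edge_prob = 0.9,
                                   between_edge_prob = 0.2,
                                   within_sign = 1,
                                   between_positive_rate = 0.05,
                                   flip_rate = 0.05,
                                   seed = 1) {
  stopifnot(all(community_sizes >= 1),
            within_edge_prob >= 0, within_edge_prob <= 1,
            between_edge_prob >= 0, between_edge_prob <= 1,
            between_positive_rate >= 0, between_positive_rate <= 1,
            flip_rate >= 0, flip_rate <= 1)
  k <- length(community_sizes)
  within_sign <- rep_len(within_sign, k)
  if (!all(within_sign %in% c(-1, 1))) {
    stop_invalid("`within_sign` entries must be +1 or -1.")
  }
  m <- sum(community_sizes)
  z <- rep(seq_len(k), community_sizes)
  labels <- sprintf("d%03d", seq_len(m))
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  zi <- z[ut[, 1]]
  zj <- z[ut[, 2]]
  within <- zi == zj
  A <- withr::with_seed(seed, {
    prob <- ifelse(within, within_edge_prob, between_edge_prob)
    present <- runif(nrow(ut)) < prob
    sgn <- ifelse(within, within_sign[zi],
                  ifelse(runif(nrow(ut)) < between_positive_rate, 1, -1))
    sgn <- ifelse(runif(nrow(ut)) < flip_rate, -sgn, sgn)
    s <- ifelse(present, sgn, 0)
    A <- matrix(0L, m, m, dimnames = list(labels, labels))
    A[ut] <- as.integer(s)
    A[ut[, c(2, 1)]] <- as.integer(s)
    A
  })
  list(
    network = new_signed_network_from_matrix(A, labels),
    partition = tibble(drug = labels, community = z)
  )
}

#' Community-linked binary features
#'
#' Emulates drug-binding-protein profiles that carry community signal: each
#' community owns a disjoint block of `floor(p / k)` marker features; a
#' drug's marker features are 1 with probability `signal`, every other
#' feature with probability `noise`. With `signal == noise` the features are
#' community-blind.
#'
#' @param partition A partition tibble (`drug`, `community`) such as the one
#'   returned by [planted_signed_network()].
#' @param p Number of features; must be at least the number of communities.
#' @param signal,noise Bernoulli rates for marker and non-marker features.
#' @param seed Integer seed.
#' @return A feature tibble: first column `drug`, then `p` binary columns
#'   named `P001`, `P002`, ...
#' @export
community_linked_features <- function(partition, p = 60, signal = 0.9,
                                      noise = 0.1, seed = 1) {
  stopifnot(signal >= 0, signal <= 1, noise >= 0, noise <= 1)
  drugs <- as.character(partition$drug)
  z <- as.integer(partition$community)
  k <- length(unique(z))
  if (p < k) stop_invalid("`p` must be at least the number of communities.")
  m <- length(drugs)
  block <- p %/% k
  us <- sort(unique(z))
  F_ <- withr::with_seed(seed, {
    M <- matrix(as.integer(runif(m * p) < noise), m, p)
    for (c in seq_along(us)) {
      rows <- which(z == us[c])
      cols <- ((c - 1) * block + 1):(c * block)
      M[rows, cols] <- matrix(as.integer(runif(length(rows) * block) < signal),
                              length(rows), block)
    }
    M
  })
  colnames(F_) <- sprintf("P%03d", seq_len(p))
  dplyr::bind_cols(tibble(drug = drugs), as_tibble(F_))
}

#' Reference cold-start benchmark
#'
#' A fixed synthetic study condition used throughout the package's tests and
#' documentation: 120 drugs in three planted communities of 40 (two strongly
#' balanced, one weakly balanced), within-community edge probability 0.9,
#' between 0.15, 5% stray positive between-edges, 5% sign flips, and 60
#' community-linked binary features at signal 0.9 / noise 0.1.
#'
#' @param seed Integer seed.
#' @param signal,noise Feature rates, overridable for ablation experiments.
#' @return A list with `network`, `partition`, and `features`.
#' @export
coldstart_benchmark <- function(seed = 1, signal = 0.9, noise = 0.1) {
  sim <- planted_signed_network(
    community_sizes = c(40, 40, 40),
    within_edge_prob = 0.9, between_edge_prob = 0.15,
    within_sign = c(1, 1, -1),
    between_positive_rate = 0.05, flip_rate = 0.05,
    seed = seed
  )
  features <- community_linked_features(sim$partition, p = 60,
                                        signal = signal, noise = noise,
                                        seed = seed + 1000L)
  list(network = sim$network, partition = sim$partition, features = features)
}

#' Hand-built illustrative signed network
#'
#' A small synthetic network with four planted communities — two strongly
#' balanced positive cliques, one weakly balanced all-negative clique, and a
#' positive triangle — knitted together by degressive edges, plus exactly one
#' unbalanced PPN triad. It is this package's own construction for
#' documentation and smoke tests (shipped as a text fixture in
#' `inst/extdata/fig1_toy_edges.csv`), not a reproduction of any published
#' drawing.
#'
#' @return A [signed_network()] with the planted partition attached as
#'   attribute `"partition"`.
#' @examples
#' toy <- fig1_toy()
#' triad_census(toy)
#' @export
fig1_toy <- function() {
  edges <- fig1_toy_edges()
  net <- signed_network(edges, labels = sprintf("d%02d", 1:15))
  attr(net, "partition") <- tibble(
    drug = sprintf("d%02d", 1:15),
    community = rep(1:4, c(4, 4, 4, 3))
  )
  net
}

fig1_toy_edges <- function() {
  clique <- function(ids, sgn) {
    cmb <- utils::combn(ids, 2)
    tibble(drug_a = cmb[1, ], drug_b = cmb[2, ], sign = sgn)
  }
  d <- function(i) sprintf("d%02d", i)
  dplyr::bind_rows(
    clique(d(1:4), 1L),    # strongly balanced community 1
    clique(d(5:8), 1L),    # strongly balanced community 2
    clique(d(9:12), -1L),  # weakly balanced community 3
    clique(d(13:15), 1L),  # strongly balanced community 4
    tibble(
      # degressive edges knit the communities together; the weak block
      # (d09-d12) shares a coherent pattern of partners (d04 and d13); the
      # single positive bridge d03-d05 closes the lone PPN triad through d01
      drug_a = d(c(1, 2, 3, 7, 8, 9, 10, 11, 12, 9, 10, 11, 12)),
      drug_b = d(c(5, 6, 5, 13, 13, 4, 4, 4, 4, 13, 13, 13, 13)),
      sign = c(-1L, -1L, 1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L)
    )
  )
}
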